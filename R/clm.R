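#' Sibling logit model for one dataset
#'
#' Resolves the full candidate panel onto the dataset's platform (the
#' dataset's own identifiers resolve to themselves), extracts the resolved
#' probes' intensity rows as predictors, and fits the per-dataset logit
#' model ("sibling-like LM", sk-LM).
#'
#' @param dataset Expression dataset (\code{\link{expression_dataset}}).
#' @param EI Identifier table: the candidate panel.
#' @param M Similarity matrix.
#' @param platforms Named platform list containing the dataset's platform.
#' @return A list of class \code{ab_sklm}: \code{dataset_id},
#'   \code{resolved} (see \code{\link{resolve_panel}}), \code{fit}
#'   (\code{\link{fit_lm}}).
#' @export
build_sk_lm <- function(dataset, EI, M, platforms) {
  stopifnot(inherits(dataset, "ab_dataset"))
  pf <- .get_platform(platforms, dataset$platform_id)
  resolved <- resolve_panel(EI, pf, M)
  X <- t(dataset$intensities[match(resolved$probe_id,
                                   rownames(dataset$intensities)),
                             , drop = FALSE])
  if (length(unique(dataset$labels)) < 2L)
    stop("dataset '", dataset$dataset_id,
         "' has samples of only one class")
  fit <- fit_lm(X, dataset$labels)
  structure(list(dataset_id = dataset$dataset_id, resolved = resolved,
                 fit = fit),
            class = "ab_sklm")
}

#' Identify a common logit model for a candidate panel
#'
#' The common logit model (c-LM) of a panel is the collection of its
#' per-dataset sibling fits, scored by the arithmetic mean of their
#' log-likelihood values.  Every dataset sees the same panel, resolved to
#' its own platform through the similarity bridge, but fits its own
#' coefficients -- which is why no cross-platform intensity normalization
#' is required.
#'
#' @param datasets List of expression datasets (>= 1).
#' @param M Similarity matrix.
#' @param EI Identifier table; gene labels must be pairwise distinct.
#' @param platforms Named platform list.
#' @return An object of class \code{ab_clm}: \code{EI}, \code{sk_lms}
#'   (named by dataset), \code{llv} (mean sibling LLV).
#' @export
identify_clm <- function(datasets, M, EI, platforms) {
  if (length(datasets) < 1L) stop("at least one dataset required")
  if (anyDuplicated(EI$gene_id))
    stop("panel gene labels must be pairwise distinct: ",
         paste(unique(EI$gene_id[duplicated(EI$gene_id)]), collapse = ", "))
  sk <- lapply(datasets, build_sk_lm, EI = EI, M = M,
               platforms = platforms)
  names(sk) <- vapply(sk, `[[`, character(1L), "dataset_id")
  structure(
    list(EI = EI, sk_lms = sk,
         llv = mean(vapply(sk, function(s) s$fit$llv, numeric(1L)))),
    class = "ab_clm")
}

#' @export
print.ab_clm <- function(x, ...) {
  cat("<c-LM> panel {", paste(format_identifiers(x$EI), collapse = ", "),
      "}\n  mean LLV = ", format(x$llv, digits = 6), " over ",
      length(x$sk_lms), " dataset(s)\n", sep = "")
  invisible(x)
}

# mean absolute standardized coefficient per panel locus across the
# sibling fits -- the GA's "how associated is this locus" signal
.locus_beta_means <- function(clm) {
  mags <- vapply(clm$sk_lms,
                 function(s) abs(s$fit$betas_std),
                 numeric(nrow(clm$EI)))
  if (is.null(dim(mags))) mags <- matrix(mags, nrow = nrow(clm$EI))
  rowMeans(mags)
}
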