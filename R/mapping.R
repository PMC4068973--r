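#' Resolve an identifier onto a target platform
#'
#' Places one panel element onto the platform a dataset was measured on.
#' If the target platform carries the identifier's gene, the same-gene
#' probe most similar to the source probe is used (\code{mode =
#' "same-gene"}; resolving onto the identifier's own platform returns the
#' probe itself with similarity 1).  Otherwise the gene is private to the
#' source platform and the target-platform probe with the highest sequence
#' similarity to the source probe stands in as a substitute (\code{mode =
#' "substitute"}).  Ties are broken toward the smallest canonical probe
#' index for reproducibility.
#'
#' @param id One-row identifier table (\code{\link{identifiers}}).
#' @param target_platform Platform to resolve onto.
#' @param M Similarity matrix indexing both the source probe and the
#'   target platform's probes.
#' @return One-row data frame with columns \code{source_platform},
#'   \code{source_probe}, \code{source_gene}, \code{platform_id},
#'   \code{probe_id}, \code{gene_id} (the target identifier), \code{mode},
#'   \code{similarity}.
#' @export
resolve_identifier <- function(id, target_platform, M) {
  stopifnot(inherits(target_platform, "ab_platform"),
            inherits(M, "ab_similarity"))
  if (nrow(target_platform$probes) < 1L)
    stop("target platform has no probes")
  src <- .sim_index(M, id$platform_id[1L], id$probe_id[1L])
  probes <- target_platform$probes
  tgt_idx <- .sim_index(M, rep(target_platform$platform_id, nrow(probes)),
                        probes$probe_id)
  same <- which(probes$gene_id == id$gene_id[1L])
  cand <- if (length(same)) same else seq_len(nrow(probes))
  sims <- M$values[src, tgt_idx[cand]]
  pick <- cand[which.max(sims)]  # which.max: first (smallest index) on ties
  data.frame(source_platform = id$platform_id[1L],
             source_probe = id$probe_id[1L],
             source_gene = id$gene_id[1L],
             platform_id = target_platform$platform_id,
             probe_id = probes$probe_id[pick],
             gene_id = probes$gene_id[pick],
             mode = if (length(same)) "same-gene" else "substitute",
             similarity = max(sims),
             stringsAsFactors = FALSE)
}

#' Resolve a whole panel onto a target platform
#'
#' Element-wise \code{\link{resolve_identifier}} preserving panel order.
#' Two panel genes may legitimately resolve to one and the same target
#' probe (through substitution); such duplicates are kept but flagged in
#' the \code{dup} column, and the downstream logit fit handles the
#' resulting rank-deficient design.
#'
#' @param EI Identifier table (ordered candidate panel).
#' @inheritParams resolve_identifier
#' @return Data frame as in \code{\link{resolve_identifier}}, one row per
#'   panel element, plus a logical column \code{dup}.
#' @export
resolve_panel <- function(EI, target_platform, M) {
  if (is.null(EI) || nrow(EI) < 1L) stop("panel must be non-empty")
  res <- do.call(rbind, lapply(seq_len(nrow(EI)), function(i)
    resolve_identifier(EI[i, , drop = FALSE], target_platform, M)))
  res$dup <- duplicated(res$probe_id) | duplicated(res$probe_id,
                                                   fromLast = TRUE)
  rownames(res) <- NULL
  res
}
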