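#' Construct a microarray platform
#'
#' A platform is an ordered set of probes, each carrying a gene label and a
#' nucleotide sequence.  The probe order given at construction is the
#' canonical index order used by every downstream structure (similarity
#' matrix columns, expression matrix rows, tie-breaking in identifier
#' resolution).
#'
#' @param platform_id Single non-empty string naming the platform.
#' @param probe_id Character vector of probe identifiers, unique within the
#'   platform.
#' @param gene_id Character vector of gene labels, one per probe.  Several
#'   probes may share a gene.
#' @param sequence Character vector of nucleotide sequences over
#'   \code{A,C,G,T,N} (lower case accepted, stored upper case), one per
#'   probe, each of length >= 1.
#'
#' @return An object of class \code{ab_platform}: a list with elements
#'   \code{platform_id} and \code{probes} (a data frame with columns
#'   \code{probe_id}, \code{gene_id}, \code{sequence}).
#' @export
platform <- function(platform_id, probe_id, gene_id, sequence) {
  stopifnot(is.character(platform_id), length(platform_id) == 1L,
            nzchar(platform_id))
  probe_id <- as.character(probe_id)
  gene_id <- as.character(gene_id)
  sequence <- toupper(as.character(sequence))
  if (length(probe_id) < 1L)
    stop("platform '", platform_id, "' must contain at least one probe")
  if (length(gene_id) != length(probe_id) ||
      length(sequence) != length(probe_id))
    stop("probe_id, gene_id and sequence must have equal length")
  if (anyDuplicated(probe_id))
    stop("duplicate probe_id on platform '", platform_id, "': ",
         paste(unique(probe_id[duplicated(probe_id)]), collapse = ", "))
  if (any(!nzchar(probe_id)) || any(!nzchar(gene_id)))
    stop("probe_id and gene_id entries must be non-empty")
  if (any(nchar(sequence) < 1L))
    stop("every probe sequence must have length >= 1")
  bad <- grepl("[^ACGTN]", sequence)
  if (any(bad))
    stop("sequence of probe '", probe_id[which(bad)[1L]],
         "' contains characters outside A,C,G,T,N")
  structure(
    list(platform_id = platform_id,
         probes = data.frame(probe_id = probe_id, gene_id = gene_id,
                             sequence = sequence,
                             stringsAsFactors = FALSE)),
    class = "ab_platform")
}

#' @export
print.ab_platform <- function(x, ...) {
  cat("<platform ", x$platform_id, "> ", nrow(x$probes), " probes, ",
      length(unique(x$probes$gene_id)), " genes\n", sep = "")
  invisible(x)
}

#' Assemble a named platform collection
#'
#' @param ... \code{ab_platform} objects.
#' @return A list of platforms named by their \code{platform_id}.
#' @export
platform_list <- function(...) {
  pls <- list(...)
  if (length(pls) == 1L && is.list(pls[[1L]]) &&
      !inherits(pls[[1L]], "ab_platform"))
    pls <- pls[[1L]]
  ok <- vapply(pls, inherits, logical(1L), what = "ab_platform")
  if (!all(ok)) stop("all arguments must be platforms")
  ids <- vapply(pls, `[[`, character(1L), "platform_id")
  if (anyDuplicated(ids)) stop("duplicate platform_id: ",
                               paste(ids[duplicated(ids)], collapse = ", "))
  names(pls) <- ids
  pls
}

#' Construct a labelled expression dataset
#'
#' Houses a probe-by-sample intensity matrix with binary tumor/normal
#' labels.  Rows must follow the platform's canonical probe order; the
#' constructor enforces this through row names.
#'
#' @param dataset_id Single string naming the dataset.
#' @param platform Platform the probes belong to (\code{\link{platform}}).
#' @param intensities Numeric matrix, rows = probes of \code{platform} (in
#'   canonical order, row names = probe ids), columns = samples.
#' @param labels Binary vector (1 = tumor, 0 = normal), one per sample.
#' @param sample_ids Optional character vector of sample names; defaults to
#'   the matrix column names.
#'
#' @return An object of class \code{ab_dataset}.
#' @export
expression_dataset <- function(dataset_id, platform, intensities, labels,
                               sample_ids = colnames(intensities)) {
  stopifnot(inherits(platform, "ab_platform"), is.matrix(intensities))
  labels <- as.integer(labels)
  if (is.null(sample_ids))
    sample_ids <- paste0("S", seq_len(ncol(intensities)))
  if (nrow(intensities) != nrow(platform$probes))
    stop("dataset '", dataset_id, "': intensity rows (", nrow(intensities),
         ") != platform probe count (", nrow(platform$probes), ")")
  if (!is.null(rownames(intensities)) &&
      !identical(rownames(intensities), platform$probes$probe_id))
    stop("dataset '", dataset_id,
         "': intensity row names do not follow the platform probe order")
  if (length(labels) != ncol(intensities))
    stop("dataset '", dataset_id, "': one label per sample required")
  if (length(sample_ids) != ncol(intensities))
    stop("dataset '", dataset_id, "': one sample_id per column required")
  if (!all(labels %in% c(0L, 1L)))
    stop("dataset '", dataset_id, "': labels must be 0 (normal) or 1 (tumor)")
  if (any(!is.finite(intensities)))
    stop("dataset '", dataset_id, "': non-finite intensities")
  rownames(intensities) <- platform$probes$probe_id
  colnames(intensities) <- sample_ids
  structure(
    list(dataset_id = as.character(dataset_id),
         platform_id = platform$platform_id,
         sample_ids = as.character(sample_ids),
         labels = labels,
         intensities = intensities),
    class = "ab_dataset")
}

#' @export
print.ab_dataset <- function(x, ...) {
  cat("<dataset ", x$dataset_id, "> on ", x$platform_id, ": ",
      nrow(x$intensities), " probes x ", length(x$sample_ids), " samples (",
      sum(x$labels == 1L), " tumor / ", sum(x$labels == 0L), " normal)\n",
      sep = "")
  invisible(x)
}

#' Build an identifier table
#'
#' An identifier is a (platform, probe, gene) triple; a panel (candidate
#' set of associated biomarkers) is an ordered table of identifiers.
#'
#' @param platform_id,probe_id,gene_id Character vectors of equal length.
#' @return A data frame with columns \code{platform_id}, \code{probe_id},
#'   \code{gene_id}, one row per identifier.
#' @export
identifiers <- function(platform_id, probe_id, gene_id) {
  data.frame(platform_id = as.character(platform_id),
             probe_id = as.character(probe_id),
             gene_id = as.character(gene_id),
             stringsAsFactors = FALSE)
}

#' Format identifiers as platform-probe-gene strings
#'
#' @param ids Identifier table (\code{\link{identifiers}}).
#' @param sep Separator between the three components.
#' @return Character vector.
#' @export
format_identifiers <- function(ids, sep = "-") {
  paste(ids$platform_id, ids$probe_id, ids$gene_id, sep = sep)
}

# Collect the identifier universe (IDF) spanned by a platform collection.
#' Identifier universe of a platform collection
#'
#' @param platforms Named list of platforms (\code{\link{platform_list}}).
#' @return Identifier table with one row per probe across all platforms,
#'   in canonical order.
#' @export
identifier_universe <- function(platforms) {
  do.call(rbind, lapply(platforms, function(pf)
    identifiers(pf$platform_id, pf$probes$probe_id, pf$probes$gene_id)))
}

# internal: look up a platform, with a clear error
.get_platform <- function(platforms, platform_id) {
  pf <- platforms[[platform_id]]
  if (is.null(pf)) stop("unknown platform '", platform_id, "'")
  pf
}
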