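#' Read a platform from probe FASTA plus annotation table
#'
#' FASTA record IDs are probe ids; the annotation TSV must have columns
#' \code{probe_id} and \code{gene_id} and one row per FASTA record.
#' Probes are ordered by the annotation file (the canonical order);
#' sequences are stored upper case.
#'
#' @param fasta_path Path to the probe-sequence FASTA.
#' @param annotation_path Path to the probe-to-gene TSV.
#' @param platform_id Platform name; defaults to the FASTA base name.
#' @return An \code{\link{platform}} object.
#' @export
read_platform <- function(fasta_path, annotation_path,
                          platform_id = sub("\\.[^.]*$", "",
                                            basename(fasta_path))) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  ann <- utils::read.delim(annotation_path, header = TRUE,
                           colClasses = "character")
  if (!all(c("probe_id", "gene_id") %in% names(ann)))
    stop("annotation file must have columns probe_id and gene_id")
  if (nrow(ann) == 0L) stop("annotation file is empty")
  ids <- sub("\\s.*$", "", names(seqs))
  if (anyDuplicated(ids))
    stop("duplicate probe_id in FASTA: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  miss <- setdiff(ids, ann$probe_id)
  if (length(miss))
    stop("FASTA record without annotation: ",
         paste(miss, collapse = ", "))
  miss <- setdiff(ann$probe_id, ids)
  if (length(miss))
    stop("annotated probe without FASTA record: ",
         paste(miss, collapse = ", "))
  sequence <- toupper(as.character(seqs))[match(ann$probe_id, ids)]
  platform(platform_id, ann$probe_id, ann$gene_id, sequence)
}

#' Write a platform as FASTA plus annotation TSV
#'
#' @param pf Platform object.
#' @param fasta_path,annotation_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_platform <- function(pf, fasta_path, annotation_path) {
  stopifnot(inherits(pf, "ab_platform"))
  dna <- Biostrings::DNAStringSet(pf$probes$sequence)
  names(dna) <- pf$probes$probe_id
  Biostrings::writeXStringSet(dna, fasta_path, width = 70L)
  utils::write.table(pf$probes[, c("probe_id", "gene_id")],
                     annotation_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta_path, annotation_path))
}

#' Read a labelled expression dataset
#'
#' The expression TSV has sample ids in the header, probe ids in the first
#' column and one intensity row per probe.  The labels TSV maps
#' \code{sample_id} to \code{class} (\code{tumor} or \code{normal}).  Rows
#' are re-ordered to the platform's canonical probe order; every platform
#' probe must be present (no imputation) and every probe row must belong
#' to the platform.
#'
#' @param tsv_path Path to the expression matrix TSV.
#' @param labels_path Path to the two-column labels TSV.
#' @param platform Platform the probes belong to.
#' @param dataset_id Dataset name; defaults to the TSV base name.
#' @return An \code{\link{expression_dataset}}.
#' @export
read_expression <- function(tsv_path, labels_path, platform,
                            dataset_id = sub("\\.[^.]*$", "",
                                             basename(tsv_path))) {
  stopifnot(inherits(platform, "ab_platform"))
  tab <- utils::read.delim(tsv_path, header = TRUE, check.names = FALSE,
                           colClasses = "character")
  probe_ids <- tab[[1L]]
  sample_ids <- names(tab)[-1L]
  raw <- as.matrix(tab[, -1L, drop = FALSE])
  vals <- suppressWarnings(array(as.numeric(raw), dim = dim(raw)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals), arr.ind = TRUE)[1L, ]
    stop("non-numeric intensity at probe row '", probe_ids[bad[1L]],
         "', sample '", sample_ids[bad[2L]], "'")
  }
  miss <- setdiff(platform$probes$probe_id, probe_ids)
  if (length(miss))
    stop("platform probe(s) absent from expression file: ",
         paste(miss, collapse = ", "))
  unknown <- setdiff(probe_ids, platform$probes$probe_id)
  if (length(unknown))
    stop("expression row(s) not on platform '", platform$platform_id,
         "': ", paste(unknown, collapse = ", "))
  if (anyDuplicated(probe_ids))
    stop("duplicated probe row(s): ",
         paste(unique(probe_ids[duplicated(probe_ids)]), collapse = ", "))
  vals <- vals[match(platform$probes$probe_id, probe_ids), ,
               drop = FALSE]
  lab <- utils::read.delim(labels_path, header = TRUE,
                           colClasses = "character")
  if (!all(c("sample_id", "class") %in% names(lab)))
    stop("labels file must have columns sample_id and class")
  unknown <- setdiff(lab$sample_id, sample_ids)
  if (length(unknown))
    stop("label for unknown sample: ", paste(unknown, collapse = ", "))
  miss <- setdiff(sample_ids, lab$sample_id)
  if (length(miss))
    stop("sample without label: ", paste(miss, collapse = ", "))
  cls <- lab$class[match(sample_ids, lab$sample_id)]
  if (!all(cls %in% c("tumor", "normal")))
    stop("labels must be 'tumor' or 'normal'")
  rownames(vals) <- platform$probes$probe_id
  colnames(vals) <- sample_ids
  expression_dataset(dataset_id, platform, vals,
                     as.integer(cls == "tumor"))
}

#' Write an expression dataset as TSV plus labels TSV
#'
#' @param dataset Expression dataset.
#' @param tsv_path,labels_path Output paths.
#' @return Invisibly, the two paths.
#' @export
write_expression <- function(dataset, tsv_path, labels_path) {
  stopifnot(inherits(dataset, "ab_dataset"))
  tab <- data.frame(probe_id = rownames(dataset$intensities),
                    dataset$intensities, check.names = FALSE,
                    stringsAsFactors = FALSE)
  utils::write.table(tab, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(
    data.frame(sample_id = dataset$sample_ids,
               class = ifelse(dataset$labels == 1L, "tumor", "normal")),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(tsv_path, labels_path))
}

#' Write / read the probe similarity matrix
#'
#' On disk the matrix is a full square TSV with a two-row composite header
#' (platform ids, then probe ids) and the same two identifier columns on
#' the left, preceded by a \code{#model=} comment line.  Values are
#' written to six decimals; both triangles are stored, the upper triangle
#' is authoritative on read and symmetry is validated to 1e-6.
#'
#' @param M \code{ab_similarity} object.
#' @param path Output (or input) path.
#' @return \code{write_similarity_matrix}: the path, invisibly.
#'   \code{read_similarity_matrix}: an \code{ab_similarity}.
#' @export
write_similarity_matrix <- function(M, path) {
  stopifnot(inherits(M, "ab_similarity"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#model=", M$model), con)
  writeLines(paste(c("platform_id", "probe_id", M$index$platform_id),
                   collapse = "\t"), con)
  writeLines(paste(c("", "", M$index$probe_id), collapse = "\t"), con)
  for (i in seq_len(nrow(M$index)))
    writeLines(paste(c(M$index$platform_id[i], M$index$probe_id[i],
                       sprintf("%.6f", M$values[i, ])),
                     collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_similarity_matrix
#' @export
read_similarity_matrix <- function(path) {
  lines <- readLines(path)
  model <- "JC69"
  is_comment <- startsWith(lines, "#")
  mline <- grep("^#model=", lines, value = TRUE)
  if (length(mline)) model <- sub("^#model=", "", mline[1L])
  lines <- lines[!is_comment]
  if (length(lines) < 3L) stop("malformed similarity matrix file")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  platform_hdr <- fields[[1L]][-(1:2)]
  probe_hdr <- fields[[2L]][-(1:2)]
  n <- length(platform_hdr)
  if (length(lines) != n + 2L)
    stop("similarity matrix is not square: ", n, " columns but ",
         length(lines) - 2L, " rows")
  rows <- fields[-(1:2)]
  row_pf <- vapply(rows, `[[`, character(1L), 1L)
  row_pr <- vapply(rows, `[[`, character(1L), 2L)
  if (!identical(row_pf, platform_hdr) || !identical(row_pr, probe_hdr))
    stop("row and column identifier headers disagree")
  vals <- t(vapply(rows, function(f) as.numeric(f[-(1:2)]), numeric(n)))
  if (anyNA(vals)) stop("non-numeric similarity value")
  if (any(vals < 0 | vals > 1))
    stop("similarity values outside [0, 1]")
  if (max(abs(vals - t(vals))) > 1e-6)
    stop("stored similarity matrix is asymmetric beyond tolerance 1e-6")
  up <- upper.tri(vals)
  sym <- vals
  sym[t(up)] <- t(vals)[t(up)]  # upper triangle authoritative
  similarity_matrix(data.frame(platform_id = platform_hdr,
                               probe_id = probe_hdr,
                               stringsAsFactors = FALSE),
                    sym, model = model)
}

#' Serialize a mined common logit model to JSON
#'
#' Records the panel identifiers, each dataset's resolved panel with its
#' fitted coefficients and LLV, the averaged LLV, and (optionally) the
#' search configuration and seed, so a mining run is fully auditable.
#'
#' @param clm \code{ab_clm} object.
#' @param path Output path.
#' @param config Optional \code{\link{ga_config}} echoed into the file.
#' @return The path, invisibly.
#' @export
write_clm <- function(clm, path, config = attr(clm, "config")) {
  stopifnot(inherits(clm, "ab_clm"))
  out <- list(
    panel = format_identifiers(clm$EI),
    identifiers = clm$EI,
    mean_llv = clm$llv,
    sk_lms = lapply(clm$sk_lms, function(s) list(
      dataset_id = s$dataset_id,
      resolved = format_identifiers(s$resolved),
      mode = s$resolved$mode,
      similarity = s$resolved$similarity,
      beta0 = s$fit$beta0,
      betas = s$fit$betas,
      llv = s$fit$llv,
      converged = s$fit$converged,
      separated = s$fit$separated)),
    elite_history = attr(clm, "history"),
    generations = attr(clm, "generations"))
  if (!is.null(config)) {
    out$config <- unclass(config)
    out$seed <- config$seed
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_clm
#' @export
read_clm <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
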