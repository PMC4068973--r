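#' Probe-sequence similarity: the cross-platform bridge
#'
#' Probes interrogating the same transcript on different array designs
#' hybridize to nearly the same nucleotide stretch, so their sequences are
#' close even when their probe/gene annotations differ.  Similarity between
#' two probe sequences is defined as one minus their pairwise
#' maximum-likelihood evolutionary distance: the two sequences are aligned
#' globally with free (unpenalized) end gaps -- a 60-mer spotted oligo must
#' be allowed to sit inside a 250-440 bp target sequence -- and the
#' branch length of the two-taxon maximum-likelihood tree under the
#' Jukes-Cantor substitution model is computed on the aligned columns.
#' That branch length has the closed form
#' \deqn{d = -\frac{3}{4}\log\left(1 - \frac{4}{3}p\right)}
#' with \eqn{p} the mismatch proportion over aligned non-gap columns.
#' Distances are clamped into [0, 1]; saturated pairs (\eqn{p \ge 3/4}) and
#' pairs with no aligned overlap get distance 1, hence similarity 0.
#'
#' @name similarity-model
NULL

# scoring scheme for the end-gap-free global alignment: match +1,
# mismatch -1, gap open -2, each further gap base -1.  N never matches.
.aln_letters <- c("A", "C", "G", "T", "N")
.aln_submat <- local({
  m <- matrix(-1, 5L, 5L, dimnames = list(.aln_letters, .aln_letters))
  diag(m) <- 1
  m["N", "N"] <- -1
  m
})

#' Align two probe sequences with free end gaps
#'
#' Global alignment whose terminal gaps are unpenalized, so a short oligo
#' aligns inside a long target sequence without cost.  Scoring: match +1,
#' mismatch -1, gap open -2, gap extend -1; an \code{N} base mismatches
#' everything, including another \code{N}.
#'
#' @param seq_a,seq_b Non-empty nucleotide strings over \code{A,C,G,T,N}.
#' @return A list with elements \code{pattern} and \code{subject} (the
#'   aligned overlap region, gaps as \code{-}), \code{overlap} (number of
#'   aligned non-gap column pairs), \code{matches}, \code{mismatches}, and
#'   \code{no_overlap} (TRUE when no column aligns at all).
#' @export
align_pair <- function(seq_a, seq_b) {
  stopifnot(is.character(seq_a), is.character(seq_b),
            length(seq_a) == 1L, length(seq_b) == 1L)
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  if (!nzchar(seq_a) || !nzchar(seq_b))
    stop("both sequences must be non-empty")
  aln <- Biostrings::pairwiseAlignment(
    seq_a, seq_b, type = "overlap", substitutionMatrix = .aln_submat,
    gapOpening = 1, gapExtension = 1)
  pat <- as.character(Biostrings::alignedPattern(aln))
  sub <- as.character(Biostrings::alignedSubject(aln))
  counts <- .count_columns(pat, sub)
  c(list(pattern = pat, subject = sub), counts)
}

# count aligned non-gap columns and mismatches (N mismatches everything)
.count_columns <- function(pat, sub) {
  if (!nzchar(pat))
    return(list(overlap = 0L, matches = 0L, mismatches = 0L,
                no_overlap = TRUE))
  a <- strsplit(pat, "", fixed = TRUE)[[1L]]
  b <- strsplit(sub, "", fixed = TRUE)[[1L]]
  both <- a != "-" & b != "-"
  n <- sum(both)
  if (n == 0L)
    return(list(overlap = 0L, matches = 0L, mismatches = 0L,
                no_overlap = TRUE))
  eq <- both & a == b & a != "N"
  list(overlap = n, matches = sum(eq), mismatches = n - sum(eq),
       no_overlap = FALSE)
}

# Jukes-Cantor two-sequence ML branch length from a mismatch proportion,
# clamped into [0,1]; saturation (p >= 3/4) maps to 1.
.jc_distance <- function(p) {
  if (p >= 0.75) return(1)
  d <- -0.75 * log(1 - (4 / 3) * p)
  min(max(d, 0), 1)
}

#' Pairwise maximum-likelihood evolutionary distance
#'
#' Jukes-Cantor ML branch length between two aligned probe sequences (see
#' \link{similarity-model}).  Pairs whose optimal alignment covers less
#' than \code{min_overlap_frac} of the shorter sequence are treated as
#' unalignable: between unrelated sequences the best-scoring end-gap-free
#' alignment is typically a spurious few-column perfect overlap, which
#' would otherwise masquerade as near-identity.  Such pairs, and pairs at
#' or beyond mutational saturation (mismatch proportion >= 3/4), are
#' assigned the maximal distance 1.
#'
#' @inheritParams align_pair
#' @param min_overlap_frac Minimum fraction of the shorter sequence that
#'   the aligned overlap must cover for the distance to be estimable.
#' @return Distance in [0, 1].
#' @export
evolutionary_distance <- function(seq_a, seq_b, min_overlap_frac = 0.5) {
  al <- align_pair(seq_a, seq_b)
  floor_cols <- ceiling(min_overlap_frac *
                          min(nchar(seq_a), nchar(seq_b)))
  if (al$no_overlap || al$overlap < floor_cols) return(1)
  .jc_distance(al$mismatches / al$overlap)
}

#' Probe-sequence similarity score
#'
#' \code{1 - evolutionary_distance(seq_a, seq_b)}; symmetric, in [0, 1],
#' 1 for identical sequences, 0 for saturated or non-overlapping pairs.
#'
#' @inheritParams evolutionary_distance
#' @return Similarity in [0, 1].
#' @export
probe_similarity <- function(seq_a, seq_b, min_overlap_frac = 0.5) {
  1 - evolutionary_distance(seq_a, seq_b, min_overlap_frac)
}

#' Construct a similarity matrix object
#'
#' @param index Identifier-like data frame with columns \code{platform_id}
#'   and \code{probe_id}, one row per probe, in canonical order.
#' @param values Square numeric matrix of similarities aligned with
#'   \code{index}.
#' @param model Name of the substitution model used (recorded in the file
#'   header on write).
#' @return An object of class \code{ab_similarity}.
#' @export
similarity_matrix <- function(index, values, model = "JC69") {
  stopifnot(is.data.frame(index), is.matrix(values))
  index <- data.frame(platform_id = as.character(index$platform_id),
                      probe_id = as.character(index$probe_id),
                      stringsAsFactors = FALSE)
  n <- nrow(index)
  if (!all(dim(values) == c(n, n)))
    stop("values must be a ", n, "x", n, " matrix matching the index")
  if (any(!is.finite(values)) || any(values < 0) || any(values > 1))
    stop("similarity values must lie in [0, 1]")
  if (max(abs(values - t(values))) > 1e-6)
    stop("similarity matrix is asymmetric beyond tolerance 1e-6")
  values <- (values + t(values)) / 2
  diag(values) <- 1
  dimnames(values) <- NULL
  structure(list(index = index, values = values, model = model),
            class = "ab_similarity")
}

#' @export
print.ab_similarity <- function(x, ...) {
  cat("<similarity matrix> ", nrow(x$index), " probes on ",
      length(unique(x$index$platform_id)), " platforms (model ",
      x$model, ")\n", sep = "")
  invisible(x)
}

# internal: canonical row index of (platform_id, probe_id) pairs in M
.sim_index <- function(M, platform_id, probe_id) {
  i <- match(paste(platform_id, probe_id, sep = "\r"),
             paste(M$index$platform_id, M$index$probe_id, sep = "\r"))
  if (anyNA(i))
    stop("probe not indexed in similarity matrix: ",
         paste(platform_id[is.na(i)], probe_id[is.na(i)], sep = "-",
               collapse = ", "))
  i
}

#' Look up similarity values
#'
#' @param M Similarity matrix (\code{\link{similarity_matrix}}).
#' @param platform_a,probe_a,platform_b,probe_b Probe coordinates
#'   (vectorized, recycled pairwise).
#' @return Numeric vector of similarities.
#' @export
sim_value <- function(M, platform_a, probe_a, platform_b, probe_b) {
  ia <- .sim_index(M, platform_a, probe_a)
  ib <- .sim_index(M, platform_b, probe_b)
  M$values[cbind(ia, ib)]
}

#' Build the all-pairs probe similarity matrix
#'
#' Computes \code{\link{probe_similarity}} for every probe pair across the
#' union of the given platforms (within- and cross-platform alike).  The
#' row/column order is the canonical order: platforms as given, probes in
#' platform order.
#'
#' @param platforms Named list of platforms (\code{\link{platform_list}}).
#' @inheritParams evolutionary_distance
#' @return An \code{ab_similarity} object.
#' @export
build_similarity_matrix <- function(platforms, min_overlap_frac = 0.5) {
  if (length(platforms) < 1L) stop("at least one platform required")
  idx <- do.call(rbind, lapply(platforms, function(pf)
    data.frame(platform_id = pf$platform_id,
               probe_id = pf$probes$probe_id, stringsAsFactors = FALSE)))
  rownames(idx) <- NULL
  seqs <- unlist(lapply(platforms, function(pf) pf$probes$sequence),
                 use.names = FALSE)
  n <- length(seqs)
  vals <- diag(1, n)
  dna <- Biostrings::DNAStringSet(seqs)
  has_n <- grepl("N", seqs, fixed = TRUE)
  lens <- nchar(seqs)
  for (i in seq_len(n - 1L)) {
    js <- (i + 1L):n
    alns <- Biostrings::pairwiseAlignment(
      dna[js], dna[[i]], type = "overlap",
      substitutionMatrix = .aln_submat, gapOpening = 1, gapExtension = 1)
    if (!has_n[i] && !any(has_n[js])) {
      # no ambiguous bases: column counts come straight from the C layer
      matches <- Biostrings::nmatch(alns)
      mismatches <- Biostrings::nmismatch(alns)
      overlap <- matches + mismatches
    } else {
      pats <- as.character(Biostrings::alignedPattern(alns))
      subs <- as.character(Biostrings::alignedSubject(alns))
      cnts <- lapply(seq_along(js), function(k)
        .count_columns(pats[k], subs[k]))
      overlap <- vapply(cnts, `[[`, integer(1L), "overlap")
      mismatches <- vapply(cnts, `[[`, integer(1L), "mismatches")
    }
    floor_cols <- ceiling(min_overlap_frac * pmin(lens[i], lens[js]))
    sims <- ifelse(
      overlap == 0L | overlap < floor_cols, 0,
      1 - vapply(ifelse(overlap > 0L, mismatches / pmax(overlap, 1L), 1),
                 .jc_distance, numeric(1L)))
    vals[i, js] <- sims
    vals[js, i] <- sims
  }
  similarity_matrix(idx, vals)
}

#' Intra- versus inter-gene cross-platform similarity summary
#'
#' For every probe, collects its similarities to probes on \emph{other}
#' platforms, split by whether the partner shares its gene label (intra)
#' or not (inter), and reports per-probe max/mean/min plus the fraction of
#' intra-eligible probes whose single best cross-platform partner shares
#' the gene.  Probes whose gene has no cross-platform partner are excluded
#' from the intra statistics and counted separately.
#'
#' @param M Similarity matrix over \code{platforms}.
#' @param platforms Named list of >= 2 platforms.
#' @return A list with \code{per_probe} (data frame: platform_id,
#'   probe_id, gene_id, group, max, mean, min), \code{group_means}
#'   (data frame of averaged max/mean/min by group), \code{frac_best_same_gene},
#'   and \code{n_no_partner}.
#' @export
summarize_similarity <- function(M, platforms) {
  if (length(platforms) < 2L) stop("at least two platforms required")
  ids <- identifier_universe(platforms)
  idx <- .sim_index(M, ids$platform_id, ids$probe_id)
  rows <- list(); best_same <- logical(0)
  n_no_partner <- 0L
  for (i in seq_len(nrow(ids))) {
    other <- which(ids$platform_id != ids$platform_id[i])
    if (!length(other)) next
    sims <- M$values[idx[i], idx[other]]
    intra <- ids$gene_id[other] == ids$gene_id[i]
    if (any(intra)) {
      s <- sims[intra]
      rows[[length(rows) + 1L]] <- data.frame(
        platform_id = ids$platform_id[i], probe_id = ids$probe_id[i],
        gene_id = ids$gene_id[i], group = "intra",
        max = max(s), mean = mean(s), min = min(s),
        stringsAsFactors = FALSE)
      best_same <- c(best_same, intra[which.max(sims)])
    } else {
      n_no_partner <- n_no_partner + 1L
    }
    if (any(!intra)) {
      s <- sims[!intra]
      rows[[length(rows) + 1L]] <- data.frame(
        platform_id = ids$platform_id[i], probe_id = ids$probe_id[i],
        gene_id = ids$gene_id[i], group = "inter",
        max = max(s), mean = mean(s), min = min(s),
        stringsAsFactors = FALSE)
    }
  }
  per_probe <- if (length(rows)) do.call(rbind, rows) else
    data.frame(platform_id = character(), probe_id = character(),
               gene_id = character(), group = character(),
               max = numeric(), mean = numeric(), min = numeric())
  group_means <- do.call(rbind, lapply(split(per_probe, per_probe$group),
    function(d) data.frame(group = d$group[1L], max = mean(d$max),
                           mean = mean(d$mean), min = mean(d$min))))
  rownames(group_means) <- NULL
  list(per_probe = per_probe,
       group_means = group_means,
       frac_best_same_gene =
         if (length(best_same)) mean(best_same) else NA_real_,
       n_no_partner = n_no_partner)
}
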