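#' Specification for the synthetic multi-platform benchmark
#'
#' Describes a simulated study: a universe of genes, several array
#' platforms that each cover a subset of those genes with probes of
#' platform-specific length and controlled sequence divergence, and one
#' expression dataset per platform whose tumor/normal labels are generated
#' by a logistic model on a small set of planted genes.  Non-planted genes
#' are decoys carrying no label signal.
#'
#' Each gene has a reference region; a platform's probe for that gene is a
#' (deterministically positioned) subsequence of the region with
#' independent per-base substitutions at \code{mut_rate}, so same-gene
#' probes across platforms are homologous while different-gene probes are
#' unrelated random sequence.  Planted genes are always covered on every
#' platform (a benchmark must be able to measure its own signal);
#' remaining genes are covered independently with probability
#' \code{gene_coverage}, producing the partial gene overlap typical of
#' real platform pairs.
#'
#' @param n_genes Number of genes in the universe.
#' @param n_platforms Number of platforms (= number of datasets).
#' @param gene_coverage Per-platform coverage probability for non-planted
#'   genes.
#' @param probe_len Probe length per platform (recycled; e.g.
#'   \code{c(250, 250, 60)} mimics long target sequences vs short spotted
#'   oligos).
#' @param probes_per_gene Probes per covered gene per platform.
#' @param mut_rate Per-base substitution probability between a gene's
#'   reference region and a platform probe.
#' @param n_samples Samples per dataset (balanced labelling emerges from
#'   \code{beta0 = 0}).
#' @param planted_genes Character vector of planted biomarker genes.
#' @param beta0 Intercept of the label-generating logistic model.
#' @param planted_betas Logistic effect per planted gene (on the latent
#'   standard-normal gene scale).  The default is calibrated so the
#'   Bayes-optimal classifier on the planted genes exceeds 97 percent
#'   accuracy, leaving headroom for held-out evaluation at desk-scale
#'   sample sizes; weaker settings (e.g. 4 per gene, Bayes about 0.91)
#'   still let the search recover the planted pair while exercising the
#'   noisy-label regime.
#' @param noise_sd Probe-level measurement noise standard deviation.
#' @param seed Integer master seed; all component generators derive their
#'   streams from it.
#' @return A list of class \code{ab_synth_spec}.
#' @export
synthetic_spec <- function(n_genes = 10L, n_platforms = 3L,
                           gene_coverage = 0.8, probe_len = 60L,
                           probes_per_gene = 1L, mut_rate = 0.02,
                           n_samples = 60L,
                           planted_genes = c("G01", "G02"),
                           beta0 = 0, planted_betas = c(16, 16),
                           noise_sd = 0.1, seed = 1L) {
  genes <- sprintf("G%02d", seq_len(n_genes))
  stopifnot(n_genes >= 1L, n_platforms >= 1L,
            gene_coverage >= 0, gene_coverage <= 1,
            mut_rate >= 0, mut_rate <= 1,
            probes_per_gene >= 1L, n_samples >= 2L)
  if (!all(planted_genes %in% genes))
    stop("planted_genes must be a subset of the gene universe (",
         genes[1L], "...", genes[n_genes], ")")
  if (length(planted_betas) != length(planted_genes))
    stop("one effect size per planted gene required")
  if (!length(planted_genes) && any(planted_betas != 0))
    stop("nonzero planted_betas require planted genes")
  structure(list(n_genes = as.integer(n_genes), genes = genes,
                 n_platforms = as.integer(n_platforms),
                 gene_coverage = gene_coverage,
                 probe_len = rep_len(as.integer(probe_len), n_platforms),
                 probes_per_gene = as.integer(probes_per_gene),
                 mut_rate = mut_rate, n_samples = as.integer(n_samples),
                 planted_genes = planted_genes, beta0 = beta0,
                 planted_betas = planted_betas, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "ab_synth_spec")
}

.BASES <- c("A", "C", "G", "T")

.mutate_seq <- function(chars, rate) {
  if (rate <= 0) return(chars)
  hit <- stats::runif(length(chars)) < rate
  if (any(hit))
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(.BASES, b), 1L), character(1L))
  chars
}

#' Generate the synthetic platforms
#'
#' Draws one reference region per gene (length twice the longest probe),
#' then cuts each platform's probes from it at deterministic offsets and
#' applies per-base substitutions at \code{mut_rate}.  Fully reproducible
#' from the spec seed.
#'
#' @param spec \code{\link{synthetic_spec}}.
#' @return A list: \code{platforms} (named platform list) and
#'   \code{references} (named character vector of gene reference regions).
#' @export
generate_platforms <- function(spec) {
  stopifnot(inherits(spec, "ab_synth_spec"))
  set.seed(spec$seed)
  ref_len <- 2L * max(spec$probe_len)
  refs <- vapply(spec$genes, function(g)
    paste(sample(.BASES, ref_len, replace = TRUE), collapse = ""),
    character(1L))
  platforms <- vector("list", spec$n_platforms)
  for (i in seq_len(spec$n_platforms)) {
    L <- spec$probe_len[i]
    covered <- spec$genes %in% spec$planted_genes |
      stats::runif(spec$n_genes) < spec$gene_coverage
    if (!any(covered)) covered[1L] <- TRUE
    pid <- character(0); gid <- character(0); sq <- character(0)
    step <- max(1L, L %/% 4L)
    for (g in spec$genes[covered]) {
      for (j in seq_len(spec$probes_per_gene)) {
        start <- min(1L + (j - 1L) * step, ref_len - L + 1L)
        chars <- strsplit(substr(refs[[g]], start, start + L - 1L),
                          "", fixed = TRUE)[[1L]]
        pid <- c(pid, paste0(g, "_p", j))
        gid <- c(gid, g)
        sq <- c(sq, paste(.mutate_seq(chars, spec$mut_rate),
                          collapse = ""))
      }
    }
    platforms[[i]] <- platform(sprintf("PF%d", i), pid, gid, sq)
  }
  list(platforms = platform_list(platforms), references = refs)
}

#' Generate one labelled expression dataset per platform
#'
#' Per sample, latent gene values are standard normal; the tumor label is
#' Bernoulli with probability
#' \code{plogis(beta0 + sum(planted_betas * g[planted]))}; each probe
#' measures its gene's latent value plus independent Gaussian noise, so
#' probes of one gene correlate through the shared latent value.  Datasets
#' share the label-generating law but draw independent samples, emulating
#' independent cohorts assayed on different platforms.
#'
#' @param platforms Named platform list from
#'   \code{\link{generate_platforms}}.
#' @param spec \code{\link{synthetic_spec}}.
#' @return List of \code{\link{expression_dataset}} objects, one per
#'   platform, named \code{DS1}, \code{DS2}, ...
#' @export
generate_expression <- function(platforms, spec) {
  stopifnot(inherits(spec, "ab_synth_spec"))
  if (!length(spec$planted_genes) && any(spec$planted_betas != 0))
    stop("nonzero planted_betas require planted genes")
  datasets <- vector("list", length(platforms))
  for (i in seq_along(platforms)) {
    set.seed(spec$seed + 1000L + i)
    pf <- platforms[[i]]
    g <- matrix(stats::rnorm(spec$n_genes * spec$n_samples),
                nrow = spec$n_genes,
                dimnames = list(spec$genes, NULL))
    eta <- spec$beta0 + if (length(spec$planted_genes))
      drop(spec$planted_betas %*%
             g[spec$planted_genes, , drop = FALSE]) else 0
    y <- stats::rbinom(spec$n_samples, 1L, stats::plogis(eta))
    intens <- g[pf$probes$gene_id, , drop = FALSE] +
      matrix(stats::rnorm(nrow(pf$probes) * spec$n_samples,
                          sd = spec$noise_sd),
             nrow = nrow(pf$probes))
    rownames(intens) <- pf$probes$probe_id
    colnames(intens) <- sprintf("%s_S%03d", pf$platform_id,
                                seq_len(spec$n_samples))
    datasets[[i]] <- expression_dataset(sprintf("DS%d", i), pf, intens, y)
  }
  names(datasets) <- vapply(datasets, `[[`, character(1L), "dataset_id")
  datasets
}

# fixed toy sequences for the worked-example world (arbitrary 40-mers;
# the similarity matrix below is hard-coded, not computed from them)
.TOY_SEQS <- c(
  "TGCAGTCAGGAACCTTGATCGGTACCTAGGCTTAGCAGTT",
  "TGCAGTCAGGAACCTTGATCGGTACCTAGGCTTAGCAGAA",
  "CCGATTAGGCATCGATTGCCAAGTCCGGATTACGGTTACC",
  "TGCAGTCAGGAACCTTGATCGGTACCAAGGCTTAGCAGTT",
  "GATCCGGTTAACGGCTTAAGCCGATCGTACCGGATCAGTT",
  "GATCCGGTTAACGGCTTAAGCCGATCGTACCGGATCAGAA",
  "CCGATTAGGCATCGATTGCCAAGTCCGGATTACGGTTAGG")

#' The seven-probe worked-example world
#'
#' Three toy platforms -- PF1 with probes P1/G1, P2/G1, P3/G3; PF2 with
#' P1/G1, P2/G2; PF3 with P1/G2, P2/G3 -- together with the printed toy
#' similarity matrix used throughout the worked examples (hard-coded, not
#' recomputed from the placeholder sequences).  Gene G3 is absent from
#' PF2 and gene G1 from PF3, exercising substitute resolution.
#'
#' @return A list: \code{platforms} (named platform list) and \code{M}
#'   (\code{ab_similarity}).
#' @export
table2_world <- function() {
  platforms <- platform_list(
    platform("PF1", c("P1", "P2", "P3"), c("G1", "G1", "G3"),
             .TOY_SEQS[1:3]),
    platform("PF2", c("P1", "P2"), c("G1", "G2"), .TOY_SEQS[4:5]),
    platform("PF3", c("P1", "P2"), c("G2", "G3"), .TOY_SEQS[6:7]))
  vals <- matrix(0, 7L, 7L)
  vals[upper.tri(vals)] <- c(
    0.9,
    0.5, 0.4,
    0.8, 0.8, 0.4,
    0.3, 0.2, 0.1, 0.0,
    0.4, 0.3, 0.5, 0.5, 0.8,
    0.1, 0.2, 0.9, 0.3, 0.4, 0.5)
  vals <- vals + t(vals)
  diag(vals) <- 1
  M <- similarity_matrix(
    data.frame(platform_id = c("PF1", "PF1", "PF1", "PF2", "PF2",
                               "PF3", "PF3"),
               probe_id = c("P1", "P2", "P3", "P1", "P2", "P1", "P2"),
               stringsAsFactors = FALSE),
    vals)
  list(platforms = platforms, M = M)
}
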