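#' Exact binomial coefficient with big-integer arithmetic
#'
#' The number of size-\code{k} probe panels from \code{n} probes, computed
#' exactly (no floating-point overflow) as the running product
#' \eqn{\prod_{i=1}^{k}(n-k+i)/i}, which stays integral at every step.
#' For array-scale inputs the count is astronomically large -- e.g. 30,000
#' choose 8 is about 1.6e31, which at 2 seconds per panel evaluation is on
#' the order of 1e24 years -- motivating the heuristic search in
#' \code{\link{run_ga}}.
#'
#' @param n,k Non-negative integers, \code{k <= n}.
#' @return A list: \code{digits} (exact decimal string), \code{value}
#'   (numeric approximation, \code{Inf} if beyond double range).
#' @export
count_combinations <- function(n, k) {
  n <- as.numeric(n); k <- as.numeric(k)
  if (n < 0 || k < 0 || n != floor(n) || k != floor(k))
    stop("n and k must be non-negative integers")
  if (k > n) stop("k must not exceed n")
  k <- min(k, n - k)
  v <- c(1)  # little-endian base-1e9 digits
  if (k >= 1) for (i in seq_len(k)) {
    v <- .big_mul(v, n - k + i)
    v <- .big_div(v, i)
  }
  s <- .big_string(v)
  list(digits = s, value = as.numeric(s))
}

# base-1e9 little-endian big integer helpers; multipliers/divisors are
# small (< 2^31), so double-precision carries stay exact (< 2^53)
.BIG_BASE <- 1e9
.big_mul <- function(v, m) {
  carry <- 0
  for (i in seq_along(v)) {
    t <- v[i] * m + carry
    v[i] <- t %% .BIG_BASE
    carry <- t %/% .BIG_BASE
  }
  while (carry > 0) {
    v <- c(v, carry %% .BIG_BASE)
    carry <- carry %/% .BIG_BASE
  }
  v
}
.big_div <- function(v, d) {  # exact division by a small integer
  rem <- 0
  for (i in rev(seq_along(v))) {
    cur <- rem * .BIG_BASE + v[i]
    v[i] <- cur %/% d
    rem <- cur %% d
  }
  if (rem != 0) stop("internal error: inexact big-integer division")
  while (length(v) > 1L && v[length(v)] == 0) v <- v[-length(v)]
  v
}
.big_string <- function(v) {
  paste0(v[length(v)],
         paste(sprintf("%09.0f", rev(v[-length(v)])), collapse = ""))
}

#' Genetic-algorithm configuration
#'
#' Control surface of the panel search.  Defaults follow the method's
#' standard setting: population size \code{PS = 300}, \code{MG = 50}
#' generations, crossover rate \code{TXR = 0.5}, and stopping threshold
#' \code{TLC = 0} -- since every LLV is negative, a zero threshold never
#' triggers early stopping and is equivalent to "no threshold".
#'
#' @param k Panel size (number of associated biomarkers sought;
#'   8 is the recommended default for unguided searches).
#' @param PS Population size.
#' @param MG Maximum number of generations.
#' @param TXR Per-locus crossover (swap) probability between paired kept
#'   individuals.
#' @param TLC LLV threshold for early stopping (search stops once the
#'   elite LLV reaches it).
#' @param seed Integer seed; all randomness of the search flows from it.
#' @param replace_prob Probability that, in each kept individual, the
#'   locus with the smallest mean absolute standardized coefficient is
#'   replaced by a freshly drawn identifier.
#' @return A list of class \code{ab_ga_config}.
#' @export
ga_config <- function(k = 8L, PS = 300L, MG = 50L, TXR = 0.5, TLC = 0,
                      seed = 1L, replace_prob = 0.5) {
  stopifnot(k >= 1L, PS >= 1L, MG >= 0L, TXR >= 0, TXR <= 1,
            replace_prob >= 0, replace_prob <= 1)
  structure(list(k = as.integer(k), PS = as.integer(PS),
                 MG = as.integer(MG), TXR = TXR, TLC = TLC,
                 seed = as.integer(seed), replace_prob = replace_prob),
            class = "ab_ga_config")
}

# fitness evaluation with caching keyed by the (unordered) panel
.panel_key <- function(EI) {
  paste(sort(format_identifiers(EI, sep = "\t")), collapse = "\n")
}
.evaluate_panel <- function(EI, datasets, M, platforms, cache) {
  key <- .panel_key(EI)
  hit <- cache[[key]]
  if (!is.null(hit)) return(hit)
  clm <- identify_clm(datasets, M, EI, platforms)
  cache[[key]] <- clm
  clm
}

# draw one panel: k identifiers uniformly without replacement from the
# universe, subject to pairwise-distinct genes
.sample_panel <- function(IDF, k) {
  rows <- integer(0); genes <- character(0)
  avail <- seq_len(nrow(IDF))
  for (j in seq_len(k)) {
    avail <- avail[!(IDF$gene_id[avail] %in% genes)]
    if (!length(avail)) stop("identifier universe has fewer than k = ",
                             k, " distinct genes")
    pick <- avail[sample.int(length(avail), 1L)]
    rows <- c(rows, pick)
    genes <- c(genes, IDF$gene_id[pick])
  }
  IDF[rows, , drop = FALSE]
}

#' Initialize the search population
#'
#' Draws \code{PS} candidate panels ("p-LMs") of \code{k} identifiers
#' each, uniformly from the identifier universe subject to distinct genes,
#' and evaluates each panel's common-logit-model fitness.
#'
#' @param IDF Identifier universe (\code{\link{identifier_universe}}).
#' @param datasets,M,platforms As in \code{\link{identify_clm}}.
#' @param config \code{\link{ga_config}}.
#' @param cache Optional environment used to cache panel fitness.
#' @return A list of class \code{ab_population}: \code{individuals} (each
#'   a list with \code{EI} and \code{clm}) and \code{elite} (best c-LM
#'   seen).
#' @export
init_population <- function(IDF, datasets, M, platforms, config,
                            cache = new.env(parent = emptyenv())) {
  if (length(unique(IDF$gene_id)) < config$k)
    stop("identifier universe has fewer than k = ", config$k,
         " distinct genes")
  individuals <- lapply(seq_len(config$PS), function(i) {
    EI <- .sample_panel(IDF, config$k)
    list(EI = EI, clm = .evaluate_panel(EI, datasets, M, platforms, cache))
  })
  llvs <- vapply(individuals, function(d) d$clm$llv, numeric(1L))
  structure(list(individuals = individuals,
                 elite = individuals[[which.max(llvs)]]$clm),
            class = "ab_population")
}

#' Roulette-wheel survival selection
#'
#' Samples \code{PS} individuals with replacement, with probability
#' proportional to the min-shifted fitness
#' \eqn{w_i = (LLV_i - \min_j LLV_j) + \epsilon},
#' \eqn{\epsilon = 10^{-6}(\max-\min+1)}: panels with larger LLV are
#' strictly more likely to survive, and the worst panel keeps a small but
#' nonzero chance.
#'
#' @param pop An \code{ab_population}.
#' @return List of kept individuals (length \code{PS}).
#' @export
roulette_select <- function(pop) {
  ind <- pop$individuals
  llvs <- vapply(ind, function(d) d$clm$llv, numeric(1L))
  w <- roulette_weights(llvs)
  ind[sample.int(length(ind), length(ind), replace = TRUE, prob = w)]
}

#' Selection weights used by the roulette wheel
#'
#' @param llvs Numeric vector of panel LLVs.
#' @return Unnormalized positive weights, monotone in \code{llvs}.
#' @export
roulette_weights <- function(llvs) {
  eps <- 1e-6 * (max(llvs) - min(llvs) + 1)
  (llvs - min(llvs)) + eps
}

#' Crossover and small-coefficient replacement
#'
#' Kept individuals are paired sequentially (1-2, 3-4, ...).  Within a
#' pair, each locus position is swapped with probability \code{TXR},
#' skipping swaps that would duplicate a gene inside either panel.  Then,
#' with probability \code{replace_prob} per individual, the locus whose
#' mean absolute standardized coefficient across the sibling fits is
#' smallest -- the identifier least associated with the clinical outcome --
#' is replaced by a fresh uniformly drawn identifier whose gene keeps the
#' panel's genes distinct.  Modified panels are re-evaluated.
#'
#' @param kept List of individuals from \code{\link{roulette_select}}.
#' @inheritParams init_population
#' @return List of individuals forming the next generation.
#' @export
crossover_and_replace <- function(kept, IDF, datasets, M, platforms,
                                  config,
                                  cache = new.env(parent = emptyenv())) {
  n <- length(kept)
  panels <- lapply(kept, `[[`, "EI")
  changed <- logical(n)
  # pairwise locus swaps
  if (n >= 2L && config$TXR > 0) {
    for (a in seq(1L, n - 1L, by = 2L)) {
      b <- a + 1L
      for (j in seq_len(config$k)) {
        if (stats::runif(1L) >= config$TXR) next
        ga <- panels[[a]]$gene_id; gb <- panels[[b]]$gene_id
        # skip swaps that would break gene distinctness in either panel
        if (panels[[b]]$gene_id[j] %in% ga[-j] ||
            panels[[a]]$gene_id[j] %in% gb[-j]) next
        tmp <- panels[[a]][j, ]
        panels[[a]][j, ] <- panels[[b]][j, ]
        panels[[b]][j, ] <- tmp
        changed[c(a, b)] <- TRUE
      }
    }
  }
  # replace the least-associated locus with a fresh identifier
  if (config$replace_prob > 0) {
    for (i in seq_len(n)) {
      if (stats::runif(1L) >= config$replace_prob) next
      clm <- if (changed[i])
        .evaluate_panel(panels[[i]], datasets, M, platforms, cache)
      else kept[[i]]$clm
      j <- which.min(.locus_beta_means(clm))
      keep_genes <- panels[[i]]$gene_id[-j]
      avail <- which(!(IDF$gene_id %in% keep_genes))
      if (!length(avail)) next
      panels[[i]][j, ] <- IDF[avail[sample.int(length(avail), 1L)],
                              c("platform_id", "probe_id", "gene_id")]
      changed[i] <- TRUE
    }
  }
  lapply(seq_len(n), function(i) {
    if (!changed[i]) return(kept[[i]])
    list(EI = panels[[i]],
         clm = .evaluate_panel(panels[[i]], datasets, M, platforms, cache))
  })
}

#' Mine an improved common logit model with a genetic algorithm
#'
#' Iterates roulette-wheel selection, pairwise crossover and
#' small-coefficient replacement for up to \code{MG} generations,
#' tracking the best panel ever evaluated (elitism), and stops early once
#' the elite LLV reaches \code{TLC}.  With the default \code{TLC = 0} the
#' search always runs the full \code{MG} generations (LLVs are negative).
#'
#' @inheritParams init_population
#' @param IDF Identifier universe to search; defaults to all probes of
#'   \code{platforms}.
#' @return The elite \code{ab_clm}, with attributes \code{history} (elite
#'   LLV after initialization and after each generation),
#'   \code{generations} (number actually run), \code{config}.
#' @export
run_ga <- function(datasets, M, platforms, config,
                   IDF = identifier_universe(platforms)) {
  stopifnot(inherits(config, "ab_ga_config"), length(datasets) >= 1L)
  set.seed(config$seed)
  cache <- new.env(parent = emptyenv())
  pop <- init_population(IDF, datasets, M, platforms, config, cache)
  elite <- pop$elite
  history <- elite$llv
  gens <- 0L
  while (gens < config$MG && elite$llv < config$TLC) {
    kept <- roulette_select(pop)
    nxt <- crossover_and_replace(kept, IDF, datasets, M, platforms,
                                 config, cache)
    llvs <- vapply(nxt, function(d) d$clm$llv, numeric(1L))
    best <- nxt[[which.max(llvs)]]$clm
    if (best$llv > elite$llv) elite <- best
    pop <- structure(list(individuals = nxt, elite = elite),
                     class = "ab_population")
    gens <- gens + 1L
    history <- c(history, elite$llv)
  }
  attr(elite, "history") <- history
  attr(elite, "generations") <- gens
  attr(elite, "config") <- config
  elite
}

#' Exhaustive panel search (brute-force oracle)
#'
#' Evaluates every distinct-gene panel of size \code{k} (one canonical
#' identifier per gene: the gene's first identifier in canonical universe
#' order) and returns the LLV-maximal common logit model.  Only feasible
#' on small universes; the guard bounds the number of gene combinations.
#'
#' @inheritParams run_ga
#' @param k Panel size.
#' @param guard Maximum number of gene combinations allowed.
#' @return The optimal \code{ab_clm} (ties resolved toward the
#'   lexicographically smallest gene combination, which the enumeration
#'   order yields for free).
#' @export
exhaustive_search <- function(datasets, M, platforms, k,
                              IDF = identifier_universe(platforms),
                              guard = 1e5) {
  genes <- unique(IDF$gene_id)
  if (k > length(genes)) stop("k exceeds the number of distinct genes")
  n_comb <- count_combinations(length(genes), k)$value
  if (n_comb > guard)
    stop("exhaustive search over ", n_comb, " panels exceeds the guard (",
         format(guard, scientific = FALSE), "); use run_ga() instead")
  canon <- IDF[!duplicated(IDF$gene_id), , drop = FALSE]
  combos <- utils::combn(length(genes), k)
  best <- NULL
  for (c_i in seq_len(ncol(combos))) {
    EI <- canon[combos[, c_i], , drop = FALSE]
    clm <- identify_clm(datasets, M, EI, platforms)
    if (is.null(best) || clm$llv > best$llv) best <- clm
  }
  best
}
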