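# shared fixtures and independent oracles, built once per test run

# worked-example world (3 toy platforms + printed similarity matrix)
toy <- table2_world()
toy_EI <- identifiers(c("PF1", "PF3"), c("P1", "P2"), c("G1", "G3"))

# standard synthetic benchmark: platforms/similarity fixed across tests,
# expression regenerated per seed where a test needs fresh cohorts
std_spec <- synthetic_spec(seed = 1L)
std_world <- generate_platforms(std_spec)
std_M <- build_similarity_matrix(std_world$platforms)
std_datasets <- generate_expression(std_world$platforms, std_spec)

# expression datasets for the standard platforms under a different seed
# (and optionally different signal parameters)
std_expression <- function(seed, planted_betas = std_spec$planted_betas,
                           n_samples = std_spec$n_samples) {
  spec <- synthetic_spec(seed = seed, planted_betas = planted_betas,
                         n_samples = n_samples)
  generate_expression(std_world$platforms, spec)
}

# panel of the two planted genes, as PF1 identifiers
std_planted_EI <- identifiers(c("PF1", "PF1"),
                              c("G01_p1", "G02_p1"),
                              c("G01", "G02"))

# small labelled dataset on a toy platform with the given intensities
toy_dataset <- function(id, pf, values, labels) {
  m <- matrix(values, nrow = nrow(pf$probes), byrow = TRUE)
  rownames(m) <- pf$probes$probe_id
  colnames(m) <- paste0(id, "_S", seq_len(ncol(m)))
  expression_dataset(id, pf, m, labels)
}

# deterministic toy datasets on the worked-example platforms
toy_datasets <- local({
  set.seed(77)
  lab <- c(1, 1, 1, 0, 0, 0)
  mk <- function(id, pf) {
    signal <- outer(rep(1, nrow(pf$probes)), ifelse(lab == 1, 1.5, -1.5))
    toy_dataset(id, pf, signal + rnorm(length(signal), sd = 0.5), lab)
  }
  list(DS1 = mk("DS1", toy$platforms$PF1),
       DS2 = mk("DS2", toy$platforms$PF2),
       DS3 = mk("DS3", toy$platforms$PF3))
})

# Eq.-style direct log-likelihood evaluation (independent of fit_lm)
oracle_llv <- function(b0, b, X, y) {
  p <- plogis(b0 + as.matrix(X) %*% b)
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(y * log(p) + (1 - y) * log(1 - p))
}

# independent two-stage grid-search MLE oracle for <= 1 predictor
grid_oracle_llv <- function(x, y) {
  ll <- function(b0, b1) oracle_llv(b0, b1, matrix(x, ncol = 1), y)
  search <- function(b0s, b1s) {
    best <- -Inf; arg <- c(0, 0)
    for (b1 in b1s) {
      v <- vapply(b0s, ll, numeric(1), b1 = b1)
      if (max(v) > best) { best <- max(v); arg <- c(b0s[which.max(v)], b1) }
    }
    list(llv = best, arg = arg)
  }
  coarse <- search(seq(-15, 15, by = 0.05), seq(-8, 8, by = 0.05))
  fine <- search(seq(coarse$arg[1] - 0.06, coarse$arg[1] + 0.06,
                     by = 5e-4),
                 seq(coarse$arg[2] - 0.06, coarse$arg[2] + 0.06,
                     by = 5e-4))
  fine$llv
}

# deterministic mutated copy of a sequence (exactly n substitutions);
# `margin` keeps substitutions away from the ends, where the end-gap-free
# aligner would clip a terminal mismatch instead of counting it
mutate_n <- function(seq, n, seed = 1, margin = 3) {
  set.seed(seed)
  chars <- strsplit(seq, "")[[1]]
  pos <- sample((margin + 1):(length(chars) - margin), n)
  for (i in pos)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
  paste(chars, collapse = "")
}

random_dna <- function(n, seed = 1) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
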