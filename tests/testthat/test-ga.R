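# tiny planted-pair instance shared by the GA tests: the standard
# synthetic world (10 genes, 3 platforms/datasets, planted G01+G02)
ga_cfg <- function(seed = 1, ...)
  ga_config(k = 2, PS = 20, MG = 10, seed = seed, ...)

test_that("panel combination counts are exact", {
  expect_identical(count_combinations(5, 2)$value, 10)
  expect_identical(count_combinations(7, 0)$value, 1)
  expect_identical(count_combinations(12, 12)$digits, "1")
  expect_identical(count_combinations(52, 5)$digits, "2598960")
  expect_error(count_combinations(3, 4), "exceed")
  expect_error(count_combinations(5.5, 2), "integer")

  # array-scale count: ~1.6e31 panels, ~1e24 years at 2 s per panel
  cc <- count_combinations(30000, 8)
  expect_identical(cc$digits, "16257139749265314547010113121250")
  expect_equal(signif(cc$value, 2), 1.6e31)
  years <- cc$value * 2 / (365.25 * 24 * 3600)
  expect_equal(signif(years, 1), 1e24)
})

test_that("population initialization is reproducible and gene-distinct", {
  IDF <- identifier_universe(std_world$platforms)
  cfg <- ga_cfg()
  set.seed(cfg$seed)
  pop1 <- init_population(IDF, std_datasets, std_M, std_world$platforms,
                          cfg)
  set.seed(cfg$seed)
  pop2 <- init_population(IDF, std_datasets, std_M, std_world$platforms,
                          cfg)
  expect_identical(lapply(pop1$individuals, `[[`, "EI"),
                   lapply(pop2$individuals, `[[`, "EI"))
  expect_length(pop1$individuals, cfg$PS)
  for (ind in pop1$individuals)
    expect_false(anyDuplicated(ind$EI$gene_id) > 0)
  # elite invariant: at least as good as every individual
  llvs <- vapply(pop1$individuals, function(d) d$clm$llv, numeric(1))
  expect_gte(pop1$elite$llv, max(llvs))

  # k equal to the number of distinct genes covers every gene
  cfg_all <- ga_config(k = 10, PS = 2, MG = 0, seed = 3)
  set.seed(3)
  pop_all <- init_population(IDF, std_datasets, std_M,
                             std_world$platforms, cfg_all)
  for (ind in pop_all$individuals)
    expect_setequal(ind$EI$gene_id, unique(IDF$gene_id))
  expect_error(init_population(IDF, std_datasets, std_M,
                               std_world$platforms,
                               ga_config(k = 11, PS = 1)),
               "fewer than")
})

test_that("roulette weights favor larger LLVs monotonically", {
  # equal fitness: uniform weights
  expect_equal(roulette_weights(c(-2, -2, -2)),
               rep(1e-6, 3))
  # two individuals at -1 and -3: the better one dominates
  w <- roulette_weights(c(-1, -3))
  eps <- 1e-6 * 3
  expect_equal(w, c(2 + eps, eps))
  expect_gt(w[1] / sum(w), 0.99)
  # strictly monotone in llv
  w3 <- roulette_weights(c(-5, -1, -3))
  expect_true(all(order(w3) == order(c(-5, -1, -3))))

  # empirical selection frequencies track the weights (multinomial 3 sigma)
  set.seed(42)
  llvs <- c(-1, -2, -4)
  pop <- structure(list(individuals = lapply(llvs, function(l)
    list(EI = identifiers("PF1", paste0("P", abs(l)), paste0("G", abs(l))),
         clm = structure(list(llv = l), class = "ab_clm")))),
    class = "ab_population")
  draws <- 2e4
  kept <- unlist(replicate(draws / 20, {
    sel <- roulette_select(pop)
    vapply(sel, function(d) d$clm$llv, numeric(1))
  }, simplify = FALSE))
  p_exp <- roulette_weights(llvs) / sum(roulette_weights(llvs))
  for (i in 1:3) {
    obs <- mean(kept == llvs[i])
    expect_lt(abs(obs - p_exp[i]),
              3 * sqrt(p_exp[i] * (1 - p_exp[i]) / length(kept)) + 1e-3)
  }
})

test_that("crossover swaps loci and preserves gene distinctness", {
  IDF <- identifier_universe(std_world$platforms)
  set.seed(11)
  cfg0 <- ga_config(k = 3, PS = 6, MG = 1, TXR = 0, replace_prob = 0)
  pop <- init_population(IDF, std_datasets, std_M, std_world$platforms,
                         cfg0)
  kept <- pop$individuals
  # TXR = 0 and replacement disabled: a no-op
  nxt <- crossover_and_replace(kept, IDF, std_datasets, std_M,
                               std_world$platforms, cfg0)
  expect_identical(lapply(nxt, `[[`, "EI"), lapply(kept, `[[`, "EI"))

  # TXR = 1 with disjoint panels: the pair swaps panels entirely
  a <- list(EI = IDF[c(1, 2), ],
            clm = identify_clm(std_datasets, std_M, IDF[c(1, 2), ],
                               std_world$platforms))
  b <- list(EI = IDF[c(3, 4), ],
            clm = identify_clm(std_datasets, std_M, IDF[c(3, 4), ],
                               std_world$platforms))
  cfg1 <- ga_config(k = 2, PS = 2, MG = 1, TXR = 1, replace_prob = 0)
  out <- crossover_and_replace(list(a, b), IDF, std_datasets, std_M,
                               std_world$platforms, cfg1)
  expect_equal(out[[1]]$EI$probe_id, b$EI$probe_id)
  expect_equal(out[[2]]$EI$probe_id, a$EI$probe_id)

  # property: distinct genes survive many random operations
  set.seed(12)
  cfg <- ga_config(k = 3, PS = 6, MG = 1, TXR = 0.7, replace_prob = 0.7)
  kept <- init_population(IDF, std_datasets, std_M, std_world$platforms,
                          cfg)$individuals
  for (rep in 1:40) {
    kept <- crossover_and_replace(kept, IDF, std_datasets, std_M,
                                  std_world$platforms, cfg)
    for (ind in kept)
      expect_false(anyDuplicated(ind$EI$gene_id) > 0)
  }
})

test_that("the exhaustive oracle enumerates distinct-gene panels", {
  # 10 genes, k = 2: 45 panels; the optimum dominates every panel
  best <- exhaustive_search(std_datasets, std_M, std_world$platforms,
                            k = 2)
  IDF <- identifier_universe(std_world$platforms)
  canon <- IDF[!duplicated(IDF$gene_id), ]
  combos <- utils::combn(nrow(canon), 2)
  llvs <- apply(combos, 2, function(ix)
    identify_clm(std_datasets, std_M, canon[ix, ],
                 std_world$platforms)$llv)
  expect_length(llvs, 45)
  expect_equal(best$llv, max(llvs), tolerance = 1e-12)
  # the planted pair is the exhaustive optimum on this instance
  expect_setequal(best$EI$gene_id, c("G01", "G02"))

  # k equal to the gene count: a single panel
  one_gene <- exhaustive_search(std_datasets, std_M,
                                std_world$platforms, k = 10)
  expect_setequal(one_gene$EI$gene_id, unique(IDF$gene_id))
  expect_error(exhaustive_search(std_datasets, std_M,
                                 std_world$platforms, k = 2, guard = 10),
               "guard")
})

test_that("the GA is elitist, reproducible, and finds the tiny optimum", {
  cfg <- ga_cfg(seed = 101)
  elite1 <- run_ga(std_datasets, std_M, std_world$platforms, cfg)
  elite2 <- run_ga(std_datasets, std_M, std_world$platforms, cfg)
  expect_identical(elite1$EI, elite2$EI)
  expect_identical(elite1$llv, elite2$llv)
  # elite trajectory never degrades
  expect_true(all(diff(attr(elite1, "history")) >= 0))

  # MG = 0 returns the best individual of the initial population
  cfg0 <- ga_cfg(seed = 5)
  cfg0$MG <- 0L
  e0 <- run_ga(std_datasets, std_M, std_world$platforms, cfg0)
  set.seed(5)
  pop <- init_population(identifier_universe(std_world$platforms),
                         std_datasets, std_M, std_world$platforms, cfg0)
  expect_identical(e0$llv, pop$elite$llv)
  expect_identical(attr(e0, "generations"), 0L)

  # GA elite matches the exhaustive optimum on the planted instance
  best <- exhaustive_search(std_datasets, std_M, std_world$platforms,
                            k = 2)
  elite <- run_ga(std_datasets, std_M, std_world$platforms,
                  ga_config(k = 2, PS = 30, MG = 25, seed = 7))
  expect_equal(elite$llv, best$llv, tolerance = 1e-9)
})
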