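test_that("end-gap-free alignment counts columns and mismatches", {
  al <- align_pair("ACGT", "ACGT")
  expect_equal(al$overlap, 4L)
  expect_equal(al$mismatches, 0L)

  # internal exact 4-mer aligns with free end gaps
  al <- align_pair("ACGTACGTAC", "GTAC")
  expect_equal(al$overlap, 4L)
  expect_equal(al$mismatches, 0L)

  # 100-mer vs a copy with exactly 10 substitutions: mismatch count is
  # known from the construction
  s <- random_dna(100, seed = 11)
  s10 <- mutate_n(s, 10, seed = 12)
  al <- align_pair(s, s10)
  expect_equal(al$overlap, 100L)
  expect_equal(al$mismatches, 10L)

  # N never matches, not even another N
  al <- align_pair("ACGTN", "ACGTN")
  expect_equal(al$matches, 4L)
  expect_equal(al$mismatches, 1L)

  expect_error(align_pair("", "ACGT"), "non-empty")
})

test_that("evolutionary distance follows the closed-form JC oracle", {
  expect_equal(evolutionary_distance("ACGTACGT", "ACGTACGT"), 0)

  # p = 0.1 over 100 columns
  s <- random_dna(100, seed = 21)
  d <- evolutionary_distance(s, mutate_n(s, 10, seed = 22))
  expect_equal(d, -0.75 * log(1 - 0.4 / 3), tolerance = 1e-9)
  expect_equal(d, 0.10732563, tolerance = 1e-7)

  # saturation boundary: p >= 0.75 clamps to 1
  s <- strsplit(random_dna(100, seed = 23), "")[[1]]
  m <- s
  m[1:75] <- vapply(m[1:75], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  expect_equal(evolutionary_distance(paste(s, collapse = ""),
                                     paste(m, collapse = "")), 1)

  # random pairs agree with the closed form evaluated on the alignment
  for (seed in 1:5) {
    a <- random_dna(80, seed = 100 + seed)
    b <- mutate_n(a, seed * 3, seed = 200 + seed)
    al <- align_pair(a, b)
    p <- al$mismatches / al$overlap
    expect_equal(evolutionary_distance(a, b),
                 min(max(-0.75 * log(1 - 4 * p / 3), 0), 1),
                 tolerance = 1e-9)
  }
})

test_that("distance matches an independent phylogenetic implementation", {
  skip_if_not_installed("ape")
  # isolated, evenly spaced substitutions keep the identity alignment
  # strictly optimal, so both routes compare the same columns
  for (seed in 1:4) {
    a <- random_dna(120, seed = 300 + seed)
    chars <- strsplit(a, "")[[1]]
    pos <- seq(10, 110, by = 36 %/% seed)
    set.seed(400 + seed)
    for (i in pos)
      chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1)
    b <- paste(chars, collapse = "")
    bin <- ape::as.DNAbin(list(a = strsplit(tolower(a), "")[[1]],
                               b = strsplit(tolower(b), "")[[1]]))
    ref <- as.numeric(ape::dist.dna(bin, model = "JC69"))
    expect_equal(evolutionary_distance(a, b), ref, tolerance = 1e-9)
  }
})

test_that("similarity is 1 - distance and monotone in substitutions", {
  s <- random_dna(150, seed = 31)
  expect_equal(probe_similarity(s, s), 1)
  d <- evolutionary_distance(s, mutate_n(s, 15, seed = 32))
  expect_equal(probe_similarity(s, mutate_n(s, 15, seed = 32)), 1 - d)

  # non-increasing in the number of substitutions applied to a copy
  sims <- vapply(c(0, 5, 15, 30, 60, 100),
                 function(n) probe_similarity(s, mutate_n(s, n, seed = 33)),
                 numeric(1))
  expect_true(all(diff(sims) <= 1e-12))
  expect_equal(sims[1], 1)
})

test_that("the all-pairs matrix is a valid symmetric bridge", {
  pls <- platform_list(
    platform("A", c("P1", "P2", "P3"), c("G1", "G1", "G3"),
             c(random_dna(60, 41), random_dna(60, 42),
               random_dna(60, 43))),
    platform("B", c("P1", "P2"), c("G1", "G2"),
             c(random_dna(60, 41), random_dna(60, 45))),
    platform("C", c("P1", "P2"), c("G2", "G3"),
             c(random_dna(60, 46), random_dna(60, 47))))
  M <- build_similarity_matrix(pls)
  expect_identical(dim(M$values), c(7L, 7L))
  expect_equal(max(abs(M$values - t(M$values))), 0, tolerance = 1e-12)
  expect_true(all(diag(M$values) == 1))
  expect_true(all(M$values >= 0 & M$values <= 1))
  # identical sequence shared across platforms: cross-platform entry 1
  expect_equal(sim_value(M, "A", "P1", "B", "P1"), 1)
  # determinism
  M2 <- build_similarity_matrix(pls)
  expect_identical(M$values, M2$values)
})

test_that("intra-gene similarity beats inter-gene similarity", {
  # two platforms, 100 shared genes; same-gene probes are lightly mutated
  # copies while different genes are unrelated random sequence
  set.seed(51)
  n_genes <- 100
  refs <- vapply(seq_len(n_genes), function(i) random_dna(60, 5000 + i),
                 character(1))
  mut <- vapply(seq_len(n_genes), function(i)
    mutate_n(refs[i], rbinom(1, 60, 0.02), seed = 6000 + i),
    character(1))
  genes <- sprintf("G%03d", seq_len(n_genes))
  pls <- platform_list(
    platform("A", paste0("a", seq_len(n_genes)), genes, refs),
    platform("B", paste0("b", seq_len(n_genes)), genes, mut))
  M <- build_similarity_matrix(pls)
  sm <- summarize_similarity(M, pls)
  gm <- sm$group_means
  expect_gt(gm$max[gm$group == "intra"], gm$max[gm$group == "inter"])
  expect_gt(sm$frac_best_same_gene, 0.9)
  expect_identical(sm$n_no_partner, 0L)
  # per-probe ordering invariant
  expect_true(all(sm$per_probe$max >= sm$per_probe$mean - 1e-12))
  expect_true(all(sm$per_probe$mean >= sm$per_probe$min - 1e-12))
})

test_that("degenerate gene sharing is flagged in the summary", {
  pls <- platform_list(
    platform("A", "P1", "G1", random_dna(40, 61)),
    platform("B", "P1", "G2", random_dna(40, 62)))
  M <- build_similarity_matrix(pls)
  sm <- summarize_similarity(M, pls)
  expect_false("intra" %in% sm$per_probe$group)
  expect_identical(sm$n_no_partner, 2L)
  expect_true(is.na(sm$frac_best_same_gene))

  # single shared gene with identical sequences: intra max is 1
  pls2 <- platform_list(
    platform("A", "P1", "G1", random_dna(40, 63)),
    platform("B", "P1", "G1", random_dna(40, 63)))
  sm2 <- summarize_similarity(build_similarity_matrix(pls2), pls2)
  expect_equal(sm2$per_probe$max[sm2$per_probe$group == "intra"],
               c(1, 1))
})
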