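test_that("simulated datasets are byte-identical under a fixed seed", {
  cfg <- coalescent_config(c(a = 10L, b = 10L), theta = 2, migration = 1,
                           L = 120)
  d1 <- simulate_dataset(cfg, seed = 99)
  d2 <- simulate_dataset(cfg, seed = 99)
  expect_identical(d1$alignment, d2$alignment)
  f1 <- tempfile(); f2 <- tempfile()
  write_fasta(d1$alignment, f1)
  write_fasta(d2$alignment, f2)
  expect_identical(readLines(f1), readLines(f2))
  d3 <- simulate_dataset(cfg, seed = 100)
  expect_false(identical(d1$alignment, d3$alignment))
})

test_that("single-deme simulator matches Watterson and pairwise expectations", {
  set.seed(423)
  cfg <- coalescent_config(c(d1 = 20L), theta = 5, migration = 0,
                           L = 570, merge_time = 0)
  stats <- replicate(800, {
    ds <- simulate_dataset(cfg)
    d <- pairwise_differences(ds$alignment)
    c(S = segregating_sites(ds$alignment)$S,
      K = mean(d[upper.tri(d)]))
  })
  a1 <- sum(1 / 1:19)
  expect_lt(abs(mean(stats["S", ]) - 5 * a1) / (5 * a1), 0.05)
  expect_lt(abs(mean(stats["K", ]) - 5) / 5, 0.07)
  # Watterson and pi estimators agree in expectation (paired t-test)
  theta_w <- stats["S", ] / a1
  expect_gt(t.test(theta_w - stats["K", ])$p.value, 0.01)
})

test_that("fixed-S generator places exactly S mutations", {
  for (i in 1:10) {
    r <- simulate_fixed_s(8, 1, seed = i)
    expect_identical(max(r$d), 1L)                 # one site splits the sample
    expect_true(any(r$d == 1L))
    expect_identical(r$k, 2L)
  }
  r <- simulate_fixed_s(88, 9, seed = 1)
  expect_identical(r, simulate_fixed_s(88, 9, seed = 1))
  # small negative bias of the fixed-S null at small S
  set.seed(424)
  D <- replicate(2000, simulate_fixed_s(88, 9, stats_only = TRUE)$D)
  expect_gt(mean(D), -0.2)
  expect_lt(mean(D), 0.1)
})

test_that("migration rate orders mean Phi-ST; isolation raises it", {
  set.seed(425)
  mean_phi <- vapply(c(0.1, 1, 10), function(M) {
    mean(replicate(20, {
      cfg <- coalescent_config(c(a = 10L, b = 10L, c = 10L), theta = 2,
                               migration = M, L = 400)
      ds <- simulate_dataset(cfg)
      d <- pairwise_differences(ds$alignment)
      am <- amova(d, ds$popmap, levels = 2, units = "subpopulation")
      unname(am$fixation["F_ST"])
    }))
  }, numeric(1))
  expect_true(all(diff(mean_phi) < 0))

  # with no migration, differentiation grows with divergence (merge) time
  set.seed(426)
  mean_iso <- vapply(c(0.5, 2, 8), function(tm) {
    mean(replicate(15, {
      cfg <- coalescent_config(c(a = 8L, b = 8L), theta = 2,
                               migration = 0, L = 400, merge_time = tm)
      ds <- simulate_dataset(cfg)
      d <- pairwise_differences(ds$alignment)
      pairwise_fst(d, ds$popmap, units = "subpopulation",
                   permutations = 0)$fst[1, 2]
    }))
  }, numeric(1))
  expect_true(all(diff(mean_iso) > 0))
  expect_error(coalescent_config(c(a = 5L, b = 5L), theta = 1,
                                 migration = 0),
               "isolated demes")
})

test_that("study fixture has the designed shape and expansion signature", {
  ds <- make_study_fixture(seed = 4)
  expect_identical(dim(ds$alignment), c(263L, 570L))
  expect_identical(length(unique(ds$popmap$subpopulation)), 9L)
  expect_identical(length(unique(ds$popmap$population)), 3L)
  expect_identical(as.vector(table(ds$popmap$population)[c("BMSA", "BEMB", "TLG")]),
                   c(88L, 88L, 87L))
  expect_identical(sort(unique(ds$popmap$group)),
                   c("rainforest", "savannah"))

  # expanded population shows more negative mean D across seeds
  popD <- sapply(1:20, function(s) {
    ds <- make_study_fixture(seed = s)
    vapply(c("BMSA", "BEMB", "TLG"), function(p) {
      idx <- ds$popmap$population == p
      m <- ds$alignment[idx, , drop = FALSE]
      S <- segregating_sites(m)$S
      if (S == 0) return(NA_real_)
      d <- pairwise_differences(m)
      tajimas_d(sum(idx), S, mean(d[upper.tri(d)]))
    }, numeric(1))
  })
  means <- rowMeans(popD, na.rm = TRUE)
  expect_lt(means["BMSA"], means["BEMB"])
  expect_lt(means["BMSA"], means["TLG"])
})

test_that("fixture Phi-ST is consistent with the island-model closed form", {
  # collapse to populations: cross-population lineage migration rate
  # M_b/2 = 1 per N generations = 3 per 3N generations; with d = 3 demes
  # of size 3N the expectation is 1/(1 + 2*Nm*(d/(d-1))) with 2Nm = 6
  expected <- 1 / (1 + 6 * 3 / 2)
  set.seed(427)
  phis <- sapply(1:12, function(s) {
    ds <- make_study_fixture(seed = s)
    d <- pairwise_differences(ds$alignment)
    f <- pairwise_fst(d, ds$popmap, permutations = 0)$fst
    f["BEMB", "TLG"]          # the two constant-size populations
  })
  se <- stats::sd(phis) / sqrt(length(phis))
  expect_lt(abs(mean(phis) - expected), 3 * se + 0.03)
})

test_that("simulated dataset files round-trip through the readers", {
  cfg <- coalescent_config(c(a = 6L, b = 6L), theta = 1.5, migration = 2,
                           L = 150)
  ds <- simulate_dataset(cfg, seed = 12)
  dir <- tempfile()
  write_sim_dataset(ds, dir)
  recs <- read_fasta(file.path(dir, "sequences.fa"))
  expect_identical(length(recs), 12L)
  expect_identical(alignment_matrix(recs), ds$alignment)
  pm <- read_popmap(file.path(dir, "popmap.tsv"), ids = names(recs))
  expect_identical(pm$subpopulation, ds$popmap$subpopulation)
  pars <- yaml::read_yaml(file.path(dir, "true_parameters.yaml"))
  expect_equal(pars$theta, 1.5)
  expect_equal(pars$seed, 12)
})
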