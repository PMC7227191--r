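test_that("two-level AMOVA reproduces the hand decomposition on TOY4", {
  d <- pairwise_differences(toy4_alignment())
  am <- amova(d, toy4_popmap(), levels = 2)
  st <- am$strata
  expect_equal(st$SS[st$source == "Total"], 1.75, tolerance = 1e-12)
  expect_equal(st$SS[st$source == "Within demes"], 0.5, tolerance = 1e-12)
  expect_equal(st$variance[st$source == "Among demes"], 0.5,
               tolerance = 1e-12)
  expect_equal(st$variance[st$source == "Within demes"], 0.25,
               tolerance = 1e-12)
  expect_equal(unname(am$fixation["F_ST"]), 2 / 3, tolerance = 1e-12)
  expect_identical(st$df[st$source == "Total"],
                   nrow(toy4_popmap()) - 1L)
})

test_that("AMOVA equals the explicit-loop oracle and sums percents to 100", {
  set.seed(411)
  for (i in 1:20) {
    ra <- random_alignment(sample(6:16, 1), sample(8:30, 1),
                           n_pops = sample(2:3, 1))
    d <- pairwise_differences(ra$aln)
    am <- amova(d, ra$popmap, levels = 2)
    want <- oracle_amova2(d, ra$popmap$population)
    st <- am$strata
    expect_equal(st$SS[1], want$ss_among, tolerance = 1e-9)
    expect_equal(st$SS[2], want$ss_within, tolerance = 1e-9)
    expect_equal(st$variance[1], want$Va, tolerance = 1e-9)
    expect_equal(st$variance[2], want$Vc, tolerance = 1e-9)
    expect_equal(unname(am$fixation["F_ST"]), want$phi_st,
                 tolerance = 1e-9)
    expect_equal(sum(st$pct_raw[-nrow(st)]), 100, tolerance = 0.1)
    expect_equal(sum(st$pct[-nrow(st)]), 100, tolerance = 0.1)
  }
})

test_that("three-level AMOVA percent variations sum to 100 and df to n-1", {
  ds <- make_study_fixture(seed = 21)
  d <- pairwise_differences(ds$alignment)
  am <- amova(d, ds$popmap, levels = 3)
  st <- am$strata
  expect_equal(sum(st$pct_raw[1:3]), 100, tolerance = 0.1)
  expect_identical(st$df[4], nrow(ds$alignment) - 1L)
  expect_true(all(st$SS >= -1e-9))
  expect_length(am$fixation, 3L)
  expect_error(amova(d, within(ds$popmap, group <- "one"), levels = 3,
                     groups = "group"),
               "degenerate design")
})

test_that("two-level Phi matches Hudson-style estimator on balanced toys", {
  d <- pairwise_differences(toy4_alignment())
  expect_equal(unname(amova(d, toy4_popmap(), levels = 2)$fixation),
               oracle_phist_hudson(d, toy4_popmap()$population),
               tolerance = 1e-9)
  set.seed(412)
  for (i in 1:10) {
    ra <- random_alignment(10, 20, n_pops = 2L)
    d <- pairwise_differences(ra$aln)
    got <- unname(amova(d, ra$popmap, levels = 2)$fixation)
    want <- oracle_phist_hudson(d, ra$popmap$population)
    expect_equal(got, want, tolerance = 1e-9)
  }
})

test_that("pairwise Phi-ST and its permutation p match exhaustive enumeration", {
  d <- pairwise_differences(toy4_alignment())
  pf <- pairwise_fst(d, toy4_popmap(), permutations = 10000, seed = 33)
  expect_equal(pf$fst["X", "Y"], 2 / 3, tolerance = 1e-12)
  exact <- oracle_exact_perm_p(d, toy4_popmap()$population)
  expect_equal(exact, 1 / 3, tolerance = 1e-12)
  se <- sqrt(exact * (1 - exact) / 10000)
  expect_lt(abs(pf$p["X", "Y"] - exact), 3 * se)

  # random toys with <= 8 individuals: Monte-Carlo within 3 SE of exact
  set.seed(413)
  for (i in 1:5) {
    ra <- random_alignment(8, 15, n_pops = 2L)
    dd <- pairwise_differences(ra$aln)
    pmc <- pairwise_fst(dd, ra$popmap, permutations = 4000,
                        seed = i)$p[1, 2]
    pex <- oracle_exact_perm_p(dd, ra$popmap$population)
    tol <- 3 * sqrt(max(pex * (1 - pex), 0.25 / 4000) / 4000) + 1e-9
    expect_lt(abs(pmc - pex), max(tol, 0.05))
  }
})

test_that("a population split at random into two shows Phi ~ 0, p large", {
  set.seed(414)
  ra <- random_alignment(20, 40, n_pops = 1L)
  pm <- ra$popmap
  pm$population <- pm$subpopulation <- rep(c("A", "B"), 10)
  d <- pairwise_differences(ra$aln)
  pf <- pairwise_fst(d, pm, permutations = 2000, seed = 3)
  expect_lt(abs(pf$fst["A", "B"]), 0.15)
  expect_gt(pf$p["A", "B"], 0.1)
})

test_that("island-model gene-flow conversion follows the printed formula", {
  expect_equal(nm_from_fst(0.5), 0.5, tolerance = 1e-12)
  expect_equal(nm_from_fst(0.152), (1 - 0.152) / (2 * 0.152),
               tolerance = 1e-12)
  expect_equal(round(nm_from_fst(0.152), 3), 2.789)
  expect_equal(nm_from_fst(1), 0, tolerance = 1e-12)
  expect_warning(na <- nm_from_fst(-0.01), "unbounded gene flow")
  expect_true(is.na(na))
  expect_error(nm_from_fst(1.2), "invalid")
})

test_that("apparent density is flies per trap per day", {
  expect_equal(apparent_density(70, 10, 7), 1)
  expect_equal(apparent_density(0, 10, 7), 0)
  expect_equal(round(apparent_density(1158, 10, 7), 2), 16.54)
  expect_error(apparent_density(10, 0, 7), "no trapping effort")
})

test_that("higher migration lowers pairwise Phi-ST (rank property)", {
  set.seed(415)
  mean_phi <- vapply(c(0.25, 1, 4), function(M) {
    vals <- replicate(25, {
      cfg <- coalescent_config(c(a = 12L, b = 12L), theta = 3,
                               migration = M, L = 300)
      ds <- simulate_dataset(cfg)
      d <- pairwise_differences(ds$alignment)
      pairwise_fst(d, ds$popmap, units = "subpopulation",
                   permutations = 0)$fst[1, 2]
    })
    mean(vals)
  }, numeric(1))
  expect_true(all(diff(mean_phi) < 0))
})
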