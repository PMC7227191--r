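test_that("mismatch spectrum tallies pair difference classes", {
  d <- pairwise_differences(toy4_alignment())
  sp <- mismatch_spectrum(d)
  expect_equal(as.numeric(sp), c(1 / 6, 1 / 2, 1 / 3), tolerance = 1e-12)
  expect_equal(sum(sp), 1, tolerance = 1e-12)
  expect_equal(attr(sp, "K"), 7 / 6, tolerance = 1e-12)

  same <- pairwise_differences(matrix("A", 5, 8))
  sp0 <- mismatch_spectrum(same)
  expect_equal(as.numeric(sp0), 1)

  set.seed(416)
  for (i in 1:10) {
    ra <- random_alignment(sample(4:12, 1), sample(6:25, 1))
    d <- pairwise_differences(ra$aln)
    sp <- mismatch_spectrum(d)
    expect_equal(as.numeric(sp), oracle_spectrum(d), tolerance = 1e-12)
    expect_equal(sum(sp), 1, tolerance = 1e-12)
    # spectrum mean equals K from the diversity module exactly
    expect_equal(attr(sp, "K"), summarize_diversity(ra$aln)$K,
                 tolerance = 1e-12)
  }
})

test_that("equilibrium mismatch law is geometric with mean theta", {
  f <- equilibrium_mismatch(1, 10)
  expect_equal(unname(f[1:3]), c(0.5, 0.25, 0.125), tolerance = 1e-12)
  expect_equal(as.numeric(equilibrium_mismatch(0, 5)),
               c(1, 0, 0, 0, 0, 0), tolerance = 1e-12)
  # infinite-series mass and truncation-corrected mean
  for (theta in c(0.5, 2, 5)) {
    jm <- ceiling(50 * theta)
    f <- equilibrium_mismatch(theta, jm)
    expect_equal(sum(f), 1, tolerance = 1e-6)
    expect_equal(sum(as.numeric(f) * (0:jm)), theta, tolerance = 1e-6)
  }
})

test_that("expansion law has the right limits", {
  th0 <- 0.5; th1 <- 40
  at0 <- expansion_mismatch(0, th0, th1, 30)
  expect_equal(as.numeric(at0),
               as.numeric(equilibrium_mismatch(th0, 30)), tolerance = 1e-9)
  old <- expansion_mismatch(500, th0, th1, 30)
  expect_equal(as.numeric(old),
               as.numeric(equilibrium_mismatch(th1, 30)), tolerance = 1e-6)
  flat <- expansion_mismatch(3, 2, 2, 30)
  expect_equal(as.numeric(flat),
               as.numeric(equilibrium_mismatch(2, 30)), tolerance = 1e-9)
})

test_that("raggedness matches hand values and is scale-free", {
  d <- pairwise_differences(toy4_alignment())
  expect_equal(raggedness(mismatch_spectrum(d)), 0.25, tolerance = 1e-12)
  expect_equal(raggedness(c(1)), 1, tolerance = 1e-12)    # point mass at 0
  # flat spectra get smoother as support grows
  rflat <- vapply(c(5, 10, 20, 40), function(k)
    raggedness(rep(1 / k, k)), numeric(1))
  expect_true(all(diff(rflat) < 0))
  # independent oracle on random spectra
  set.seed(417)
  for (i in 1:10) {
    x <- runif(sample(3:12, 1)); x <- x / sum(x)
    expect_equal(raggedness(x), oracle_raggedness(x), tolerance = 1e-12)
  }
})

test_that("sudden-expansion fit recovers parameters from exact spectra", {
  truth <- expansion_mismatch(3, 0.5, 50, 40)
  fit <- fit_sudden_expansion(truth / sum(truth), n = 50)
  expect_lt(fit$SSD, 1e-6)
  expect_lt(abs(fit$tau - 3), 0.5)

  # equilibrium input: no-expansion degeneracy (tau ~ 0 or theta0 ~ theta1)
  eq <- equilibrium_mismatch(2, 40, renormalize = TRUE)
  feq <- fit_sudden_expansion(eq, n = 50)
  expect_lt(feq$SSD, 1e-4)
  expect_true(feq$tau < 0.5 ||
                abs(feq$theta0 - feq$theta1) < 0.2 * feq$theta1)
})

test_that("fitted tau rank-orders with simulated expansion age", {
  set.seed(418)
  ages <- c(1, 4, 10)
  mean_tau <- vapply(ages, function(tau) {
    vals <- replicate(12, {
      sp <- mitopop:::sim_expansion_spectrum(40, tau, 0.5, 60)
      if (length(sp) < 2) return(NA_real_)
      fit_sudden_expansion(sp, 40)$tau
    })
    mean(vals, na.rm = TRUE)
  }, numeric(1))
  expect_true(all(diff(mean_tau) > 0))
})

test_that("bootstrap p-values detect misfit and are seed-reproducible", {
  # two clades ten mutations apart: maximally bimodal spectrum
  blockA <- matrix("A", 6, 30)
  blockB <- matrix("A", 6, 30)
  blockB[, 1:10] <- "T"
  m <- rbind(blockA, blockB)
  rownames(m) <- sprintf("t%02d", 1:12)
  set.seed(419)
  m[cbind(1:12, 25 + (1:12 %% 5))] <- "G"   # add light within-clade noise
  d <- pairwise_differences(m)
  fit <- fit_sudden_expansion(mismatch_spectrum(d), n = 12)
  fit <- mismatch_pvalues(fit, reps = 300, seed = 7)
  expect_lt(fit$p_SSD, 0.05)

  # determinism under a fixed seed
  sp <- mismatch_spectrum(pairwise_differences(toy4_alignment()))
  f1 <- mismatch_pvalues(fit_sudden_expansion(sp, 4), reps = 100, seed = 11)
  f2 <- mismatch_pvalues(fit_sudden_expansion(sp, 4), reps = 100, seed = 11)
  expect_identical(f1$p_SSD, f2$p_SSD)
  expect_identical(f1$p_r, f2$p_r)
  expect_error(mismatch_pvalues(fit, reps = 50), "insufficient replicates")
})

test_that("SSD p-values are roughly uniform under the fitted model", {
  set.seed(420)
  n <- 25
  ps <- replicate(25, {
    sp <- mitopop:::sim_expansion_spectrum(n, 3, 0.5, 25)
    if (length(sp) < 2) return(NA_real_)
    fit <- fit_sudden_expansion(sp, n)
    mismatch_pvalues(fit, reps = 100)$p_SSD
  })
  ps <- ps[!is.na(ps)]
  # calibration: not concentrated at either extreme
  expect_gt(mean(ps > 0.05), 0.6)
  expect_gt(stats::sd(ps), 0.1)
})
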