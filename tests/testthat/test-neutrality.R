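test_that("Tajima constants match hand arithmetic and the harmonic oracle", {
  c4 <- tajima_constants(4)
  expect_equal(c4$a1, 11 / 6, tolerance = 1e-12)
  expect_equal(c4$a2, 49 / 36, tolerance = 1e-12)
  expect_equal(c4$e1, 0.005510, tolerance = 1e-4)
  expect_equal(c4$e2, 0.002690, tolerance = 1e-4)
  expect_error(tajima_constants(2), "sample too small")
  expect_equal(tajima_constants(88)$a1, sum(1 / 1:87), tolerance = 1e-12)
  # a1 strictly increasing in n
  a1s <- vapply(4:30, function(n) tajima_constants(n)$a1, numeric(1))
  expect_true(all(diff(a1s) > 0))
})

test_that("Tajima's D matches the literal-formula oracle and hand values", {
  expect_equal(tajimas_d(4, 2, 7 / 6), 0.5916, tolerance = 1e-4)
  expect_equal(tajimas_d(4, 2, 7 / 6), oracle_tajima_d(4, 2, 7 / 6),
               tolerance = 1e-12)
  set.seed(406)
  for (i in 1:100) {
    n <- sample(4:200, 1)
    S <- sample(1:250, 1)
    K <- runif(1, 0, 20)
    expect_equal(tajimas_d(n, S, K), oracle_tajima_d(n, S, K),
                 tolerance = 1e-9)
  }
  expect_warning(D0 <- tajimas_d(10, 0, 0), "undefined")
  expect_true(is.na(D0))
})

test_that("log Stirling triangle reproduces exact integers for n <= 12", {
  for (n in c(1:8, 12)) {
    expect_equal(exp(log_stirling1(n)), oracle_stirling1(n),
                 tolerance = 1e-12)
  }
  # the documented recurrence holds on the log scale
  for (n in 3:12) {
    prev <- exp(log_stirling1(n - 1))
    cur <- exp(log_stirling1(n))
    expect_equal(cur, c(0, prev) + (n - 1) * c(prev, 0), tolerance = 1e-10)
  }
})

test_that("Ewens allele-count distribution is normalized", {
  for (n in c(10, 50, 100)) {
    for (theta in c(0.1, 1, 10)) {
      expect_equal(sum(exp(ewens_log_pmf(n, theta))), 1, tolerance = 1e-10)
    }
  }
})

test_that("Fu's Fs matches exact rational evaluation and Table-style inputs", {
  # n=4, k=3, theta=7/6: S' = (6 t^3 + t^4)/(t(t+1)(t+2)(t+3))
  t <- 7 / 6
  sp <- (6 * t^3 + t^4) / (t * (t + 1) * (t + 2) * (t + 3))
  got <- fu_fs(4, 3, t)
  expect_equal(got$S_prime, sp, tolerance = 1e-12)
  expect_equal(got$Fs, log(sp / (1 - sp)), tolerance = 1e-12)
  expect_equal(got$Fs, -0.658, tolerance = 1e-3)
  # haplotype-rich samples give negative Fs; haplotype-poor positive
  expect_lt(fu_fs(88, 25, 7.0867)$Fs, 0)
  expect_gt(fu_fs(88, 2, 7.0867)$Fs, 0)
  expect_error(fu_fs(10, 11, 1))
  expect_error(fu_fs(10, 3, 0))
})

test_that("simulation p-values are reproducible and validated", {
  expect_error(tajimas_d_pvalue(20, 5, -1, reps = 10), "insufficient replicates")
  expect_error(fu_fs_pvalue(20, 5, -1, reps = 10), "insufficient replicates")
  p1 <- tajimas_d_pvalue(20, 5, -1.2, reps = 200, seed = 9)
  p2 <- tajimas_d_pvalue(20, 5, -1.2, reps = 200, seed = 9)
  expect_identical(as.numeric(p1), as.numeric(p2))
  expect_gte(as.numeric(p1), 0)
  expect_lte(as.numeric(p1), 1)
})

test_that("fixed-S null is centred near zero and reacts to expansion", {
  set.seed(407)
  D <- replicate(2000, simulate_fixed_s(25, 8, stats_only = TRUE)$D)
  expect_gt(mean(D), -0.15)
  expect_lt(mean(D), 0.15)

  # strong recent expansion pushes D negative
  set.seed(408)
  cfg <- coalescent_config(c(d1 = 30L), theta = 4, migration = 0,
                           L = 570, merge_time = 0,
                           expansion = list(tau = 1, factor = 50))
  Dexp <- replicate(300, {
    ds <- simulate_dataset(cfg)
    m <- ds$alignment
    S <- segregating_sites(m)$S
    if (S == 0) return(NA_real_)
    d <- pairwise_differences(m)
    tajimas_d(nrow(m), S, mean(d[upper.tri(d)]))
  })
  expect_lt(mean(Dexp, na.rm = TRUE), -0.5)
})

test_that("Fu's Fs null rejection rate reflects its conservativeness", {
  set.seed(409)
  n <- 30; S <- 10
  null_stats <- replicate(600, {
    st <- simulate_fixed_s(n, S, stats_only = TRUE)
    fu_fs(n, st$k, st$K)$Fs
  })
  crit <- quantile(null_stats, 0.05, names = FALSE)
  fresh <- replicate(400, {
    st <- simulate_fixed_s(n, S, stats_only = TRUE)
    fu_fs(n, st$k, st$K)$Fs
  })
  expect_lte(mean(fresh <= crit), 0.12)   # ~5% by construction
})

test_that("neutrality_test wraps the statistics consistently", {
  set.seed(410)
  ra <- random_alignment(12, 40)
  out <- neutrality_test(ra$aln, reps = 150, seed = 5, unit = "u1")
  expect_identical(out$unit, "u1")
  d <- pairwise_differences(ra$aln)
  K <- mean(d[upper.tri(d)])
  expect_equal(out$K, K, tolerance = 1e-12)
  expect_equal(out$D, tajimas_d(12, out$S, K), tolerance = 1e-12)
  expect_true(out$p_D >= 0 && out$p_D <= 1)
  expect_true(out$p_Fs >= 0 && out$p_Fs <= 1)
})
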