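# Tajima's D and Fu's Fs, with p-values from a fixed-S coalescent null.

#' Tajima's test constants
#'
#' The closed-form normalizing constants of Tajima's D for a sample of
#' size n: a1, a2 (partial harmonic sums), b1, b2, c1, c2, e1, e2.
#'
#' @param n Sample size (>= 4).
#' @return Named list with the eight constants and n.
#' @export
tajima_constants <- function(n) {
  if (n < 4L) stop("sample too small for D: need n >= 4")
  i <- seq_len(n - 1L)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(n = n, a1 = a1, a2 = a2, b1 = b1, b2 = b2,
       c1 = c1, c2 = c2, e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D statistic
#'
#' Contrasts two estimators of the scaled mutation rate: the mean pairwise
#' difference K and Watterson's S/a1.
#' \deqn{D = (K - S/a_1) / \sqrt{e_1 S + e_2 S(S-1)}}
#' With no polymorphism (S = 0) the statistic is undefined and \code{NA}
#' is returned.
#'
#' @param n Sample size (>= 4).
#' @param S Number of segregating sites.
#' @param K Mean pairwise nucleotide differences.
#' @return D (numeric scalar; \code{NA_real_} when S = 0).
#' @export
tajimas_d <- function(n, S, K) {
  cst <- tajima_constants(n)
  if (S == 0L) {
    warning("Tajima's D undefined: no polymorphism (S = 0)")
    return(NA_real_)
  }
  (K - S / cst$a1) / sqrt(cst$e1 * S + cst$e2 * S * (S - 1))
}

#' Coalescent-simulation p-value for Tajima's D
#'
#' Empirical p-value of an observed D against the fixed-S neutral null:
#' constant-size coalescent genealogies of size n on which exactly S
#' mutations are dropped with probability proportional to branch length.
#' The default \code{tail = "lower"} reports \eqn{\Pr(D_{sim} \le
#' D_{obs})}, the convention of the simulation-based packages whose
#' published tables this reproduces; \code{"two.sided"} doubles the
#' smaller tail.
#'
#' @param n,S Sample size and segregating sites defining the null.
#' @param D_obs Observed statistic.
#' @param reps Number of coalescent replicates (>= 100).
#' @param seed Optional RNG seed for reproducibility.
#' @param tail \code{"lower"} (default) or \code{"two.sided"}.
#' @return p-value in [0, 1] with attributes \code{reps} and \code{seed}.
#' @export
tajimas_d_pvalue <- function(n, S, D_obs, reps = 10000L, seed = NULL,
                             tail = c("lower", "two.sided")) {
  tail <- match.arg(tail)
  if (reps < 100L) stop("insufficient replicates: need reps >= 100")
  set_local_seed(seed)
  Dnull <- replicate(reps, simulate_fixed_s(n, S, stats_only = TRUE)$D)
  p <- if (tail == "lower") {
    mean(Dnull <= D_obs)
  } else {
    min(1, 2 * min(mean(Dnull <= D_obs), mean(Dnull >= D_obs)))
  }
  structure(p, reps = reps, seed = seed)
}

# cache for the log-Stirling triangle (grown on demand)
.stirling_cache <- new.env(parent = emptyenv())

#' Unsigned Stirling numbers of the first kind (log scale)
#'
#' Row n of the triangle |S(n, k)|, k = 1..n, computed by the recurrence
#' |S(n,k)| = |S(n-1,k-1)| + (n-1) |S(n-1,k)| carried in log space so that
#' n in the hundreds is exact to double precision on the log scale.
#'
#' @param n Row index (>= 1).
#' @return Numeric vector of length n: \code{log(|S(n, 1..n)|)}.
#' @export
log_stirling1 <- function(n) {
  stopifnot(n >= 1L)
  rows <- .stirling_cache$rows
  if (is.null(rows)) rows <- list(`1` = 0)      # |S(1,1)| = 1
  m <- length(rows)
  if (n > m) {
    for (nn in (m + 1L):n) {
      prev <- rows[[nn - 1L]]
      rows[[nn]] <- log_add_exp(c(-Inf, prev) + 0,
                                log(nn - 1) + c(prev, -Inf))
    }
    .stirling_cache$rows <- rows
  }
  rows[[n]]
}

#' Ewens sampling-formula allele-count probabilities
#'
#' \deqn{P(K = k \mid n, \theta) = |S(n,k)| \theta^k / (\theta)_{(n)}}
#' with \eqn{(\theta)_{(n)}} the rising factorial, on the log scale.
#'
#' @param n Sample size.
#' @param theta Scaled mutation rate (> 0).
#' @return Numeric vector of log-probabilities for k = 1..n.
#' @export
ewens_log_pmf <- function(n, theta) {
  stopifnot(theta > 0)
  log_stirling1(n) + seq_len(n) * log(theta) -
    sum(log(theta + 0:(n - 1L)))
}

#' Fu's Fs statistic
#'
#' From the Ewens sampling formula, the tail probability of observing at
#' least the observed number of distinct haplotypes given the diversity
#' level \eqn{\hat\theta} (the mean pairwise difference K):
#' \deqn{S' = \Pr(K_{alleles} \ge k_{obs} \mid \hat\theta), \quad
#'       F_s = \ln\frac{S'}{1 - S'}}
#' Large haplotype counts relative to \eqn{\hat\theta} give small S' and
#' strongly negative Fs — the signature of demographic expansion.
#'
#' @param n Sample size.
#' @param k_obs Observed number of distinct haplotypes (1..n).
#' @param theta Positive diversity estimate (use K).
#' @return List with \code{Fs} and \code{S_prime}.  \code{Fs} is
#'   \code{NA_real_} when S' underflows to 0 or rounds to 1.
#' @export
fu_fs <- function(n, k_obs, theta) {
  stopifnot(k_obs >= 1L, k_obs <= n, theta > 0)
  lp <- ewens_log_pmf(n, theta)
  s_prime <- exp(log_sum_exp(lp[k_obs:n]))
  if (s_prime <= 0 || s_prime >= 1) {
    warning("Fs undefined: tail probability is numerically 0 or 1")
    return(list(Fs = NA_real_, S_prime = s_prime))
  }
  list(Fs = log(s_prime / (1 - s_prime)), S_prime = s_prime)
}

#' Coalescent-simulation p-value for Fu's Fs
#'
#' One-tailed p-value: the fraction of fixed-S neutral coalescent
#' replicates whose simulated Fs (computed from that replicate's own
#' haplotype count and mean pairwise difference) is at most the observed
#' value.
#'
#' @inheritParams tajimas_d_pvalue
#' @param Fs_obs Observed Fu's Fs.
#' @return p-value in [0, 1] with attributes \code{reps} and \code{seed}.
#' @export
fu_fs_pvalue <- function(n, S, Fs_obs, reps = 10000L, seed = NULL) {
  if (reps < 100L) stop("insufficient replicates: need reps >= 100")
  set_local_seed(seed)
  sims <- replicate(reps, {
    st <- simulate_fixed_s(n, S, stats_only = TRUE)
    if (st$K <= 0) NA_real_ else fu_fs(n, st$k, st$K)$Fs
  })
  p <- mean(sims <= Fs_obs, na.rm = TRUE)
  structure(p, reps = reps, seed = seed)
}

#' Neutrality tests for one alignment unit
#'
#' Computes S, K, Tajima's D and Fu's Fs for a gap-free alignment, with
#' optional simulation p-values.
#'
#' @param alignment Gap-free alignment matrix (n >= 4).
#' @param reps Replicates for the coalescent nulls (0 to skip p-values).
#' @param seed Optional seed for the nulls.
#' @param unit Unit label.
#' @return One-row data.frame: unit, n, S, K, D, p_D, Fs, S_prime, p_Fs,
#'   reps, seed.
#' @export
neutrality_test <- function(alignment, reps = 10000L, seed = NULL,
                            unit = "pooled") {
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  tab <- collapse_haplotypes(m)
  S <- segregating_sites(m)$S
  d <- pairwise_differences(m)
  K <- sum(d[upper.tri(d)]) * 2 / (n * (n - 1))
  D <- if (S > 0L) tajimas_d(n, S, K) else NA_real_
  fs <- if (K > 0) fu_fs(n, tab$h, K) else list(Fs = NA_real_,
                                                S_prime = NA_real_)
  p_D <- p_Fs <- NA_real_
  if (reps > 0L && S > 0L) {
    seeds <- derive_seeds(seed, 2L)
    p_D <- as.numeric(tajimas_d_pvalue(n, S, D, reps, seeds[[1L]]))
    if (is.finite(fs$Fs)) {
      p_Fs <- as.numeric(fu_fs_pvalue(n, S, fs$Fs, reps, seeds[[2L]]))
    }
  }
  data.frame(unit = unit, n = n, S = S, K = K, D = D, p_D = p_D,
             Fs = fs$Fs, S_prime = fs$S_prime, p_Fs = p_Fs,
             reps = reps, seed = if (is.null(seed)) NA_integer_ else seed,
             stringsAsFactors = FALSE)
}
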