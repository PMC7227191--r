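# Mismatch distributions, the sudden-expansion model, SSD and
# Harpending's raggedness with parametric-bootstrap p-values.

#' Observed mismatch spectrum
#'
#' Relative frequencies of pairwise difference counts over all C(n,2)
#' unordered sequence pairs.
#'
#' @param dist Pairwise difference matrix ([pairwise_differences()]).
#' @return Object of class \code{"mismatch_spectrum"}: numeric vector of
#'   frequencies named by difference class 0..d, with attributes
#'   \code{pairs} and \code{K} (spectrum mean).
#' @export
mismatch_spectrum <- function(dist) {
  n <- nrow(dist)
  if (is.null(n) || n < 2L) stop("insufficient sequences: need n >= 2")
  dd <- dist[upper.tri(dist)]
  dmax <- max(dd)
  x <- tabulate(dd + 1L, nbins = dmax + 1L) / length(dd)
  names(x) <- 0:dmax
  structure(x, pairs = length(dd), K = sum((0:dmax) * x),
            class = "mismatch_spectrum")
}

#' Equilibrium (stationary) mismatch distribution
#'
#' Under a constant-size neutral coalescent the number of differences
#' between two sequences is geometric:
#' \deqn{\hat F_j(\theta) = \theta^j / (\theta + 1)^{j+1}}
#'
#' @param theta Scaled mutation rate (>= 0).
#' @param j_max Largest difference class returned.
#' @param renormalize Fold the truncated tail mass back by renormalizing
#'   to sum 1 (recorded in the \code{renormalized} attribute).
#' @return Numeric vector of expected frequencies for classes 0..j_max.
#' @export
equilibrium_mismatch <- function(theta, j_max, renormalize = FALSE) {
  stopifnot(theta >= 0, j_max >= 0)
  j <- 0:j_max
  if (theta == 0) {
    f <- c(1, rep(0, j_max))
  } else {
    f <- exp(j * log(theta) - (j + 1) * log(theta + 1))
  }
  if (renormalize) f <- f / sum(f)
  names(f) <- j
  structure(f, renormalized = renormalize)
}

#' Expected mismatch distribution under sudden expansion
#'
#' The classical pure demographic-expansion law: a population at
#' stationarity with scaled size \eqn{\theta_0} grew instantaneously to
#' \eqn{\theta_1} at time \eqn{\tau} (in units of 1/(2u)) before the
#' present:
#' \deqn{F_j(\tau,\theta_0,\theta_1) = \hat F_j(\theta_1) +
#'   e^{-\tau/\theta_1} \sum_{i=0}^{j} \mathrm{Pois}(i;\tau)
#'   [\hat F_{j-i}(\theta_0) - \hat F_{j-i}(\theta_1)]}
#' which reduces to \eqn{\hat F_j(\theta_0)} at \eqn{\tau = 0} and to
#' \eqn{\hat F_j(\theta_1)} as \eqn{\tau \to \infty}.
#'
#' @param tau Expansion age in mutational units (>= 0).
#' @param theta0,theta1 Pre-/post-expansion scaled sizes (0 <= theta0,
#'   theta1 > 0).
#' @param j_max Largest difference class.
#' @return Expected frequencies for classes 0..j_max (not renormalized).
#' @export
expansion_mismatch <- function(tau, theta0, theta1, j_max) {
  stopifnot(tau >= 0, theta0 >= 0, theta1 > 0, j_max >= 0)
  f1 <- equilibrium_mismatch(theta1, j_max)
  f0 <- equilibrium_mismatch(theta0, j_max)
  w <- stats::dpois(0:j_max, tau)
  diff <- f0 - f1
  conv <- vapply(0:j_max, function(j)
    sum(w[1:(j + 1L)] * diff[(j + 1L):1L]), numeric(1L))
  out <- as.numeric(f1) + exp(-tau / theta1) * conv
  names(out) <- 0:j_max
  pmax(out, 0)
}

#' Harpending's raggedness index
#'
#' \deqn{r = \sum_{i=1}^{d+1} (x_i - x_{i-1})^2} with \eqn{x_{d+1} = 0};
#' small for the smooth unimodal spectra produced by demographic
#' expansion, large for ragged multimodal spectra.
#'
#' @param obs Mismatch spectrum (frequencies over classes 0..d).
#' @return r (numeric scalar).
#' @export
raggedness <- function(obs) {
  x <- c(as.numeric(obs), 0)
  sum(diff(x)^2)
}

# SSD between an observed spectrum and the model at (tau, theta0, theta1),
# both renormalized over a common support 0..d_cmp
ssd_objective <- function(par, obs, d_cmp) {
  f <- expansion_mismatch(par[1L], par[2L], par[3L], d_cmp)
  f <- f / sum(f)
  x <- c(as.numeric(obs), rep(0, d_cmp + 1L - length(obs)))
  sum((x - f)^2)
}

#' Fit the sudden-expansion model to a mismatch spectrum
#'
#' Least-squares fit of (tau, theta0, theta1) minimizing the sum of
#' squared deviations (SSD) between the observed spectrum and
#' [expansion_mismatch()], via a coarse grid search refined by
#' Nelder-Mead.  theta1 is capped at 10 times the largest observed
#' difference class (recorded in the result) to avoid the flat ridge at
#' theta1 -> infinity, and theta0 <= theta1 is enforced.
#'
#' @param obs A [mismatch_spectrum()] (or plain frequency vector over
#'   classes 0..d).
#' @param n Sample size the spectrum came from (carried into bootstrap).
#' @return Object of class \code{"mismatch_fit"}: tau, theta0, theta1,
#'   SSD, raggedness r, expected spectrum, convergence flag, theta1 cap.
#' @export
fit_sudden_expansion <- function(obs, n = NULL) {
  x <- as.numeric(obs)
  if (length(x) < 2L) stop("need a spectrum with >= 2 classes")
  d_obs <- length(x) - 1L
  Kobs <- sum((0:d_obs) * x) / sum(x)
  cap <- max(10 * d_obs, 1)
  tau_grid <- unique(pmin(c(0, 0.5, 1, 2, 4, 8, 16, Kobs, 2 * Kobs),
                          2 * cap))
  th0_grid <- c(0, 0.1, 0.5, 1, 2, 5)
  th1_grid <- unique(pmin(c(1, 5, 20, 50, 100, cap), cap))
  best <- NULL
  for (tau in tau_grid) for (t0 in th0_grid) for (t1 in th1_grid) {
    if (t0 > t1) next
    val <- ssd_objective(c(tau, t0, t1), x, max(d_obs, ceiling(tau) + 5L))
    if (is.null(best) || val < best$val) {
      best <- list(par = c(tau, t0, t1), val = val)
    }
  }
  # refine on a transformed scale keeping tau >= 0, 0 <= theta0 <= theta1 <= cap
  to_free <- function(p) c(log(p[1L] + 1e-6),
                           stats::qlogis(min(max(p[2L] / max(p[3L], 1e-6),
                                                 1e-6), 1 - 1e-6)),
                           stats::qlogis(min(max(p[3L] / cap, 1e-6),
                                             1 - 1e-6)))
  from_free <- function(q) {
    t1 <- stats::plogis(q[3L]) * cap
    c(max(exp(q[1L]) - 1e-6, 0), stats::plogis(q[2L]) * t1, t1)
  }
  opt <- stats::optim(to_free(best$par), function(q) {
    p <- from_free(q)
    ssd_objective(p, x, max(d_obs, ceiling(p[1L]) + 5L))
  }, method = "Nelder-Mead", control = list(maxit = 400L))
  par <- from_free(opt$par)
  converged <- opt$convergence == 0L
  if (opt$value > best$val) {        # fall back to the best grid point
    par <- best$par
    converged <- FALSE
  }
  d_cmp <- max(d_obs, ceiling(par[1L]) + 5L)
  expected <- expansion_mismatch(par[1L], par[2L], par[3L], d_cmp)
  expected <- expected / sum(expected)
  structure(list(tau = max(par[1L], 0), theta0 = par[2L], theta1 = par[3L],
                 SSD = min(opt$value, best$val),
                 r = raggedness(x),
                 observed = x, expected = expected,
                 n = n, theta1_cap = cap, converged = converged),
            class = "mismatch_fit")
}

#' @export
print.mismatch_fit <- function(x, ...) {
  cat(sprintf(
    "Sudden-expansion fit: tau = %.3f, theta0 = %.3f, theta1 = %.3f\n",
    x$tau, x$theta0, x$theta1))
  cat(sprintf("SSD = %.5f   raggedness r = %.5f\n", x$SSD, x$r))
  if (!is.null(x$p_SSD)) {
    cat(sprintf("P(SSD) = %.3f   P(r) = %.3f  (%d bootstrap reps)\n",
                x$p_SSD, x$p_r, x$reps))
  }
  if (!x$converged) cat("note: optimizer did not converge; grid optimum reported\n")
  invisible(x)
}

# one coalescent replicate under the fitted expansion model, returning its
# mismatch spectrum.  Present-day theta is theta1; before tau/theta1
# (coalescent units) the population is theta0/theta1 times the present size.
sim_expansion_spectrum <- function(n, tau, theta0, theta1) {
  hist <- NULL
  if (tau > 0 && theta0 < theta1) {
    hist <- data.frame(time = tau / theta1,
                       size = max(theta0 / theta1, 1e-4))
  }
  g <- sim_genealogy(n, hist)
  blen <- g$time[g$parent[seq_len(2L * n - 2L)]] - g$time[seq_len(2L * n - 2L)]
  nmut <- rpois(1L, theta1 * sum(blen) / 2)
  if (nmut == 0L) {
    return(structure(c(`0` = 1), pairs = n * (n - 1) / 2, K = 0,
                     class = "mismatch_spectrum"))
  }
  mut_branch <- sample.int(2L * n - 2L, nmut, replace = TRUE, prob = blen)
  ls <- leaf_sets(g)
  X <- ls[mut_branch, , drop = FALSE]
  storage.mode(X) <- "numeric"
  ci <- colSums(X)
  d <- outer(ci, ci, "+") - 2 * crossprod(X)
  mismatch_spectrum(round(d))
}

#' Parametric-bootstrap p-values for SSD and raggedness
#'
#' Simulates \code{reps} coalescent samples of size n under the fitted
#' (tau, theta0, theta1), refits each with the same grid/optimizer
#' settings, and reports the fraction of replicates whose SSD
#' (respectively raggedness) is at least the observed value.
#'
#' @param fit A [fit_sudden_expansion()] result.
#' @param n Sample size (defaults to \code{fit$n}).
#' @param reps Bootstrap replicates (>= 100).
#' @param seed Optional RNG seed.
#' @return The fit with \code{p_SSD}, \code{p_r}, \code{reps}, \code{seed}
#'   filled in.
#' @export
mismatch_pvalues <- function(fit, n = fit$n, reps = 1000L, seed = NULL) {
  stopifnot(inherits(fit, "mismatch_fit"))
  if (is.null(n)) stop("sample size n is required")
  if (reps < 100L) stop("insufficient replicates: need reps >= 100")
  set_local_seed(seed)
  sims <- vapply(seq_len(reps), function(i) {
    sp <- sim_expansion_spectrum(n, fit$tau, fit$theta0, fit$theta1)
    if (length(sp) < 2L) sp <- c(as.numeric(sp), 0)  # monomorphic replicate
    rf <- fit_sudden_expansion(sp, n)
    c(rf$SSD, raggedness(sp))
  }, numeric(2L))
  fit$p_SSD <- mean(sims[1L, ] >= fit$SSD - 1e-12)
  fit$p_r <- mean(sims[2L, ] >= fit$r - 1e-12)
  fit$reps <- reps
  fit$seed <- seed
  fit
}
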