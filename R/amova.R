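# Distance-based hierarchical AMOVA (Excoffier-style), pairwise Phi-ST
# with permutation significance, island-model gene-flow conversion and the
# trap-survey apparent-density index.

# block sums of a squared-distance matrix by a grouping factor:
# out[g1, g2] = sum of d2 over pairs (i in g1, j in g2)
block_sums <- function(d2, f) {
  w <- rowsum(d2, f, reorder = FALSE)
  t(rowsum(t(w), f, reorder = FALSE))
}

# core variance-component decomposition; f = deme factor, g = group factor
# (NULL for 2-level).  d2 is the matrix of squared intersequence distances.
amova_components <- function(d2, f, g = NULL) {
  N <- nrow(d2)
  f <- droplevels(as.factor(f))
  ss_within_units <- function(fac) {
    bs <- block_sums(d2, fac)
    sum(diag(bs) / (2 * as.vector(table(fac))))
  }
  ss_total <- sum(d2) / (2 * N)
  ss_wp <- ss_within_units(f)          # within demes
  np <- as.vector(table(f))
  P <- length(np)
  if (is.null(g)) {
    df <- c(P - 1L, N - P)
    ss <- c(ss_total - ss_wp, ss_wp)
    ms <- ss / df
    ncoef <- (N - sum(np^2) / N) / (P - 1L)
    sig_c <- ms[2L]
    sig_a <- (ms[1L] - sig_c) / ncoef
    list(df = df, ss = ss, sigma = c(a = sig_a, c = sig_c),
         n_coef = c(n = ncoef))
  } else {
    g <- droplevels(as.factor(g))
    G <- nlevels(g)
    ss_wg <- ss_within_units(g)        # within groups
    ss_ag <- ss_total - ss_wg
    ss_ap <- ss_wg - ss_wp
    df <- c(G - 1L, P - G, N - P)
    ss <- c(ss_ag, ss_ap, ss_wp)
    ms <- ss / df
    # unequal-size coefficients
    gl <- tapply(f, g, function(x) as.vector(table(droplevels(x))))
    ng <- as.vector(tapply(rep(1, N), g, sum))
    A <- sum(vapply(seq_along(gl),
                    function(i) sum(gl[[i]]^2) / ng[i], numeric(1)))
    n1 <- (N - A) / (P - G)
    n2 <- (A - sum(np^2) / N) / (G - 1L)
    n3 <- (N - sum(ng^2) / N) / (G - 1L)
    sig_c <- ms[3L]
    sig_b <- (ms[2L] - sig_c) / n1
    sig_a <- (ms[1L] - sig_c - n2 * sig_b) / n3
    list(df = df, ss = ss, sigma = c(a = sig_a, b = sig_b, c = sig_c),
         n_coef = c(n1 = n1, n2 = n2, n3 = n3))
  }
}

fixation_from_sigma <- function(sig) {
  tot <- sum(sig)
  if (length(sig) == 2L) {
    c(F_ST = unname(sig["a"] / tot))
  } else {
    c(F_CT = unname(sig["a"] / tot),
      F_SC = unname(sig["b"] / (sig["b"] + sig["c"])),
      F_ST = unname((sig["a"] + sig["b"]) / tot))
  }
}

#' Hierarchical analysis of molecular variance (AMOVA)
#'
#' Distance-based AMOVA on a matrix of pairwise nucleotide differences
#' (used as squared Euclidean distances).  The 2-level design partitions
#' variance among and within demes; the 3-level design adds a grouping of
#' demes (among groups / among demes within groups / within demes).
#' Fixation indices are \eqn{F_{CT} = V_a / V}, \eqn{F_{SC} = V_b /
#' (V_b + V_c)}, \eqn{F_{ST} = (V_a + V_b) / V}.
#'
#' Permutation p-values follow the classical three schemes: F_CT permutes
#' whole demes across groups, F_SC permutes individuals across demes
#' within their group, F_ST permutes individuals across demes regardless
#' of grouping.  P-values are tail proportions (no +1 correction), with
#' ties counted at tolerance 1e-12, so p = 0 is possible.
#'
#' @param dist Symmetric matrix of pairwise differences from
#'   [pairwise_differences()] (ids as dimnames).
#' @param popmap Popmap covering all ids.
#' @param levels 2 or 3.
#' @param units Popmap column holding the deme level (default
#'   \code{"subpopulation"} for 3-level, \code{"population"} for 2-level).
#' @param groups Popmap column holding the grouping for the 3-level design
#'   (default \code{"population"}).
#' @param permutations Number of permutations per index (0 = none).
#' @param seed Optional RNG seed.
#' @return Object of class \code{"amova"}: strata table (df, SS, variance
#'   components, raw and floored percent variation), fixation indices,
#'   permutation p-values, coefficients.
#' @export
amova <- function(dist, popmap, levels = 3L,
                  units = if (levels == 3L) "subpopulation" else "population",
                  groups = "population",
                  permutations = 0L, seed = NULL) {
  stopifnot(levels %in% c(2L, 3L))
  ids <- rownames(dist)
  popmap <- validate_popmap(popmap, ids)
  d2 <- dist
  storage.mode(d2) <- "numeric"
  f <- factor(popmap[[units]], levels = unique(popmap[[units]]))
  g <- NULL
  if (levels == 3L) {
    g <- factor(popmap[[groups]], levels = unique(popmap[[groups]]))
    if (nlevels(g) < 2L) stop("degenerate design: need >= 2 groups")
    if (nlevels(f) <= nlevels(g)) {
      stop("degenerate design: need more demes than groups")
    }
  } else if (nlevels(f) < 2L) {
    stop("degenerate design: need >= 2 demes")
  }
  if (any(table(f) < 1L)) stop("degenerate design: empty deme")
  comp <- amova_components(d2, f, g)
  fix <- fixation_from_sigma(comp$sigma)
  pct_raw <- 100 * comp$sigma / sum(comp$sigma)
  pos <- pmax(comp$sigma, 0)
  pct_floor <- 100 * pos / sum(pos)

  pvals <- setNames(rep(NA_real_, length(fix)), names(fix))
  if (permutations > 0L) {
    set_local_seed(seed)
    tol <- 1e-12
    if (levels == 2L) {
      null_fst <- replicate(permutations, {
        fp <- sample(f)
        fixation_from_sigma(amova_components(d2, fp)$sigma)["F_ST"]
      })
      pvals["F_ST"] <- mean(null_fst >= fix["F_ST"] - tol)
    } else {
      # F_ST: individuals across demes regardless of grouping (the group
      # of each deme is kept)
      deme_group <- tapply(as.integer(g), f, function(x) x[1L])
      null_st <- replicate(permutations, {
        fp <- sample(f)
        gp <- factor(levels(g)[deme_group[as.integer(fp)]],
                     levels = levels(g))
        fixation_from_sigma(amova_components(d2, fp, gp)$sigma)["F_ST"]
      })
      # F_SC: individuals across demes within their group
      idx_by_group <- split(seq_along(f), g)
      null_sc <- replicate(permutations, {
        fp <- f
        for (ix in idx_by_group) fp[ix] <- sample(fp[ix])
        fixation_from_sigma(amova_components(d2, fp, g)$sigma)["F_SC"]
      })
      # F_CT: whole demes across groups
      n_demes_per_group <- table(deme_group)
      null_ct <- replicate(permutations, {
        new_group <- sample(as.integer(deme_group))
        gp <- factor(levels(g)[new_group[as.integer(f)]],
                     levels = levels(g))
        fixation_from_sigma(amova_components(d2, f, gp)$sigma)["F_CT"]
      })
      pvals["F_ST"] <- mean(null_st >= fix["F_ST"] - tol)
      pvals["F_SC"] <- mean(null_sc >= fix["F_SC"] - tol)
      pvals["F_CT"] <- mean(null_ct >= fix["F_CT"] - tol)
    }
  }
  strata <- if (levels == 3L) {
    c("Among groups", "Among demes within groups", "Within demes")
  } else {
    c("Among demes", "Within demes")
  }
  structure(list(levels = levels,
                 strata = data.frame(
                   source = c(strata, "Total"),
                   df = c(comp$df, sum(comp$df)),
                   SS = c(comp$ss, sum(comp$ss)),
                   variance = c(comp$sigma, sum(comp$sigma)),
                   pct_raw = c(pct_raw, 100),
                   pct = c(pct_floor, 100),
                   stringsAsFactors = FALSE),
                 fixation = fix, p_values = pvals,
                 n_coefficients = comp$n_coef,
                 permutations = permutations, seed = seed),
            class = "amova")
}

#' @export
print.amova <- function(x, digits = 5, ...) {
  cat("AMOVA (", x$levels, "-level, distance-based)\n", sep = "")
  df <- x$strata
  df$SS <- round(df$SS, 3)
  df$variance <- round(df$variance, digits)
  df$pct <- round(df$pct, 2)
  print(df[, c("source", "df", "SS", "variance", "pct")], row.names = FALSE)
  for (nm in names(x$fixation)) {
    cat(sprintf("%s = %.5f", nm, x$fixation[nm]))
    if (!is.na(x$p_values[nm])) {
      cat(sprintf("  (P = %.4g, %d permutations)",
                  x$p_values[nm], x$permutations))
    }
    cat("\n")
  }
  invisible(x)
}

#' Pairwise Phi-ST between populations with permutation significance
#'
#' Each population pair's Phi-ST comes from a 2-level distance-based AMOVA
#' restricted to that pair; significance from permuting individuals
#' between the two populations.  \code{method = "haplotype"} replaces the
#' nucleotide-difference distance by the 0/1 different-haplotype
#' indicator, giving a haplotype-frequency-based F_ST.
#'
#' @param dist Pairwise difference matrix over all individuals.
#' @param popmap Popmap covering the ids.
#' @param units Popmap column defining the populations compared.
#' @param permutations Permutations per pair (default 10000).
#' @param seed Optional seed.
#' @param method \code{"distance"} (default) or \code{"haplotype"}.
#' @return Object of class \code{"pairwise_fst"}: matrices \code{fst},
#'   \code{p}, \code{nm} (island-model migrant estimates).
#' @export
pairwise_fst <- function(dist, popmap, units = "population",
                         permutations = 10000L, seed = NULL,
                         method = c("distance", "haplotype")) {
  method <- match.arg(method)
  ids <- rownames(dist)
  popmap <- validate_popmap(popmap, ids)
  d2 <- dist
  if (method == "haplotype") d2 <- (dist > 0) * 1
  storage.mode(d2) <- "numeric"
  f <- factor(popmap[[units]], levels = unique(popmap[[units]]))
  if (nlevels(f) < 2L) stop("need >= 2 populations")
  if (any(table(f) < 2L)) stop("insufficient sample: population with < 2 members")
  pops <- levels(f)
  P <- length(pops)
  fst <- p <- matrix(NA_real_, P, P, dimnames = list(pops, pops))
  seeds <- derive_seeds(seed, P * (P - 1L) / 2L)
  s <- 0L
  for (i in seq_len(P - 1L)) for (j in (i + 1L):P) {
    s <- s + 1L
    idx <- which(f %in% pops[c(i, j)])
    dd <- d2[idx, idx]
    ff <- droplevels(f[idx])
    obs <- fixation_from_sigma(amova_components(dd, ff)$sigma)["F_ST"]
    fst[i, j] <- fst[j, i] <- obs
    if (permutations > 0L) {
      set_local_seed(seeds[[s]])
      null <- replicate(permutations, {
        fp <- sample(ff)
        fixation_from_sigma(amova_components(dd, fp)$sigma)["F_ST"]
      })
      p[i, j] <- p[j, i] <- mean(null >= obs - 1e-12)
    }
  }
  diag(fst) <- 0
  nm <- suppressWarnings(apply(fst, c(1, 2), nm_from_fst))
  diag(nm) <- NA_real_
  structure(list(fst = fst, p = p, nm = nm, method = method,
                 permutations = permutations, seed = seed),
            class = "pairwise_fst")
}

#' @export
print.pairwise_fst <- function(x, ...) {
  cat("Pairwise Phi-ST (", x$method, " method, ",
      x$permutations, " permutations)\n", sep = "")
  print(round(x$fst, 4))
  if (!all(is.na(x$p))) {
    cat("P-values:\n")
    print(round(x$p, 4))
  }
  invisible(x)
}

#' Island-model gene flow from a fixation index
#'
#' For a haploid, maternally inherited marker under the island model,
#' \eqn{N_m = (1 - F_{ST}) / (2 F_{ST})} — the effective number of female
#' migrants per generation.
#'
#' @param fst Fixation index in (0, 1].
#' @return Nm.  \code{fst <= 0} returns \code{NA_real_} with a warning
#'   (gene flow unbounded); \code{fst > 1} is an error.
#' @export
nm_from_fst <- function(fst) {
  if (is.na(fst)) return(NA_real_)
  if (fst > 1) stop("invalid fixation index > 1")
  if (fst <= 0) {
    warning("unbounded gene flow: fst <= 0, Nm reported as NA")
    return(NA_real_)
  }
  (1 - fst) / (2 * fst)
}

#' Apparent density from a trap survey
#'
#' Flies per trap per day: \eqn{FTD = \Sigma F / (T \cdot D)}.
#'
#' @param total_flies Total flies caught.
#' @param traps Number of functioning traps.
#' @param days Trapping days.
#' @return FTD (numeric scalar).
#' @export
apparent_density <- function(total_flies, traps, days) {
  stopifnot(total_flies >= 0, traps >= 0, days >= 0)
  if (traps * days <= 0) stop("no trapping effort: traps x days is zero")
  total_flies / (traps * days)
}
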