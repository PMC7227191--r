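# Shared fixtures and independent brute-force oracles.
#
# TOY4: four 10 bp sequences, two populations (X: s1,s2; Y: s3,s4),
# variable at sites 5 and 10, pairwise differences
# d12=1 d13=2 d14=2 d23=1 d24=1 d34=0.

toy4_records <- function() {
  c(s1 = "ACGTAACGTA", s2 = "ACGTCACGTA",
    s3 = "ACGTCACGTG", s4 = "ACGTCACGTG")
}

toy4_alignment <- function() complete_deletion(toy4_records())

toy4_popmap <- function() {
  data.frame(sample_id = paste0("s", 1:4),
             subpopulation = c("X", "X", "Y", "Y"),
             population = c("X", "X", "Y", "Y"),
             group = "all", stringsAsFactors = FALSE)
}

toy4_fasta <- function(dir = tempdir()) {
  path <- file.path(dir, "toy4.fa")
  writeLines(c(">s1", "ACGTAACGTA", ">s2", "ACGTCACGTA",
               ">s3", "ACGTCACGTG", ">s4", "ACGTCACGTG"), path)
  path
}

toy4_popmap_tsv <- function(dir = tempdir()) {
  path <- file.path(dir, "toy4_popmap.tsv")
  write.table(toy4_popmap(), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  path
}

random_alignment <- function(n, L, n_pops = 2L, polymorphic = TRUE) {
  m <- matrix(sample(c("A", "C", "G", "T"), n * L, replace = TRUE,
                     prob = c(0.7, 0.1, 0.1, 0.1)),
              n, L, dimnames = list(sprintf("r%02d", seq_len(n)), NULL))
  if (polymorphic && all(apply(m, 2, function(x) length(unique(x))) == 1)) {
    m[1, 1] <- setdiff(c("A", "C", "G", "T"), m[1, 1])[1]
  }
  pops <- sort(rep_len(paste0("P", seq_len(n_pops)), n))
  pm <- data.frame(sample_id = rownames(m), subpopulation = pops,
                   population = pops, group = "all",
                   stringsAsFactors = FALSE)
  list(aln = m, popmap = pm)
}

# ---- independent oracles (naive double loops, literal formulas) --------

oracle_distances <- function(m) {
  n <- nrow(m)
  d <- matrix(0L, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    d[i, j] <- sum(m[i, ] != m[j, ])
  }
  d
}

oracle_diversity <- function(m) {
  n <- nrow(m)
  d <- oracle_distances(m)
  K <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) K <- K + d[i, j]
  K <- K * 2 / (n * (n - 1))
  seqs <- apply(m, 1, paste0, collapse = "")
  p <- as.vector(table(seqs)) / n
  Hd <- n * (1 - sum(p^2)) / (n - 1)
  S <- 0L
  for (j in seq_len(ncol(m))) if (length(unique(m[, j])) > 1) S <- S + 1L
  list(K = K, Pi = K / ncol(m), Hd = Hd, S = S, h = length(p))
}

# literal-formula Tajima's D (independent path from tajima_constants)
oracle_tajima_d <- function(n, S, K) {
  a1 <- sum(1 / seq_len(n - 1))
  a2 <- sum(1 / seq_len(n - 1)^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1
  e2 <- c2 / (a1^2 + a2)
  (K - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# exact integer Stirling numbers of the first kind, n small
oracle_stirling1 <- function(n) {
  s <- matrix(0, n + 1, n + 1)
  s[1, 1] <- 1          # |S(0,0)| = 1
  for (nn in seq_len(n)) {
    for (k in seq_len(nn)) {
      s[nn + 1, k + 1] <- s[nn, k] + (nn - 1) * s[nn, k + 1]
    }
  }
  s[n + 1, -1]          # |S(n, 1..n)|
}

# explicit-loop 2-level AMOVA on a difference matrix (Excoffier SS
# decomposition with unequal-size coefficient)
oracle_amova2 <- function(d, pops) {
  n <- length(pops)
  ss_total <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) ss_total <- ss_total + d[i, j]
  ss_total <- ss_total / n
  ss_within <- 0
  for (p in unique(pops)) {
    idx <- which(pops == p)
    np <- length(idx)
    if (np < 2) next
    s <- 0
    for (a in idx) for (b in idx) if (a < b) s <- s + d[a, b]
    ss_within <- ss_within + s / np
  }
  ss_among <- ss_total - ss_within
  P <- length(unique(pops))
  np2 <- sum(table(pops)^2)
  ncoef <- (n - np2 / n) / (P - 1)
  ms_among <- ss_among / (P - 1)
  ms_within <- ss_within / (n - P)
  va <- (ms_among - ms_within) / ncoef
  vc <- ms_within
  list(ss_total = ss_total, ss_among = ss_among, ss_within = ss_within,
       Va = va, Vc = vc, phi_st = va / (va + vc))
}

# Hudson-style Phi for two equal-sized populations:
# 1 - mean(within) / mean(between)
oracle_phist_hudson <- function(d, pops) {
  u <- unique(pops)
  stopifnot(length(u) == 2)
  within <- between <- c()
  n <- length(pops)
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (pops[i] == pops[j]) within <- c(within, d[i, j])
    else between <- c(between, d[i, j])
  }
  1 - mean(within) / mean(between)
}

oracle_spectrum <- function(d) {
  n <- nrow(d)
  v <- c()
  for (i in 1:(n - 1)) for (j in (i + 1):n) v <- c(v, d[i, j])
  counts <- sapply(0:max(v), function(k) sum(v == k))
  counts / length(v)
}

oracle_raggedness <- function(x) {
  x <- c(x, 0)
  r <- 0
  for (i in 2:length(x)) r <- r + (x[i] - x[i - 1])^2
  r
}

# exhaustive permutation p-value for a two-population Phi-ST
oracle_exact_perm_p <- function(d, pops) {
  n <- length(pops)
  obs <- oracle_amova2(d, pops)$phi_st
  perms <- combn(n, sum(pops == unique(pops)[1]))
  vals <- apply(perms, 2, function(idx) {
    pp <- rep(unique(pops)[2], n)
    pp[idx] <- unique(pops)[1]
    oracle_amova2(d, pp)$phi_st
  })
  mean(vals >= obs - 1e-12)
}
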