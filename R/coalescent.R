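# Haploid coalescent machinery: fixed-S neutral null genealogies and a
# structured (island-model) simulator with optional instantaneous
# expansion, emitting FASTA-writable alignments.
#
# Time is measured in haploid coalescent units of N generations per deme;
# mutations occur at rate theta/2 per lineage per unit time, so that the
# equilibrium expectation of the mean pairwise difference in one deme is
# theta and of S is theta * a1(n).

# Kingman topology for n lineages under piecewise-constant relative size.
# size_history: data.frame(time, size) of change points (size relative to
# the present = 1), sorted by time; NULL for constant size.
# Returns parent/time vectors; nodes 1..n are leaves, n+1..2n-1 internal.
sim_genealogy <- function(n, size_history = NULL) {
  n <- as.integer(n)
  parent <- integer(2L * n - 1L)
  time <- numeric(2L * n - 1L)
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  bp_times <- if (is.null(size_history)) numeric(0) else size_history$time
  bp_sizes <- if (is.null(size_history)) numeric(0) else size_history$size
  cur_size <- function(t) {
    if (!length(bp_times)) return(1)
    idx <- sum(bp_times <= t)
    if (idx == 0L) 1 else bp_sizes[idx]
  }
  while (length(active) > 1L) {
    k <- length(active)
    repeat {
      s <- cur_size(t)
      rate <- k * (k - 1) / 2 / s
      dt <- rexp(1L, rate)
      nb <- bp_times[bp_times > t]
      if (length(nb) && t + dt > nb[1L]) {
        t <- nb[1L]       # cross the size change point, redraw
      } else {
        t <- t + dt
        break
      }
    }
    pick <- sample.int(k, 2L)
    a <- active[pick[1L]]; b <- active[pick[2L]]
    parent[c(a, b)] <- nxt
    time[nxt] <- t
    active <- c(active[-pick], nxt)
    nxt <- nxt + 1L
  }
  list(parent = parent, time = time, n = n)
}

# descendant-leaf count below every node
leaf_counts <- function(g) {
  n <- g$n
  cnt <- c(rep(1L, n), integer(n - 1L))
  for (v in seq_len(2L * n - 2L)) cnt[g$parent[v]] <- cnt[g$parent[v]] + cnt[v]
  cnt
}

# logical (2n-1) x n matrix of leaf membership below every node
leaf_sets <- function(g) {
  n <- g$n
  ls <- matrix(FALSE, 2L * n - 1L, n)
  ls[cbind(seq_len(n), seq_len(n))] <- TRUE
  # parents are always created after their children, so ascending order works
  for (v in seq_len(2L * n - 2L)) ls[g$parent[v], ] <-
      ls[g$parent[v], ] | ls[v, ]
  ls
}

#' Simulate a neutral fixed-S coalescent replicate
#'
#' Constant-size Kingman genealogy of size n with exactly S mutations
#' placed on branches with probability proportional to branch length.
#' This is the null generator behind the Tajima's D and Fu's Fs p-values.
#'
#' @param n Sample size (>= 2; >= 4 for D).
#' @param S Number of segregating mutations (>= 1).
#' @param seed Optional RNG seed.
#' @param stats_only If TRUE (cheap path) return only the summary
#'   statistics S, K, k (haplotype count) and D; otherwise also the full
#'   pairwise difference matrix.
#' @return List with \code{S}, \code{K}, \code{k}, \code{D} and, unless
#'   \code{stats_only}, \code{d} (n x n integer difference matrix).
#' @export
simulate_fixed_s <- function(n, S, seed = NULL, stats_only = FALSE) {
  stopifnot(n >= 2L, S >= 1L)
  n <- as.integer(n); S <- as.integer(S)
  set_local_seed(seed)
  g <- sim_genealogy(n)
  blen <- g$time[g$parent[seq_len(2L * n - 2L)]] -
    g$time[seq_len(2L * n - 2L)]
  mut_branch <- sample.int(2L * n - 2L, S, replace = TRUE, prob = blen)
  cnt <- leaf_counts(g)
  c_m <- cnt[mut_branch]
  K <- sum(2 * c_m * (n - c_m)) / (n * (n - 1))
  # haplotype classes: connected components after cutting mutated branches
  par <- seq_len(2L * n - 1L)
  find <- function(x) { while (par[x] != x) { par[x] <<- par[par[x]]; x <- par[x] }; x }
  mut <- tabulate(mut_branch, nbins = 2L * n - 2L) > 0L
  for (v in seq_len(2L * n - 2L)) {
    if (!mut[v]) par[find(v)] <- find(g$parent[v])
  }
  k <- length(unique(vapply(seq_len(n), find, integer(1L))))
  D <- if (n >= 4L) tajimas_d(n, S, K) else NA_real_
  out <- list(S = S, K = K, k = k, D = D)
  if (!stats_only) {
    ls <- leaf_sets(g)
    X <- ls[mut_branch, , drop = FALSE]
    storage.mode(X) <- "numeric"
    ci <- colSums(X)
    d <- outer(ci, ci, "+") - 2 * crossprod(X)
    d[abs(d) < 1e-9] <- 0
    storage.mode(d) <- "integer"
    out$d <- d
  }
  out
}

#' Configuration for the structured coalescent simulator
#'
#' @param sample_sizes Named integer vector: sequences sampled per deme
#'   (names become subpopulation labels).
#' @param theta Scaled mutation rate per locus per deme (> 0); the
#'   equilibrium expectation of the within-deme mean pairwise difference.
#' @param migration Either a single scaled rate M (each lineage emigrates
#'   at rate M/2 to a uniformly chosen other deme) or a full deme x deme
#'   matrix of per-lineage jump rates.
#' @param L Locus length in bp (default 570).
#' @param expansion Optional instantaneous expansion:
#'   \code{list(tau =} expansion age in mutational units (2ut),
#'   \code{factor =} present/ancestral size ratio (> 1 for growth),
#'   \code{demes =} deme names affected (default all).  Before
#'   time \code{tau / theta} (coalescent units) the affected demes are
#'   \code{factor} times smaller.
#' @param deme_populations Optional named vector mapping deme ->
#'   population for a 3-level hierarchy (default: each deme is its own
#'   population).
#' @param deme_groups Likewise for population -> group.
#' @param merge_time Time (coalescent units) at which all demes merge into
#'   one ancestral pool; \code{Inf} requires migration > 0.
#' @return List of class \code{"coalescent_config"}.
#' @export
coalescent_config <- function(sample_sizes, theta, migration = 1,
                              L = 570L, expansion = NULL,
                              deme_populations = NULL, deme_groups = NULL,
                              merge_time = Inf) {
  stopifnot(theta > 0, all(sample_sizes >= 1L), L >= 1L)
  d <- length(sample_sizes)
  if (is.null(names(sample_sizes))) {
    names(sample_sizes) <- paste0("deme", seq_len(d))
  }
  if (is.matrix(migration)) {
    stopifnot(nrow(migration) == d, ncol(migration) == d,
              all(migration >= 0))
    mig <- migration
    diag(mig) <- 0
  } else {
    stopifnot(length(migration) == 1L, migration >= 0)
    mig <- matrix(if (d > 1L) migration / 2 / (d - 1L) else 0, d, d)
    diag(mig) <- 0
  }
  if (d > 1L && all(rowSums(mig) == 0) && !is.finite(merge_time)) {
    stop("isolated demes never coalesce: give migration > 0 or a finite merge_time")
  }
  if (!is.null(expansion)) {
    stopifnot(is.list(expansion), expansion$tau >= 0, expansion$factor > 0)
    if (is.null(expansion$demes)) expansion$demes <- names(sample_sizes)
  }
  pops <- deme_populations %||% setNames(names(sample_sizes),
                                         names(sample_sizes))
  grps <- deme_groups %||% setNames(rep("all", length(unique(pops))),
                                    unique(pops))
  structure(list(sample_sizes = sample_sizes, theta = theta, mig = mig,
                 L = as.integer(L), expansion = expansion,
                 deme_populations = pops, deme_groups = grps,
                 merge_time = merge_time),
            class = "coalescent_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# structured genealogy under the config; returns parent/time plus total
# branch length
sim_structured_genealogy <- function(cfg) {
  sizes <- cfg$sample_sizes
  d <- length(sizes)
  n <- as.integer(sum(sizes))
  parent <- integer(2L * n - 1L)
  time <- numeric(2L * n - 1L)
  deme_of <- rep(seq_len(d), sizes)        # per active lineage
  active <- seq_len(n)
  t <- 0
  nxt <- n + 1L
  exp_t <- if (is.null(cfg$expansion)) Inf else
    cfg$expansion$tau / cfg$theta
  exp_demes <- if (is.null(cfg$expansion)) integer(0) else
    match(cfg$expansion$demes, names(sizes))
  exp_factor <- if (is.null(cfg$expansion)) 1 else cfg$expansion$factor
  merged <- FALSE
  while (length(active) > 1L) {
    if (!merged && t >= cfg$merge_time) {
      deme_of[] <- 1L
      merged <- TRUE
    }
    # per-deme coalescent rates (ancestral demes are smaller before
    # (i.e. at times older than) the expansion -> faster coalescence)
    kd <- tabulate(deme_of, nbins = d)
    rate_mult <- rep(1, d)
    if (t >= exp_t) rate_mult[exp_demes] <- exp_factor
    coal_rate <- kd * (kd - 1) / 2 * rate_mult
    mig_rate <- if (merged) rep(0, d) else kd * rowSums(cfg$mig)
    R <- sum(coal_rate) + sum(mig_rate)
    crossings <- c(exp_t, cfg$merge_time)
    crossings <- crossings[is.finite(crossings) & crossings > t]
    if (R <= 0) {
      # nothing can happen until the next demographic event (e.g. all
      # demes down to one lineage before the ancestral merge)
      if (!length(crossings)) stop("internal: zero total event rate")
      t <- min(crossings)
      next
    }
    dt <- rexp(1L, R)
    if (length(crossings) && t + dt > min(crossings)) {
      t <- min(crossings)
      next
    }
    t <- t + dt
    ev <- sample.int(2L * d, 1L, prob = c(coal_rate, mig_rate))
    if (ev <= d) {                          # coalescence in deme ev
      in_deme <- which(deme_of == ev)
      pick <- in_deme[sample.int(length(in_deme), 2L)]
      a <- active[pick[1L]]; b <- active[pick[2L]]
      parent[c(a, b)] <- nxt
      time[nxt] <- t
      active <- c(active[-pick], nxt)
      deme_of <- c(deme_of[-pick], ev)
      nxt <- nxt + 1L
    } else {                                # migration out of deme ev - d
      src <- ev - d
      in_deme <- which(deme_of == src)
      lin <- in_deme[sample.int(length(in_deme), 1L)]
      deme_of[lin] <- sample.int(d, 1L, prob = cfg$mig[src, ])
    }
  }
  list(parent = parent, time = time, n = n,
       tmrca = t, tbl = sum(time[parent[seq_len(2L * n - 2L)]] -
                              time[seq_len(2L * n - 2L)]))
}

#' Simulate a structured-coalescent sequence dataset
#'
#' Generates a genealogy under the island model described by the config,
#' drops Poisson(theta * TBL / 2) mutations on branches (probability
#' proportional to length), assigns each mutation its own uniformly chosen
#' site (collisions re-drawn, i.e. sites are sampled without replacement)
#' and emits sequences from an all-A ancestral state with random
#' alternative alleles.
#'
#' @param config A [coalescent_config()].
#' @param seed Optional RNG seed; identical (config, seed) pairs reproduce
#'   the dataset exactly.
#' @return Object of class \code{"sim_dataset"}: list with
#'   \code{alignment} (character matrix), \code{popmap}, \code{config},
#'   \code{n_mutations}, \code{tmrca}, \code{total_branch_length}.
#' @export
simulate_dataset <- function(config, seed = NULL) {
  stopifnot(inherits(config, "coalescent_config"))
  set_local_seed(seed)
  g <- sim_structured_genealogy(config)
  n <- g$n
  L <- config$L
  blen <- g$time[g$parent[seq_len(2L * n - 2L)]] - g$time[seq_len(2L * n - 2L)]
  nmut <- rpois(1L, config$theta * g$tbl / 2)
  if (nmut > L) {
    stop("more mutations (", nmut, ") than sites (", L,
         "): increase L or decrease theta")
  }
  demes <- names(config$sample_sizes)
  ids <- unlist(mapply(function(nm, k)
    sprintf("%s_%03d", nm, seq_len(k)),
    demes, config$sample_sizes, SIMPLIFY = FALSE), use.names = FALSE)
  aln <- matrix("A", n, L, dimnames = list(ids, NULL))
  if (nmut > 0L) {
    mut_branch <- sample.int(2L * n - 2L, nmut, replace = TRUE, prob = blen)
    sites <- sample.int(L, nmut)            # distinct sites
    derived <- vapply(seq_len(nmut), function(i)
      sample(c("C", "G", "T"), 1L), character(1L))
    ls <- leaf_sets(g)
    for (i in seq_len(nmut)) {
      aln[ls[mut_branch[i], ], sites[i]] <- derived[i]
    }
  }
  subpop <- rep(demes, config$sample_sizes)
  pop <- unname(config$deme_populations[subpop])
  popmap <- data.frame(sample_id = ids,
                       subpopulation = subpop,
                       population = pop,
                       group = unname(config$deme_groups[pop]),
                       stringsAsFactors = FALSE)
  structure(list(alignment = aln, popmap = popmap, config = config,
                 n_mutations = nmut, tmrca = g$tmrca,
                 total_branch_length = g$tbl,
                 seed = seed),
            class = "sim_dataset")
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat("Simulated dataset:", nrow(x$alignment), "sequences x",
      ncol(x$alignment), "bp,", x$n_mutations, "mutations\n")
  cat("Demes:", paste(names(x$config$sample_sizes), collapse = ", "), "\n")
  invisible(x)
}

#' Write a simulated dataset (FASTA + popmap + true parameters)
#'
#' @param x A [simulate_dataset()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_dataset <- function(x, dir) {
  stopifnot(inherits(x, "sim_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(x$alignment, file.path(dir, "sequences.fa"))
  write_popmap(x$popmap, file.path(dir, "popmap.tsv"))
  cfg <- x$config
  yaml::write_yaml(list(theta = cfg$theta,
                        sample_sizes = as.list(cfg$sample_sizes),
                        L = cfg$L,
                        migration = as.vector(cfg$mig),
                        expansion = cfg$expansion,
                        seed = x$seed,
                        n_mutations = x$n_mutations,
                        tmrca = x$tmrca,
                        total_branch_length = x$total_branch_length),
                   file.path(dir, "true_parameters.yaml"))
  invisible(dir)
}

#' Study-shaped synthetic fixture
#'
#' A 3 population x 3 subpopulation design with sample sizes 88, 88 and 87
#' and a 570 bp locus, mirroring a riverine tsetse mtDNA survey: strong
#' gene flow among subpopulations within a population, restricted flow
#' between populations (expected pairwise Phi-ST roughly 0.05-0.15), and a
#' recent 10-fold expansion in one population.  Intended as the end-to-end
#' pipeline test input.
#'
#' @param seed RNG seed.
#' @return A [simulate_dataset()] result.
#' @export
make_study_fixture <- function(seed = 1L) {
  pops <- c("BMSA", "BEMB", "TLG")
  demes <- as.vector(outer(pops, 1:3, paste0))   # BMSA1.. order
  demes <- sort(demes)
  sizes <- setNames(rep(29L, 9L), demes)
  sizes[c("BMSA1", "BEMB1")] <- 30L              # 88, 88, 87
  popof <- setNames(sub("[0-9]$", "", demes), demes)
  m_within <- 10; m_between <- 2
  mig <- matrix(0, 9, 9, dimnames = list(demes, demes))
  for (i in seq_len(9)) for (j in seq_len(9)) {
    if (i == j) next
    same <- popof[i] == popof[j]
    mig[i, j] <- if (same) m_within / 2 / 2 else m_between / 2 / 6
  }
  cfg <- coalescent_config(
    sample_sizes = sizes, theta = 0.8, migration = mig, L = 570L,
    expansion = list(tau = 0.4, factor = 10,
                     demes = grep("^BMSA", demes, value = TRUE)),
    deme_populations = popof,
    deme_groups = setNames(c("savannah", "rainforest", "savannah"),
                           c("BEMB", "BMSA", "TLG")))
  simulate_dataset(cfg, seed = seed)
}
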