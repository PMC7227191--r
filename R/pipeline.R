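# End-to-end orchestration: FASTA + popmap -> report bundle.

#' Run the full mitochondrial population-genetics pipeline
#'
#' From a multi-FASTA of aligned same-locus sequences and a population
#' map, produces the complete report bundle: per-unit diversity indices,
#' neutrality tests, hierarchical AMOVA, pairwise Phi-ST with gene-flow
#' estimates, per-unit mismatch distributions with sudden-expansion fits,
#' the haplotype table and the median-joining network.
#'
#' Stages can be skipped by name (\code{"neutrality"}, \code{"amova"},
#' \code{"fst"}, \code{"mismatch"}, \code{"network"}); a MANIFEST file
#' records which outputs were written.  Indices are reported at 4 decimals
#' (D and Fs at 5) in the TSVs; full-precision copies go to
#' \code{full_precision/}.
#'
#' @param fasta Path to the FASTA file (alternatively pass an alignment
#'   via \code{alignment}).
#' @param popmap Path to the popmap TSV, or a popmap data.frame.
#' @param out_dir Output directory (created).
#' @param alignment Optional pre-loaded alignment matrix (overrides
#'   \code{fasta}).
#' @param units Unit levels for the per-unit statistics.
#' @param permutations Permutations for AMOVA / pairwise tests.
#' @param neutrality_reps Coalescent replicates for D / Fs p-values
#'   (0 disables the p-values).
#' @param bootstrap_reps Bootstrap replicates for mismatch p-values
#'   (0 disables them).
#' @param amova_groupings Named list of 3-level AMOVA designs; each entry
#'   is \code{c(units = <column>, groups = <column>)}.  The default runs
#'   the subpopulations-grouped-by-population design plus, when a
#'   non-trivial \code{group} column is present, subpopulations grouped by
#'   \code{group} (e.g. an ecological grouping).
#' @param seed RNG seed (mandatory when any stochastic stage is enabled).
#' @param skip Character vector of stage names to skip.
#' @return Invisibly, a list with every stage result and the output paths.
#' @export
run_pipeline <- function(fasta = NULL, popmap, out_dir,
                         alignment = NULL,
                         units = c("subpopulation", "population", "pooled"),
                         permutations = 10000L,
                         neutrality_reps = 10000L,
                         bootstrap_reps = 1000L,
                         amova_groupings = NULL,
                         seed = NULL, skip = character(0)) {
  stochastic <- permutations > 0L || neutrality_reps > 0L ||
    bootstrap_reps > 0L
  if (stochastic && is.null(seed)) {
    stop("seed is mandatory when a stochastic stage is enabled")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp_dir <- file.path(out_dir, "full_precision")
  dir.create(fp_dir, showWarnings = FALSE)
  manifest <- character(0)
  emit <- function(df, name, round_cols = NULL, digits = 4L) {
    write.table(df, file.path(fp_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
    if (!is.null(round_cols)) {
      for (cc in intersect(round_cols, names(df))) {
        df[[cc]] <- round(df[[cc]], digits)
      }
    }
    write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
    manifest <<- c(manifest, name)
  }
  stage <- function(name) !(name %in% skip)
  log_line <- function(...) message(sprintf(...))

  if (is.null(alignment)) {
    if (is.null(fasta)) stop("give either fasta or alignment")
    alignment <- alignment_matrix(read_fasta(fasta))
  }
  if (is.character(popmap) && length(popmap) == 1L) {
    popmap <- read_popmap(popmap)
  }
  aln <- complete_deletion(alignment)
  popmap <- validate_popmap(popmap, rownames(aln))
  log_line("pipeline: %d sequences, %d analyzable sites (seed %s)",
           nrow(aln), ncol(aln), if (is.null(seed)) "none" else seed)
  seeds <- derive_seeds(seed, 5L)
  results <- list(alignment = aln, popmap = popmap)

  tab <- collapse_haplotypes(aln, popmap)
  sharing <- classify_sharing(tab)
  results$haplotypes <- tab
  results$sharing <- sharing
  write_haplotype_table(tab, file.path(out_dir, "haplotypes.tsv"))
  manifest <- c(manifest, "haplotypes.tsv")

  div <- diversity_by_unit(aln, popmap, units)
  results$diversity <- div
  emit(div, "diversity.tsv", c("K", "Pi", "Hd"))

  dmat <- pairwise_differences(aln)
  results$distances <- dmat

  unit_subsets <- function() {
    out <- list()
    for (level in setdiff(units, "pooled")) {
      for (u in unique(popmap[[level]])) {
        idx <- popmap[[level]] == u
        if (sum(idx) >= 4L) out[[u]] <- which(idx)
      }
    }
    if ("pooled" %in% units) out$pooled <- seq_len(nrow(aln))
    out
  }

  if (stage("neutrality")) {
    rows <- list()
    sub <- unit_subsets()
    ns <- derive_seeds(seeds[[1L]], length(sub))
    for (i in seq_along(sub)) {
      rows[[i]] <- neutrality_test(aln[sub[[i]], , drop = FALSE],
                                   reps = neutrality_reps,
                                   seed = ns[[i]], unit = names(sub)[i])
    }
    neut <- do.call(rbind, rows)
    results$neutrality <- neut
    emit(neut, "neutrality.tsv", c("K", "D", "Fs", "S_prime"), 5L)
  }

  if (stage("amova")) {
    groupings <- amova_groupings
    if (is.null(groupings)) {
      groupings <- list(region = c(units = "subpopulation",
                                   groups = "population"))
      if (length(unique(popmap$group)) > 1L &&
          !identical(unname(popmap$group), unname(popmap$population))) {
        groupings$ecology <- c(units = "subpopulation", groups = "group")
      }
    }
    results$amova <- list()
    for (nm in names(groupings)) {
      gg <- groupings[[nm]]
      can3 <- length(unique(popmap[[gg[["groups"]]]])) >= 2L &&
        length(unique(popmap[[gg[["units"]]]])) >
          length(unique(popmap[[gg[["groups"]]]]))
      am <- if (can3) {
        amova(dmat, popmap, levels = 3L, units = gg[["units"]],
              groups = gg[["groups"]], permutations = permutations,
              seed = seeds[[2L]])
      } else {
        amova(dmat, popmap, levels = 2L, units = gg[["units"]],
              permutations = permutations, seed = seeds[[2L]])
      }
      results$amova[[nm]] <- am
      df <- am$strata
      df$fixation <- c(names(am$fixation),
                       rep("", nrow(df) - length(am$fixation)))
      df$index <- c(unname(am$fixation),
                    rep(NA_real_, nrow(df) - length(am$fixation)))
      df$p <- c(unname(am$p_values),
                rep(NA_real_, nrow(df) - length(am$p_values)))
      emit(df, paste0("amova_", nm, ".tsv"),
           c("SS", "variance", "pct_raw", "pct", "index", "p"))
    }
  }

  if (stage("fst")) {
    pf <- pairwise_fst(dmat, popmap, permutations = permutations,
                       seed = seeds[[3L]])
    results$fst <- pf
    wm <- function(m, name) {
      df <- data.frame(population = rownames(m), round(m, 4),
                       check.names = FALSE)
      write.table(df, file.path(out_dir, name), sep = "\t", quote = FALSE,
                  row.names = FALSE)
      manifest <<- c(manifest, name)
    }
    wm(pf$fst, "fst_matrix.tsv")
    if (!all(is.na(pf$p))) wm(pf$p, "fst_pvalues.tsv")
    wm(pf$nm, "nm.tsv")
  }

  if (stage("mismatch")) {
    dir.create(file.path(out_dir, "mismatch"), showWarnings = FALSE)
    sub <- unit_subsets()
    ms <- derive_seeds(seeds[[4L]], length(sub))
    rows <- list()
    for (i in seq_along(sub)) {
      u <- names(sub)[i]
      dd <- dmat[sub[[i]], sub[[i]]]
      sp <- mismatch_spectrum(dd)
      fit <- fit_sudden_expansion(sp, n = length(sub[[i]]))
      if (bootstrap_reps > 0L) {
        fit <- mismatch_pvalues(fit, reps = bootstrap_reps,
                                seed = ms[[i]])
      }
      results$mismatch[[u]] <- fit
      spec_df <- data.frame(class = seq_along(fit$observed) - 1L,
                            observed = fit$observed,
                            expected = fit$expected[seq_along(fit$observed)])
      write.table(spec_df, file.path(out_dir, "mismatch",
                                     paste0(u, ".csv")),
                  sep = ",", quote = FALSE, row.names = FALSE)
      manifest <- c(manifest, file.path("mismatch", paste0(u, ".csv")))
      rows[[i]] <- data.frame(unit = u, n = length(sub[[i]]),
                              tau = fit$tau, theta0 = fit$theta0,
                              theta1 = fit$theta1, SSD = fit$SSD,
                              p_SSD = fit$p_SSD %||% NA_real_,
                              r = fit$r, p_r = fit$p_r %||% NA_real_,
                              reps = bootstrap_reps)
    }
    emit(do.call(rbind, rows), "fit.tsv",
         c("tau", "theta0", "theta1", "SSD", "r"))
  }

  if (stage("network")) {
    net <- build_mjn(tab)
    results$network <- net
    export_network(net, file.path(out_dir, "network.graphml"), "graphml")
    export_network(net, file.path(out_dir, "network"), "tsv")
    manifest <- c(manifest, "network.graphml", "network.nodes.tsv",
                  "network.edges.tsv")
  }

  writeLines(c(sprintf("# mitopop %s", as.character(utils::packageVersion("mitopop"))),
               sprintf("seed: %s", if (is.null(seed)) "none" else seed),
               sprintf("permutations: %d", permutations),
               sprintf("neutrality_reps: %d", neutrality_reps),
               sprintf("bootstrap_reps: %d", bootstrap_reps),
               sprintf("skipped: %s",
                       if (length(skip)) paste(skip, collapse = ",") else "none"),
               "outputs:", paste0("  - ", manifest)),
             file.path(out_dir, "MANIFEST"))
  results$manifest <- manifest
  invisible(results)
}

#' Read a pipeline configuration YAML
#'
#' Flat-schema YAML with any of the [run_pipeline()] arguments
#' (\code{fasta}, \code{popmap}, \code{out_dir}, \code{units},
#' \code{permutations}, \code{neutrality_reps}, \code{bootstrap_reps},
#' \code{seed}, \code{skip}).
#'
#' @param path YAML file path.
#' @return Named list of arguments for [run_pipeline()].
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  allowed <- c("fasta", "popmap", "out_dir", "units", "permutations",
               "neutrality_reps", "bootstrap_reps", "seed", "skip")
  bad <- setdiff(names(cfg), allowed)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  cfg
}
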