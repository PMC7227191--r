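#' Pairwise nucleotide-difference matrix
#'
#' Exact Hamming difference counts between every pair of sequences,
#' computed over all sites of a gap-free alignment.  Internally uses
#' per-base indicator matrices and one cross-product per base, so it scales
#' to hundreds of sequences.
#'
#' @param alignment Gap-free alignment matrix (post [complete_deletion()]).
#' @return Symmetric integer matrix of difference counts with sequence ids
#'   as dimnames and attribute \code{L} (number of sites compared).
#' @export
pairwise_differences <- function(alignment) {
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  if (n < 2L) stop("insufficient sequences: need n >= 2")
  L <- ncol(m)
  matches <- matrix(0, n, n)
  for (b in c("A", "C", "G", "T")) {
    ind <- m == b
    storage.mode(ind) <- "numeric"
    matches <- matches + tcrossprod(ind)
  }
  d <- L - matches
  d[abs(d) < 1e-9] <- 0
  storage.mode(d) <- "integer"
  dimnames(d) <- list(rownames(m), rownames(m))
  attr(d, "L") <- L
  d
}

#' Diversity indices for one analysis unit
#'
#' Computes the classical summary of within-unit mitochondrial variation:
#' \itemize{
#' \item \code{K}: mean number of pairwise nucleotide differences,
#'   \eqn{K = \frac{2}{n(n-1)} \sum_{i<j} d_{ij}}
#' \item \code{Pi}: nucleotide diversity per site, \eqn{\pi = K / L}
#' \item \code{Hd}: haplotype (gene) diversity,
#'   \eqn{H_d = \frac{n}{n-1}(1 - \sum_i p_i^2)} with haplotype relative
#'   frequencies \eqn{p_i}
#' \item \code{S}: number of segregating sites.
#' }
#' Values are carried at full precision; use \code{round(x, 4)} for
#' report-style display.
#'
#' @param alignment Gap-free alignment matrix of the unit's sequences.
#' @param table Optional pre-computed [collapse_haplotypes()] result for
#'   the same alignment (recomputed if missing).
#' @param unit Label for the unit (default \code{"pooled"}).
#' @return One-row data.frame: unit, n, h, S, K, Pi, Hd.
#' @export
summarize_diversity <- function(alignment, table = NULL, unit = "pooled") {
  m <- alignment_matrix(alignment)
  n <- nrow(m)
  if (n < 2L) stop("insufficient sequences: need n >= 2")
  if (is.null(table)) table <- collapse_haplotypes(m)
  d <- pairwise_differences(m)
  K <- sum(d[upper.tri(d)]) * 2 / (n * (n - 1))
  p <- table$count / n
  Hd <- n * (1 - sum(p^2)) / (n - 1)
  data.frame(unit = unit, n = n, h = table$h,
             S = segregating_sites(m)$S,
             K = K, Pi = K / ncol(m), Hd = Hd,
             stringsAsFactors = FALSE)
}

#' Diversity indices for every analysis unit
#'
#' One row per subpopulation, per population, and for the pooled sample
#' (units with fewer than 2 sequences are skipped).
#'
#' @param alignment Gap-free alignment matrix.
#' @param popmap Popmap data.frame covering all rownames.
#' @param units Which unit levels to include.
#' @return data.frame with columns level, unit, n, h, S, K, Pi, Hd.
#' @export
diversity_by_unit <- function(alignment, popmap,
                              units = c("subpopulation", "population",
                                        "pooled")) {
  m <- alignment_matrix(alignment)
  popmap <- validate_popmap(popmap, rownames(m))
  units <- match.arg(units, several.ok = TRUE)
  out <- list()
  for (level in setdiff(units, "pooled")) {
    for (u in unique(popmap[[level]])) {
      idx <- popmap[[level]] == u
      if (sum(idx) < 2L) next
      row <- summarize_diversity(m[idx, , drop = FALSE], unit = u)
      out[[length(out) + 1L]] <- cbind(level = level, row)
    }
  }
  if ("pooled" %in% units) {
    out[[length(out) + 1L]] <-
      cbind(level = "pooled", summarize_diversity(m, unit = "pooled"))
  }
  do.call(rbind, out)
}
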