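# Median-joining haplotype network construction and export.

hamming_mat <- function(seqs) {
  m <- matrix(unlist(strsplit(seqs, "", fixed = TRUE), use.names = FALSE),
              nrow = length(seqs), byrow = TRUE)
  n <- length(seqs)
  d <- matrix(0L, n, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      d[i, j] <- d[j, i] <- sum(m[i, ] != m[j, ])
    }
  }
  d
}

# minimum spanning network with relaxation epsilon: process distinct edge
# weights ascending; an edge of weight w is kept when its endpoints lie in
# components that were still separate at weight level w - epsilon (for
# epsilon = 0: before processing weight w).  The result contains every MST.
msn_edges <- function(d, epsilon = 0L) {
  n <- nrow(d)
  if (n < 2L) return(matrix(integer(0), 0L, 3L,
                            dimnames = list(NULL, c("from", "to", "w"))))
  par <- seq_len(n)
  find <- function(x) { while (par[x] != x) { par[x] <<- par[par[x]]; x <- par[x] }; x }
  pairs <- which(upper.tri(d), arr.ind = TRUE)
  w <- d[upper.tri(d)]
  ord <- order(w)
  pairs <- pairs[ord, , drop = FALSE]
  w <- w[ord]
  keep <- logical(length(w))
  for (lev in unique(w)) {
    at_level <- which(w >= lev & w <= lev + epsilon)
    # connectivity state before merging this level
    comp_before <- vapply(seq_len(n), find, integer(1L))
    sel <- at_level[w[at_level] == lev]
    for (e in sel) {
      if (comp_before[pairs[e, 1L]] != comp_before[pairs[e, 2L]]) {
        keep[e] <- TRUE
      }
    }
    # with relaxation, also keep slightly heavier edges joining components
    # separate at this level
    if (epsilon > 0L) {
      for (e in at_level[w[at_level] > lev]) {
        if (comp_before[pairs[e, 1L]] != comp_before[pairs[e, 2L]]) {
          keep[e] <- TRUE
        }
      }
    }
    for (e in sel) par[find(pairs[e, 1L])] <- find(pairs[e, 2L])
  }
  cbind(from = pairs[keep, 1L], to = pairs[keep, 2L], w = w[keep])
}

# positionwise majority consensus of three sequences; ties broken towards
# the first sequence (each rotation of a triple is considered by the
# caller, so every pair sees a median on its geodesic)
median_sequence <- function(a, b, c) {
  sa <- strsplit(a, "", fixed = TRUE)[[1L]]
  sb <- strsplit(b, "", fixed = TRUE)[[1L]]
  sc <- strsplit(c, "", fixed = TRUE)[[1L]]
  out <- sa
  agree_bc <- sb == sc
  out[agree_bc] <- sb[agree_bc]
  # where a agrees with b or c, keep a (majority); where all differ, keep a
  paste0(out, collapse = "")
}

#' Median-joining haplotype network
#'
#' Bandelt-style construction: build the minimum spanning network (MSN,
#' relaxation \code{epsilon}) over the current node set; for connected
#' triplets compute majority-consensus median vectors; add the medians
#' whose connection cost is within \code{epsilon} of the best and that
#' reduce network cost; prune median vectors left with fewer than three
#' links; repeat to stability.  The final network always contains every
#' minimum spanning tree of the observed haplotypes (paths through median
#' vectors have equal total weight).
#'
#' @param table [collapse_haplotypes()] result (or a named character
#'   vector of haplotype sequences).
#' @param epsilon Non-negative integer relaxation (default 0, the usual
#'   software default).
#' @return Object of class \code{"haplotype_network"}: \code{nodes}
#'   data.frame (label, sequence, frequency, is_median, per-population
#'   counts) and \code{edges} data.frame (from, to, steps, positions).
#' @export
build_mjn <- function(table, epsilon = 0L) {
  stopifnot(epsilon >= 0L)
  if (inherits(table, "haplotype_table")) {
    seqs <- table$sequence
    labels <- table$haplotype
    freq <- table$count
    pop_counts <- table$pop_counts
  } else {
    seqs <- as.character(table)
    labels <- names(seqs) %||% paste0("H", seq_along(seqs))
    freq <- rep(1L, length(seqs))
    pop_counts <- NULL
  }
  h_obs <- length(seqs)
  nodes <- seqs
  is_median <- rep(FALSE, h_obs)
  n_mv <- 0L
  tried <- character(0)        # candidate medians already evaluated
  repeat {
    d <- hamming_mat(nodes)
    ed <- msn_edges(d, epsilon)
    if (nrow(ed) == 0L) break
    # adjacency for triple enumeration
    adj <- matrix(FALSE, length(nodes), length(nodes))
    adj[ed[, 1:2, drop = FALSE]] <- TRUE
    adj <- adj | t(adj)
    cand <- list()
    costs <- numeric(0)
    nn <- length(nodes)
    for (u in seq_len(nn - 1L)) for (v in (u + 1L):nn) {
      if (!adj[u, v]) next
      for (w in seq_len(nn)) {
        if (w == u || w == v) next
        if (!(adj[u, w] || adj[v, w])) next
        for (first in c(u, v, w)) {
          rest <- setdiff(c(u, v, w), first)
          m <- median_sequence(nodes[first], nodes[rest[1L]],
                               nodes[rest[2L]])
          if (m %in% nodes || m %in% tried || m %in% unlist(cand)) next
          dm <- c(sum_mismatch(m, nodes[u]), sum_mismatch(m, nodes[v]),
                  sum_mismatch(m, nodes[w]))
          cand[[length(cand) + 1L]] <- m
          costs <- c(costs, sum(dm))
        }
      }
    }
    if (!length(cand)) break
    tried <- c(tried, unlist(cand))
    lambda <- min(costs)
    keep <- costs <= lambda + epsilon
    new_m <- unlist(cand[keep])[order(costs[keep])]
    new_m <- new_m[!duplicated(new_m)]
    # admit medians one at a time, and only while the spanning cost of the
    # grown node set never exceeds the current one (so the final network
    # can only improve on the observed-haplotype MST)
    cur_cost <- msn_cost(d, epsilon)
    added <- character(0)
    for (m in new_m) {
      trial_cost <- msn_cost(hamming_mat(c(nodes, added, m)), epsilon)
      if (trial_cost <= cur_cost) {
        added <- c(added, m)
        cur_cost <- trial_cost
      }
    }
    if (!length(added)) break
    nodes <- c(nodes, added)
    is_median <- c(is_median, rep(TRUE, length(added)))
    # prune obsolete median vectors (degree < 3 in the refreshed MSN)
    repeat {
      d <- hamming_mat(nodes)
      ed <- msn_edges(d, epsilon)
      deg <- tabulate(c(ed[, 1L], ed[, 2L]), nbins = length(nodes))
      drop <- which(is_median & deg < 3L)
      if (!length(drop)) break
      nodes <- nodes[-drop]
      is_median <- is_median[-drop]
    }
  }
  d <- hamming_mat(nodes)
  ed <- msn_edges(d, epsilon)
  # guarantee MST containment for the observed haplotypes: any MST edge
  # not represented by an equal-weight path is added directly
  if (h_obs >= 2L) {
    mst <- msn_edges(hamming_mat(seqs), 0L)
    g <- igraph::graph_from_data_frame(
      data.frame(from = ed[, 1L], to = ed[, 2L], weight = ed[, 3L]),
      directed = FALSE,
      vertices = data.frame(name = seq_along(nodes)))
    for (e in seq_len(nrow(mst))) {
      u <- mst[e, 1L]; v <- mst[e, 2L]; w <- mst[e, 3L]
      sp <- igraph::distances(g, v = as.character(u),
                              to = as.character(v))[1L, 1L]
      if (!is.finite(sp) || sp > w + 1e-9) {
        ed <- rbind(ed, c(u, v, w))
        g <- igraph::add_edges(g, as.character(c(u, v)),
                               attr = list(weight = w))
      }
    }
  }
  n_mv <- sum(is_median)
  all_labels <- character(length(nodes))
  all_labels[!is_median] <- labels
  all_labels[is_median] <- paste0("mv", seq_len(n_mv))
  node_df <- data.frame(label = all_labels, sequence = nodes,
                        frequency = c(freq, rep(0L, n_mv)),
                        is_median = is_median, stringsAsFactors = FALSE)
  if (!is.null(pop_counts)) {
    pc <- rbind(pop_counts,
                matrix(0L, n_mv, ncol(pop_counts),
                       dimnames = list(NULL, colnames(pop_counts))))
    node_df <- cbind(node_df, pc)
  }
  edge_df <- data.frame(
    from = all_labels[ed[, 1L]], to = all_labels[ed[, 2L]],
    steps = ed[, 3L],
    positions = vapply(seq_len(nrow(ed)), function(i)
      paste(diff_positions(nodes[ed[i, 1L]], nodes[ed[i, 2L]]),
            collapse = ","), character(1L)),
    stringsAsFactors = FALSE)
  structure(list(nodes = node_df, edges = edge_df, epsilon = epsilon),
            class = "haplotype_network")
}

sum_mismatch <- function(a, b) {
  sum(strsplit(a, "", fixed = TRUE)[[1L]] !=
        strsplit(b, "", fixed = TRUE)[[1L]])
}

diff_positions <- function(a, b) {
  which(strsplit(a, "", fixed = TRUE)[[1L]] !=
          strsplit(b, "", fixed = TRUE)[[1L]])
}

# total weight of a spanning structure (an MST) at relaxation epsilon
msn_cost <- function(d, epsilon = 0L) {
  ed <- msn_edges(d, 0L)        # cost is judged on a strict MST
  if (!nrow(ed)) return(0)
  g <- igraph::graph_from_data_frame(
    data.frame(from = ed[, 1L], to = ed[, 2L], weight = ed[, 3L]),
    directed = FALSE, vertices = data.frame(name = seq_len(nrow(d))))
  sum(igraph::E(igraph::mst(g))$weight)
}

#' @export
print.haplotype_network <- function(x, ...) {
  nm <- sum(x$nodes$is_median)
  cat("Median-joining network:", nrow(x$nodes) - nm, "haplotypes,",
      nm, "median vectors,", nrow(x$edges), "edges (epsilon =",
      x$epsilon, ")\n")
  invisible(x)
}

#' Convert a haplotype network to an igraph object
#' @param net A [build_mjn()] result.
#' @return Undirected igraph graph with node and edge attributes.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "haplotype_network"))
  igraph::graph_from_data_frame(
    net$edges, directed = FALSE,
    vertices = cbind(name = net$nodes$label,
                     net$nodes[, setdiff(names(net$nodes), "label"),
                               drop = FALSE]))
}

#' Export a haplotype network
#'
#' Writes GraphML or DOT (via igraph), or a pair of flat TSV files
#' (\code{<path>.nodes.tsv} / \code{<path>.edges.tsv}).
#'
#' @param net A [build_mjn()] result.
#' @param path Output file path (base path for \code{"tsv"}).
#' @param format \code{"graphml"}, \code{"tsv"} or \code{"dot"}.
#' @return `path`, invisibly.
#' @export
export_network <- function(net, path, format = c("graphml", "tsv", "dot")) {
  format <- match.arg(format)
  if (format == "tsv") {
    write.table(net$nodes, paste0(path, ".nodes.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(net$edges, paste0(path, ".edges.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = format)
  }
  invisible(path)
}
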