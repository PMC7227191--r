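#' Collapse aligned sequences into haplotypes
#'
#' Identical (post-filter) sequences share a haplotype.  Haplotypes are
#' labelled \code{H1..Hh} in order of first occurrence in the alignment;
#' the labels carry no meaning beyond input order.
#'
#' @param alignment Gap-free character matrix from [complete_deletion()]
#'   (or any matrix over \code{A,C,G,T} with rownames).
#' @param popmap Optional popmap data.frame; when given, per-population and
#'   per-subpopulation counts are tabulated.
#' @return An object of class \code{"haplotype_table"}: a list with
#'   \itemize{
#'   \item \code{haplotype}: labels \code{H1..Hh}
#'   \item \code{sequence}: one residue string per haplotype
#'   \item \code{count}: total copies of each haplotype
#'   \item \code{members}: list of sample ids per haplotype
#'   \item \code{pop_counts}: haplotype x population count matrix
#'   \item \code{subpop_counts}: haplotype x subpopulation count matrix
#'   \item \code{n}, \code{h}: sequence and haplotype numbers
#'   }
#' @export
collapse_haplotypes <- function(alignment, popmap = NULL) {
  m <- alignment_matrix(alignment)
  if (is.null(rownames(m))) {
    rownames(m) <- sprintf("seq%03d", seq_len(nrow(m)))
  }
  seqs <- unname(apply(m, 1L, paste0, collapse = ""))
  ids <- rownames(m)
  key <- match(seqs, unique(seqs))       # first-occurrence order
  h <- max(key)
  lab <- paste0("H", seq_len(h))
  members <- split(ids, factor(key, levels = seq_len(h)))
  names(members) <- lab
  counts <- as.integer(lengths(members))

  pop_counts <- subpop_counts <- NULL
  if (!is.null(popmap)) {
    popmap <- validate_popmap(popmap, ids)
    tab <- function(col) {
      f <- factor(popmap[[col]], levels = unique(popmap[[col]]))
      t(vapply(members, function(mm)
        as.integer(table(f[match(mm, popmap$sample_id)])),
        integer(nlevels(f))))
    }
    pop_counts <- tab("population")
    subpop_counts <- tab("subpopulation")
    colnames(pop_counts) <- unique(popmap$population)
    colnames(subpop_counts) <- unique(popmap$subpopulation)
    if (is.null(dim(pop_counts))) pop_counts <- matrix(pop_counts, ncol = 1)
    rownames(pop_counts) <- rownames(subpop_counts) <- lab
  }
  structure(list(haplotype = lab,
                 sequence = unname(unique(seqs)),
                 count = counts,
                 members = members,
                 pop_counts = pop_counts,
                 subpop_counts = subpop_counts,
                 n = nrow(m), h = h),
            class = "haplotype_table")
}

#' @export
print.haplotype_table <- function(x, ...) {
  cat("Haplotype table:", x$h, "haplotypes among", x$n, "sequences\n")
  df <- data.frame(haplotype = x$haplotype, count = x$count)
  if (!is.null(x$pop_counts)) df <- cbind(df, x$pop_counts)
  print(head(df, 15L), row.names = FALSE)
  if (x$h > 15L) cat("...", x$h - 15L, "more\n")
  invisible(x)
}

#' Classify haplotypes as private or shared among populations
#'
#' A haplotype is \emph{private} when it is observed in exactly one
#' population and \emph{shared} otherwise.  With a single population every
#' haplotype is private by this definition.  Haplotypes with a single copy
#' overall are additionally flagged as singletons.
#'
#' @param table A [collapse_haplotypes()] result built with a popmap.
#' @return An object of class \code{"haplotype_sharing"}: list with a
#'   per-haplotype data.frame (\code{status}, presence pattern, singleton
#'   flag), per-population private counts, and the global percentage of
#'   private and shared haplotypes (2 decimals).
#' @export
classify_sharing <- function(table) {
  stopifnot(inherits(table, "haplotype_table"))
  pc <- table$pop_counts
  if (is.null(pc)) {
    pc <- matrix(table$count, ncol = 1, dimnames = list(table$haplotype, "all"))
  }
  present <- pc > 0L
  npops_with <- rowSums(present)
  status <- ifelse(npops_with == 1L, "private", "shared")
  pattern <- apply(present, 1L, function(r)
    paste(colnames(pc)[r], collapse = "+"))
  per_hap <- data.frame(haplotype = table$haplotype,
                        count = table$count,
                        status = status,
                        populations = pattern,
                        singleton = table$count == 1L,
                        stringsAsFactors = FALSE)
  private_by_pop <- colSums(present & npops_with == 1L)
  priv_pct <- round(100 * mean(status == "private"), 2)
  structure(list(per_haplotype = per_hap,
                 private_by_pop = private_by_pop,
                 private_pct = priv_pct,
                 shared_pct = round(100 - priv_pct, 2),
                 n_singletons = sum(per_hap$singleton)),
            class = "haplotype_sharing")
}

#' @export
print.haplotype_sharing <- function(x, ...) {
  cat(sprintf("Private haplotypes: %.2f%%  shared: %.2f%%  (singletons: %d)\n",
              x$private_pct, x$shared_pct, x$n_singletons))
  cat("Private per population:\n")
  print(x$private_by_pop)
  invisible(x)
}

#' Segregating (polymorphic) sites
#'
#' @param alignment Gap-free alignment matrix.
#' @return List with \code{S} (number of columns holding >= 2 distinct
#'   residues) and \code{positions} (1-based positions in the filtered
#'   alignment; \code{original_positions} maps back through the
#'   complete-deletion filter when available).
#' @export
segregating_sites <- function(alignment) {
  m <- alignment_matrix(alignment)
  poly <- which(apply(m, 2L, function(col) length(unique(col)) > 1L))
  ret <- attr(alignment, "retained_sites")
  list(S = length(poly),
       positions = poly,
       original_positions = if (!is.null(ret)) ret[poly] else poly)
}

#' Write a haplotype table with sharing status to TSV
#'
#' Columns: haplotype_id, sequence, total_count, one count column per
#' population, status.
#'
#' @param table [collapse_haplotypes()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_haplotype_table <- function(table, path) {
  sharing <- classify_sharing(table)
  df <- data.frame(haplotype_id = table$haplotype,
                   sequence = table$sequence,
                   total_count = table$count,
                   stringsAsFactors = FALSE)
  if (!is.null(table$pop_counts)) df <- cbind(df, table$pop_counts)
  df$status <- sharing$per_haplotype$status
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
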