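#' Read a multi-FASTA file of same-locus nucleotide sequences
#'
#' Reads a (wrapped or unwrapped) multi-FASTA file, uppercases residues and
#' validates identifiers.  Identifiers are the first whitespace-delimited
#' token of each header line.
#'
#' @param path Path to a FASTA file.
#' @return A named character vector of residue strings, in file order.
#'   Residues are uppercase over the IUPAC nucleotide alphabet
#'   (\code{A C G T}, ambiguity codes, \code{N}, \code{-}).
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">s1", "acgt", ">s2", "ACGA"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    stop("no sequences: file not found: ", path)
  }
  seqs <- withCallingHandlers(
    Biostrings::readDNAStringSet(path, format = "fasta"),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("invalid residue: non-IUPAC character in ", path, call. = FALSE)
      }
      invokeRestart("muffleWarning")
    }
  )
  if (length(seqs) == 0L) {
    stop("no sequences in ", path)
  }
  ids <- sub("\\s.*$", "", names(seqs))
  if (any(!nzchar(ids))) {
    stop("empty sequence identifier in ", path)
  }
  if (anyDuplicated(ids)) {
    stop("duplicate identifier: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  res <- toupper(as.character(seqs))
  names(res) <- ids
  res
}

#' Write sequences to FASTA
#'
#' @param x Named character vector of residue strings, or an alignment
#'   matrix as returned by [alignment_matrix()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  if (is.matrix(x)) x <- apply(x, 1L, paste0, collapse = "")
  dss <- Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(dss, filepath = path, width = 70L)
  invisible(path)
}

#' Assemble equal-length sequence records into an alignment matrix
#'
#' Sequences must already be aligned (equal length); no alignment is
#' attempted here.
#'
#' @param records Named character vector as returned by [read_fasta()].
#' @return Character matrix (sequences x sites) with rownames set to the
#'   sequence identifiers.
#' @export
alignment_matrix <- function(records) {
  if (is.matrix(records)) return(records)
  stopifnot(is.character(records), length(records) >= 1L)
  if (is.null(names(records)) || any(!nzchar(names(records)))) {
    stop("records must be named by sequence identifier")
  }
  len <- nchar(records)
  if (length(unique(len)) != 1L) {
    stop("sequences are of unequal length; inputs must be pre-aligned")
  }
  m <- matrix(unlist(strsplit(records, "", fixed = TRUE), use.names = FALSE),
              nrow = length(records), ncol = len[1L], byrow = TRUE)
  rownames(m) <- names(records)
  m
}

#' Complete-deletion site filtering
#'
#' Removes every alignment column that contains, in any sequence, a
#' character other than \code{A}, \code{C}, \code{G} or \code{T} — i.e.
#' gaps, \code{N} and IUPAC ambiguity codes are all treated as missing data
#' and their sites are deleted globally.  Retained original site positions
#' (1-based) are recorded in the \code{"retained_sites"} attribute.
#'
#' @param x Alignment matrix or named character vector of equal-length
#'   sequences.
#' @return Filtered character matrix over \code{\{A,C,G,T\}} with attribute
#'   \code{retained_sites}.
#' @export
complete_deletion <- function(x) {
  m <- alignment_matrix(x)
  prev <- attr(m, "retained_sites")
  keep_col <- apply(m, 2L, function(col) all(col %in% c("A", "C", "G", "T")))
  if (!any(keep_col)) {
    stop("no analyzable sites: every column contains a gap or ambiguity")
  }
  out <- m[, keep_col, drop = FALSE]
  rownames(out) <- rownames(m)
  attr(out, "retained_sites") <-
    if (is.null(prev)) which(keep_col) else prev[keep_col]
  out
}

#' Read a population map
#'
#' Reads the tab-separated hierarchy file with header
#' \code{sample_id<TAB>subpopulation<TAB>population<TAB>group} assigning
#' each sequence to the three-level sampling hierarchy (trapping site,
#' locality, region/ecozone).
#'
#' @param path Path to the TSV file.
#' @param ids Optional character vector of sequence identifiers that must
#'   all be present in the map (typically \code{names(read_fasta(...))}).
#' @return A data.frame with columns \code{sample_id}, \code{subpopulation},
#'   \code{population}, \code{group}.
#' @export
read_popmap <- function(path, ids = NULL) {
  pm <- read.delim(path, header = TRUE, sep = "\t",
                   colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "subpopulation", "population", "group")
  if (!all(need %in% names(pm))) {
    stop("popmap must have columns: ", paste(need, collapse = ", "))
  }
  pm <- pm[, need]
  validate_popmap(pm, ids)
}

#' Build a population map from sample-code prefixes
#'
#' Convenience constructor for sample codes whose leading alphabetic prefix
#' encodes the locality of origin (e.g. \code{BMSA65}, \code{TLG103}).
#' Subpopulation defaults to the population and all samples fall in one
#' group.
#'
#' @param ids Character vector of sample codes.
#' @param group Single group label (default \code{"all"}).
#' @return A popmap data.frame (see [read_popmap()]).
#' @export
popmap_from_prefix <- function(ids, group = "all") {
  pop <- sub("^([A-Za-z]+).*$", "\\1", ids)
  validate_popmap(data.frame(sample_id = ids, subpopulation = pop,
                             population = pop, group = group,
                             stringsAsFactors = FALSE), ids)
}

# shared popmap validation: total mapping and hierarchy consistency
validate_popmap <- function(pm, ids = NULL) {
  if (anyDuplicated(pm$sample_id)) {
    stop("duplicate identifier in popmap: ",
         paste(unique(pm$sample_id[duplicated(pm$sample_id)]), collapse = ", "))
  }
  if (!is.null(ids)) {
    missing <- setdiff(ids, pm$sample_id)
    if (length(missing)) {
      stop("missing assignment for: ", paste(missing, collapse = ", "))
    }
    pm <- pm[match(ids, pm$sample_id), , drop = FALSE]
    rownames(pm) <- NULL
  }
  sp <- unique(pm[, c("subpopulation", "population")])
  if (anyDuplicated(sp$subpopulation)) {
    stop("inconsistent hierarchy: subpopulation assigned to >1 population")
  }
  pg <- unique(pm[, c("population", "group")])
  if (anyDuplicated(pg$population)) {
    stop("inconsistent hierarchy: population assigned to >1 group")
  }
  pm
}

#' Write a population map to TSV
#' @param pm Popmap data.frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_popmap <- function(pm, path) {
  write.table(pm, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
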