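#' Progressive multiple alignment
#'
#' Aligns the records with MAFFT (progressive alignment on a k-mer
#' distance guide tree, with iterative refinement disabled for
#' determinism). Residues are never edited: de-gapping any output row
#' reproduces the input sequence exactly.
#'
#' @param records a [seq_tbl] of one molecule type (>= 1 row).
#' @return The records with gapped `residues` of equal length, row order
#'   preserved.
#' @export
progressive_align <- function(records) {
  stopifnot(nrow(records) >= 1L)
  if (nrow(records) == 1L) return(as_alignment(records))
  if (Sys.which("mafft") == "") stop("mafft executable not found on PATH")
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  writeLines(paste0(">", records$id, "\n", records$residues), fin)
  status <- system2("mafft", c("--quiet", "--retree", "2", fin),
                    stdout = fout, stderr = FALSE)
  if (status != 0L) stop("mafft failed with status ", status)
  set <- Biostrings::readBStringSet(fout)
  aligned <- toupper(as.character(set))
  names(aligned) <- sub("\\s.*$", "", names(set))
  out <- records
  out$residues <- unname(aligned[records$id])
  as_alignment(out)
}

#' Remove gap-rich alignment columns
#'
#' Deletes columns whose gap fraction is at or above the threshold
#' (default 0.15: a column gapped in 15% or more of the rows is removed).
#'
#' @param alignment an alignment [seq_tbl].
#' @param max_gap_fraction removal threshold (inclusive).
#' @return The filtered alignment, row order preserved.
#' @export
filter_gap_columns <- function(alignment, max_gap_fraction = 0.15) {
  m <- aln_matrix(alignment)
  gap_frac <- colMeans(m == "-")
  keep <- gap_frac < max_gap_fraction
  if (!any(keep)) stop("empty alignment after filtering")
  aln_from_matrix(m[, keep, drop = FALSE], alignment)
}

#' Remove short alignment rows
#'
#' Drops partial sequences: rows whose non-gap residue count is below
#' `min_fraction` of the alignment width (a row at exactly the threshold
#' is kept).
#'
#' @param alignment an alignment [seq_tbl].
#' @param min_fraction required non-gap fraction of the alignment width.
#' @return The filtered alignment.
#' @export
drop_short_rows <- function(alignment, min_fraction = 0.75) {
  m <- aln_matrix(alignment)
  frac <- rowMeans(m != "-")
  keep <- frac >= min_fraction
  if (sum(keep) < 2L) stop("fewer than 2 rows remain after filtering")
  alignment[keep, , drop = FALSE]
}
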