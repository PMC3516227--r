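STOP_CODONS <- c("TAA", "TAG", "TGA")

translate_codons <- function(codons) {
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X"
  unname(aa)
}

# residues from a seq_tbl row, a single string, or a consensus profile
one_sequence <- function(x) {
  if (inherits(x, "consensus_profile")) return(x$consensus)
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    return(x$residues)
  }
  stopifnot(is.character(x), length(x) == 1L)
  toupper(x)
}

#' Locate the longest open reading frame
#'
#' Scans all three frames on both strands for the longest ATG-to-stop
#' reading frame of at least `min_codons` codons (start and stop included).
#' The interval is reported in 0-based half-open coordinates on the input
#' strand; for minus-strand ORFs the interval still refers to forward
#' coordinates. Ties prefer the plus strand, then the smaller start.
#'
#' @param x a nucleotide sequence (string or single-row [seq_tbl]).
#' @param min_codons minimum ORF length in codons.
#' @return A list with `start`, `end` (0-based half-open; both `NA` when no
#'   ORF qualifies), `frame` (0-2), `strand` (`"+"`/`"-"`), `intact`
#'   (logical: a qualifying stop-terminated ORF exists), and `n_codons`.
#' @export
locate_orf <- function(x, min_codons = 100L) {
  s <- one_sequence(x)
  best <- NULL
  n <- nchar(s)
  for (strand in c("+", "-")) {
    str <- if (strand == "+") s else revcomp(s)
    for (frame in 0:2) {
      ncod <- (nchar(str) - frame) %/% 3L
      if (ncod < 1L) next
      starts <- frame + 3L * (seq_len(ncod) - 1L) + 1L
      codons <- substring(str, starts, starts + 2L)
      is_stop <- codons %in% STOP_CODONS
      is_atg <- codons == "ATG"
      open <- NA_integer_
      for (i in seq_len(ncod)) {
        if (is.na(open) && is_atg[i]) open <- i
        if (!is.na(open) && is_stop[i]) {
          len <- i - open + 1L
          if (len >= min_codons && (is.null(best) || len > best$n_codons)) {
            a <- starts[open] - 1L          # 0-based on current strand
            b <- starts[i] + 2L
            if (strand == "-") { tmp <- a; a <- n - b; b <- n - tmp }
            best <- list(start = a, end = b, frame = frame,
                         strand = strand, intact = TRUE, n_codons = len)
          }
          open <- NA_integer_
        }
      }
    }
  }
  if (is.null(best)) {
    best <- list(start = NA_integer_, end = NA_integer_,
                 frame = NA_integer_, strand = NA_character_,
                 intact = FALSE, n_codons = 0L)
  }
  best
}

# The reference ORF nucleotide sequence from a consensus profile or string.
reference_orf <- function(reference, min_codons = 50L) {
  s <- one_sequence(reference)
  ann <- locate_orf(s, min_codons = min_codons)
  if (!ann$intact) stop("reference carries no intact ORF")
  orf <- substr(s, ann$start + 1L, ann$end)
  if (ann$strand == "-") orf <- revcomp(orf)
  orf
}

#' Deduce the transposase peptide from a possibly disrupted copy
#'
#' Aligns a copy to the reference (consensus) ORF and translates it in the
#' consensus frame, excising codons disrupted by frameshifts (indels whose
#' length is not a multiple of 3) or nonsense substitutions. Indels of
#' length divisible by 3 are treated as clean codon insertion/deletion, not
#' frameshifts; inserted codons relative to the consensus frame are
#' dropped, so the peptide is never longer than the reference ORF in
#' codons. On an intact copy the result equals naive translation (terminal
#' stop removed).
#'
#' @param copy a nucleotide sequence (string or single-row [seq_tbl]).
#' @param reference the consensus: a `consensus_profile`, or a nucleotide
#'   string containing the reference ORF.
#' @param min_coverage minimum fraction of the reference ORF the copy must
#'   align to.
#' @return The peptide string, with attributes `n_frameshift` and
#'   `n_nonsense` counting excised codons.
#' @export
deduce_peptide <- function(copy, reference, min_coverage = 0.5) {
  qry <- one_sequence(copy)
  ref <- reference_orf(reference)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(qry), Biostrings::DNAString(ref),
    type = "overlap", substitutionMatrix = nuc_submat(1, -1),
    gapOpening = 4, gapExtension = 1)
  qa <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::subject(pa)), "")[[1L]]
  ref_off <- Biostrings::start(Biostrings::subject(pa)) - 1L  # 0-based
  covered <- sum(sa != "-" & qa != "-")
  if (covered < min_coverage * nchar(ref)) {
    stop("insufficient homology: copy covers ", covered, " of ",
         nchar(ref), " reference ORF positions")
  }
  n_codons <- nchar(ref) %/% 3L
  # copy nucleotides assigned to each reference-frame codon; insertion
  # columns (ref gap) attach to the codon of the last reference position
  seg <- vector("list", n_codons)
  ref_pos <- ref_off
  for (i in seq_along(sa)) {
    if (sa[i] != "-") ref_pos <- ref_pos + 1L
    cod <- (ref_pos - 1L) %/% 3L + 1L
    if (qa[i] != "-" && cod >= 1L && cod <= n_codons) {
      seg[[cod]] <- c(seg[[cod]], qa[i])
    }
  }
  n_fs <- 0L; n_stop <- 0L
  out <- character(0)
  for (cod in seq_len(n_codons)) {
    s <- seg[[cod]]
    if (is.null(s) || length(s) == 0L) next      # deleted/uncovered codon
    if (length(s) %% 3L != 0L) {                 # frameshift codon
      n_fs <- n_fs + 1L
      next
    }
    aa <- translate_codons(paste(s[1:3], collapse = ""))
    if (aa == "*") {
      if (cod < n_codons) n_stop <- n_stop + 1L  # terminal stop is expected
      next
    }
    out <- c(out, aa)
  }
  structure(paste(out, collapse = ""), n_frameshift = n_fs,
            n_nonsense = n_stop)
}

#' Classify copies as intact or disrupted and report disruptions
#'
#' Runs [deduce_peptide()] on every record and summarises how many
#' frameshift and nonsense codons were excised; a copy is intact when
#' neither occurred and it covers the full reference ORF.
#'
#' @param records a [seq_tbl] of nucleotide copies.
#' @param reference consensus profile or ORF-bearing reference string.
#' @param min_coverage coverage floor passed to [deduce_peptide()];
#'   uncoverable copies are reported with `NA` counts.
#' @return A tibble: `id`, `n_frameshift`, `n_nonsense`, `intact`,
#'   `peptide`.
#' @export
disruption_report <- function(records, reference, min_coverage = 0.5) {
  rows <- lapply(seq_len(nrow(records)), function(i) {
    pep <- tryCatch(
      deduce_peptide(records$residues[i], reference, min_coverage),
      error = function(e) NULL)
    if (is.null(pep)) {
      return(tibble::tibble(id = records$id[i], n_frameshift = NA_integer_,
                            n_nonsense = NA_integer_, intact = FALSE,
                            peptide = NA_character_))
    }
    ref_codons <- nchar(reference_orf(reference)) %/% 3L
    tibble::tibble(
      id = records$id[i],
      n_frameshift = attr(pep, "n_frameshift"),
      n_nonsense = attr(pep, "n_nonsense"),
      intact = attr(pep, "n_frameshift") == 0L &&
        attr(pep, "n_nonsense") == 0L &&
        nchar(pep) >= ref_codons - 1L,
      peptide = as.character(pep))
  })
  dplyr::bind_rows(rows)
}
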