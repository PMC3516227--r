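#' Sequence records as tibbles
#'
#' Throughout mosaicTE a collection of sequences is a tibble with columns
#' `id` (unique, non-empty), `description` (free text; may carry a
#' `species=` token), `species`, `source` (one of `"genomic"`, `"est"`,
#' `"simulated"`, `"consensus"`) and `residues` (uppercase string).
#' Nucleotide residues are over `A,C,G,T,N,-`; peptides over the amino-acid
#' alphabet plus `X,*,-`.
#'
#' @param id character vector of unique record ids.
#' @param residues character vector of sequences (uppercased on build).
#' @param description free-text descriptions; defaults to `""`.
#' @param species species tags; when `NULL`, parsed from a `species=` token
#'   in the description, else `"unknown"`.
#' @param source provenance tag, recycled.
#' @return A tibble of class `seq_tbl`.
#' @export
seq_tbl <- function(id, residues, description = "", species = NULL,
                    source = "genomic") {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues)) {
    stop("id and residues must have equal length")
  }
  if (any(!nzchar(id))) stop("sequence ids must be non-empty")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id: ", id[duplicated(id)][1L])
  }
  if (any(!nzchar(residues))) {
    stop("empty residues for id: ", id[!nzchar(residues)][1L])
  }
  description <- rep_len(as.character(description), length(id))
  if (is.null(species)) species <- species_from_description(description)
  species <- rep_len(as.character(species), length(id))
  source <- rep_len(match.arg(source, c("genomic", "est", "simulated",
                                        "consensus"), several.ok = TRUE),
                    length(id))
  tibble::new_tibble(
    tibble::tibble(id = id, description = description, species = species,
                   source = source, residues = residues),
    class = "seq_tbl"
  )
}

species_from_description <- function(description) {
  m <- stringr::str_match(description, "species=(\\S+)")[, 2L]
  ifelse(is.na(m), "unknown", m)
}

#' Read a FASTA file into a seq_tbl
#'
#' Residues are uppercased on read. The species tag is parsed from a
#' `species=` token in the header description when present, otherwise set
#' to `"unknown"`. Record order follows file order.
#'
#' @param path path to a FASTA file.
#' @param source provenance tag stored on every record.
#' @return A [seq_tbl].
#' @export
read_fasta <- function(path, source = "genomic") {
  if (!file.exists(path)) stop("no such file: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("no records in ", path)
  headers <- names(set)
  id <- sub("\\s.*$", "", headers)
  description <- ifelse(grepl("\\s", headers),
                        sub("^\\S+\\s+", "", headers), "")
  if (anyDuplicated(id)) {
    stop("duplicate sequence id in ", path, ": ", id[duplicated(id)][1L])
  }
  seq_tbl(id = id, residues = as.character(set),
          description = description, source = source)
}

#' Write a seq_tbl to FASTA
#'
#' Headers are `>id description`; sequence lines wrap at 60 columns.
#' `write_fasta()` then [read_fasta()] round-trips ids, descriptions and
#' residues exactly.
#'
#' @param records a [seq_tbl] (or compatible data frame); must be non-empty.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (nrow(records) == 0L) stop("cannot write empty record set")
  header <- ifelse(nzchar(records$description),
                   paste(records$id, records$description), records$id)
  lines <- character(0)
  wrapped <- lapply(records$residues, function(s) {
    n <- nchar(s)
    substring(s, seq(1L, n, 60L), pmin(seq(1L, n, 60L) + 59L, n))
  })
  out <- unlist(Map(function(h, body) c(paste0(">", h), body),
                    header, wrapped), use.names = FALSE)
  writeLines(out, path)
  invisible(path)
}

#' Parse a Newick string into an ape phylo tree
#'
#' Light syntactic validation (balanced parentheses, terminating
#' semicolon) reports the character offset of the first problem; parsing
#' is then delegated to ape. Edges without a stated branch length default
#' to 1.0.
#'
#' @param text a single Newick string.
#' @return An `ape::phylo` tree.
#' @export
parse_newick <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("newick parse error at offset ", i - 1L,
             ": unbalanced ')'")
      }
    }
  }
  if (depth != 0L) {
    stop("newick parse error at offset ", length(chars),
         ": ", depth, " unclosed '('")
  }
  if (!grepl(";\\s*$", text)) {
    stop("newick parse error at offset ", length(chars),
         ": missing terminating ';'")
  }
  tree <- ape::read.tree(text = text)
  if (is.null(tree)) stop("newick parse error at offset 0: unparseable")
  if (is.null(tree$edge.length)) {
    tree$edge.length <- rep(1, nrow(tree$edge))
  } else {
    tree$edge.length[is.na(tree$edge.length)] <- 1
  }
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label: ",
         tree$tip.label[duplicated(tree$tip.label)][1L])
  }
  if (any(tree$edge.length < 0)) stop("negative branch length in newick")
  tree
}

#' Serialize a tree to Newick
#'
#' Bootstrap supports stored in `node.label` are emitted as internal node
#' labels.
#'
#' @param tree an `ape::phylo` tree.
#' @param path optional output path; when `NULL` the string is returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
write_newick <- function(tree, path = NULL) {
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

# Convert seq_tbl rows to a named character vector
seq_vec <- function(records) {
  stats::setNames(records$residues, records$id)
}

# Alignment container: a seq_tbl whose residues all have equal length
as_alignment <- function(records) {
  len <- nchar(records$residues)
  if (length(unique(len)) != 1L) stop("rows differ in length")
  if (len[1L] < 1L) stop("alignment must have at least one column")
  records
}

# Character matrix (rows = sequences) from an alignment seq_tbl
aln_matrix <- function(alignment) {
  m <- do.call(rbind, strsplit(alignment$residues, "", fixed = TRUE))
  rownames(m) <- alignment$id
  m
}

# Rebuild the residues column from a character matrix, keeping metadata
aln_from_matrix <- function(m, template) {
  out <- template[match(rownames(m), template$id), , drop = FALSE]
  out$residues <- unname(apply(m, 1L, paste, collapse = ""))
  tibble::as_tibble(out)
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}
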