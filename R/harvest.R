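#' @importFrom stats setNames
NULL

# Strict substitution matrices: N / X mismatch everything (including
# themselves); no ambiguity credit.
nuc_submat <- function(match = 1, mismatch = -2) {
  letters <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(letters, letters))
  diag(m)[1:4] <- match
  m["N", "N"] <- mismatch
  m
}

aa_submat <- function(match = 1, mismatch = -1) {
  letters <- strsplit("ARNDCQEGHILKMFPSTWYVX*", "")[[1L]]
  m <- matrix(mismatch, length(letters), length(letters),
              dimnames = list(letters, letters))
  diag(m) <- match
  m["X", "X"] <- mismatch
  m
}

is_nucleotide <- function(x) {
  mean(strsplit(toupper(x), "")[[1L]] %in% c("A", "C", "G", "T", "N", "-")) >
    0.95
}

# Pairwise alignment wrapper returning gapped strings, identity over
# gap-excluded columns, and 1-based subject coordinates.
align_pair <- function(a, b, type = "global", nucleotide = TRUE,
                       match = 1, mismatch = -1, gap_open = 4,
                       gap_extend = 1) {
  submat <- if (nucleotide) nuc_submat(match, mismatch)
            else aa_submat(match, mismatch)
  cls <- if (nucleotide) Biostrings::DNAString else Biostrings::AAString
  a2 <- gsub("-", "", a, fixed = TRUE)
  b2 <- gsub("-", "", b, fixed = TRUE)
  pa <- Biostrings::pairwiseAlignment(
    cls(a2), cls(b2), type = type, substitutionMatrix = submat,
    gapOpening = gap_open, gapExtension = gap_extend)
  qa <- strsplit(as.character(Biostrings::pattern(pa)), "")[[1L]]
  sa <- strsplit(as.character(Biostrings::subject(pa)), "")[[1L]]
  both <- qa != "-" & sa != "-"
  ident <- if (sum(both) == 0L) 0 else 100 * mean(qa[both] == sa[both])
  list(q_aln = paste(qa, collapse = ""), s_aln = paste(sa, collapse = ""),
       identity = ident, compared = sum(both), columns = length(qa),
       q_start = Biostrings::start(Biostrings::pattern(pa)),
       q_end = Biostrings::end(Biostrings::pattern(pa)),
       s_start = Biostrings::start(Biostrings::subject(pa)),
       s_end = Biostrings::end(Biostrings::subject(pa)),
       score = Biostrings::score(pa))
}

# shared k-mer seed check used to skip hopeless subjects
shares_word <- function(a, b, word = 11L) {
  n <- nchar(a)
  if (n < word || nchar(b) < word) return(FALSE)
  starts <- seq_len(n - word + 1L)
  words <- unique(substring(a, starts, starts + word - 1L))
  any(vapply(words, function(w) grepl(w, b, fixed = TRUE), TRUE))
}

#' Similarity search of a query element against a sequence set
#'
#' Seed-and-extend local search: subjects sharing at least one exact
#' word with the query (either strand) are aligned locally
#' (Smith-Waterman scoring: match +1, mismatch -2, gap open 5, gap extend
#' 2, mirroring megablast-style defaults). Reverse-strand hits are
#' reported with subject coordinates on the forward strand and strand
#' `"-"`; the gapped hit alignment is kept in query orientation so hits
#' can be stacked on query coordinates. Hits are sorted by descending
#' identity, then aligned length.
#'
#' @param query a nucleotide string or single-row [seq_tbl].
#' @param subjects a [seq_tbl] of nucleotide sequences.
#' @param min_identity minimum percent identity over gap-excluded aligned
#'   columns.
#' @param min_length minimum alignment length in columns.
#' @param word_size exact-word seed length.
#' @return A tibble of hits (`query_id`, `subject_id`, `strand`,
#'   `identity`, `aligned_length`, `s_start`/`s_end` and
#'   `q_start`/`q_end` 0-based half-open, `q_aln`, `s_aln`), with the
#'   query length in attribute `query_length`.
#' @export
similarity_search <- function(query, subjects, min_identity = 90,
                              min_length = 100, word_size = 11L) {
  qid <- if (is.data.frame(query)) query$id else "query"
  q <- one_sequence(query)
  rows <- list()
  for (i in seq_len(nrow(subjects))) {
    subj <- subjects$residues[i]
    slen <- nchar(subj)
    for (strand in c("+", "-")) {
      s <- if (strand == "+") subj else revcomp(subj)
      if (!shares_word(q, s, word_size)) next
      al <- align_pair(q, s, type = "local", nucleotide = TRUE,
                       match = 1, mismatch = -2, gap_open = 5,
                       gap_extend = 2)
      if (al$columns < min_length || al$identity < min_identity) next
      ss <- al$s_start - 1L; se <- al$s_end        # 0-based half-open
      if (strand == "-") { tmp <- ss; ss <- slen - se; se <- slen - tmp }
      rows[[length(rows) + 1L]] <- tibble::tibble(
        query_id = qid, subject_id = subjects$id[i], strand = strand,
        identity = al$identity, aligned_length = al$columns,
        s_start = ss, s_end = se,
        q_start = al$q_start - 1L, q_end = al$q_end,
        q_aln = al$q_aln, s_aln = al$s_aln)
    }
  }
  hits <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(query_id = character(), subject_id = character(),
                   strand = character(), identity = numeric(),
                   aligned_length = integer(), s_start = integer(),
                   s_end = integer(), q_start = integer(),
                   q_end = integer(), q_aln = character(),
                   s_aln = character())
  hits <- hits[order(-hits$identity, -hits$aligned_length), , drop = FALSE]
  attr(hits, "query_length") <- nchar(q)
  hits
}

#' Greedy assembly of overlapping sequence fragments
#'
#' Single-linkage greedy merging: while any pair of fragments shares an
#' end-to-end overlap of at least `min_overlap` bp at `min_identity`
#' percent identity or better, the best-scoring pair is merged into one
#' contig, taking the majority base in the overlap (ties to the
#' alphabetically first base). A lightweight stand-in for CAP3 assembly at
#' desk scale.
#'
#' @param records a [seq_tbl] of nucleotide fragments.
#' @param min_identity minimum percent identity in the overlap.
#' @param min_overlap minimum overlap length in bp.
#' @return A [seq_tbl] of contigs (never more rows than the input);
#'   merged contigs carry the constituent ids in the description.
#' @export
merge_overlapping_fragments <- function(records, min_identity = 99,
                                        min_overlap = 40) {
  recs <- as.list(setNames(records$residues, records$id))
  species <- setNames(records$species, records$id)
  repeat {
    ids <- names(recs)
    if (length(ids) < 2L) break
    best <- NULL
    for (i in seq_along(ids)[-length(ids)]) {
      for (j in (i + 1L):length(ids)) {
        al <- align_pair(recs[[i]], recs[[j]], type = "overlap",
                         nucleotide = TRUE, match = 1, mismatch = -2,
                         gap_open = 5, gap_extend = 2)
        if (al$compared >= min_overlap && al$identity >= min_identity &&
            (is.null(best) || al$compared > best$al$compared)) {
          best <- list(i = i, j = j, al = al)
        }
      }
    }
    if (is.null(best)) break
    a <- recs[[best$i]]; b <- recs[[best$j]]; al <- best$al
    merged <- merge_two(a, b, al)
    new_id <- paste0(ids[best$i], "+", ids[best$j])
    sp <- species[[ids[best$i]]]
    recs[[best$j]] <- NULL
    recs[[best$i]] <- merged
    names(recs)[best$i] <- new_id
    species[new_id] <- sp
  }
  seq_tbl(id = names(recs), residues = unlist(recs, use.names = FALSE),
          description = ifelse(grepl("+", names(recs), fixed = TRUE),
                               "merged contig", ""),
          species = unname(species[names(recs)]), source = "genomic")
}

# Merge two fragments given their end-free overlap alignment: left
# overhang + majority-called overlap + right overhang.
merge_two <- function(a, b, al) {
  qa <- strsplit(al$q_aln, "")[[1L]]
  sa <- strsplit(al$s_aln, "")[[1L]]
  mid <- vapply(seq_along(qa), function(k) {
    if (qa[k] == "-") return(sa[k])
    if (sa[k] == "-") return(qa[k])
    if (qa[k] == sa[k]) return(qa[k])
    min(qa[k], sa[k])                    # 1-vs-1 tie: alphabetical
  }, "")
  left_a <- substr(a, 1L, al$q_start - 1L)
  left_b <- substr(b, 1L, al$s_start - 1L)
  right_a <- substr(a, al$q_end + 1L, nchar(a))
  right_b <- substr(b, al$s_end + 1L, nchar(b))
  left <- if (nchar(left_a) >= nchar(left_b)) left_a else left_b
  right <- if (nchar(right_a) >= nchar(right_b)) right_a else right_b
  paste0(left, paste(mid, collapse = ""), right)
}

#' Majority-rule consensus from stacked search hits
#'
#' Hits are stacked on query coordinates (insertions relative to the query
#' are ignored); positions outside a hit's span count as gaps. Per column
#' the most frequent residue wins, ties broken in the fixed order
#' A < C < G < T with the gap losing all ties; columns where the gap is
#' the strict plurality are deleted from the consensus string.
#'
#' @param hits a hit tibble from [similarity_search()] (needs the
#'   `query_length` attribute or an explicit `query_length`).
#' @param top_n number of top-ranked hits to stack (all, with a warning,
#'   when fewer are available).
#' @param query_length length of the query frame.
#' @return An object of class `consensus_profile`: list with `counts`
#'   (5 x L matrix over A,C,G,T,-), `consensus` (string), `n_hits`,
#'   `kept_columns` (0-based query positions retained).
#' @export
build_consensus <- function(hits, top_n = 300,
                            query_length = attr(hits, "query_length")) {
  stopifnot(top_n >= 1, !is.null(query_length))
  if (nrow(hits) < top_n) {
    warning("only ", nrow(hits), " hits available (requested ", top_n, ")")
  }
  use <- hits[seq_len(min(top_n, nrow(hits))), , drop = FALSE]
  L <- query_length
  counts <- matrix(0L, nrow = 5L, ncol = L,
                   dimnames = list(c("A", "C", "G", "T", "-"), NULL))
  for (i in seq_len(nrow(use))) {
    qa <- strsplit(use$q_aln[i], "")[[1L]]
    sa <- strsplit(use$s_aln[i], "")[[1L]]
    col <- rep("-", L)
    pos <- use$q_start[i]                 # 0-based
    for (k in seq_along(qa)) {
      if (qa[k] != "-") {
        pos <- pos + 1L
        col[pos] <- sa[k]                 # '-' when subject gapped
      }
    }
    col[!col %in% c("A", "C", "G", "T")] <- "-"   # N and gaps both vote '-'
    idx <- match(col, rownames(counts))
    for (r in 1:5) counts[r, ] <- counts[r, ] + (idx == r)
  }
  winner <- apply(counts, 2L, function(v) {
    res <- v[1:4]
    top <- which(res == max(res))[1L]     # A<C<G<T tie-break by order
    if (v[5L] > max(res)) 5L else top
  })
  keep <- which(winner != 5L)
  consensus <- paste(rownames(counts)[winner[keep]], collapse = "")
  structure(list(counts = counts, consensus = consensus,
                 n_hits = nrow(use), kept_columns = keep - 1L),
            class = "consensus_profile")
}

#' @export
print.consensus_profile <- function(x, ...) {
  cat("Majority-rule consensus of", x$n_hits, "stacked hits:",
      nchar(x$consensus), "nt\n")
  invisible(x)
}

#' Turn a consensus profile into a sequence record
#'
#' @param profile a `consensus_profile`.
#' @param id record id.
#' @return A single-row [seq_tbl] with `source = "consensus"`.
#' @export
consensus_record <- function(profile, id = "consensus") {
  seq_tbl(id = id, residues = profile$consensus,
          description = paste0("majority-rule consensus of ",
                               profile$n_hits, " hits"),
          species = "consensus", source = "consensus")
}

#' Keep hits overlapping the consensus ORF
#'
#' Retains hits whose query-coordinate span covers at least `min_fraction`
#' of the ORF interval (inclusive at the boundary).
#'
#' @param hits a hit tibble.
#' @param orf_start,orf_end ORF interval on the query, 0-based half-open.
#' @param min_fraction required covered fraction of the ORF length.
#' @return The filtered hit tibble.
#' @export
filter_by_orf_overlap <- function(hits, orf_start, orf_end,
                                  min_fraction = 0.75) {
  stopifnot(orf_end > orf_start)
  ov <- pmax(0L, pmin(hits$q_end, orf_end) - pmax(hits$q_start, orf_start))
  out <- hits[ov >= min_fraction * (orf_end - orf_start), , drop = FALSE]
  attr(out, "query_length") <- attr(hits, "query_length")
  out
}

#' Remove highly similar sequences within each species
#'
#' Single-linkage clustering at the identity threshold (pairwise
#' end-free alignment, identity over gap-excluded columns), performed
#' independently within each species tag; one representative per cluster
#' -- the longest sequence, ties broken by lexicographically smallest id.
#'
#' @param records a [seq_tbl] of one molecule type.
#' @param nt_threshold percent identity threshold for nucleotides.
#' @param aa_threshold percent identity threshold for peptides.
#' @return The representative subset of `records`.
#' @export
dedupe_representatives <- function(records, nt_threshold = 95,
                                   aa_threshold = 80) {
  keep <- character(0)
  for (sp in unique(records$species)) {
    sub <- records[records$species == sp, , drop = FALSE]
    n <- nrow(sub)
    if (n == 1L) { keep <- c(keep, sub$id); next }
    nt <- is_nucleotide(sub$residues[1L])
    thr <- if (nt) nt_threshold else aa_threshold
    parent <- seq_len(n)
    find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        al <- align_pair(sub$residues[i], sub$residues[j],
                         type = "overlap", nucleotide = nt)
        # a duplicate must be similar over a substantial shared stretch:
        # require the gap-excluded overlap to cover at least half of the
        # shorter sequence, so incidental end overlaps never link records
        floor_len <- 0.5 * min(nchar(sub$residues[i]),
                               nchar(sub$residues[j]))
        if (al$compared >= floor_len && al$identity >= thr) {
          parent[find(j)] <- find(i)
        }
      }
    }
    root <- vapply(seq_len(n), find, 1L)
    for (cl in unique(root)) {
      members <- sub[root == cl, , drop = FALSE]
      members <- members[order(-nchar(members$residues), members$id), ,
                         drop = FALSE]
      keep <- c(keep, members$id[1L])
    }
  }
  records[records$id %in% keep, , drop = FALSE]
}

#' Copy count and genome fraction from filtered hits
#'
#' Counts hits passing the identity filter and the genomic space they
#' occupy (union of subject intervals per subject). The fraction is
#' reported unrounded.
#'
#' @param hits a hit tibble.
#' @param min_identity identity floor in percent.
#' @param assembly_size assembly size in bp (> 0).
#' @return A list: `copies`, `occupied_bp`, `fraction`.
#' @export
count_copies_and_fraction <- function(hits, min_identity = 90,
                                      assembly_size) {
  stopifnot(assembly_size > 0)
  use <- hits[hits$identity >= min_identity, , drop = FALSE]
  if (nrow(use) == 0L) {
    return(list(copies = 0L, occupied_bp = 0L, fraction = 0))
  }
  occupied <- 0L
  for (sid in unique(use$subject_id)) {
    iv <- use[use$subject_id == sid, c("s_start", "s_end"), drop = FALSE]
    iv <- iv[order(iv$s_start), , drop = FALSE]
    cur_s <- iv$s_start[1L]; cur_e <- iv$s_end[1L]
    if (nrow(iv) > 1L) {
      for (k in 2L:nrow(iv)) {
        if (iv$s_start[k] <= cur_e) {
          cur_e <- max(cur_e, iv$s_end[k])
        } else {
          occupied <- occupied + (cur_e - cur_s)
          cur_s <- iv$s_start[k]; cur_e <- iv$s_end[k]
        }
      }
    }
    occupied <- occupied + (cur_e - cur_s)
  }
  list(copies = nrow(use), occupied_bp = as.integer(occupied),
       fraction = occupied / assembly_size)
}

# matches of a primer on a template with <= max_mismatch mismatches;
# returns 0-based half-open starts/ends on the template
primer_sites <- function(primer, template, max_mismatch) {
  m <- Biostrings::matchPattern(Biostrings::DNAString(primer),
                                Biostrings::DNAString(template),
                                max.mismatch = max_mismatch,
                                with.indels = FALSE, fixed = TRUE)
  if (length(m) == 0L) {
    return(tibble::tibble(start = integer(), end = integer(),
                          mismatches = integer()))
  }
  mm <- vapply(seq_along(m), function(i) {
    sum(strsplit(as.character(m[[i]]), "")[[1L]] !=
          strsplit(primer, "")[[1L]])
  }, 1L)
  tibble::tibble(start = Biostrings::start(m) - 1L,
                 end = Biostrings::end(m), mismatches = mm)
}

#' In-silico PCR
#'
#' Finds amplifiable products: the forward primer on the forward strand
#' and the reverse complement of the reverse primer downstream, each with
#' at most `max_mismatch` mismatches but an exact match over the 3
#' 3'-terminal bases, product at most `max_product` bp. Both template
#' orientations are screened; hits on the reverse orientation are
#' reported with forward-strand coordinates and strand `"-"`.
#'
#' @param templates a [seq_tbl] of nucleotide templates.
#' @param forward,reverse primer sequences, 5'->3', at least 15 nt.
#' @param max_mismatch mismatch allowance per primer site.
#' @param max_product maximum product length in bp.
#' @return A tibble of amplicons: `template_id`, `strand`, `f_start`,
#'   `f_end`, `r_start`, `r_end` (0-based half-open on the reported
#'   orientation), `product_length`, `mismatches`.
#' @export
in_silico_pcr <- function(templates, forward, reverse, max_mismatch = 2,
                          max_product = 2000) {
  forward <- toupper(forward); reverse <- toupper(reverse)
  stopifnot(nchar(forward) >= 15, nchar(reverse) >= 15)
  rows <- list()
  scan_one <- function(template, tid, strand) {
    f <- primer_sites(forward, template, max_mismatch)
    if (nrow(f)) {
      f3 <- substr(forward, nchar(forward) - 2L, nchar(forward))
      f <- f[substr(template, f$end - 2L, f$end) == f3, , drop = FALSE]
    }
    if (nrow(f) == 0L) return()
    rc <- revcomp(reverse)
    r <- primer_sites(rc, template, max_mismatch)
    if (nrow(r)) {
      # reverse primer 3' end = first 3 bases of its reverse complement
      r3 <- substr(rc, 1L, 3L)
      r <- r[substr(template, r$start + 1L, r$start + 3L) == r3, ,
             drop = FALSE]
    }
    if (nrow(r) == 0L) return()
    for (i in seq_len(nrow(f))) {
      for (j in seq_len(nrow(r))) {
        if (r$start[j] < f$end[i]) next
        prod <- r$end[j] - f$start[i]
        if (prod > max_product) next
        rows[[length(rows) + 1L]] <<- tibble::tibble(
          template_id = tid, strand = strand,
          f_start = f$start[i], f_end = f$end[i],
          r_start = r$start[j], r_end = r$end[j],
          product_length = prod,
          mismatches = f$mismatches[i] + r$mismatches[j])
      }
    }
  }
  for (t in seq_len(nrow(templates))) {
    scan_one(templates$residues[t], templates$id[t], "+")
    scan_one(revcomp(templates$residues[t]), templates$id[t], "-")
  }
  if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(template_id = character(), strand = character(),
                   f_start = integer(), f_end = integer(),
                   r_start = integer(), r_end = integer(),
                   product_length = integer(), mismatches = integer())
}
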