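#' Pipeline configuration
#'
#' Collects every threshold of the analysis in one validated object. All
#' coordinates are 0-based half-open; all randomness derives from the
#' single `seed` (stage-local streams are offsets of it); the config and
#' seed are recorded in the run log.
#'
#' @param query_path FASTA with the query element (first record used).
#' @param subject_path FASTA with the per-species sequence pool
#'   (species tags carried as `species=` description tokens).
#' @param host_tree_path optional Newick host species tree.
#' @param presence_path optional two-column TSV (species, state) for loss
#'   counting.
#' @param out_dir output directory.
#' @param min_identity,min_length similarity-search thresholds.
#' @param top_n hits stacked into the consensus.
#' @param orf_min_codons minimum ORF length when annotating the consensus.
#' @param orf_overlap_fraction required hit overlap with the consensus ORF.
#' @param merge_identity,merge_overlap fragment-assembly thresholds.
#' @param dedup_nt,dedup_aa within-species deduplication thresholds.
#' @param max_gap_fraction,min_row_fraction alignment filters.
#' @param group1_floor,divergent_ceiling identity-group thresholds.
#' @param bin_width identity histogram bin width.
#' @param bootstrap bootstrap replicates (0 for none).
#' @param ncat Gamma rate categories.
#' @param min_support support gate for transfer calls.
#' @param seed integer RNG seed.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(query_path, subject_path,
                            host_tree_path = NULL, presence_path = NULL,
                            out_dir = "mosaicte_out",
                            min_identity = 80, min_length = 100,
                            top_n = 300, orf_min_codons = 100,
                            orf_overlap_fraction = 0.75,
                            merge_identity = 99, merge_overlap = 40,
                            dedup_nt = 95, dedup_aa = 80,
                            max_gap_fraction = 0.15,
                            min_row_fraction = 0.75,
                            group1_floor = 92.5, divergent_ceiling = 90,
                            bin_width = 0.5, bootstrap = 0, ncat = 4,
                            min_support = 0, seed = 1) {
  frac_ok <- function(x) x >= 0 && x <= 1
  pct_ok <- function(x) x >= 0 && x <= 100
  stopifnot(pct_ok(min_identity), pct_ok(merge_identity), pct_ok(dedup_nt),
            pct_ok(dedup_aa), pct_ok(group1_floor),
            pct_ok(divergent_ceiling), pct_ok(min_support),
            frac_ok(orf_overlap_fraction), frac_ok(max_gap_fraction),
            frac_ok(min_row_fraction), bootstrap >= 0, ncat >= 1,
            bin_width > 0, top_n >= 1)
  for (p in c(query_path, subject_path, host_tree_path, presence_path)) {
    if (!is.null(p) && !file.exists(p)) stop("missing input path: ", p)
  }
  fields <- names(formals(pipeline_config))
  structure(mget(fields, envir = environment()), class = "pipeline_config")
}

#' Run the full transfer-detection pipeline
#'
#' Stages: similarity search of the query element; majority-rule
#' consensus of the top hits; re-search with the consensus; ORF-overlap
#' hit filter; retrieval, fragment merging and within-species
#' deduplication; multiple alignment with gap-column and short-row
#' filters; neighbor-joining tree (with bootstrap supports when
#' requested); identity-to-consensus distribution, histogram and group
#' classification; Ka/Ks over group-1 pairs; transfer calls; and -- when
#' a presence pattern is supplied -- Dollo loss counting on the host
#' tree. Every stage writes its table to `out_dir`; a JSON run log
#' records all thresholds and the seed. Deterministic given the seed.
#'
#' @param config a [pipeline_config].
#' @return Invisibly, a list with the main results (`consensus`, `tree`,
#'   `identities`, `groups`, `kaks`, `transfer_calls`, `losses`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  out <- function(...) file.path(config$out_dir, ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  query <- stage("load_query", read_fasta(config$query_path)[1L, ])
  subjects <- stage("load_subjects", read_fasta(config$subject_path))

  hits <- stage("search", similarity_search(
    query, subjects, min_identity = config$min_identity,
    min_length = config$min_length))
  profile <- stage("consensus",
                   suppressWarnings(build_consensus(hits, config$top_n)))
  cons_rec <- consensus_record(profile)
  write_fasta(cons_rec, out("consensus.fasta"))

  hits2 <- stage("research", similarity_search(
    cons_rec, subjects, min_identity = config$min_identity,
    min_length = config$min_length))
  orf <- stage("orf", locate_orf(profile$consensus,
                                 min_codons = config$orf_min_codons))
  if (orf$intact) {
    hits2 <- stage("orf_filter", filter_by_orf_overlap(
      hits2, orf$start, orf$end, config$orf_overlap_fraction))
  }
  utils::write.table(
    hits2[, setdiff(names(hits2), c("q_aln", "s_aln"))],
    out("hits.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)

  retrieved <- subjects[subjects$id %in% hits2$subject_id, , drop = FALSE]
  merged <- stage("merge", merge_overlapping_fragments(
    retrieved, config$merge_identity, config$merge_overlap))
  reps <- stage("dedupe", dedupe_representatives(
    merged, config$dedup_nt, config$dedup_aa))

  results <- list(consensus = profile)
  if (nrow(reps) >= 3L) {
    aln <- stage("align", progressive_align(reps))
    aln <- stage("gap_filter",
                 filter_gap_columns(aln, config$max_gap_fraction))
    aln <- stage("row_filter",
                 drop_short_rows(aln, config$min_row_fraction))
    write_fasta(aln, out("alignment.fasta"))
    tree <- stage("tree", build_nj(p_distance(aln)))
    if (config$bootstrap >= 1) {
      tree <- stage("bootstrap", bootstrap_support(
        aln, replicates = config$bootstrap, seed = config$seed + 11L,
        tree = tree))
    }
    write_newick(tree, out("tree.nwk"))
    results$tree <- tree

    species <- stats::setNames(aln$species, aln$id)
    calls <- stage("transfers",
                   call_transfers(tree, species,
                                  min_support = config$min_support))
    utils::write.table(calls, out("transfer_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    results$transfer_calls <- calls
  }

  idents <- stage("identity", identity_to_consensus(subjects, profile))
  groups <- stage("groups", classify_groups(
    idents, config$group1_floor, config$divergent_ceiling))
  hist <- stage("histogram", histogram_identities(idents, config$bin_width))
  utils::write.table(groups, out("identity_groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(hist, out("identity_histogram.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  results$identities <- idents
  results$groups <- groups

  g1 <- groups$id[groups$group == "group1"]
  if (orf$intact && length(g1) >= 2L) {
    kaks <- stage("kaks", kaks_group_pairs(
      subjects[subjects$id %in% g1, , drop = FALSE], profile,
      max_pairs = 50L, seed = config$seed + 23L))
    utils::write.table(kaks, out("kaks.tsv"), sep = "\t", quote = FALSE,
                       row.names = FALSE)
    results$kaks <- kaks
  }

  if (!is.null(config$host_tree_path) && !is.null(config$presence_path)) {
    host <- parse_newick(paste(readLines(config$host_tree_path),
                               collapse = ""))
    pattern <- utils::read.delim(config$presence_path)
    losses <- stage("losses", dollo_loss_count(host, pattern))
    writeLines(c(paste0("losses\t", losses$losses),
                 paste0("branches\t",
                        paste(losses$loss_branches, collapse = ","))),
               out("loss_report.tsv"))
    results$losses <- losses
  }

  log <- config
  log$out_dir <- NULL
  log <- lapply(unclass(log), function(x) if (is.null(x)) NA else x)
  log$package_version <- as.character(utils::packageVersion("mosaicTE"))
  jsonlite::write_json(log, out("run_log.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(results)
}

#' Ka/Ks over pairs of family members in the consensus reading frame
#'
#' Extracts the consensus-frame coding region of each record via
#' [deduce_peptide()]'s alignment machinery, then computes Nei-Gojobori
#' Ka/Ks for sampled record pairs directly on their codon-aligned
#' nucleotide sequences (pairwise end-free alignment to the consensus
#' ORF; codons with gaps are skipped inside [nei_gojobori()]).
#'
#' @param records a [seq_tbl] of nucleotide family members.
#' @param reference consensus profile or reference ORF string.
#' @param max_pairs maximum number of pairs sampled.
#' @param seed RNG seed for the pair sample.
#' @return A tibble with one [nei_gojobori()] row per pair plus `id_a`,
#'   `id_b`.
#' @export
kaks_group_pairs <- function(records, reference, max_pairs = 50L,
                             seed = 1) {
  ref <- reference_orf(reference)
  framed <- list()
  for (i in seq_len(nrow(records))) {
    cds <- tryCatch(codon_align_to_reference(records$residues[i], ref),
                    error = function(e) NULL)
    if (!is.null(cds)) framed[[records$id[i]]] <- cds
  }
  ids <- names(framed)
  if (length(ids) < 2L) stop("fewer than two codon-alignable records")
  pairs <- utils::combn(ids, 2L)
  withr::local_seed(seed)
  if (ncol(pairs) > max_pairs) {
    pairs <- pairs[, sample.int(ncol(pairs), max_pairs), drop = FALSE]
  }
  rows <- lapply(seq_len(ncol(pairs)), function(k) {
    a <- pairs[1L, k]; b <- pairs[2L, k]
    res <- tryCatch(nei_gojobori(framed[[a]], framed[[b]]),
                    error = function(e) NULL)
    if (is.null(res)) return(NULL)
    dplyr::bind_cols(tibble::tibble(id_a = a, id_b = b), res)
  })
  dplyr::bind_rows(Filter(Negate(is.null), rows))
}

# project a copy onto the reference ORF codon frame: one character per
# reference position ('-' where the copy is gapped/uncovered)
codon_align_to_reference <- function(copy, ref_orf) {
  al <- align_pair(copy, ref_orf, type = "overlap")
  qa <- strsplit(al$q_aln, "")[[1L]]
  sa <- strsplit(al$s_aln, "")[[1L]]
  proj <- rep("-", nchar(ref_orf))
  pos <- al$s_start - 1L
  for (k in seq_along(sa)) {
    if (sa[k] != "-") {
      pos <- pos + 1L
      if (qa[k] != "-") proj[pos] <- qa[k]
    }
  }
  if (sum(proj != "-") < nchar(ref_orf) / 2) {
    stop("insufficient coverage of the reference ORF")
  }
  paste(proj, collapse = "")
}
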