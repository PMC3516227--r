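#' Percent identity of sequences to a family consensus
#'
#' Aligns each record to the consensus (end-free pairwise alignment, both
#' strands, better strand kept) and reports identity over gap-excluded
#' columns. Records with fewer aligned sites than the floor are dropped;
#' their ids are kept in attribute `dropped`.
#'
#' @param records a [seq_tbl] of nucleotide sequences.
#' @param consensus a `consensus_profile` or consensus string.
#' @param min_sites minimum number of gap-excluded aligned sites.
#' @return A tibble: `id`, `species`, `identity` (percent), `compared`.
#' @export
identity_to_consensus <- function(records, consensus, min_sites = 150) {
  cons <- one_sequence(consensus)
  rows <- list(); dropped <- character(0)
  for (i in seq_len(nrow(records))) {
    fw <- align_pair(records$residues[i], cons, type = "overlap")
    rv <- align_pair(revcomp(records$residues[i]), cons, type = "overlap")
    al <- if (rv$identity > fw$identity && rv$compared >= fw$compared / 2)
      rv else fw
    if (al$compared < min_sites) {
      dropped <- c(dropped, records$id[i])
      next
    }
    rows[[length(rows) + 1L]] <- tibble::tibble(
      id = records$id[i], species = records$species[i],
      identity = al$identity, compared = al$compared)
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(id = character(), species = character(),
                   identity = numeric(), compared = integer())
  if (length(dropped)) {
    message(length(dropped), " record(s) below the ", min_sites,
            "-site floor dropped: ", paste(dropped, collapse = ", "))
  }
  attr(out, "dropped") <- dropped
  out
}

#' Bin identities into a per-species histogram
#'
#' Right-closed bins of the given width aligned to multiples of the width;
#' counts are partitioned by species and sum to the number of inputs.
#'
#' @param identities tibble from [identity_to_consensus()].
#' @param bin_width bin width in identity percent (> 0).
#' @return A tibble: `bin_low`, `bin_high`, `species`, `count`.
#' @export
histogram_identities <- function(identities, bin_width = 0.5) {
  stopifnot(bin_width > 0)
  if (nrow(identities) == 0L) {
    return(tibble::tibble(bin_low = numeric(), bin_high = numeric(),
                          species = character(), count = integer()))
  }
  lo <- bin_width * floor(min(identities$identity) / bin_width)
  if (min(identities$identity) == lo) lo <- lo - bin_width  # right-closed
  breaks <- seq(lo, bin_width * ceiling(100 / bin_width) + bin_width,
                by = bin_width)
  bin <- cut(identities$identity, breaks = breaks, right = TRUE)
  out <- identities |>
    dplyr::mutate(bin = bin) |>
    dplyr::count(.data$bin, .data$species, name = "count") |>
    dplyr::mutate(bin_low = breaks[as.integer(.data$bin)],
                  bin_high = breaks[as.integer(.data$bin) + 1L]) |>
    dplyr::select("bin_low", "bin_high", "species", "count") |>
    dplyr::arrange(.data$bin_low, .data$species)
  out
}

#' Classify sequences into recent and divergent element groups
#'
#' Sequences at or above the group-1 floor belong to the young
#' cross-species family; sequences below the divergent ceiling to the old
#' family; anything in between is unassigned.
#'
#' @param identities tibble from [identity_to_consensus()].
#' @param group1_floor identity floor (percent) for the recent family.
#' @param divergent_ceiling identity ceiling (percent, exclusive) for the
#'   divergent family.
#' @return The input with a `group` column
#'   (`"group1"`/`"group2"`/`"unassigned"`).
#' @export
classify_groups <- function(identities, group1_floor = 92.5,
                            divergent_ceiling = 90) {
  if (group1_floor < divergent_ceiling) {
    stop("group1_floor must be >= divergent_ceiling")
  }
  dplyr::mutate(identities, group = dplyr::case_when(
    .data$identity >= group1_floor ~ "group1",
    .data$identity < divergent_ceiling ~ "group2",
    TRUE ~ "unassigned"))
}

# --- Nei-Gojobori (1986) unweighted pathway Ka/Ks -------------------------

ng_codon_sites <- function(codon) {
  nts <- strsplit(codon, "")[[1L]]
  aa <- translate_codons(codon)
  syn <- 0
  for (k in 1:3) {
    for (alt in setdiff(NT, nts[k])) {
      mut <- nts; mut[k] <- alt
      if (translate_codons(paste(mut, collapse = "")) == aa) {
        syn <- syn + 1 / 3
      }
    }
  }
  syn
}

# syn/nonsyn differences between two codons, averaged over all minimal
# pathways; pathways through stop codons are excluded unless all are
ng_codon_diffs <- function(ca, cb) {
  a <- strsplit(ca, "")[[1L]]; b <- strsplit(cb, "")[[1L]]
  pos <- which(a != b)
  nd <- length(pos)
  if (nd == 0L) return(c(sd = 0, nd = 0))
  paths <- if (nd == 1L) list(pos) else {
    perms <- if (nd == 2L) list(pos, rev(pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                  c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(o) pos[o])
    }
    perms
  }
  score_path <- function(order) {
    cur <- a; sd <- 0; nd_ <- 0; through_stop <- FALSE
    for (k in order) {
      nxt <- cur; nxt[k] <- b[k]
      aa1 <- translate_codons(paste(cur, collapse = ""))
      aa2 <- translate_codons(paste(nxt, collapse = ""))
      if (aa2 == "*" && !identical(nxt, b)) through_stop <- TRUE
      if (aa1 == aa2) sd <- sd + 1 else nd_ <- nd_ + 1
      cur <- nxt
    }
    c(sd, nd_, through_stop)
  }
  scored <- t(vapply(paths, score_path, numeric(3)))
  ok <- scored[, 3L] == 0
  if (!any(ok)) ok <- rep(TRUE, nrow(scored))
  c(sd = mean(scored[ok, 1L]), nd = mean(scored[ok, 2L]))
}

jc_correct <- function(p) {
  if (is.na(p)) return(NA_real_)
  if (p >= 3 / 4) {
    warning("saturated: p >= 3/4, distance undefined")
    return(NA_real_)
  }
  -3 / 4 * log(1 - 4 * p / 3)
}

#' Nei-Gojobori Ka/Ks for a pair of coding sequences
#'
#' Unweighted pathway counting (Nei & Gojobori 1986): synonymous site
#' fractions per codon position under the standard code (changes to stop
#' codons count as nonsynonymous, so `S + N` equals the number of
#' compared nucleotides exactly); codons differing at several positions
#' are averaged over all minimal pathways, excluding pathways through
#' stop codons; Jukes-Cantor correction `d = -3/4 ln(1 - 4p/3)`. Codon
#' pairs containing ambiguous bases, gaps, or stop codons are skipped and
#' counted. `omega` is reported missing (not infinite) when `dS = 0`.
#'
#' @param a,b in-frame nucleotide sequences of equal length (multiple
#'   of 3).
#' @return A one-row tibble: `S`, `N`, `Sd`, `Nd`, `pS`, `pN`, `dS`,
#'   `dN`, `omega`, `codons_compared`, `codons_skipped`.
#' @export
nei_gojobori <- function(a, b) {
  a <- toupper(one_sequence(a)); b <- toupper(one_sequence(b))
  stopifnot(nchar(a) == nchar(b), nchar(a) %% 3L == 0L)
  n_cod <- nchar(a) %/% 3L
  starts <- 3L * (seq_len(n_cod) - 1L) + 1L
  ca <- substring(a, starts, starts + 2L)
  cb <- substring(b, starts, starts + 2L)
  clean <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb) &
    !(ca %in% STOP_CODONS) & !(cb %in% STOP_CODONS)
  skipped <- sum(!clean)
  ca <- ca[clean]; cb <- cb[clean]
  if (length(ca) == 0L) stop("no comparable codons")
  S <- (sum(vapply(ca, ng_codon_sites, 1)) +
          sum(vapply(cb, ng_codon_sites, 1))) / 2
  N <- 3 * length(ca) - S
  diffs <- t(mapply(ng_codon_diffs, ca, cb))
  Sd <- sum(diffs[, "sd"]); Nd <- sum(diffs[, "nd"])
  pS <- Sd / S; pN <- Nd / N
  dS <- jc_correct(pS); dN <- jc_correct(pN)
  omega <- if (is.na(dS) || is.na(dN) || dS == 0) NA_real_ else dN / dS
  tibble::tibble(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
                 dS = dS, dN = dN, omega = omega,
                 codons_compared = length(ca), codons_skipped = skipped)
}

# --- Dollo loss counting --------------------------------------------------

#' Minimum losses under single-origin vertical transmission
#'
#' Dollo parsimony with one gain at `origin`: the minimum number of
#' independent loss events equals the number of maximal subtrees below
#' the origin whose (known-state) taxa are all absent. Taxa with unknown
#' state are pruned before counting.
#'
#' @param tree a rooted `ape::phylo` species tree.
#' @param pattern a data frame with columns `species` and `state`
#'   (`"present"`, `"absent"`, `"unknown"`).
#' @param origin label or node number of the gain node; defaults to the
#'   root.
#' @return A list: `losses` (count) and `loss_branches` (character vector
#'   naming the child node of each loss branch: tip labels, or
#'   `node<k>`).
#' @export
dollo_loss_count <- function(tree, pattern, origin = NULL) {
  stopifnot(all(c("species", "state") %in% names(pattern)))
  state <- setNames(pattern$state, pattern$species)
  missing_sp <- setdiff(tree$tip.label, names(state))
  if (length(missing_sp)) {
    stop("no state for species: ", paste(missing_sp, collapse = ", "))
  }
  unknown <- names(state)[state == "unknown"]
  if (length(unknown)) {
    tree <- ape::drop.tip(tree, intersect(unknown, tree$tip.label))
  }
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  origin_node <- if (is.null(origin)) root else {
    if (is.character(origin)) {
      hit <- match(origin, c(tree$tip.label, tree$node.label))
      if (is.na(hit)) stop("unknown origin node: ", origin)
      hit
    } else as.integer(origin)
  }
  present_tips <- which(state[tree$tip.label] == "present")
  below <- descendant_tips(tree, origin_node)
  if (!all(present_tips %in% below)) {
    stop("origin violates single-gain assumption: present taxon outside ",
         "the origin subtree")
  }
  # all-absent flag per node, postorder
  nn <- ntip + tree$Nnode
  all_absent <- rep(NA, nn)
  all_absent[seq_len(ntip)] <- state[tree$tip.label] == "absent"
  po <- ape::reorder.phylo(tree, "postorder")$edge
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1L]; ch <- po[e, 2L]
    if (is.na(all_absent[p])) all_absent[p] <- TRUE
    all_absent[p] <- all_absent[p] && all_absent[ch]
  }
  node_name <- function(v) {
    ifelse(v <= ntip, tree$tip.label[v], paste0("node", v))
  }
  # losses: edges below the origin whose child subtree is all-absent but
  # whose parent subtree is not (maximal absent subtrees)
  losses <- character(0)
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; ch <- tree$edge[e, 2L]
    if (!is_descendant(tree, p, origin_node)) next
    if (all_absent[ch] && !all_absent[p]) {
      losses <- c(losses, node_name(ch))
    }
  }
  if (all_absent[origin_node]) losses <- node_name(origin_node)
  list(losses = length(losses), loss_branches = losses)
}

descendant_tips <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(node)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  unlist(lapply(kids, descendant_tips, tree = tree))
}

# is `node` a proper descendant of (or equal to) `anc`?
is_descendant <- function(tree, node, anc) {
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  cur <- node
  repeat {
    if (cur == anc) return(TRUE)
    if (cur == root) return(FALSE)
    parent <- tree$edge[tree$edge[, 2L] == cur, 1L]
    if (length(parent) == 0L) return(FALSE)
    cur <- parent
  }
}

# Fitch parsimony count of a tip character on a (possibly unrooted) tree
fitch_changes <- function(tree, states) {
  ntip <- length(tree$tip.label)
  sets <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) sets[[i]] <- states[[tree$tip.label[i]]]
  po <- ape::reorder.phylo(tree, "postorder")$edge
  changes <- 0L
  for (e in seq_len(nrow(po))) {
    p <- po[e, 1L]; ch <- po[e, 2L]
    if (is.null(sets[[p]])) {
      sets[[p]] <- sets[[ch]]
    } else {
      inter <- intersect(sets[[p]], sets[[ch]])
      if (length(inter)) {
        sets[[p]] <- inter
      } else {
        sets[[p]] <- union(sets[[p]], sets[[ch]])
        changes <- changes + 1L
      }
    }
  }
  changes
}

#' Call horizontal-transfer events from a tagged gene tree
#'
#' Implements the nesting argument: element copies of a recipient species
#' that sit inside a clade of another species' copies cannot be explained
#' by vertical descent. For every species whose copies are
#' non-monophyletic on the (midpoint-rooted) gene tree, single-species
#' intruder clusters inside its span are emitted as transfer calls, with
#' the surrounding species set as donor clade. A global mosaicism verdict
#' is also computed: `TRUE` when the species character needs more than
#' `|species| - 1` Fitch parsimony changes on the gene tree.
#'
#' @param tree gene tree (`ape::phylo`); bootstrap supports, when present
#'   in `node.label`, gate the calls.
#' @param species named character vector mapping every leaf label to its
#'   species tag.
#' @param min_support minimum support of the recipient cluster node
#'   (clusters without a stored support pass).
#' @return A tibble of calls (`recipient`, `donor`, `n_recipient_copies`,
#'   `support`) with attributes `mosaic` (logical) and `fitch_changes`.
#' @export
call_transfers <- function(tree, species, min_support = 0) {
  tips <- tree$tip.label
  untagged <- setdiff(tips, names(species))
  if (length(untagged)) {
    stop("untagged leaf: ", paste(untagged, collapse = ", "))
  }
  sp <- species[tips]
  n_changes <- fitch_changes(tree, as.list(setNames(sp, tips)))
  mosaic <- n_changes > length(unique(sp)) - 1L
  rooted <- if (ape::is.rooted(tree)) tree else phangorn::midpoint(tree)
  ntip <- length(tips)
  calls <- list()
  supports <- rooted$node.label
  node_support <- function(node) {
    if (node <= ntip) return(NA_real_)
    if (is.null(supports)) return(NA_real_)
    suppressWarnings(as.numeric(supports[node - ntip]))
  }
  for (d in unique(sp)) {
    d_tips <- which(sp[rooted$tip.label] == d)
    if (length(d_tips) < 2L) next
    mrca <- ape::getMRCA(rooted, d_tips)
    span <- descendant_tips(rooted, mrca)
    intruders <- setdiff(span, d_tips)
    if (!length(intruders)) next
    donors <- setdiff(unique(sp[rooted$tip.label[span]]), NA)
    for (s in unique(sp[rooted$tip.label[intruders]])) {
      if (s == d) next
      s_in <- intruders[sp[rooted$tip.label[intruders]] == s]
      s_all <- which(sp[rooted$tip.label] == s)
      if (!all(s_all %in% span)) next    # not fully nested inside d's span
      cl_node <- if (length(s_in) == 1L) s_in else
        ape::getMRCA(rooted, s_in)
      # recipient cluster must contain only s plus (a minority of) d: the
      # donor's own source lineage legitimately nests with the transferred
      # copies, but any third species or a d-majority voids the cluster
      if (cl_node > ntip) {
        below <- sp[rooted$tip.label[descendant_tips(rooted, cl_node)]]
        if (!all(below %in% c(s, d))) next
        if (sum(below == d) >= sum(below == s)) next
      }
      supp <- node_support(cl_node)
      if (!is.na(supp) && supp < min_support) next
      calls[[length(calls) + 1L]] <- tibble::tibble(
        recipient = s,
        donor = paste(sort(setdiff(donors, s)), collapse = ","),
        n_recipient_copies = length(s_in),
        support = supp)
    }
  }
  out <- if (length(calls)) dplyr::distinct(dplyr::bind_rows(calls)) else
    tibble::tibble(recipient = character(), donor = character(),
                   n_recipient_copies = integer(), support = numeric())
  attr(out, "mosaic") <- mosaic
  attr(out, "fitch_changes") <- n_changes
  out
}
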