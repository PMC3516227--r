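# does `taxa` form one side of a bipartition (unrooted monophyly)?
is_split <- function(tree, taxa) {
  tips <- tree$tip.label
  taxa <- sort(taxa)
  if (length(taxa) <= 1L || length(taxa) >= length(tips)) return(TRUE)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  for (p in parts) {
    side <- sort(labs[p])
    if (identical(side, taxa) ||
        identical(sort(setdiff(tips, side)), taxa)) {
      return(TRUE)
    }
  }
  FALSE
}

# rooted binary subtree for `taxa` built by NJ on the induced distances
induced_subtree_rootings <- function(alignment, taxa, root_edge = 0.05) {
  d <- p_distance(alignment[alignment$id %in% taxa, , drop = FALSE])
  if (length(taxa) == 2L) {
    h <- max(d[taxa[1L], taxa[2L]] / 2, 1e-6)
    sub <- ape::read.tree(text = sprintf("(%s:%g,%s:%g);",
                                         taxa[1L], h, taxa[2L], h))
    sub$root.edge <- root_edge
    return(list(sub))
  }
  un <- ape::unroot(build_nj(d[taxa, taxa]))
  ntip <- length(un$tip.label)
  # one rooting per edge of the unrooted subtree: the side of the group
  # facing the rest of the tree is part of the constrained topology and
  # must be searched, not fixed by an arbitrary outgroup choice
  subs <- lapply(seq_len(nrow(un$edge)), function(e) {
    ch <- un$edge[e, 2L]
    og <- if (ch <= ntip) un$tip.label[ch] else
      un$tip.label[phangorn::Descendants(un, ch, "tips")[[1L]]]
    if (length(og) >= ntip) return(NULL)
    tr <- tryCatch(ape::root(un, outgroup = og, resolve.root = TRUE),
                   error = function(err) NULL)
    if (!is.null(tr)) tr$root.edge <- root_edge
    tr
  })
  Filter(Negate(is.null), subs)
}

#' Best tree under a monophyly constraint
#'
#' Forces the given taxa to be monophyletic: if they already form a
#' bipartition of the tree, the input is returned unchanged. Otherwise
#' they are pruned, their induced subtree (neighbor joining on the induced
#' distance submatrix, tried in every rooting) is reattached on every
#' backbone branch, each
#' placement is scored by GTR+Gamma log-likelihood at the grafted branch
#' lengths, and the leading placements are refined with a full
#' branch-length optimization; the best refined tree is returned.
#'
#' @param tree the unconstrained tree.
#' @param taxa leaf labels to constrain (2 <= n <= leaves - 2).
#' @param alignment nucleotide alignment used for scoring.
#' @param params a [gtr_params].
#' @return The best constrained tree, log-likelihood in attribute
#'   `loglik`.
#' @export
constrain_monophyly <- function(tree, taxa, alignment, params) {
  tips <- tree$tip.label
  stopifnot(all(taxa %in% tips))
  if (length(taxa) < 2L || length(taxa) > length(tips) - 2L) {
    stop("trivial constraint: need 2 <= |taxa| <= leaves - 2")
  }
  if (is_split(tree, taxa)) return(tree)
  backbone <- ape::drop.tip(tree, taxa)
  subs <- induced_subtree_rootings(alignment, taxa)
  all_tips <- sort(tips)
  grafts <- expand.grid(edge = seq_len(nrow(backbone$edge)),
                        rooting = seq_along(subs))
  candidates <- lapply(seq_len(nrow(grafts)), function(g) {
    e <- grafts$edge[g]
    sub <- subs[[grafts$rooting[g]]]
    where <- backbone$edge[e, 2L]
    pos <- backbone$edge.length[e] / 2
    # position 0 makes bind.tree replace the target tip rather than
    # graft beside it; a zero-length branch offers no interior point
    if (pos <= 0) return(NULL)
    tr <- tryCatch(ape::bind.tree(backbone, sub, where = where,
                                  position = pos),
                   error = function(err) NULL)
    if (is.null(tr)) return(NULL)
    tr <- ape::unroot(tr)
    if (!identical(sort(tr$tip.label), all_tips)) return(NULL)
    tr
  })
  candidates <- Filter(Negate(is.null), candidates)
  if (!length(candidates)) stop("no feasible attachment point")
  # rank placements by likelihood at the grafted branch lengths, then
  # fully optimize only the leading candidates
  quick <- vapply(candidates, function(tr) {
    gtr_gamma_loglik(alignment, tr, params)
  }, 1)
  top <- order(quick, decreasing = TRUE)[seq_len(min(3L,
                                                     length(candidates)))]
  refined <- lapply(candidates[top], function(tr) {
    optimize_branch_lengths(alignment, tr, params, max_passes = 3L)
  })
  scores <- vapply(refined, attr, 1, "loglik")
  refined[[which.max(scores)]]
}

#' Kishino-Hasegawa topology test with RELL resampling
#'
#' Optimizes branch lengths for every candidate topology, identifies the
#' best by total GTR+Gamma log-likelihood, and tests each alternative
#' against it: per-site log-likelihood differences are resampled
#' (resampling estimated log-likelihoods) and the one-sided p-value is
#' the fraction of centered resampled differences at least as large as
#' the observed one.
#'
#' @param alignment a nucleotide alignment [seq_tbl].
#' @param trees list of `phylo` trees on the identical leaf set.
#' @param params a [gtr_params].
#' @param replicates RELL bootstrap replicates.
#' @param seed RNG seed.
#' @param optimize optimize branch lengths per topology first.
#' @return A tibble: `tree`, `loglik`, `delta` (lnL behind the best tree;
#'   0 for the best) and `p_value` (1 for the best).
#' @export
topology_test_rell <- function(alignment, trees, params,
                               replicates = 1000, seed = 1,
                               optimize = TRUE) {
  stopifnot(length(trees) >= 2L)
  leafsets <- lapply(trees, function(t) sort(t$tip.label))
  if (!all(vapply(leafsets, identical, TRUE, leafsets[[1L]]))) {
    stop("trees must share an identical leaf set")
  }
  withr::local_seed(seed)
  site_ll <- list()
  totals <- numeric(length(trees))
  for (k in seq_along(trees)) {
    tr <- trees[[k]]
    if (optimize) {
      tr <- optimize_branch_lengths(alignment, tr, params, max_passes = 3L)
    }
    ll <- gtr_gamma_loglik(alignment, tr, params, per_site = TRUE)
    site_ll[[k]] <- attr(ll, "site_loglik")
    totals[k] <- as.numeric(ll)
  }
  best <- which.max(totals)
  nsites <- length(site_ll[[best]])
  counts <- stats::rmultinom(replicates, nsites, rep(1 / nsites, nsites))
  p <- numeric(length(trees))
  for (k in seq_along(trees)) {
    if (k == best) { p[k] <- 1; next }
    dsite <- site_ll[[best]] - site_ll[[k]]
    d_obs <- sum(dsite)
    d_rep <- as.numeric(crossprod(counts, dsite))
    centered <- d_rep - mean(d_rep)
    p[k] <- mean(centered >= d_obs)
  }
  tibble::tibble(tree = seq_along(trees), loglik = totals,
                 delta = max(totals) - totals, p_value = p)
}
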