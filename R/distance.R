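#' Proportion-of-differing-sites distance matrix
#'
#' Pairwise p-distances under pairwise deletion: columns with a gap in
#' either row are excluded for that pair; `N`/`X` residues count as
#' differences. Works for nucleotide and peptide alignments alike.
#'
#' @param alignment an alignment [seq_tbl] (>= 2 rows).
#' @return A symmetric numeric matrix with row/column names.
#' @export
p_distance <- function(alignment) {
  m <- aln_matrix(alignment)
  n <- nrow(m)
  stopifnot(n >= 2L)
  ambiguous <- m == "N" | m == "X"
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- m[i, ] != "-" & m[j, ] != "-"
      if (!any(ok)) {
        stop("no comparable sites between ", rownames(m)[i], " and ",
             rownames(m)[j])
      }
      diff <- (m[i, ok] != m[j, ok]) | ambiguous[i, ok] | ambiguous[j, ok]
      d[i, j] <- d[j, i] <- mean(diff)
    }
  }
  d
}

#' Poisson multiple-hit correction
#'
#' Corrects an observed difference proportion for unobserved multiple
#' substitutions: `d = -ln(1 - p)`. Monotone increasing and always
#' at least `p`.
#'
#' @param p proportion(s) of differing sites in `[0, 1)`.
#' @return Corrected distance(s).
#' @export
poisson_distance <- function(p) {
  if (any(p < 0)) stop("p must be non-negative")
  if (any(p >= 1)) stop("saturated: p >= 1")
  -log(1 - p)
}

# distance matrix straight from an alignment, optionally Poisson-corrected
dist_matrix <- function(alignment, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  d <- p_distance(alignment)
  if (correction == "poisson") d[] <- poisson_distance(d)
  d
}

#' Neighbor-joining tree
#'
#' Saitou-Nei agglomeration on the Q criterion. Ties in Q are broken by
#' the smallest pair of current taxon indices; negative branch length
#' estimates are clamped to zero with the deficit moved to the sister
#' branch. Returns an unrooted tree; on an additive matrix the generating
#' topology and path distances are recovered exactly.
#'
#' @param d a symmetric distance matrix with labels (>= 3 taxa).
#' @return An unrooted `ape::phylo` tree.
#' @export
build_nj <- function(d) {
  stopifnot(is.matrix(d), nrow(d) == ncol(d), nrow(d) >= 3L)
  if (any(!is.finite(d))) stop("non-finite distance matrix entries")
  labels <- rownames(d)
  n <- nrow(d)
  # each active cluster is a Newick fragment
  frag <- labels
  D <- d
  fmt <- function(x) sprintf("%.12g", max(x, 0))
  while (n > 3L) {
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, "+")
    diag(Q) <- Inf
    best <- which(Q == min(Q), arr.ind = TRUE)
    best <- best[best[, 1L] < best[, 2L], , drop = FALSE]
    best <- best[order(best[, 1L], best[, 2L]), , drop = FALSE]
    i <- best[1L, 1L]; j <- best[1L, 2L]
    vi <- D[i, j] / 2 + (r[i] - r[j]) / (2 * (n - 2))
    vj <- D[i, j] - vi
    if (vi < 0) { vj <- vj + vi; vi <- 0 }
    if (vj < 0) { vi <- vi + vj; vj <- 0 }
    new_frag <- paste0("(", frag[i], ":", fmt(vi), ",",
                       frag[j], ":", fmt(vj), ")")
    dk <- (D[i, ] + D[j, ] - D[i, j]) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dk[keep]),
               c(dk[keep], 0))
    frag <- c(frag[keep], new_frag)
    n <- n - 1L
  }
  va <- (D[1, 2] + D[1, 3] - D[2, 3]) / 2
  vb <- D[1, 2] - va
  vc <- D[1, 3] - va
  txt <- paste0("(", frag[1L], ":", fmt(va), ",", frag[2L], ":", fmt(vb),
                ",", frag[3L], ":", fmt(vc), ");")
  ape::read.tree(text = txt)
}

# canonical bipartition keys of all internal edges of an unrooted tree
tree_splits <- function(tree) {
  tips <- sort(tree$tip.label)
  ntip <- length(tips)
  parts <- ape::prop.part(tree)
  keys <- character(0)
  labs <- attr(parts, "labels")
  for (p in parts) {
    side <- sort(labs[p])
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (!(tips[1L] %in% side)) side <- setdiff(tips, side)
    keys <- c(keys, paste(side, collapse = "|"))
  }
  unique(keys)
}

#' Bootstrap support for tree bipartitions
#'
#' Resamples alignment columns with replacement, rebuilds a tree per
#' replicate with `tree_fun`, and annotates each internal edge of the
#' reference tree with the percentage of replicate trees containing its
#' bipartition. Deterministic for a fixed seed.
#'
#' @param alignment an alignment [seq_tbl].
#' @param replicates number of bootstrap replicates (>= 1).
#' @param seed RNG seed.
#' @param tree_fun function mapping an alignment to a `phylo` tree;
#'   defaults to neighbor joining on p-distances.
#' @param tree reference tree; defaults to `tree_fun(alignment)`.
#' @return The reference tree with integer supports in `node.label`.
#' @export
bootstrap_support <- function(alignment, replicates = 1000, seed = 1,
                              tree_fun = function(a) build_nj(p_distance(a)),
                              tree = NULL) {
  stopifnot(replicates >= 1)
  if (is.null(tree)) tree <- tree_fun(alignment)
  withr::local_seed(seed)
  m <- aln_matrix(alignment)
  tally <- new.env(parent = emptyenv())
  for (b in seq_len(replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rep_aln <- aln_from_matrix(m[, cols, drop = FALSE], alignment)
    rep_tree <- tree_fun(rep_aln)
    for (key in tree_splits(rep_tree)) {
      assign(key, (if (exists(key, tally)) get(key, tally) else 0L) + 1L,
             tally)
    }
  }
  ntip <- length(tree$tip.label)
  node_support <- rep(NA_integer_, tree$Nnode)
  parts <- ape::prop.part(tree)
  labs <- attr(parts, "labels")
  tips <- sort(tree$tip.label)
  for (k in seq_along(parts)) {
    side <- sort(labs[parts[[k]]])
    node <- ntip + k
    if (length(side) <= 1L || length(side) >= ntip - 1L) next
    if (!(tips[1L] %in% side)) side <- setdiff(tips, side)
    key <- paste(side, collapse = "|")
    hits <- if (exists(key, tally)) get(key, tally) else 0L
    node_support[node - ntip] <- as.integer(round(100 * hits / replicates))
  }
  tree$node.label <- node_support
  tree
}
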