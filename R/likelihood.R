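#' GTR+Gamma model parameters
#'
#' @param rates the six exchangeabilities in the order AC, AG, AT, CG, CT,
#'   GT (all > 0; scale is arbitrary).
#' @param base_freq equilibrium base frequencies (A, C, G, T), summing to 1.
#' @param alpha Gamma shape for among-site rate variation (> 0); `Inf`
#'   collapses to homogeneous rates.
#' @param ncat number of equal-weight discrete rate categories.
#' @return A list of class `gtr_params`.
#' @export
gtr_params <- function(rates = rep(1, 6), base_freq = rep(0.25, 4),
                       alpha = Inf, ncat = 4L) {
  stopifnot(length(rates) == 6L, all(rates > 0),
            length(base_freq) == 4L, all(base_freq > 0),
            alpha > 0, ncat >= 1L)
  if (abs(sum(base_freq) - 1) > 1e-9) stop("base frequencies must sum to 1")
  structure(list(rates = as.numeric(rates),
                 base_freq = as.numeric(base_freq),
                 alpha = alpha, ncat = as.integer(ncat)),
            class = "gtr_params")
}

# normalized GTR rate matrix (expected rate 1 substitution/site)
gtr_q <- function(params) {
  s <- params$rates; pi <- params$base_freq
  q <- matrix(0, 4, 4, dimnames = list(NT, NT))
  q["A", "C"] <- s[1]; q["A", "G"] <- s[2]; q["A", "T"] <- s[3]
  q["C", "G"] <- s[4]; q["C", "T"] <- s[5]; q["G", "T"] <- s[6]
  q <- q + t(q)
  q <- q * rep(pi, each = 4)        # q_ij = s_ij * pi_j
  diag(q) <- -rowSums(q)
  scale <- -sum(pi * diag(q))
  q / scale
}

# eigen-decomposition of Q via the symmetrized form, for fast P(t)
gtr_eigen <- function(params) {
  q <- gtr_q(params)
  pi <- params$base_freq
  sp <- sqrt(pi)
  B <- diag(sp) %*% q %*% diag(1 / sp)
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  list(values = e$values,
       right = diag(1 / sp) %*% e$vectors,
       left = t(e$vectors) %*% diag(sp))
}

gtr_pmat <- function(eig, t) {
  p <- eig$right %*% (exp(eig$values * t) * eig$left)
  p[p < 0] <- 0
  dimnames(p) <- list(NT, NT)
  p
}

# mean-of-quantile-interval discrete Gamma rates (equal weights)
discrete_gamma_rates <- function(alpha, ncat) {
  if (ncat == 1L || !is.finite(alpha)) return(rep(1, ncat))
  b <- stats::qgamma(seq(0, 1, length.out = ncat + 1L), alpha, alpha)
  ncat * (stats::pgamma(b[-1L], alpha + 1, alpha) -
            stats::pgamma(b[-(ncat + 1L)], alpha + 1, alpha))
}

# compress alignment columns into site patterns over rows `labels`
site_patterns <- function(alignment, labels) {
  m <- aln_matrix(alignment)
  if (!all(labels %in% rownames(m))) {
    missing <- setdiff(labels, rownames(m))
    stop("leaf without alignment row: ", missing[1L])
  }
  m <- m[labels, , drop = FALSE]
  key <- apply(m, 2L, paste, collapse = "")
  uniq <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[uniq])))
  list(m = m[, uniq, drop = FALSE], weight = w,
       index = match(key, key[uniq]))
}

leaf_lik <- function(chars) {
  L <- matrix(0, 4L, length(chars))
  idx <- match(chars, NT)
  known <- !is.na(idx)
  L[cbind(idx[known], which(known))] <- 1
  L[, !known] <- 1              # gap/N: missing data
  L
}

# Felsenstein pruning over all categories; returns per-pattern log-lik
prune_loglik <- function(patterns, tree, params, eig, rates) {
  ntip <- length(tree$tip.label)
  tr <- ape::reorder.phylo(tree, "postorder")
  edges <- tr$edge; elen <- tr$edge.length
  npat <- ncol(patterns$m)
  pi <- params$base_freq
  site_l <- matrix(0, length(rates), npat)
  leafL <- lapply(seq_len(ntip),
                  function(i) leaf_lik(patterns$m[tr$tip.label[i], ]))
  for (ci in seq_along(rates)) {
    L <- vector("list", ntip + tr$Nnode)
    logscale <- numeric(npat)
    for (i in seq_len(ntip)) L[[i]] <- leafL[[i]]
    for (e in seq_len(nrow(edges))) {
      parent <- edges[e, 1L]; child <- edges[e, 2L]
      P <- gtr_pmat(eig, elen[e] * rates[ci])
      contrib <- P %*% L[[child]]
      if (is.null(L[[parent]])) {
        L[[parent]] <- contrib
      } else {
        L[[parent]] <- L[[parent]] * contrib
        mx <- apply(L[[parent]], 2L, max)
        mx[mx <= 0] <- 1
        L[[parent]] <- sweep(L[[parent]], 2L, mx, "/")
        logscale <- logscale + log(mx)
      }
    }
    root <- edges[nrow(edges), 1L]
    site_l[ci, ] <- log(colSums(pi * L[[root]])) + logscale
  }
  # average over equal-weight categories in log space
  mx <- apply(site_l, 2L, max)
  log(colMeans(exp(sweep(site_l, 2L, mx, "-")))) + mx
}

#' GTR+Gamma log-likelihood of a tree
#'
#' Felsenstein pruning under the general time-reversible model with
#' equal-weight discrete Gamma rate categories (mean-of-quantile-interval
#' rates). Gaps and ambiguous bases are treated as missing data. The
#' value is invariant under re-rooting (the model is reversible).
#'
#' @param alignment a nucleotide alignment [seq_tbl] containing a row for
#'   every tree leaf.
#' @param tree an `ape::phylo` tree with branch lengths.
#' @param params a [gtr_params].
#' @param per_site when `TRUE`, the per-site log-likelihood vector is
#'   attached as attribute `site_loglik`.
#' @return The total log-likelihood (a single number <= 0).
#' @export
gtr_gamma_loglik <- function(alignment, tree, params, per_site = FALSE) {
  stopifnot(inherits(params, "gtr_params"))
  patterns <- site_patterns(alignment, tree$tip.label)
  eig <- gtr_eigen(params)
  rates <- discrete_gamma_rates(params$alpha, params$ncat)
  pat_l <- prune_loglik(patterns, tree, params, eig, rates)
  total <- sum(pat_l * patterns$weight)
  if (per_site) attr(total, "site_loglik") <- pat_l[patterns$index]
  total
}

#' Optimize branch lengths on a fixed topology
#'
#' Cycles over branches, optimizing each length by Brent's method at the
#' current values of the others, until the likelihood gain in a full pass
#' drops below `tol`.
#'
#' @param alignment a nucleotide alignment [seq_tbl].
#' @param tree tree whose topology is kept fixed.
#' @param params a [gtr_params].
#' @param max_passes maximum optimization sweeps over all branches.
#' @param tol log-likelihood convergence tolerance per pass.
#' @param max_branch upper bound on a branch length.
#' @return The tree with optimized branch lengths; the final
#'   log-likelihood is attached as attribute `loglik`.
#' @export
optimize_branch_lengths <- function(alignment, tree, params,
                                    max_passes = 4L, tol = 1e-3,
                                    max_branch = 10) {
  patterns <- site_patterns(alignment, tree$tip.label)
  eig <- gtr_eigen(params)
  rates <- discrete_gamma_rates(params$alpha, params$ncat)
  obj <- function(tr) sum(prune_loglik(patterns, tr, params, eig, rates) *
                            patterns$weight)
  cur <- obj(tree)
  for (pass in seq_len(max_passes)) {
    prev <- cur
    for (e in seq_along(tree$edge.length)) {
      f <- function(x) {
        tree$edge.length[e] <- x
        obj(tree)
      }
      opt <- stats::optimize(f, c(1e-8, max_branch), maximum = TRUE,
                             tol = 1e-5)
      if (opt$objective > cur) {
        tree$edge.length[e] <- opt$maximum
        cur <- opt$objective
      }
    }
    if (cur - prev < tol) break
  }
  attr(tree, "loglik") <- cur
  tree
}

#' Estimate GTR+Gamma parameters on a fixed tree
#'
#' Base frequencies are taken as empirical; exchangeabilities (relative to
#' GT = 1) and the Gamma shape are optimized by Nelder-Mead on the log
#' scale, alternating once with a branch-length pass.
#'
#' @param alignment a nucleotide alignment [seq_tbl].
#' @param tree evaluation tree with branch lengths.
#' @param ncat number of Gamma categories.
#' @param optimize_branches alternate with a branch-length optimization
#'   pass.
#' @return A [gtr_params] with attribute `loglik`.
#' @export
estimate_gtr <- function(alignment, tree, ncat = 4L,
                         optimize_branches = TRUE) {
  chars <- unlist(strsplit(alignment$residues, ""), use.names = FALSE)
  tab <- table(factor(chars, levels = NT))
  freq <- pmax(as.numeric(tab), 1) / max(sum(tab), 1)
  freq <- freq / sum(freq)
  make <- function(theta) {
    gtr_params(rates = c(exp(theta[1:5]), 1), base_freq = freq,
               alpha = exp(theta[6]), ncat = ncat)
  }
  obj <- function(theta) {
    -gtr_gamma_loglik(alignment, tree, make(theta))
  }
  fit <- stats::optim(c(rep(0, 5), 0), obj, method = "Nelder-Mead",
                      control = list(maxit = 300))
  params <- make(fit$par)
  if (optimize_branches) {
    tree <- optimize_branch_lengths(alignment, tree, params,
                                    max_passes = 1L)
    fit <- stats::optim(fit$par, function(theta) {
      -gtr_gamma_loglik(alignment, tree, make(theta))
    }, method = "Nelder-Mead", control = list(maxit = 200))
    params <- make(fit$par)
  }
  attr(params, "loglik") <- -fit$value
  params
}
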