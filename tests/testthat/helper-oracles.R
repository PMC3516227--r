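# Independent oracles used to check [DERIVED] expectations. These are
# deliberately naive re-implementations (enumeration / dynamic
# programming from first principles) kept separate from the package code
# so each check exercises two independent routes to the same number.

# ---- Smith-Waterman (Gotoh affine-gap, local) oracle ----------------------
# Returns best local alignment score, gapped strings and 1-based
# coordinates. O(nm) full DP with traceback; no heuristics.
oracle_local_align <- function(a, b, match = 1, mismatch = -2,
                               gap_open = -5, gap_extend = -2) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)       # best ending in a match/mismatch
  X <- matrix(NEG, n + 1, m + 1)     # gap in b (consume a)
  Y <- matrix(NEG, n + 1, m + 1)     # gap in a (consume b)
  H <- matrix(0, n + 1, m + 1)       # best of the three, floored at 0
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (A[i] == B[j]) match else mismatch
      M[i + 1, j + 1] <- H[i, j] + s
      X[i + 1, j + 1] <- max(H[i, j + 1] + gap_open + gap_extend,
                             X[i, j + 1] + gap_extend)
      Y[i + 1, j + 1] <- max(H[i + 1, j] + gap_open + gap_extend,
                             Y[i + 1, j] + gap_extend)
      H[i + 1, j + 1] <- max(0, M[i + 1, j + 1], X[i + 1, j + 1],
                             Y[i + 1, j + 1])
    }
  }
  best <- which(H == max(H), arr.ind = TRUE)
  # deterministic endpoint: smallest i then j
  best <- best[order(best[, 1], best[, 2]), , drop = FALSE][1, ]
  i <- best[1]; j <- best[2]
  qa <- character(0); sa <- character(0)
  state <- c("M", "X", "Y")[which.max(c(M[i, j], X[i, j], Y[i, j]))]
  end_i <- i - 1; end_j <- j - 1
  while (i > 1 && j > 1 && H[i, j] > 0) {
    if (state == "M") {
      qa <- c(A[i - 1], qa); sa <- c(B[j - 1], sa)
      i <- i - 1; j <- j - 1
      if (H[i, j] == 0) break
      state <- c("M", "X", "Y")[which.max(c(M[i, j], X[i, j], Y[i, j]))]
    } else if (state == "X") {
      qa <- c(A[i - 1], qa); sa <- c("-", sa)
      from_open <- H[i - 1, j] + gap_open + gap_extend
      state <- if (X[i, j] == from_open) "H" else "X"
      i <- i - 1
      if (state == "H") {
        if (H[i, j] == 0) break
        state <- c("M", "X", "Y")[which.max(c(M[i, j], X[i, j], Y[i, j]))]
      }
    } else {
      qa <- c("-", qa); sa <- c(B[j - 1], sa)
      from_open <- H[i, j - 1] + gap_open + gap_extend
      state <- if (Y[i, j] == from_open) "H" else "Y"
      j <- j - 1
      if (state == "H") {
        if (H[i, j] == 0) break
        state <- c("M", "X", "Y")[which.max(c(M[i, j], X[i, j], Y[i, j]))]
      }
    }
  }
  cols <- qa != "-" & sa != "-"
  ident <- if (any(cols)) 100 * sum(qa[cols] == sa[cols]) / sum(cols) else 0
  list(score = max(H), q_aln = paste(qa, collapse = ""),
       s_aln = paste(sa, collapse = ""), identity = ident,
       q_start = i, q_end = end_i, s_start = j, s_end = end_j)
}

# affine-gap score of a given gapped alignment (same scheme as the oracle)
oracle_score_alignment <- function(qa, sa, match = 1, mismatch = -2,
                                   gap_open = -5, gap_extend = -2) {
  q <- strsplit(qa, "")[[1]]; s <- strsplit(sa, "")[[1]]
  score <- 0; in_gap <- ""
  for (k in seq_along(q)) {
    side <- if (q[k] == "-") "q" else if (s[k] == "-") "s" else ""
    if (side != "") {
      score <- score + gap_extend + if (in_gap == side) 0 else gap_open
    } else {
      score <- score + if (q[k] == s[k]) match else mismatch
    }
    in_gap <- side
  }
  score
}

# ---- global (Needleman-Wunsch) alignment column-count oracle --------------
oracle_global_columns <- function(a, b, match = 1, mismatch = -1,
                                  gap = -2) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B)
  D <- matrix(0, n + 1, m + 1)
  D[, 1] <- gap * (0:n); D[1, ] <- gap * (0:m)
  for (i in seq_len(n)) for (j in seq_len(m)) {
    s <- if (A[i] == B[j]) match else mismatch
    D[i + 1, j + 1] <- max(D[i, j] + s, D[i, j + 1] + gap,
                           D[i + 1, j] + gap)
  }
  # traceback counting columns
  i <- n + 1; j <- m + 1; cols <- 0
  while (i > 1 || j > 1) {
    s <- if (i > 1 && j > 1 && A[i - 1] == B[j - 1]) match else mismatch
    if (i > 1 && j > 1 && D[i, j] == D[i - 1, j - 1] + s) {
      i <- i - 1; j <- j - 1
    } else if (i > 1 && D[i, j] == D[i - 1, j] + gap) {
      i <- i - 1
    } else {
      j <- j - 1
    }
    cols <- cols + 1
  }
  cols
}

# normalized GTR rate matrix built independently of the package internals
oracle_gtr_q <- function(params) {
  nt <- c("A", "C", "G", "T")
  s <- params$rates  # AC, AG, AT, CG, CT, GT
  pi <- params$base_freq
  Q <- matrix(0, 4, 4, dimnames = list(nt, nt))
  Q["A", "C"] <- s[1] * pi[2]; Q["A", "G"] <- s[2] * pi[3]
  Q["A", "T"] <- s[3] * pi[4]
  Q["C", "A"] <- s[1] * pi[1]; Q["C", "G"] <- s[4] * pi[3]
  Q["C", "T"] <- s[5] * pi[4]
  Q["G", "A"] <- s[2] * pi[1]; Q["G", "C"] <- s[4] * pi[2]
  Q["G", "T"] <- s[6] * pi[4]
  Q["T", "A"] <- s[3] * pi[1]; Q["T", "C"] <- s[5] * pi[2]
  Q["T", "G"] <- s[6] * pi[3]
  diag(Q) <- -rowSums(Q)
  Q / sum(pi * -diag(Q))
}

# ---- GTR+Gamma likelihood by brute-force state enumeration ----------------
# Sums over every assignment of states to internal nodes; usable only for
# tiny trees. Gamma handled by the same equal-weight category scheme.
oracle_gtr_gamma_loglik <- function(alignment, tree, params) {
  nt <- c("A", "C", "G", "T")
  mats <- lapply(seq_len(nrow(alignment)), function(i) {
    strsplit(alignment$residues[i], "")[[1]]
  })
  names(mats) <- alignment$id
  rates <- mosaicTE:::discrete_gamma_rates(params$alpha, params$ncat)
  ntip <- length(tree$tip.label)
  nnode <- tree$Nnode
  root <- ntip + 1L
  # per-category transition matrices per edge
  nsite <- nchar(alignment$residues[1])
  total <- 0
  for (s in seq_len(nsite)) {
    site_lik <- 0
    for (r in rates) {
      Q <- oracle_gtr_q(params)
      P <- lapply(seq_len(nrow(tree$edge)), function(e) {
        as.matrix(Matrix::expm(Q * tree$edge.length[e] * r))
      })
      # enumerate internal states
      grid <- as.matrix(expand.grid(rep(list(1:4), nnode)))
      lik_r <- 0
      for (g in seq_len(nrow(grid))) {
        states <- integer(ntip + nnode)
        states[(ntip + 1):(ntip + nnode)] <- grid[g, ]
        p <- params$base_freq[states[root]]
        ok <- TRUE
        for (e in seq_len(nrow(tree$edge))) {
          par <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
          if (ch <= ntip) {
            obs <- mats[[tree$tip.label[ch]]][s]
            if (obs %in% nt) {
              p <- p * P[[e]][states[par], match(obs, nt)]
            } # gap/N: sum over all states = row sum = 1
          } else {
            p <- p * P[[e]][states[par], states[ch]]
          }
          if (p == 0) { ok <- FALSE; break }
        }
        if (ok) lik_r <- lik_r + p
      }
      site_lik <- site_lik + lik_r / params$ncat
    }
    total <- total + log(site_lik)
  }
  total
}

# ---- exhaustive NJ oracle -------------------------------------------------
# All unrooted topologies on <=6 taxa, ordinary least-squares branch
# lengths, minimum sum-of-squares wins. Returns the winning ape tree.
oracle_all_topologies <- function(labels) {
  phangorn::allTrees(length(labels), rooted = FALSE, tip.label = labels)
}

oracle_ls_fit <- function(topo, d) {
  # design matrix: path indicator of each edge for each taxon pair
  labels <- topo$tip.label
  n <- length(labels)
  topo$edge.length <- rep(1, nrow(topo$edge))
  pairs <- t(combn(n, 2))
  X <- matrix(0, nrow(pairs), nrow(topo$edge))
  for (k in seq_len(nrow(pairs))) {
    pth <- ape::nodepath(topo, pairs[k, 1], pairs[k, 2])
    for (e in seq_len(nrow(topo$edge))) {
      if (topo$edge[e, 1] %in% pth && topo$edge[e, 2] %in% pth) {
        X[k, e] <- 1
      }
    }
  }
  y <- d[cbind(labels[pairs[, 1]], labels[pairs[, 2]])]
  fit <- stats::lm.fit(X, y)
  list(lengths = fit$coefficients, ssq = sum(fit$residuals^2))
}

oracle_best_tree_ls <- function(d) {
  labels <- rownames(d)
  topos <- oracle_all_topologies(labels)
  best <- NULL; best_ssq <- Inf
  for (i in seq_along(topos)) {
    topo <- topos[[i]]  # [[ restores the shared tip labels of multiPhylo
    f <- oracle_ls_fit(topo, d)
    if (f$ssq < best_ssq) {
      best_ssq <- f$ssq
      topo$edge.length <- pmax(f$lengths, 0)
      best <- topo
    }
  }
  best
}

# random additive distance matrix from a random binary tree
random_additive_matrix <- function(ntaxa, seed) {
  withr::local_seed(seed)
  tr <- ape::rtree(ntaxa, rooted = FALSE,
                   br = function(n) stats::runif(n, 0.1, 2))
  tr$tip.label <- sort(tr$tip.label)[sample.int(ntaxa)]
  list(tree = tr, d = cophenetic(tr))
}

# ---- brute-force Dollo loss oracle ----------------------------------------
# Smallest set of loss edges below the origin reproducing the pattern,
# found by increasing-size exhaustive search over edge subsets.
oracle_dollo_min_losses <- function(tree, pattern, origin = NULL) {
  state <- setNames(pattern$state, pattern$species)
  keep <- names(state)[state != "unknown"]
  tree <- ape::keep.tip(tree, intersect(tree$tip.label, keep))
  ntip <- length(tree$tip.label)
  origin_node <- if (is.null(origin)) ntip + 1L else origin
  target <- state[tree$tip.label] == "absent"
  below_tips <- function(node) {
    if (node <= ntip) return(node)
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, below_tips))
  }
  in_origin <- below_tips(origin_node)
  edges <- seq_len(nrow(tree$edge))
  realized <- function(loss_edges) {
    absent <- rep(FALSE, ntip)
    absent[setdiff(seq_len(ntip), in_origin)] <- TRUE
    for (e in loss_edges) {
      absent[intersect(below_tips(tree$edge[e, 2]), seq_len(ntip))] <- TRUE
    }
    absent
  }
  if (identical(unname(realized(integer(0))), unname(target))) return(0L)
  for (k in seq_len(length(edges))) {
    subsets <- combn(edges, k)
    for (c_i in seq_len(ncol(subsets))) {
      if (identical(unname(realized(subsets[, c_i])), unname(target))) {
        return(k)
      }
    }
  }
  stop("no loss placement reproduces the pattern")
}

# ---- Fitch changes by exhaustive internal-state enumeration ---------------
oracle_fitch_min_changes <- function(tree, tipstates) {
  ntip <- length(tree$tip.label)
  vals <- sort(unique(unlist(tipstates)))
  nnode <- tree$Nnode
  grid <- as.matrix(expand.grid(rep(list(vals), nnode)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    assign <- c(unlist(tipstates[tree$tip.label]), grid[g, ])
    changes <- sum(assign[tree$edge[, 1]] != assign[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# ---- K80 expected divergence via numerical matrix exponential -------------
oracle_k80_expected_p <- function(d, kappa) {
  # rate matrix with transitions A<->G, C<->T
  nt <- c("A", "C", "G", "T")
  beta <- 1 / (kappa + 2); alpha <- kappa * beta
  Q <- matrix(beta, 4, 4, dimnames = list(nt, nt))
  Q["A", "G"] <- alpha; Q["G", "A"] <- alpha
  Q["C", "T"] <- alpha; Q["T", "C"] <- alpha
  diag(Q) <- 0; diag(Q) <- -rowSums(Q)
  # scale to 1 expected substitution per unit
  Q <- Q / sum(-diag(Q) * rep(1 / 4, 4))
  P <- as.matrix(Matrix::expm(Q * d))
  1 - mean(diag(P))
}
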