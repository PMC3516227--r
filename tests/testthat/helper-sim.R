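# Small fixture builders shared across test files.

random_nt <- function(n, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# seq_tbl from named character vector
tbl_of <- function(x, species = "unknown") {
  seq_tbl(id = names(x), residues = unname(x),
          species = rep_len(species, length(x)))
}

# a small aligned seq_tbl (rows already equal length)
aln_of <- function(x, species = "unknown") tbl_of(x, species)

# random GTR parameter draw for likelihood oracles
random_gtr <- function(seed, ncat = 2, gamma = TRUE) {
  withr::local_seed(seed)
  freqs <- stats::runif(4, 0.5, 1.5); freqs <- freqs / sum(freqs)
  gtr_params(rates = stats::runif(6, 0.3, 3), base_freq = freqs,
             alpha = if (gamma) stats::runif(1, 0.3, 3) else Inf,
             ncat = ncat)
}

# fixed four-leaf host tree used by simulator tests
host4 <- function() {
  parse_newick("((L:0.05,X:0.05):0.02,(T1:0.04,T2:0.04):0.03);")
}

# TRUE when the gene tree positively resolves against monophyly of `taxa`:
# the taxa|rest split must be incompatible with the tree after collapsing
# zero-length branches (a claim carried only by a zero-length branch is no
# claim at all)
resolves_against_monophyly <- function(tree, taxa) {
  tr <- ape::di2multi(tree, tol = 1e-8)
  tips <- tr$tip.label
  ntip <- length(tips)
  if (tr$Nnode < 2L) return(FALSE)
  for (node in (ntip + 2L):(ntip + tr$Nnode)) {
    A <- tips[phangorn::Descendants(tr, node, "tips")[[1L]]]
    compatible <- length(intersect(A, taxa)) == 0L ||
      all(A %in% taxa) || all(taxa %in% A) ||
      length(union(A, taxa)) == ntip
    if (!compatible) return(TRUE)
  }
  FALSE
}
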