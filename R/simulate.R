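#' @importFrom rlang .data
NULL

NT <- c("A", "C", "G", "T")

# K80 transition probability matrix for expected `d` substitutions/site and
# transition/transversion rate ratio kappa. State order A,C,G,T.
k80_pmat <- function(d, kappa = 2) {
  stopifnot(d >= 0, kappa > 0)
  beta <- 1 / (kappa + 2)
  alpha <- kappa * beta
  e1 <- exp(-4 * beta * d)
  e2 <- exp(-2 * (alpha + beta) * d)
  same <- 0.25 + 0.25 * e1 + 0.5 * e2
  ts <- 0.25 + 0.25 * e1 - 0.5 * e2
  tv <- 0.25 - 0.25 * e1
  p <- matrix(tv, 4, 4, dimnames = list(NT, NT))
  diag(p) <- same
  p["A", "G"] <- p["G", "A"] <- ts
  p["C", "T"] <- p["T", "C"] <- ts
  p
}

# Expected proportion of differing sites between two sequences separated by
# total path `d` substitutions/site under K80.
k80_expected_p <- function(d, kappa = 2) {
  p <- k80_pmat(d, kappa)
  1 - mean(diag(p))
}

seq_to_int <- function(x) {
  match(strsplit(x, "", fixed = TRUE)[[1L]], NT)
}

int_to_seq <- function(v) paste(NT[v], collapse = "")

# Evolve integer-coded sites through transition matrix `p` (rows sum to 1).
sample_states <- function(states, p) {
  cum <- t(apply(p, 1L, cumsum))
  r <- stats::runif(length(states))
  rowSums(cum[states, , drop = FALSE] < r) + 1L
}

#' Configure a transposable-element family simulation
#'
#' Defines the evolutionary scenario: vertical descent of element copies
#' along a host tree, intragenomic proliferation, neutral sequence decay
#' under a K80 substitution process, short indels, and optional horizontal
#' transfer events with a proliferation burst in the recipient genome.
#'
#' The defaults mirror a recently proliferated Tc1-type family: a 1,610-nt
#' master element carrying a single long transposase open reading frame,
#' transition bias `kappa = 2`, and a proliferation burst placed at the
#' family origin and after every transfer.
#'
#' @param host_tree an `ape::phylo` host species tree with branch lengths
#'   in substitutions/site.
#' @param master master element nucleotide sequence; when `NULL` a random
#'   element of `master_length` nt containing one ORF is generated from
#'   `seed`.
#' @param master_length length of the generated master element (nt).
#' @param birth_rate copy births per existing copy per unit branch length.
#' @param rate_multiplier per-copy substitution rate multiplier applied to
#'   host branch lengths.
#' @param kappa K80 transition/transversion rate ratio.
#' @param indel_rate indel events per copy per unit branch length.
#' @param indel_geom geometric decay parameter for indel lengths 1-3.
#' @param transfers a data frame with columns `donor`, `recipient` (branch
#'   ids, named by the child node: tip labels for terminal branches),
#'   `time` (fraction along the recipient branch in `[0,1]`).
#' @param burst number of copies seeded at the family origin and created
#'   from the single transferred copy after each transfer.
#' @param origin node at which the family originates: a tip label or
#'   `"node<k>"` internal-node id; `NULL` seeds the family at the host
#'   root, so every species inherits it vertically. Seeding it on one
#'   lineage makes all other species' copies purely transfer-derived.
#' @param seed integer RNG seed; all simulator randomness derives from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(host_tree, master = NULL, master_length = 1610,
                       birth_rate = 0, rate_multiplier = 1, kappa = 2,
                       indel_rate = 0, indel_geom = 0.5,
                       transfers = NULL, burst = 5, origin = NULL,
                       seed = 1) {
  stopifnot(inherits(host_tree, "phylo"),
            birth_rate >= 0, rate_multiplier >= 0, kappa > 0,
            indel_rate >= 0, burst >= 1)
  if (is.null(host_tree$edge.length)) stop("host tree needs branch lengths")
  if (is.null(master)) {
    master <- random_master_element(master_length, seed = seed)
  }
  master <- toupper(master)
  orf <- locate_orf(master, min_codons = 50)
  if (!orf$intact) stop("master element must contain an intact ORF")
  if (substr(master, orf$start + 1L, orf$start + 3L) != "ATG") {
    stop("master ORF must start with ATG")
  }
  if (!is.null(transfers)) {
    transfers <- tibble::as_tibble(transfers)
    stopifnot(all(c("donor", "recipient", "time") %in% names(transfers)))
  }
  structure(list(host_tree = host_tree, master = master, orf = orf,
                 birth_rate = birth_rate, rate_multiplier = rate_multiplier,
                 kappa = kappa, indel_rate = indel_rate,
                 indel_geom = indel_geom, transfers = transfers,
                 burst = as.integer(burst), origin = origin,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Generate a random master element with a single long ORF
#'
#' Builds a nucleotide element of the requested length whose central region
#' is an intact open reading frame (ATG ... stop, no internal stops),
#' flanked by non-coding sequence hardened against competing ORFs.
#'
#' @param length total element length in nt (>= 200).
#' @param orf_fraction fraction of the element devoted to the ORF.
#' @param seed RNG seed.
#' @return A nucleotide string.
#' @export
random_master_element <- function(length = 1610, orf_fraction = 0.63,
                                  seed = 1) {
  stopifnot(length >= 200)
  withr::local_seed(seed)
  codons <- max(20L, floor(length * orf_fraction / 3) - 2L)
  sense <- setdiff(apply(expand.grid(NT, NT, NT), 1L, paste, collapse = ""),
                   c("TAA", "TAG", "TGA"))
  orf <- paste0("ATG", paste(sample(sense, codons, replace = TRUE),
                             collapse = ""), "TAA")
  flank_total <- length - nchar(orf)
  left_n <- floor(flank_total / 2)
  rand_nt <- function(n) paste(sample(NT, n, replace = TRUE), collapse = "")
  left <- rand_nt(left_n)
  if (left_n >= 3L) {
    # in-frame stop just upstream of the ORF blocks read-through extension
    substr(left, left_n - 2L, left_n) <- "TAA"
  }
  right <- rand_nt(flank_total - left_n)
  element <- paste0(left, orf, right)
  # disrupt any competing ORF that could rival the designed one
  for (iter in 1:20) {
    ann <- locate_orf(element, min_codons = 50)
    if (is.na(ann$start) ||
        (ann$start == left_n && ann$end == left_n + nchar(orf))) {
      break
    }
    starts <- seq(ann$start, ann$end - 3L, by = 3L)
    outside <- starts[starts + 3L <= left_n | starts >= left_n + nchar(orf)]
    mid <- if (length(outside)) outside[ceiling(length(outside) / 2)] else
      starts[ceiling(length(starts) / 2)]
    stop_codon <- if (ann$strand == "+") "TAA" else "TTA"
    substr(element, mid + 1L, mid + 3L) <- stop_codon
  }
  ann <- locate_orf(element, min_codons = 50)
  if (is.na(ann$start) || ann$start != left_n) {
    stop("failed to build a master element with a dominant ORF; ",
         "try another seed")
  }
  element
}

# Apply `n_events` random indels (length 1-3, geometric decay) to sequence x.
apply_indels <- function(x, n_events, geom_p) {
  for (k in seq_len(n_events)) {
    len <- min(3L, stats::rgeom(1L, geom_p) + 1L)
    n <- nchar(x)
    if (stats::runif(1) < 0.5 && n > len + 1L) {       # deletion
      pos <- sample.int(n - len, 1L)
      x <- paste0(substr(x, 1L, pos - 1L), substr(x, pos + len, n))
    } else {                                           # insertion
      pos <- sample.int(n, 1L)
      ins <- paste(sample(NT, len, replace = TRUE), collapse = "")
      x <- paste0(substr(x, 1L, pos), ins, substr(x, pos + 1L, n))
    }
  }
  x
}

# Evolve a set of copies over `dist` substitutions/site (already scaled).
evolve_copies <- function(copies, dist, kappa, indel_rate, indel_geom) {
  if (dist <= 0 || length(copies) == 0L) return(copies)
  p <- k80_pmat(dist, kappa)
  lapply(copies, function(x) {
    v <- sample_states(seq_to_int(x), p)
    x2 <- int_to_seq(v)
    n_ind <- stats::rpois(1L, indel_rate * dist)
    if (n_ind > 0L) x2 <- apply_indels(x2, n_ind, indel_geom)
    x2
  })
}

#' Simulate a transposable-element family on a host tree
#'
#' Copies descend vertically from a burst of `burst` identical master
#' copies at the root, mutate under K80 (plus short indels), proliferate at
#' `birth_rate`, and -- when transfer events are configured -- a single
#' randomly chosen extant donor copy is copied into the recipient lineage
#' at the stated time and burst-amplified there. Ground truth (genealogy,
#' realized transfers, ORF status, per-species presence) is returned
#' alongside the sequences.
#'
#' @param config a [sim_config].
#' @return A list with `records` (a [seq_tbl] of extant copies at the
#'   leaves, tagged by species) and `truth` (list: `genealogy`,
#'   `transfers`, `orf_status`, `presence`).
#' @export
evolve_family <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::local_seed(config$seed)
  tree <- config$host_tree
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  depths <- ape::node.depth.edgelength(tree)
  node_name <- c(tree$tip.label,
                 paste0("node", seq_len(tree$Nnode) + ntip)[])
  edge_child <- tree$edge[, 2L]
  edge_of <- function(branch_id) {
    idx <- match(branch_id, node_name[edge_child])
    if (is.na(idx)) stop("unknown branch id: ", branch_id)
    idx
  }

  transfers <- config$transfers
  if (!is.null(transfers) && nrow(transfers) > 0L) {
    transfers$donor_edge <- vapply(transfers$donor, edge_of, 1L)
    transfers$recipient_edge <- vapply(transfers$recipient, edge_of, 1L)
    transfers$abs_time <- depths[tree$edge[transfers$recipient_edge, 1L]] +
      transfers$time * tree$edge.length[transfers$recipient_edge]
    d_start <- depths[tree$edge[transfers$donor_edge, 1L]]
    d_end <- depths[edge_child[transfers$donor_edge]]
    bad <- transfers$abs_time < d_start - 1e-9 |
      transfers$abs_time > d_end + 1e-9
    if (any(bad)) {
      stop("transfer between non-contemporaneous branches: ",
           transfers$donor[bad][1L], " -> ", transfers$recipient[bad][1L])
    }
  } else {
    transfers <- tibble::tibble(donor = character(), recipient = character(),
                                time = numeric(), donor_edge = integer(),
                                recipient_edge = integer(),
                                abs_time = numeric())
  }

  counter <- 0L
  gene_rows <- list()
  new_copy <- function(parent, branch, time, origin) {
    counter <<- counter + 1L
    id <- sprintf("cp%05d", counter)
    gene_rows[[length(gene_rows) + 1L]] <<-
      tibble::tibble(copy_id = id, parent_copy = parent, branch = branch,
                     birth_time = time, origin = origin)
    id
  }

  mult <- config$rate_multiplier
  # node states: list of named character vectors (copy id -> sequence)
  states <- vector("list", ntip + tree$Nnode)
  origin_node <- if (is.null(config$origin)) root else {
    hit <- match(config$origin, node_name)
    if (is.na(hit)) stop("unknown origin node: ", config$origin)
    hit
  }
  seed_family <- function(node) {
    ids <- vapply(seq_len(config$burst), function(i) {
      new_copy(NA_character_, node_name[node], depths[node], "root")
    }, "")
    stats::setNames(rep(config$master, config$burst), ids)
  }
  states[[root]] <- if (origin_node == root) seed_family(root) else
    character(0)

  snapshots <- vector("list", nrow(transfers))   # donor copies at abs_time
  done_edge <- rep(FALSE, nrow(tree$edge))

  run_edge <- function(e) {
    parent <- tree$edge[e, 1L]; child <- tree$edge[e, 2L]
    len <- tree$edge.length[e]
    t0 <- depths[parent]
    copies <- states[[parent]]
    # fork lineage-local copy ids so sister branches never share ids
    if (length(copies)) {
      ids <- vapply(names(copies), function(pid) {
        new_copy(pid, node_name[child], t0, "descent")
      }, "", USE.NAMES = FALSE)
      names(copies) <- ids
    }
    # family seeded at the start of the origin branch
    if (child == origin_node) copies <- c(copies, seed_family(parent))
    # event schedule along this edge: births, donor snapshots, injections
    ev <- tibble::tibble(time = numeric(), kind = character(),
                         idx = integer())
    if (config$birth_rate > 0 && length(copies) > 0L) {
      nb <- stats::rpois(1L, config$birth_rate * len * length(copies))
      if (nb > 0L) {
        ev <- dplyr::bind_rows(ev, tibble::tibble(
          time = t0 + sort(stats::runif(nb)) * len, kind = "birth",
          idx = NA_integer_))
      }
    }
    don <- which(transfers$donor_edge == e)
    if (length(don)) {
      ev <- dplyr::bind_rows(ev, tibble::tibble(
        time = transfers$abs_time[don], kind = "snapshot", idx = don))
    }
    rec <- which(transfers$recipient_edge == e)
    if (length(rec)) {
      ev <- dplyr::bind_rows(ev, tibble::tibble(
        time = transfers$abs_time[rec], kind = "inject", idx = rec))
    }
    ev <- ev[order(ev$time), , drop = FALSE]
    now <- t0
    for (i in seq_len(nrow(ev))) {
      seg <- (ev$time[i] - now) * mult
      copies <- stats::setNames(
        evolve_copies(as.list(copies), seg, config$kappa,
                      config$indel_rate, config$indel_geom) |> unlist(),
        names(copies))
      if (is.null(copies)) copies <- character(0)
      now <- ev$time[i]
      if (ev$kind[i] == "birth" && length(copies) > 0L) {
        src <- sample(names(copies), 1L)
        id <- new_copy(src, node_name[child], now, "birth")
        copies[id] <- copies[[src]]
      } else if (ev$kind[i] == "snapshot") {
        k <- ev$idx[i]
        if (length(copies) == 0L) {
          stop("transfer ", k, ": donor lineage carries no copies")
        }
        src <- sample(names(copies), 1L)
        snapshots[[k]] <<- stats::setNames(copies[[src]], src)
      } else if (ev$kind[i] == "inject") {
        k <- ev$idx[i]
        snap <- snapshots[[k]]
        if (is.null(snap)) stop("internal: snapshot not ready")
        ids <- vapply(seq_len(config$burst), function(j) {
          new_copy(names(snap), node_name[child], now,
                   paste0("transfer", k))
        }, "")
        copies <- c(copies, stats::setNames(rep(unname(snap), config$burst),
                                            ids))
      }
    }
    seg <- (t0 + len - now) * mult
    copies <- stats::setNames(
      evolve_copies(as.list(copies), seg, config$kappa,
                    config$indel_rate, config$indel_geom) |> unlist(),
      names(copies))
    if (is.null(copies)) copies <- character(0)
    states[[child]] <<- copies
    done_edge[e] <<- TRUE
  }

  # process edges parents-first; defer recipient edges until their donor
  # snapshot exists
  pending <- order(depths[edge_child])
  while (length(pending)) {
    progressed <- FALSE
    for (e in pending) {
      parent <- tree$edge[e, 1L]
      parent_ready <- parent == root ||
        done_edge[match(parent, edge_child)]
      rec <- which(transfers$recipient_edge == e)
      snaps_ready <- all(vapply(rec, function(k) {
        done_edge[transfers$donor_edge[k]] ||
          transfers$donor_edge[k] == e
      }, TRUE))
      if (parent_ready && snaps_ready) {
        run_edge(e)
        pending <- setdiff(pending, e)
        progressed <- TRUE
        break
      }
    }
    if (!progressed) stop("circular transfer dependencies between branches")
  }

  genealogy <- dplyr::bind_rows(gene_rows)
  recs <- lapply(seq_len(ntip), function(tip) {
    copies <- states[[tip]]
    if (length(copies) == 0L) return(NULL)
    sp <- tree$tip.label[tip]
    seq_tbl(id = names(copies), residues = unname(copies),
            description = paste0("species=", sp), source = "simulated")
  })
  records <- dplyr::bind_rows(recs)
  min_codons <- max(10L, floor((config$orf$end - config$orf$start) / 3L) - 2L)
  orf_status <- tibble::tibble(
    copy_id = records$id,
    intact = vapply(records$residues, function(s) {
      locate_orf(s, min_codons = min_codons)$intact
    }, TRUE, USE.NAMES = FALSE))
  presence <- tibble::tibble(
    species = tree$tip.label,
    present = vapply(seq_len(ntip),
                     function(i) length(states[[i]]) > 0L, TRUE))
  list(records = records,
       truth = list(genealogy = genealogy,
                    transfers = transfers[, c("donor", "recipient", "time")],
                    orf_status = orf_status, presence = presence))
}

#' Emit an old, divergent within-species element family
#'
#' Generates copies of the master element that have each decayed
#' independently for `age` substitutions/site -- the signature of an
#' ancient family confined to a single genome, far more divergent than a
#' recently proliferated one.
#'
#' @param config a [sim_config].
#' @param age divergence of each copy from the master, substitutions/site
#'   (> 0).
#' @param n_copies number of copies to emit.
#' @param species species tag (defaults to the first host-tree tip).
#' @return A [seq_tbl].
#' @export
emit_background_family <- function(config, age,
                                   n_copies = config$burst,
                                   species = config$host_tree$tip.label[1L]) {
  stopifnot(inherits(config, "sim_config"))
  if (age <= 0) stop("age must be > 0")
  withr::local_seed(config$seed + 7901L)
  p <- k80_pmat(age, config$kappa)
  master_int <- seq_to_int(config$master)
  res <- vapply(seq_len(n_copies), function(i) {
    int_to_seq(sample_states(master_int, p))
  }, "")
  seq_tbl(id = sprintf("bg%04d", seq_len(n_copies)), residues = res,
          description = paste0("species=", species), source = "simulated")
}

#' Fragment sequences into EST-like records
#'
#' Each fragment is a contiguous substring of its source: uniform start
#' position, geometric length with the requested mean (clamped to the
#' sequence end, so whole copies can be returned). The source id is kept
#' in the description.
#'
#' @param records a [seq_tbl].
#' @param mean_length mean fragment length (>= 50).
#' @param seed RNG seed.
#' @param per_record fragments drawn per input record.
#' @return A [seq_tbl] of fragments tagged `source = "est"`.
#' @export
fragmentize <- function(records, mean_length, seed = 1, per_record = 1L) {
  stopifnot(mean_length >= 50)
  withr::local_seed(seed)
  rows <- list()
  for (i in seq_len(nrow(records))) {
    n <- nchar(records$residues[i])
    for (j in seq_len(per_record)) {
      start <- sample.int(n, 1L)
      len <- stats::rgeom(1L, 1 / mean_length) + 1L
      end <- min(n, start + len - 1L)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        id = sprintf("%s_f%d", records$id[i], j),
        residues = substr(records$residues[i], start, end),
        description = paste0("fragment_of=", records$id[i],
                             " species=", records$species[i]),
        species = records$species[i])
    }
  }
  frags <- dplyr::bind_rows(rows)
  frags <- frags[nchar(frags$residues) >= 1L, , drop = FALSE]
  seq_tbl(id = frags$id, residues = frags$residues,
          description = frags$description, species = frags$species,
          source = "est")
}
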