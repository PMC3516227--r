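#' Bundled cross-vertebrate element survey
#'
#' A genomic PCR-style survey of the recent (group 1) Tc1 element family
#' across 30 vertebrates: a species phylogeny plus per-species
#' presence/absence of the element. The element is present in the two
#' northern-hemisphere lampreys and in a patchy, non-monophyletic set of
#' teleosts (salmonids, pike, perch, cyprinids), and absent from
#' hagfishes, southern-hemisphere lampreys, cartilaginous fishes,
#' non-teleost ray-finned fishes and sarcopterygians -- the mosaic
#' distribution whose vertical-transmission explanation requires many
#' independent losses (see [dollo_loss_count()]).
#'
#' @return A list: `tree` (rooted `ape::phylo`), `pattern` (tibble with
#'   `species`, `state`), `teleosts` (character vector of the teleost
#'   species in the survey).
#' @export
element_survey <- function() {
  tree_path <- system.file("extdata", "vertebrate_survey_tree.nwk",
                           package = "mosaicTE", mustWork = TRUE)
  tsv_path <- system.file("extdata", "vertebrate_survey_presence.tsv",
                          package = "mosaicTE", mustWork = TRUE)
  tree <- parse_newick(paste(readLines(tree_path), collapse = ""))
  pattern <- tibble::as_tibble(utils::read.delim(tsv_path))
  teleosts <- c("Zebrafish", "European_chub", "Barbel", "Northern_pike",
                "Atlantic_salmon", "Lake_trout", "Grayling", "Medaka",
                "Green_spotted_pufferfish", "Stickleback",
                "European_perch", "Walleye", "African_cichlid", "Bullhead")
  list(tree = tree, pattern = pattern, teleosts = teleosts)
}

#' Independent element losses implied by vertical transmission
#'
#' Counts the minimum number of independent losses a single-gain vertical
#' scenario would require, split into losses outside and inside a focal
#' clade (typically the teleosts, where the element is patchily present).
#'
#' @param tree rooted species tree.
#' @param pattern presence/absence tibble (`species`, `state`).
#' @param focal_clade species whose most recent common ancestor delimits
#'   the focal clade.
#' @return A list: `total`, `outside`, `inside`, and the loss branch
#'   lists.
#' @export
loss_accounting <- function(tree, pattern, focal_clade) {
  full <- dollo_loss_count(tree, pattern)
  mrca <- ape::getMRCA(tree, intersect(focal_clade, tree$tip.label))
  clade <- ape::extract.clade(tree, mrca)
  inside <- dollo_loss_count(
    clade, pattern[pattern$species %in% clade$tip.label, , drop = FALSE])
  list(total = full$losses,
       outside = full$losses - inside$losses,
       inside = inside$losses,
       loss_branches = full$loss_branches,
       inside_branches = inside$loss_branches)
}
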