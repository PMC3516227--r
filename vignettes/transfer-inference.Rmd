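---
title: "Methods: detecting horizontal transposon transfer from mosaic phylogenetic distributions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: detecting horizontal transposon transfer from mosaic phylogenetic distributions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The scientific question

Tc1/mariner DNA transposons occasionally appear in host lineages where
vertical descent cannot plausibly have put them: nearly identical copies
in two distantly related hosts, absent from everything in between. This
*mosaic phylogenetic distribution* is the classical signature of
horizontal transfer (HT). mosaicTE implements the complete desk analysis
for making that argument quantitative, plus a simulator that generates
element families with known ground truth so every inferential step can
be validated.

The argument has four independent legs, and the package implements all
four so that none has to carry the conclusion alone:

1. **Identity structure.** A recently active family forms a tight,
   high-identity cluster around its consensus; an anciently resident
   family is diffuse. A young family shared across distant hosts is
   anomalous under vertical descent.
2. **Phylogenetic incongruence.** In the element genealogy, copies from
   the recipient host nest *inside* the donor's diversity instead of
   forming a sister group, and constrained trees forcing host-species
   monophyly score significantly worse (Kishino–Hasegawa/RELL).
3. **Loss accounting.** Explaining a patchy presence/absence pattern by
   vertical transmission alone requires a specific minimum number of
   independent losses under Dollo parsimony (single gain, unlimited
   losses); an implausibly large count argues for transfer.
4. **Neutrality.** Transposase ORFs in HT candidates evolve with
   Ka/Ks near one — they are genomic fossils decaying neutrally, so
   high identity across hosts cannot be explained by purifying
   selection on an anciently shared copy.

## The element model

An element family descends from one *master* element: a ~1.6 kb
nucleotide sequence whose central ~63% is an intact transposase ORF
(`random_master_element()` hardens the flanks against competing ORFs so
annotation is unambiguous). Copies accumulate substitutions under K80
(transition/transversion ratio `kappa`, default 2) and optional
indels; a copy's age is therefore readable from its divergence from the
family consensus. `locate_orf()`/`deduce_peptide()` classify each copy's
ORF as intact, frameshifted, or nonsense-disrupted, with disrupted
codons excised the way a human curator would restore the reading frame.

## What the simulator emulates — and what it does not

`evolve_family()` runs an event-driven simulation along a host species
tree. It emulates:

- seeding of the family at the start of a chosen origin branch
  (default: the root), with a proliferation `burst` of copies;
- neutral sequence decay: K80 substitutions scaled per branch, optional
  geometric-length indels;
- copy birth along branches (`birth_rate`), giving paralog structure;
- horizontal transfers at specified `(donor, recipient, time)` events —
  a copy is sampled from the donor lineage at that time and seeds a
  burst in the recipient;
- EST-like observation: `fragmentize()` cuts copies into
  uniform-start, geometric-length fragments, and
  `emit_background_family()` adds an old, diverged family for
  two-component identity distributions.

It deliberately does **not** emulate selection on the transposase (all
sites are neutral, which is the empirically supported regime for these
elements), host demography, insertion-site preference, or excision.
Those would add realism without changing what the validation needs: a
known genealogy against which the inference can be scored.

**Burst timing** is an open modeling question. The simulator places the
proliferation burst at the moment of seeding (family origin or transfer
arrival), which matches the "invasion then quiescence" life cycle
usually inferred for Tc1 elements. Real families may burst repeatedly
or after a lag; the identity distribution would then be multimodal in
ways the two-family simulation does not produce. The grouping code
makes no unimodality assumption, so this limits only the simulator, not
the inference.

## Defaults and why

- `master_length = 1610`, `orf_fraction = 0.63`: a typical Tc1 element
  (~340-residue transposase plus inverted-repeat flanks).
- `kappa = 2`: the textbook transition bias for neutral vertebrate DNA.
- `burst = 5` per seeding: small enough to keep desk-scale runs fast,
  large enough that within-host clades are resolvable.
- Identity grouping thresholds 92.5% / 90%: the young, cross-host
  family occupies 92.5–100% identity to its consensus; anciently
  resident copies fall below 90%. Copies between the thresholds stay
  `unassigned` rather than being forced into a group.
- Histogram `bin_width = 0.5` percentage points: identities live on a
  0–100 scale and the gap between a 2%-divergence family and a
  30%-divergence family spans dozens of bins, so the bin width only
  needs to resolve the *recent* family's spread. With ~150 comparable
  sites as the floor, one misidentified site moves identity by at most
  ~0.7 points; 0.5-point bins are at that resolution, and the split is
  insensitive to doubling or halving it. Bins are right-closed so the
  100% bin contains the exact-match copies.
- Deduplication at 95% nucleotide / 80% peptide identity within a host:
  two hits are the same insertion if they differ by less than the
  family's own within-host spread.

## The neutrality check and kappa = 1

Nei–Gojobori (1986) pathway counting treats every substitution type as
equally likely when classifying sites as synonymous or nonsynonymous.
Under a transition-biased neutral process (`kappa > 1`), transitions are
enriched and transitions at third positions are disproportionately
synonymous, so NG86 reports dS > dN and a spuriously low omega even
for perfectly neutral sequence. The acceptance check for "omega near 1
under neutrality" therefore simulates with `kappa = 1`, where the NG86
assumption holds and any deviation of the median omega from 1 would
indicate a counting bug rather than a modeling artifact. With the
default `kappa = 2` the same simulation gives a median omega around
0.7–0.8 — a bias to keep in mind when reading empirical NG86 values,
and the reason omega "close to one" (not "equal to one") is the neutral
signature quoted for real elements.

## Phylogenetic engines and their cross-checks

Every phylogenetic result is computable by two routes:

- `build_nj()` (Saitou–Nei with Studier–Keppler criterion) is exact on
  additive matrices; the test suite checks it against exhaustive
  topology enumeration with ordinary least-squares branch lengths.
- `gtr_gamma_loglik()` implements Felsenstein pruning with discrete-
  Gamma rates; it is checked against brute-force enumeration of all
  internal states (an independently constructed rate matrix and matrix
  exponential) and against `phangorn::pml`.
- `dollo_loss_count()` maps losses as maximal absent subtrees below the
  single gain; it is checked against exhaustive search over loss-edge
  subsets.
- `topology_test_rell()` optimizes branch lengths per topology and
  resamples per-site log-likelihoods (RELL) for the one-sided KH test.

## Transfer calling

`call_transfers()` encodes the nesting argument directly: for each
candidate donor host, it finds foreign-host clusters fully nested
inside the donor's span of the element tree. The recipient cluster may
contain a minority of donor tips — the transferred lineage's source —
but no third host and no donor majority. A Fitch parsimony count of
host-state changes above `n_hosts - 1` flags the tree as mosaic. The
method's scope is a donor-resident family: if the recipient also has
deep native copies of the same family, nesting is no longer the right
signature and the topology test must carry the argument.

## What the topology test can and cannot reject

A subtlety worth stating plainly: when the gene tree contains copies
from only two hosts and the recipient's copies descend from a *single*
transfer, they form one clade attached at one point — and a clade's
stem edge always defines the donor|recipient bipartition, so the
constrained topology is compatible with the data and the KH/RELL test
correctly fails to reject. Rejection of host monophyly requires the
recipient's copies to sit in **two or more clusters** inside the
donor's diversity (repeated invasions, as in the empirical systems that
motivate this package) or a gene tree sampled across several host
species. The acceptance check for the topology test therefore simulates
two independent transfer events; the single-transfer case is the domain
of the nesting-based caller, which reads direction off the rooted tree
rather than testing an unrooted split.

## Limitations

- Alignment is delegated to MAFFT; at divergences where alignment
  itself is ambiguous (>~40%), identity and tree estimates inherit that
  ambiguity.
- NG86 is the historically faithful counting method, not the best
  available estimator; for publication-grade omega on biased data use
  a maximum-likelihood codon model.
- The transfer caller reports direction from nesting topology alone;
  with sparse sampling of the donor lineage, direction can be
  unresolved even when transfer is certain.
- Dollo counting assumes a single gain; families with recurrent
  invasion violate it, and `dollo_loss_count()` refuses patterns that
  are inconsistent with the declared origin rather than guessing.

## A minimal end-to-end run

```{r}
library(mosaicTE)
host <- parse_newick("((L:0.05,X:0.05):0.02,(T1:0.04,T2:0.04):0.03);")
cfg <- sim_config(host, burst = 20, origin = "L", seed = 1,
                  transfers = data.frame(donor = "L", recipient = "T1",
                                         time = 0.9))
fam <- evolve_family(cfg)
aln <- progressive_align(fam$records)
gene <- build_nj(p_distance(aln))
call_transfers(gene, setNames(aln$species, aln$id))
```
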