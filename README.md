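# mosaicTE

Detecting horizontal transfer of Tc1/mariner DNA transposons from
mosaic phylogenetic distributions.

## The science

DNA transposons of the Tc1/mariner superfamily are genomic parasites
that normally spread vertically, parent to offspring, slowly decaying
into fossils once their transposase is disrupted. Occasionally a family
shows up where vertical descent cannot put it: nearly identical copies
in two distantly related host lineages — say, a jawless lamprey and a
teleost fish — with nothing comparable in the lineages between them.
That **mosaic phylogenetic distribution** is the classical signature of
**horizontal transfer** (HT), plausibly mediated by a physical bridge
between the hosts such as parasitism.

Making that argument quantitative takes four independent lines of
evidence, all implemented here:

1. **Identity structure** — a recently active family forms a tight
   cluster of copies at 92.5–100% identity to its majority-rule
   consensus, while an anciently resident family sits below 90%
   (`identity_to_consensus()`, `histogram_identities()`,
   `classify_groups()`).
2. **Phylogenetic incongruence** — in the element genealogy the
   recipient's copies nest *inside* the donor's diversity
   (`build_nj()`, `call_transfers()`), and forcing host-species
   monophyly costs a significant amount of log-likelihood under the
   Kishino–Hasegawa/RELL test (`gtr_gamma_loglik()`,
   `constrain_monophyly()`, `topology_test_rell()`).
3. **Loss accounting** — explaining the presence/absence survey by
   vertical transmission alone requires a minimum number of independent
   losses under Dollo parsimony (`dollo_loss_count()`; the bundled
   vertebrate survey requires 6 outside the teleosts).
4. **Neutrality** — Nei–Gojobori Ka/Ks near 1 (`nei_gojobori()`) shows
   the copies are decaying fossils, so cross-host identity cannot be
   rescued by purifying selection.

A simulator of element-family evolution on a host tree
(`sim_config()`, `evolve_family()`) provides ground truth — known
master sequence, genealogy, and injected transfers — against which
every step of the inference is validated. Element harvesting from raw
sequence pools (`similarity_search()`, `merge_overlapping_fragments()`,
`build_consensus()`, `in_silico_pcr()`), ORF annotation with curator-
style disrupted-codon excision (`locate_orf()`, `deduce_peptide()`),
and a one-call pipeline (`pipeline_config()`, `run_pipeline()`) round
out the toolkit. A command-line front end lives in `exec/mosaicte`.

## Worked example

Simulate a family resident in a parasite lineage `L` that jumps once,
recently, into the teleost `T1`; then recover the transfer from
sequence alone.

```r
library(mosaicTE)

host <- parse_newick("((L:0.05,X:0.05):0.02,(T1:0.04,T2:0.04):0.03);")
cfg <- sim_config(host, burst = 20, origin = "L", seed = 1,
                  transfers = data.frame(donor = "L", recipient = "T1",
                                         time = 0.9))
fam <- evolve_family(cfg)
fam$records
#> # A tibble: 40 × 5
#>    id      description species source    residues
#>    <chr>   <chr>       <chr>   <chr>     <chr>
#>  1 cp00001 species=L   L       simulated ATATGCGAGCATTATCGTGGCTATCAAGCTGGGCCAGT…
#>  2 cp00002 species=L   L       simulated ATATGCGAGCATTATCAGGGGTGTCAAGCGGGGCCAGT…
#>  3 cp00003 species=L   L       simulated ATATGCGAGCACTATCGGGGCTATCAAGCTGGGCCACT…
#> # ℹ 37 more rows

aln  <- progressive_align(fam$records)
gene <- build_nj(p_distance(aln))
calls <- call_transfers(gene, setNames(aln$species, aln$id))
calls
#> # A tibble: 1 × 4
#>   recipient donor n_recipient_copies support
#>   <chr>     <chr>              <int>   <dbl>
#> 1 T1        L                     20      NA
attr(calls, "mosaic")
#> [1] TRUE
```

The caller names the true recipient (`T1`) and donor (`L`), and the
Fitch host-state count flags the genealogy as mosaic. The identity side
of the argument:

```r
ids <- identity_to_consensus(fam$records, cfg$master)
classify_groups(ids)
#> # A tibble: 40 × 5
#>   id      species identity compared group
#>   <chr>   <chr>      <dbl>    <int> <chr>
#> 1 cp00001 L           95.1     1610 group1
#> 2 cp00002 L           94.3     1610 group1
#> 3 cp00003 L           94.8     1610 group1
#> # ℹ 37 more rows
```

All 40 copies — lamprey-lineage and teleost alike — sit in the young,
high-identity `group1`, exactly the cross-host identity anomaly that
motivates the transfer hypothesis.

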