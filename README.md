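# polarniche

Polar-adaptation inference for ocean giant viruses from metagenomic
abundance profiles.

Giant viruses (*Nucleocytoviricota*, mirusviruses) infect marine
eukaryotic plankton across the global ocean, and their communities split
sharply at the polar front. `polarniche` is an R implementation of the
computational pipeline behind that kind of study, for microbial
ecologists and virologists who have genome-resolved abundance tables
(RPKM per genome per metagenome), sample metadata, a phylogenomic tree
and gene-family annotations, and want to:

* estimate **robust ecological optima and tolerances** — each entity's
  abundance shares populate a fixed-size weighted vector of
  environmental values (n = 10,000), whose median Q2 is the optimum and
  Q1–Q3 the tolerance;
* classify genomes into **Polar / Nonpolar / Unknown** niches by
  zero-signal rules plus Wilcoxon rank-sum tests with BH correction;
* quantify the community barrier with richness/Shannon/Pielou,
  Bray–Curtis dissimilarity and **ANOSIM** (R statistic, permutation p);
* reconstruct **ancestral niches** under the two-state equal-rates
  Markov model (P(stay, t) = ½ + ½e^(−2qt), pruning likelihood, ML rate,
  marginal node posteriors), count niche-adaptation events along
  branches, and place them in time with **relative evolutionary
  divergence** (RED);
* test the **phylogenetic signal** of gene-family distributions with
  Pagel's λ against the Brownian-motion null (χ²₁ likelihood-ratio
  test), and compare polar/nonpolar **Faith's phylogenetic diversity**;
* predict **hosts** from a virus–eukaryote co-occurrence network:
  clr transformation, a pluggable association scorer, best-edge pooling
  across size fractions, a protein-similarity support test, and
  clade-level enrichment on the viral tree (one-sided Fisher + BH);
* test **polar-specific gene and pathway enrichment** (lineage-level
  Fisher tests, pathway candidate/display rules, genome-level polar-KO
  fractions with Kruskal–Wallis and Dunn post-hoc tests).

A first-class synthetic-data generator (`synth_config()`,
`synth_dataset()`) emulates the structure of a global ocean survey —
latitude gradient, thermal response curves, a niche trait evolved on a
birth–death tree with exact transition truth, planted polar gene
families and planted virus–host clade links — so the entire pipeline is
testable end to end with known ground truth. See the methods vignette
(`vignettes/polar-adaptation-methods.Rmd`) for the models, defaults and
design decisions.

## Worked example

```r
library(polarniche)

cfg <- synth_config(seed = 1)      # committed study conditions
ds  <- synth_dataset(cfg)          # data + ground truth

# Polar/Nonpolar genome niches from the abundance profiles
part <- setNames(ifelse(ds$samples$biome == "Polar", "Polar", "Nonpolar"),
                 ds$samples$sample_id)
niche <- assign_binary_niche(ds$abundance, part)
table(niche$label)
#> Nonpolar    Polar  Unknown
#>      105       44        1

# ancestral niche reconstruction on the labeled genomes
labels <- setNames(niche$label, niche$entity_id)
keep   <- names(labels)[labels %in% c("Polar", "Nonpolar")]
tree   <- ape::drop.tip(ds$tree, setdiff(ds$tree$tip.label, keep))
fit    <- fit_er(tree, labels[keep])
fit
#> Equal-rates niche model: q = 1.097, logLik = -64.8251
#> Ancestral states: Nonpolar=120, Polar=28
count_transitions(fit)
#> Niche transitions: 18 Nonpolar->Polar, 2 Polar->Nonpolar

# the polar barrier in community composition
d <- bray_curtis(ds$abundance)
anosim_test(d, part[colnames(ds$abundance$rpkm)], n_perm = 999, seed = 1)
#> ANOSIM: R = 0.7645, p = 0.001 (999 permutations; groups: Nonpolar=372, Polar=108)
```

The niche table says 44 of 150 genomes live in the polar biome (the
generator planted a ~1/3 polar composition; one genome stays `Unknown`
rather than being guessed). The ER fit estimates the niche-switching
rate and reconstructs most ancestors as Nonpolar, with 20 adaptation
events along the branches, and the ANOSIM R of 0.76 at p = 0.001 is the
polar barrier: between-biome community dissimilarity far exceeds
within-biome dissimilarity.

`run_all(cfg, "out/")` executes the whole pipeline (community → niche →
phylogeny → network → enrichment), writes one TSV per result plus a
checksummed `manifest.json`, and is byte-identical on rerun with the
same seed. A thin command-line wrapper is installed at
`inst/scripts/polarniche` (`polarniche synth ...`,
`polarniche run-all ... [--only stage]`).

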