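---
title: "Multilayer hub discovery among GWAS loci: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multilayer hub discovery among GWAS loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snphub)
```

## The problem

Meta-analyses of genome-wide association studies (GWAS) for type 2 diabetes
have produced hundreds of replicated SNPs, many of which sit outside genes
and carry no obvious biological interpretation. snphub implements an
analysis that asks whether such SNPs participate in *regulatory hubs*:
groups of GWAS loci that come together in the three-dimensional nucleus
(chromatin contacts), share expression effects (trans-eQTLs), or are linked
by curated protein/phenotype evidence — either directly or through
*intermediary* loci that are not themselves GWAS hits.

The pipeline has four computational stages, each exposed as ordinary
functions and combined by `run_all()`:

1. **Locus definition** — SNPs are collapsed into haplotype-block loci.
2. **eQTL scanning** — per-population Spearman association with a
   cross-population compound verdict.
3. **Graph assembly** — a multilayer locus graph with `spatial`, `eqtl` and
   `functional` edges.
4. **Hub discovery** — connected sets of two or more GWAS loci, with the
   bridging paths that explain them.

## Locus definition

Two SNPs belong to the same haplotype block when their pairwise linkage
disequilibrium satisfies $r^2 \ge 0.8$ **or** $D' \ge 0.8$, using the
standard coefficients

$$D = p_{AB} - p_A p_B, \qquad
  D' = |D| / D_\max, \qquad
  r^2 = \frac{D^2}{p_A(1-p_A)\,p_B(1-p_B)},$$

with $D_\max = \min\{p_A(1-p_B),\,(1-p_A)p_B\}$ for $D>0$ and
$\min\{p_A p_B,\,(1-p_A)(1-p_B)\}$ for $D<0$. The disjunction is read as an
edge rule on SNP pairs and closed transitively: loci are the connected
components of the resulting graph (`collapse_blocks()`). This is the
weakest closure consistent with "all SNPs sharing" a coefficient at those
levels, and it is what a brute-force component oracle verifies in the test
suite. Cross-chromosome merging is impossible by construction.

Haplotype frequencies come from phased haplotypes when available, otherwise
from the classic two-locus EM over unphased genotype tables
(`estimate_haplotype_freqs()`): only double heterozygotes are
phase-ambiguous; the E step splits them between coupling and repulsion
configurations. EM runs to a tolerance of 1e-8 (at most 1000 iterations)
and is initialized at linkage equilibrium, which also breaks likelihood
ties toward smaller $|D|$ — the conservative direction for block building.
Monomorphic SNPs raise a distinct `snphub_monomorphic` condition, because
undefined LD is not a numeric failure. Missing genotypes are deleted
pairwise.

Pairwise LD is only computed within a 500 kb same-chromosome window
(configurable). Blocks are local structures; the window bounds the
quadratic pair cost, and any pair *inside* the window that lacks an LD
entry is a hard error rather than a silent non-edge. Loci are named by the
genes their span overlaps, joined by `/` in genomic order (`CELSR2/PSRC1`);
spans overlapping no gene fall back to `chrom:start-end`, which is how
gene-desert loci such as `21q22.3`-style regions keep usable identifiers.

A note on $D'$ at small sample sizes: whenever one of the four haplotype
classes is unobserved, the sample $D'$ is exactly 1 regardless of the true
value. With rare alleles this happens often, so the pipeline computes LD on
the pooled panel (all populations stacked) by default — at eight panels of
60 samples the pooled 960 haplotypes make spurious boundary estimates
negligible, while the planted within-block structure is population-shared
and unaffected by pooling.

## eQTL scanning and the compound verdict

Each SNP–probe pair is tested per population with a tie-corrected
(average-rank) Spearman statistic (`spearman_assoc()`). The two-sided
p-value is exact — full enumeration of the $n!$ permutations — for
$n \le 9$, and uses the $t$ approximation
$t = \rho\sqrt{(n-2)/(1-\rho^2)}$ on $n-2$ degrees of freedom otherwise.
Constant vectors and populations with fewer than 5 usable samples are
*untestable*, deliberately distinct from "not significant": an untestable
population never enters the verdict count. The exact and approximate
p-values agree to about 0.01 in the small-p region that drives decisions
for untied data; heavily tied dosages widen the mid-range gap (a property
of the approximation, quantified in the tests).

The pair-level verdict (`compound_verdict()`) is the compound
cross-population rule:

* **replication**: $p < 0.05$ in at least 3 testable populations, or
* **single population**: any $p < 0.001$,

with replication reported when both fire. "Three of the test populations"
counts only testable ones. No additional multiple-testing correction is
applied — the compound rule *is* the procedure's guard against chance — but
a Benjamini–Hochberg column is emitted for inspection and never used in
verdicts. Under a global null with eight independent populations the
verdict's false-positive rate has the closed form
$1 - \sum_{k=0}^{2}\binom{8}{k}(0.05-0.001)^k\,0.95^{8-k} \approx 0.0134$,
which the acceptance suite verifies empirically against 20,000 simulated
null pairs.

Pairs are classified cis/trans with a 1 Mb window (a common eQTL
convention; the distance is measured to the nearest probe edge and a
distance exactly equal to the window is still cis). Trans means a different
chromosome or beyond the window. Probes without a genomic location are
`unclassified` and excluded from trans-edge construction. Expression is
assumed pre-adjusted; no normalization is performed.

## Graph assembly

`map_contacts_to_loci()` turns contact anchor pairs (BEDPE, converted to
1-based inclusive internally) into `spatial` edges: an edge is emitted when
the two anchors overlap two *different* loci, each extended by a 10 kb
flank (proximity-ligation anchors are fragment-scale while loci are
gene-scale; set the flank to 0 for strict overlap). Same-locus anchor pairs
are self-loops and dropped; duplicate contacts merge into a single edge
that accumulates the contact ids as evidence. Chromosome names are
normalized to the bare form internally; mixing `chr1` and `1` across files
is an explicit error unless auto-normalization is left on.

`eqtl_edges()` adds an `eqtl` edge for every significant verdict whose SNP
and probe map to different loci, and `functional_edges()` reads curated
links (e.g. a documented protein–protein interaction between the products
of two loci) from a table — they are never inferred computationally.
`build_graph()` keeps parallel edges across layers distinct, carries the
GWAS flag onto nodes, and retains isolated GWAS loci so that "no
connections" is visible rather than silent.

## Hub discovery

A *bridging path* is a simple path between two distinct GWAS loci whose
interior nodes are all non-GWAS, of length at most `max_path_len` edges
(default 3 — long enough for both a one-intermediary bridge and a
two-intermediary chain mixing spatial and functional steps, which is the
longest pattern in the worked examples). `find_hubs()` restricts the graph
to edges lying on some bridging path and reports the connected components
of that restriction containing at least `min_gwas` (default 2) GWAS loci,
together with every bridging path and its per-edge layer sequence. All
layers are traversable by default; `layers =` restricts the analysis, e.g.
to spatial-only evidence. Paths are simple because intermediaries are
physical loci — revisiting one adds no evidence. Hub identity is the set
of GWAS members, and output order (descending GWAS count, then
lexicographic) is deterministic and independent of input order.

`shared_intermediary_pairs()` reports the weaker pattern of two GWAS loci
touching the same intermediary, one triple per unordered pair.

```{r example}
g <- read_graph_fixture(snphub_fixture("hub3way_edges.tsv"),
                        snphub_fixture("hub3way_loci.tsv"))
find_hubs(g)
```

## The synthetic generator

Real inputs of this kind (reference-panel genotypes, lymphoblastoid
expression, chromatin-contact databases) are not shipped; the generator
(`simulate_study()`) produces a complete, planted-truth study instead:

* **Genotypes** — eight panels (HapMap-style labels) of 60 diploid samples;
  per-population allele frequencies uniform on [0.05, 0.95]. Within a
  planted block every SNP copies a shared latent haplotype with per-SNP
  flip probability $(1-\sqrt{c})/2$, so the haplotype correlation is
  monotone in the level $c$ and equals 1 exactly at $c = 1$ (literally
  duplicated columns). Blocks are independent of each other.
* **Expression** — additive model: $\text{expr} = \sum \beta \cdot
  \text{dosage} + \mathcal N(0, \sigma^2)$, with $\beta = 1.5$ expression
  units per allele copy and $\sigma = 1$ as defaults; probes without a
  planted effect are pure noise. These magnitudes give a strong but not
  deterministic per-population signal at $n = 60$, so the compound verdict
  is exercised rather than trivialized.
* **Contacts** — each planted hub contributes one anchor pair (or one
  functional edge) per GWAS member toward its intermediary; background
  contacts are placed uniformly on non-locus sequence with a guard band and
  rejection resampling, so they cannot create additional GWAS–GWAS
  connections. Exhausted rejection is a reported error, not a silent
  degradation.
* **Truth tables** — the block partition, the planted eQTL pairs, and the
  planted hub member sets, written as JSON alongside the standard-format
  inputs (phased VCF + dosage TSV, expression TSV, BEDPE, BED, TSV).

All randomness flows from one user seed; each stage derives a fixed offset
stream from it, so every artifact is reproducible bit-for-bit and the
stages can also be re-run individually.

What the generator does **not** emulate: coalescent genealogies, admixture,
genotyping error, microarray normalization artifacts, distance-decay
contact background, or realistic LD decay within blocks. Passing tests on
this generator therefore demonstrate the correctness of the algorithms
under their stated model, not robustness to every artifact of real data.

The default scenario plants 12 SNPs in four perfect-LD blocks plus
singletons across three chromosomes, two eQTLs (one trans, one cis — the
cis one demonstrates the same-locus/no-edge rule), and three hubs: a
two-GWAS hub doubly bridged by contacts and a trans-eQTL, a three-GWAS hub
through one intermediary, and a hub whose second GWAS locus is a
gene-desert (fallback-named) locus reached through a functional link. Two
of the block pairs sit within the 500 kb LD window of each other, so block
separation is genuinely tested rather than granted by the window.

## Numerical and degenerate-input choices

* Spearman p-values are clamped to the smallest positive double rather
  than 0 (a two-sided permutation p is never exactly 0), keeping the
  verdict's domain check `p` in (0, 1] meaningful.
* EM haplotype frequencies are clamped to their Fréchet bounds against
  floating-point drift; `ld_pair()` rejects inconsistent triples.
* `evaluate_hubs()` uses the conventions: precision 1 when nothing is
  detected, recall 1 when nothing was planted; an exact GWAS-member-set
  match defines a recovered hub.
* Degenerate simulator settings are exact: `noise_sd = 0` with `beta = 0`
  yields all-zero expression; `beta = 1` with no noise reproduces the
  dosage column.

## Problem sizes

The test suite and the acceptance script use the study sizes stated above
(8 × 60 samples; 20,000 null pairs of 8 × 100 for the type-I-error check;
200 replicates for eQTL recovery; 100 random instances per brute-force
oracle comparison; 10,000 fuzzed cases per invariant). The pipeline tests
run the same scenario at 8 × 15 samples, which preserves every planted
structure.

## Known limitations

* The LD collapse uses point estimates; no confidence-interval style block
  definition is attempted, and multi-allelic sites are out of scope.
* The contact layer treats the input contact list as given evidence — no
  Hi-C normalization or contact significance testing is performed.
* The eQTL stage fits no covariates; expression is expected pre-adjusted.
* Hub detection enumerates simple bridging paths, which is exponential in
  `max_path_len`; the default of 3 keeps this trivially fast on locus
  graphs of realistic sparsity.
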