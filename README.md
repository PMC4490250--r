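# snphub

Multilayer hub discovery among GWAS loci: linkage-disequilibrium block
collapsing, cross-population trans-eQTL scanning, and chromatin-contact
graph analysis in one pipeline.

## What it is for

Many replicated type-2-diabetes GWAS SNPs fall outside genes and explain
nothing by themselves. snphub is for researchers who want to ask whether
such loci participate in **regulatory hubs**: sets of two or more GWAS loci
connected in the 3D nucleus — directly, or through *intermediary* loci —
across three evidence layers:

* **spatial** edges from chromatin-contact anchor pairs (BEDPE),
* **eqtl** edges from significant trans SNP–expression associations,
* **functional** edges from curated protein/phenotype links.

## The core statistics and rules

* **Loci**: SNPs are collapsed into haplotype blocks; two SNPs join when
  their pairwise LD satisfies *r² ≥ 0.8 or D′ ≥ 0.8* (standard
  definitions: D = p_AB − p_A·p_B, D′ = |D|/D_max,
  r² = D²/(p_A(1−p_A)p_B(1−p_B))), closed transitively via connected
  components. Haplotype frequencies come from phased haplotypes or from a
  two-locus EM over unphased genotype tables. Loci are named by their
  overlapping genes (`CELSR2/PSRC1`), with `chrom:start-end` fallbacks.
* **eQTL verdict**: per population, a tie-corrected Spearman test (exact
  permutation p for n ≤ 9, t-approximation above); a SNP–probe pair is
  significant when *p < 0.05 in at least three testable populations* or
  *p < 0.001 in any single one*. Trans means a different chromosome or
  more than 1 Mb away.
* **Hubs**: connected components of the graph restricted to edges lying on
  simple GWAS-to-GWAS paths of length ≤ 3 whose interior nodes are
  non-GWAS, reported with every bridging path and its layer sequence.

A synthetic-data generator plants haplotype blocks, additive eQTL effects
and hub contact lists with known truth, so the whole pipeline is testable
offline.

## Worked example

The package ships a transcription of a published three-way hub as a
fixture: three GWAS loci (TM6SF2, CTRB1/BCAR1, CELSR2/PSRC1) whose spatial
neighbourhoods overlap through the KCNIP3 locus and through a BCAR3–BCAR1
protein interaction.

```r
library(snphub)
g <- read_graph_fixture(snphub_fixture("hub3way_edges.tsv"),
                        snphub_fixture("hub3way_loci.tsv"))
find_hubs(g)
#> 1 hub(s)
#> hub_01: 3 GWAS loci [CELSR2/PSRC1, CTRB1/BCAR1, TM6SF2]
#>   intermediaries: BCAR3, KCNIP3
#>   path: CELSR2/PSRC1 - BCAR3 - CTRB1/BCAR1  (spatial,functional)
#>   path: CTRB1/BCAR1 - KCNIP3 - TM6SF2  (spatial,spatial)
```

Read: the three GWAS loci form one hub. CELSR2/PSRC1 reaches CTRB1/BCAR1
in two steps — a chromatin contact to BCAR3, then the curated BCAR3–BCAR1
protein link — while TM6SF2 reaches CTRB1/BCAR1 through two chromatin
contacts via KCNIP3. Neither intermediary is itself a GWAS locus.

The weaker shared-intermediary pattern is also queryable:

```r
g2 <- read_graph_fixture(snphub_fixture("grm5_bridge_edges.tsv"),
                         snphub_fixture("grm5_bridge_loci.tsv"))
shared_intermediary_pairs(g2)
#>   gwas_u  gwas_v intermediary
#> 1  HNF1A IGF2BP2         GRM5
```

For a full run on your own files (or on `simulate_study()` output), build a
`pipeline_config()` pointing at the GWAS SNP list, per-population genotype
and expression files, probe and gene annotations, contacts and functional
links, then call `run_all(cfg)`; artifacts (locus table, LD pairs, eQTL
results, GraphML graph, hub reports, run log and summary report) land in
`out_dir`.

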