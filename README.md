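# clonetrail

Reconstructing the clonal evolution of a tumor from multi-region sequencing
of a single patient.

## The scientific problem

Diffuse midline gliomas and other solid tumors are mosaics: each biopsy or
autopsy punch core mixes normal cells with one or more tumor clones, and the
clones differ between anatomical sites. Given somatic ref/alt read counts
for a set of mutations across several regions of one patient — plus germline
heterozygous-site B-allele counts and arm-level coverage from tumor and
matched normal — `clonetrail` answers, in order:

* which chromosome arms are duplicated, deleted, or under copy-neutral LOH
  in each sample (B-allele imbalance × normalized coverage decision table);
* what each mutation's cellular frequency is after correcting its read
  counts for those events (duplication `Alt' = Alt/2`; deletion
  `Ref' = Ref + Alt`; chrX in XY `Ref' = 2·Ref + Alt`; CN-LOH
  `Ref' = Ref + Alt/2, Alt' = Alt/2`; CCF = `min(1, 2·VAF'/purity)`);
* how the mutations group into clones and how the clones are related — a
  binomial-mixture EM clusters mutations by their frequency profile across
  regions, and an exhaustive search over all k^(k−1) rooted labeled clone
  trees finds the maximum-penalized-likelihood tree under the pigeonhole
  condition (in every sample, a parent clone's frequency ≥ the sum of its
  children's), together with per-sample clonal mixing proportions;
* which mutation came first: a partial temporal order built from
  CCF dominance across regions, with tolerance tied to binomial standard
  errors, plus spatial (ubiquitous / shared / private) and driver
  (main / accessory / passenger) classification and detection of obligate
  oncohistone partnerships — including the case where two complementary
  sibling subclones carry different partners;
* what a droplet digital PCR assay measured: Poisson occupancy
  `λ = −ln(1 − positives/total)`, copies/µl, and mutant percentage with a
  delta-method interval.

A fully seeded synthetic-cohort generator (`simulate_cohort()`) produces
ground-truth clone trees, region mixtures, CNV events, and read counts at
exome-like (70×) or amplicon-like (4,000×) depth, so the entire pipeline is
validated end-to-end without external data. The tree machinery is a
deliberate deterministic simplification of MCMC-based subclonal
reconstruction (Dirichlet-process clustering + tree-structured
stick-breaking): finite-mixture EM with BIC plus exhaustive enumeration, so
identical inputs always give identical trees.

## Worked example

A six-region patient with a truncal oncohistone-like mutation (`M0001`,
H3F3A-like) and two complementary partner subclones — TP53-like (`M0002`)
in regions R1–R3, PPM1D-like (`M0003`) in R4–R6:

```r
library(clonetrail)
co   <- branching_partner_cohort(seed = 1)
ccf  <- estimate_ccf(apply_corrections(co$counts))
cl   <- cluster_mutations(ccf, k_max = 6, seed = 1)
tree <- fit_tree(ccf, cl)
cat(export_tree(tree, "newick"))
#> ((C2,C3)C1)normal;
round(tree$mixing, 3)
#>           R1    R2    R3    R4    R5    R6
#> C1     0.305 0.297 0.298 0.294 0.316 0.281
#> C2     0.000 0.000 0.000 0.500 0.495 0.518
#> C3     0.495 0.496 0.499 0.000 0.000 0.000
#> normal 0.200 0.208 0.203 0.206 0.189 0.201
```

Three mutation clusters are found; the tree nests both subclone clusters
under the trunk (`C1`), and the mixing proportions recover the generating
truth (trunk-only cells ≈ 0.3 everywhere, the active subclone ≈ 0.5 in its
half of the regions, normal contamination ≈ 0.2).

```r
po <- build_partial_order(ccf, c("M0001", "M0002", "M0003"))
po$roots
#> [1] "M0001"
po$pairs
#>   earlier later
#> 1   M0001 M0002
#> 2   M0001 M0003
po$incomparable
#>       a     b
#> 1 M0002 M0003

pres  <- build_presence_matrix(co$counts, "amplicon")
genes <- setNames(co$truth$mutations$gene, co$truth$mutations$mutation_id)
detect_obligate_partners(pres, genes)[c("obligate", "mode")]
#> $obligate
#> [1] TRUE
#> $mode
#> [1] "complementary"
```

The oncohistone-like mutation is the sole candidate initial event, the two
partners are on distinct branches (their order cannot be resolved against
each other), and the partnership is obligate via complementary subclones:
every tumor sample carries the oncohistone mutation together with at least
one partner, but no single partner covers all samples.

## Package layout

| file | contents |
|---|---|
| `R/sim_config.R`, `R/sim_cohort.R` | synthetic cohort generator + ground truth |
| `R/variant_io.R` | count-TSV / VCF-AD ingestion, presence calling |
| `R/arm_cnv.R` | folded-BAF imbalance test, coverage ratios, arm calls |
| `R/count_correction.R` | the four CNV read-count corrections |
| `R/clone_reconstruct.R`, `R/tree_search.R` | CCF, EM clustering, tree enumeration/fit/prune/export |
| `R/order_classify.R` | temporal order, spatial/driver classes, partners |
| `R/ddpcr.R` | Poisson droplet quantification |
| `vignettes/multiregion-clonal-evolution.Rmd` | model, assumptions, design choices |

See the vignette for the model details, tunable parameters, and known
limitations.
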