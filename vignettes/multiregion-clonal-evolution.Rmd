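---
title: "Reconstructing clonal evolution from multi-region tumor sequencing"
author: "clonetrail"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Reconstructing clonal evolution from multi-region tumor sequencing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonetrail)
```

## The problem

When several spatially distinct samples of one patient's tumor are sequenced
— for instance punch cores from different neuroanatomical sites of an
autopsied diffuse midline glioma — each sample is a mixture of normal cells
and one or more tumor clones. The variant allele fraction (VAF) of a somatic
mutation in a sample then reflects three confounded quantities: the fraction
of cells carrying the mutation, the local copy number at its locus, and the
sample's tumor purity. `clonetrail` implements the chain of computations
that untangles them:

1. **Arm-level CNV calling** from germline B-allele imbalance plus
   tumor/normal coverage (`call_cnv_profile()`).
2. **Copy-number-aware count correction** mapping each mutation's read
   counts back to a diploid-equivalent scale (`apply_corrections()`).
3. **Cellular-frequency estimation and clustering** of mutations that move
   together across regions (`estimate_ccf()`, `cluster_mutations()`).
4. **Clone-tree fitting** under the parent–child sum condition, with
   per-sample mixing proportions (`fit_tree()`, `prune_tree()`).
5. **Temporal ordering and classification** of mutations — which came
   first, which are ubiquitous/shared/private, which are main or accessory
   drivers, and whether the truncal oncohistone-like mutation has an
   obligate partner (`build_partial_order()`, `classify_spatial()`,
   `classify_driver()`, `detect_obligate_partners()`).
6. **ddPCR quantification** for orthogonal validation of mutant fractions
   (`poisson_lambda()`, `mutant_fraction()`).

A seeded synthetic-cohort generator (`simulate_cohort()`) produces
multi-region data with known clone trees, mixtures, and CNV events, so every
stage is testable without any external download.

## Count correction

Read counts are corrected per sample according to the arm event at the
mutation's locus:

| event | Ref' | Alt' |
|---|---|---|
| duplication | Ref | Alt / 2 |
| deletion | Ref + Alt | Alt |
| chrX hemizygous (XY) | 2·Ref + Alt | Alt |
| copy-neutral LOH | Ref + Alt / 2 | Alt / 2 |

Each rule maps a *clonal heterozygous* mutation back to the diploid VAF of
0.5 at purity 1. Working through the algebra shows which haplotype
configuration each rule assumes: halving Alt under a duplication restores
0.5 only if the *mutant-bearing* homolog was duplicated (raw VAF 2/3), and
the CN-LOH rule assumes the mutant haplotype was the one retained (raw VAF
1). The simulator therefore uses those configurations as defaults, making
generation and correction exact inverses; the flags
`mutant_homolog_duplicated = FALSE` and `mutant_allele_retained = FALSE`
deliberately violate the assumptions to measure robustness. For subclonal
mutations the blanket per-sample correction is only approximate — e.g. a
mutation at cell fraction G on an arm clonally duplicated at purity p has
corrected cellular frequency 2G/(2 + p − G) rather than G — a known residual
bias of arm-level correction that grows with the CNV's clonal fraction.
Corrected counts are kept real-valued; rounding to integers happens once, in
`estimate_ccf()`, where the binomial likelihood needs counts.

## Arm-level CNV model

For each (sample, arm) the caller computes the mean folded B-allele
deviation `mean(|BAF − 0.5|)` over germline heterozygous sites and a
median-centered `log2(tumor/normal)` coverage ratio. Significance of the
imbalance is assessed against a Monte-Carlo null that resimulates balanced
binomial counts *at the observed site depths* (default 10,000 replicates),
which keeps the test calibrated across the ~60-fold depth range between
exome and amplicon data; a folded-deviation floor (`dev_min = 0.05`) guards
against significant-but-negligible shifts at extreme depth. The decision
table is: significant imbalance + coverage up → duplication; + coverage
down → deletion; + coverage unchanged (|ratio| ≤ 0.15) → copy-neutral LOH;
otherwise neutral. The ±0.15 log2 band and α = 0.01 are configurable
(`cnv_thresholds()`); ±0.15 sits halfway between 0 and the ≈ +0.32/−0.42
expected for a clonal single-copy gain/loss at purity ~0.7. Arms with fewer
than 10 evaluable sites (depth ≥ 10) are reported unevaluable rather than
called. Arm membership is supplied as data (a column in the input), keeping
the package genome-build-agnostic.

Detection power at 70× with 100 sites is essentially complete for events at
clonal fraction ≥ 0.6 and falls off steeply below ~0.3; a fraction-0.2 event
is usually indistinguishable from the null. This floor is intrinsic to the
depth, not a tuning artifact, and the test suite asserts it in both
directions.

## Cellular frequencies, clustering, and the clone tree

The cellular frequency (CCF) of a mutation is `min(1, 2·VAF'/purity)`. When
purity is unknown it defaults to 1, leaving frequencies on the purity-scaled
cell-fraction scale; all constraints below are scale-invariant under that
choice, and mixing proportions then come out as fractions of *all* cells,
directly comparable to a simulator's ground truth.

Mutations are clustered with a finite binomial-mixture EM: component mean
VAFs are shared across a cluster's members per sample, the number of
components is chosen by BIC over k = 1..`k_max`, and ten seeded restarts
guard against local optima. This is a deterministic, desk-scale replacement
for Dirichlet-process clustering of cellular frequencies followed by
tree-structured stick-breaking; the posterior machinery is traded for an
exhaustive, exactly reproducible search.

Candidate trees are all rooted labeled trees over the k clusters — k^(k−1)
of them, generated from Prüfer sequences — with a normal root attached above
the single truncal cluster (a tumor has one founding clone). Each candidate
is scored per sample by projecting the observed cluster frequencies onto its
feasible polytope {f = A·m, m ≥ 0, Σm ≤ 1} (A the ancestor matrix, m the
mixing proportions) via nonnegative least squares, then summing the binomial
log-likelihood of the member counts at the projected frequencies minus
λ × (projection distance), λ = 100 by default.

Two numerical choices matter here:

* **Sum-condition tolerance.** The pigeonhole constraint (parent frequency ≥
  sum of children) is enforced with slack `0.02 + 2·SE`, where SE pools the
  binomial standard errors of the cluster means involved. Without it, a
  parent whose own mixing proportion is ~0 in some region acquires a tiny
  noise-induced violation that an incorrect flatter tree does not, and the
  argmax systematically flips away from true nestings.
* **Tie-breaking.** Trees tied on score are resolved by (i) fewer
  tolerance-exceeding edges, (ii) *maximal nestedness* (most ancestor
  pairs), (iii) lexicographically smallest parent vector. The nestedness
  preference implements the dominance/ancestry heuristic: a spurious nesting
  must survive `f_parent ≥ f_child` in every region and is falsifiable,
  whereas a spurious flat placement never is; preferring the nested
  candidate is therefore the lower-risk deterministic choice. The size of
  the tied set is reported (`n_ties`) so users can see genuine ambiguity.

Identifiability has hard limits that no scorer can cross: a chain A→B and
siblings {A,B} explain the same frequencies exactly whenever
f_A + f_B ≤ 1 in every sample, and chance dominance of one subclone over
another in *all* regions is indistinguishable from ancestry. The
noiseless-instance generator (`random_noiseless_instance()`) therefore
rejection-samples instances in which the true tree is the unique candidate
feasible within tolerance and all non-ancestral clade frequencies cross —
the recovery guarantees asserted in the tests are statements about
identifiable instances, and the residual ~5% of random deep-sequencing
cohorts that fail exact recovery are dominated by exactly these
information-theoretic ties.

For display, `prune_tree()` collapses nodes whose mixing proportion stays
below 0.05 in every sample into their nearest surviving ancestor, mirroring
the convention of drawing only trajectories with contribution ≥ 0.05; the
fitted tree is never altered.

## Temporal order and mutation classes

`pairwise_order()` calls mutation A earlier than B when A's CCF is at least
B's in every shared sample (within tolerance) and strictly larger in at
least one; both-directions excesses mean distinct branches (incomparable),
and never separating beyond tolerance leaves the pair unresolved — the
expected outcome for a truncal driver and its obligate partner, which sit in
the same clone. The tolerance is twice the pooled binomial SE of the CCF
difference (a shrunk VAF estimate keeps it positive at 0/1 counts), so the
same rule works at 70× and 4,000×. The aggregated partial order is
transitively reduced, any cycle (possible only through tolerance asymmetries)
is demoted to unresolved with a warning, and mutations never observed later
than another are reported as candidate initial events.

Spatial classes over the declared tumor samples: present in all evaluable →
ubiquitous, in ≥ 2 but not all → shared, in exactly 1 → private. By default
"tumor samples" are those with at least one present driver-gene mutation;
the driver list is configuration data seeded with the recurrent oncohistone
partners (H3 variants, TP53, PPM1D, ACVR1, PIK3R1, PIK3CA, ATRX, PTEN).
Driver categories follow the three-way scheme: main drivers are
driver-gene, truncal, and ubiquitous; accessory drivers are driver-gene but
subclonal or non-ubiquitous; everything else is a passenger.
`detect_obligate_partners()` reports per-sample co-occurrence with the
oncohistone-like mutation and distinguishes a single covering partner from
complementary sibling subclones whose union covers all samples.

## The synthetic cohort generator

`simulate_cohort()` draws: a clone tree by sequential uniform attachment
below a fixed truncal clone; per-region purity uniform in `purity_range`
split across clones by a symmetric Dirichlet; independent per-region
subclone dropout (default probability 0.2) to create the
early-versus-late-spread spatial heterogeneity seen in real multi-region
studies; Poisson(0.5) arm events per clone assigned to the trunk by default
(arm-scale aneuploidy in this tumor type is predominantly shared across
regions; `cnv_truncal_only = FALSE` enables subclonal events); read depth
Poisson around `mean_depth` (70 exome-like, 4,000 amplicon-like) with
binomial allele sampling; and germline het-site B-allele counts whose
expected BAF follows the copy model (duplication at aggregate fraction f
shifts the gained allele to (1+f)/(2+f), deletion to 1/(2−f) for the
retained allele, CN-LOH to (1±f)/2), with site depth scaled by mean copy
number. Everything is a deterministic function of the configuration,
including the seed; identical configurations regenerate byte-identical
files.

What the generator does *not* emulate — sequencing error, mapping bias,
overdispersion beyond binomial, whole-genome doubling, subclonal copy
number nested inside mutations' clones — bounds what passing tests show:
they validate the mathematics and the decision logic at realistic depths and
mixture structure, not robustness to platform artifacts.

Purity is exposed as a free parameter (default range 0.7–0.9) because
per-core purity is generally unreported for autopsy material; the default
range matches histologically tumor-rich cores.

## Validation studies and problem sizes

The test suite runs, among others: exhaustive equivalence of the count
corrections against an independently coded formula table over ref, alt ∈
[0, 200]; recovery of 4-clone trees from 100 seeded six-region cohorts at
4,000× (≥ 90% exact topology, mixing MAE ≤ 0.05); the
truncal-oncohistone/complementary-partner pattern in 20/20 replicates;
noiseless exactness of fit and temporal order on 200 identifiable instances
with up to 5 clones against a brute-force enumeration oracle; arm-caller
sensitivity ≥ 0.95 at clonal fraction ≥ 0.6 (100 sites, 70×) with ≤ 5%
false positives over 500 null arms and zero duplication/deletion confusion
at |log2 ratio| ≥ 0.3; and ddPCR occupancy bias < 1% with ≥ 93% interval
coverage over 1,000 Monte-Carlo partitions. These sizes keep the full suite
in the minutes range on a single core while leaving the binomial standard
errors far smaller than the effects being asserted.

## Worked example

```{r example, eval = FALSE}
co <- branching_partner_cohort(seed = 1)
ccf <- estimate_ccf(apply_corrections(co$counts))
cl <- cluster_mutations(ccf, k_max = 6, seed = 1)
tree <- fit_tree(ccf, cl)
cat(export_tree(tree, "newick"))
po <- build_partial_order(ccf, c("M0001", "M0002", "M0003"))
po$roots
```

See the README for this example with the numbers it prints.

## Known limitations

* Arm-level events only; no sub-arm breakpoints, no joint purity/ploidy
  estimation, no locus-level integer copy number or mutation multiplicity.
* The exhaustive tree search stops at 7 clusters by design; beyond that the
  function errors rather than silently switching to a heuristic.
* Edge support is reported as deterministic tie-set size, not a posterior
  probability.
* Corrections assume at most one arm event per locus per sample and the
  haplotype configurations described above.
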