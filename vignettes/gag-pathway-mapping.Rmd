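---
title: "Estimating GAG pathway activity from expression profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating GAG pathway activity from expression profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gagmap)
```

## The problem

Glycosaminoglycans (GAGs) — chondroitin sulfate (CS), dermatan sulfate (DS),
heparan sulfate (HS), keratan sulfate (KS) and hyaluronan (HA) — are linear
polysaccharides whose abundance and sulfation patterns change in
differentiation, inflammation and cancer. Measuring GAG content
biochemically is laborious; but every biosynthetic and catabolic step is
catalyzed by known enzymes, so the transcript abundance of those enzyme
genes is a usable proxy for a tissue's capacity to run each step.
`gagmap` turns bulk RNA-seq TPM profiles into *reaction-level activity
estimates* over the GAG pathways and compares them between conditions
(typically tumor vs normal).

## The knowledge base

The packaged knowledge base (`load_kb()`) curates 29 enzymatic reactions in
five categories — GAG backbone assembly (12 numbered steps: the
xylose-initiated linker tetrasaccharide, then the HS and CS/DS branches),
HS sulfation (5 steps), CS/DS sulfation (5 steps), KS biosynthesis (4
steps) and HA synthesis/catabolism (3 steps) — plus auxiliary gene sets
(nucleotide-sugar and PAPS transporters, PAPS synthesis, nucleotide
catabolism, and transcriptional/Golgi regulators), 66 distinct genes in
total. An alias table maps common alternative symbols (`BPNT2`, `CEMIP2`,
`HYAL5`) to the canonical ones.

Two curation points were genuinely open and are decided here:

* **EXT1/EXT2 appears in two backbone steps.** The HS polymerase is an
  obligate EXT1–EXT2 heterocomplex carrying both the GlcA-transferase and
  GlcNAc-transferase activities, which the pathway map draws as steps 8 and
  9. We keep both steps (the diagram contract) and relax the
  one-reaction-per-gene validation rule exactly for identical gene groups
  within one category.
* **HA catabolism membership.** Cell-surface depolymerization is assigned
  to TMEM2 and hydrolysis to HYAL1/HYAL2/SPAM1. Hyaluronidase family
  boundaries are debated; the KB is a versioned data file precisely so
  users can re-curate it, with `validate_kb()` guarding structural
  integrity.
* **CHSY1/CHSY3/CHPF/CHPF2 are modeled as alternatives** (max), although
  chondroitin polymerization really requires a pair of these proteins: any
  two of them form an active complex, so "some functional pair exists" is
  approximated by the best-expressed member. This is an approximation, and
  it is deliberately optimistic for lowly expressed partners.

## From genes to reactions

Gene-level TPM is aggregated per reaction with GPR-style (gene–protein–
reaction) rules:

* alternative isozymes (`ALTERNATIVES`): activity = **max** of member TPM —
  one sufficient isozyme carries the reaction;
* obligate complex subunits (`COMPLEX`, only EXT1/EXT2 here): activity =
  **min** — the scarcest subunit limits complex abundance.

Ties are broken by KB listing order, so aggregation is deterministic, and
the contributing gene is recorded per (reaction, sample) as provenance.
Under the permissive missing-gene policy an absent alternative is dropped
(other isozymes can act) while an absent complex subunit contributes 0 (no
subunit, no complex).

## Tissue profiling

For atlas-style tables (one consensus column per tissue), reaction
activities are z-scored per reaction (sample sd, $n-1$; a population-sd
flag exists) so that tissues are compared within each reaction, then
clustered with Euclidean distance and complete linkage — the common default
of R heatmap tooling; the linkage is configurable because the choice is a
convention, not a result. Items are label-sorted before clustering so tied
merge heights resolve deterministically. Gene–gene co-expression across
tissues uses the Pearson correlation on TPM as provided; the gene subset is
always explicit (published gene-panel subsets are not always enumerable
from figure legends, so the package never guesses one).

## Tumor–normal comparison

For two cohorts the per-target effect is the pseudocounted median ratio

$$\mathrm{fc} = \frac{\tilde{x}_\mathrm{tumor} + 1}{\tilde{x}_\mathrm{normal} + 1},$$

classified **UP** if fc > 1.5 and **DOWN** if fc < 0.667 (strict
inequalities; internally the lower threshold is exactly $1/1.5$ so the
classification is antisymmetric under swapping the cohorts). The raw
median ratio (`fc_raw`) is reported alongside, because the +1 pseudocount
shrinks fold changes of lowly expressed genes toward 1: for a gene with
true change $f$ and normal-arm median $B$ TPM the pseudocounted value is
$(fB+1)/(B+1)$, which for $f = 0.4$ cannot come within 15% of 0.4 unless
$B \gtrsim 10$ TPM. `fc_raw` is the unbiased estimator of the planted
change under the simulation model and is what parameter-recovery checks
assert on.

Reaction-level records are computed **aggregate-then-median**: each
sample's TPM vector is mapped to reaction activities first, cohort medians
second — this mirrors feeding each sample through the pathway map. The
reverse ordering (median TPM per gene first, aggregation second) is
available behind a flag for sensitivity analysis; it yields no per-sample
activities, so its reaction records have no p-value.

Significance uses the **unpaired** two-sided Wilcoxon rank-sum test. The
matched-pairs signed-rank test often named in this setting is impossible
for unequal cohort sizes (e.g. 662 tumors vs 1146 normals); the paired
variant is exposed separately (`rank_test_paired()`) for genuinely paired
designs. P-values are exact (via the null U distribution for tie-free
layouts up to 25 per arm, or full enumeration of group assignments for
small tied layouts) and otherwise use the tie-corrected normal
approximation with continuity correction. No multiple-testing correction
is applied by default — the classification contract is on fold changes,
with p-values displayed at the conventional 0.0001 level — and a
Benjamini–Hochberg column is available via `bh = TRUE`.

## Rendering

`render_pathway()` draws one category as a layered left-to-right SVG:
nodes are glycan intermediates, edges are reactions labeled with step
number and gene symbols, colored pink (UP), green (DOWN) or gray. The
layout is a pure function of the KB graph (longest-path layering,
label-sorted layers), so output is byte-identical across runs; the layout
is *not* a replica of any hand-drawn pathway map, whose geometry is an
illustration rather than an algorithm. Colors are configurable; the
semantic mapping, not the hue, is the contract.

## The synthetic-data generator

Because the real inputs (tissue atlas tables, multi-gigabyte TCGA/GTEx
matrices) are not redistributable, every stage is exercised on simulated
data with known truth:

* **Noise model.** log2 TPM = baseline + effect + $\mathcal{N}(0,
  \sigma)$, exponentiated — log-normal noise on TPM, the standard
  first-order model for relative bulk expression. Columns are never
  renormalized, so planted effects are exactly recoverable in expectation
  (the median of a log-normal equals its scale).
* **Tissue panels** (`simulate_tissues()`): 37 named tissues, 20 of them a
  HIGH_GAG archetype receiving `delta` = 3 extra log2 units (8-fold) on
  every reaction gene, noise sd 0.3 — emulating the two-cluster structure
  atlas profiling shows, with high-GAG reproductive/glandular/neural
  tissues against low-GAG liver/pancreas/muscle/gut.
* **Cohorts** (`simulate_cohorts()`): 100 samples per arm by default (a
  desk-scale stand-in for thousand-sample public cohorts), noise sd 0.5,
  and named per-gene planted fold changes multiplying the tumor TPM scale.
* **Baselines.** Per-gene baseline log2 TPM means are frozen in a fixture
  file. Most were drawn once from Uniform(0, 8) (about 1–256 TPM, the bulk
  of expressed genes); the five genes used as planted-change targets in
  recovery studies (CHST3 16, CHST15 8, VCAN 64, DCN 256, DSE 16 TPM) are
  pinned at GTEx-typical abundances, because genes whose fold changes are
  studied in real cohorts are robustly expressed there, and (per the
  pseudocount arithmetic above) a low-abundance baseline would make the
  recovery target unattainable for any estimator using pseudocounted
  medians.

What passing these simulations does **not** show: robustness to count
noise at low expression, batch effects, compositional distortion between
cohorts, tissue heterogeneity within a cohort, or annotation drift between
expression releases — none of which the generator emulates.

## Problem sizes and numerical choices

Validation runs use 200 replicate cohort pairs (100 samples per arm) for
fold-change recovery, 20 seeds for the 37-tissue clustering and null
false-positive checks, exhaustive enumeration for rank-test layouts up to
6 per arm, and 100 random 66-gene matrices against a brute-force
aggregation oracle. Degenerate inputs are handled explicitly: zero-variance
rows z-score to all zeros and are flagged; zero-variance genes are dropped
from correlation with a flag; all-tied rank tests return p = 1; aggregation
ties resolve to the first-listed gene.

## Limitations

Reaction activity is a transcriptional proxy: it ignores translation,
enzyme kinetics, substrate availability and localization, and is not
quantitative in glycan units. The max/min rules are coarse (notably for
the chondroitin polymerase family). Cohort comparisons against public
tumor/normal collections inherit those collections' batch structure, which
the package does not model.
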