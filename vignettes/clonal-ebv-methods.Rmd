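---
title: "Methods: clonality-aware genetic EBVs and GBF indicators"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonality-aware genetic EBVs and GBF indicators}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(clonalEBV)
```

`clonalEBV` computes the four genetic Essential Biodiversity Variables —
diversity, differentiation, effective population size and inbreeding —
plus genotypic richness and the two GBF genetic indicators, for SNP data
from partially clonal organisms. This vignette documents the statistical
model behind each stage, the tunable parameters, what the synthetic-data
generator does and does not emulate, and the design choices made where the
methodology was genuinely open.

## Genotype representation and filtering

Genotypes are alt-allele dosages (0/1/2, `NA` missing) over biallelic
SNPs with a locus map (chromosome, position, RAD tag). The filter cascade
applies, in a fixed order, the thresholds typical of
reduced-representation eelgrass data: biallelic only; site missingness
≤ 0.10; site heterozygote fraction ≤ 0.5 (computed among non-missing
calls — an excess of heterozygotes at a site indicates paralogous
mapping); samples ≥ 0.40 missing dropped; one SNP per RAD tag, keeping
the highest minor-allele frequency with ties broken by lowest position
(deterministic); monomorphic sites dropped; samples > 0.25 missing
dropped. Every step lands in an audit table, and the cascade is
idempotent. ROH detection must see monomorphic sites, so
`filter_cascade(keep_monomorphic = TRUE)` provides the parallel all-sites
matrix.

## Clone calling

Two missing-aware distances are offered. The *bitwise* distance is the
mean per-locus allele mismatch `|g_i − g_j| / 2` over loci called in both
samples; the *Euclidean* distance is the root of the summed squared
dosage differences rescaled by `n_loci / n_shared`. Which per-allele
convention the original clone-calling literature uses varies; the bitwise
definition here is the per-allele mismatch rate, the default because its
unit (expected allele differences per locus) is directly comparable to a
genotyping error rate.

The clone threshold is calibrated from the data: agglomerative clustering
(single, complete or UPGMA/average linkage) of the distance matrix yields
merge heights that are bimodal when clones are present — tiny heights
merge ramets of one genet, larger heights merge distinct genotypes. The
threshold is the midpoint of the largest gap in the sorted merge heights.
No closed form for this cutoff is standard in the literature, so the gap
diagnostics (`gap_low`, `gap_high`, `heights`) are returned and a
user-supplied threshold overrides prediction everywhere downstream.
Technical replicates — the same extraction library-prepped and sequenced
twice — bound the error-induced distance between true clones;
`validate_with_replicates` fails the calibration if any replicate pair
would split at the candidate threshold.

Clone correction removes technical replicates first (keeping the least
missing sample of each replicate group), then keeps one representative
per MLL within each meadow; an MLL spanning two meadows keeps one
representative in each so that shared clones remain visible to
between-meadow statistics. Representative choice (least missingness, then
lexicographic id) is a package convention; distances are not recomputed
after correction.

## Diversity

Per meadow on clone-corrected data: Ho is the mean over loci of the
observed heterozygote fraction; uHe is the unbiased expected
heterozygosity `2p(1−p) · 2n/(2n−1)` averaged over loci; F_IS is
`1 − mean(Ho)/mean(uHe)` — a ratio of means rather than a mean of
per-locus ratios, because near-monomorphic loci make per-locus F_IS
explode; π is the per-site pairwise nucleotide diversity
`2·x_ref·x_alt / (n_al(n_al−1))` averaged over all retained sites (a
switch restricts it to polymorphic sites). The correction factor
`2n/(2n−1)`, with n the number of MLLs, is also applied to the
polymorphic-site count and π (`upol`, `upi`); which statistics receive it
is ambiguous in practice, so raw and corrected columns are both emitted,
with `upol_round` as the integer-rounded convenience column. Private
alleles are alleles observed in exactly one meadow, counted for that
meadow; summed over meadows they equal the number of single-meadow
alleles (a conservation law asserted in the tests). Meadows with fewer
than 2 MLLs are flagged `computed = FALSE` rather than given misleading
statistics. Genotypic richness is `R = (nMLL − 1)/(nInd − 1)`.

## Structure

PCA mean-imputes missing dosages per locus, centres, and does not scale.
Ancestry estimation is a masked non-negative matrix factorization: dosages
`X = G/2` are factorized as `Q F` with `Q` rows projected onto the
probability simplex and `F` clipped to (0,1), by alternating least
squares with EM-style imputation of unobserved entries. Model choice
holds out a 5% mask of called genotypes and scores each run by the
cross-entropy (mean negative binomial log-likelihood per held-out allele);
the chosen K minimises the mean cross-entropy. This reproduces the
decision surface of sparse-NMF ancestry tools with a fully specified
optimizer; the exact regularized optimizer of those tools is intentionally
not reproduced. Defaults (K 1–8, 5 runs, 5% mask, 200-iteration cap,
relative tolerance 1e-5) are sized for desk use; missing genotypes are
excluded from the masked likelihood rather than imputed into it. DAPC
memberships come from a linear discriminant on the leading principal
components (default: smallest number of axes explaining ≥ 80% of
variance, capped at n/3 — the cap keeps the discriminant well-posed at
small n). Meadows are assigned to the argmax of their mean assignment
vector; disagreement with a second method or a tie leaves the meadow
unlabelled with a flag, which is how a nearly monoclonal meadow with
unstable assignment drops out of cluster summaries.

## Differentiation

Pairwise FST is the Weir–Cockerham 1984 estimator combined over loci as a
ratio of sums of the variance components; negative estimates are reported
as-is. Significance uses label permutations within the pair with the
add-one correction `(1 + #{θ* ≥ θ}) / (n_perm + 1)` (999 permutations by
default, the permutation literature's standard; the underlying survey
methodology does not state a count), then Benjamini–Hochberg FDR across
pairs. AMOVA decomposes squared Euclidean inter-individual distances into
among-cluster, among-meadow-within-cluster and within-meadow components
with the standard unequal-size expected-mean-square coefficients;
permutations respect the tested level (whole meadows among clusters;
individuals among meadows within clusters; individuals freely for the
overall Φ_ST). In-water distances snap meadows to the nearest sea cell of
a land/sea grid (snaps logged), then take shortest paths over sea cells
with 8-neighbour moves and great-circle edge lengths; bathymetry-weighted
least-cost paths are out of scope since the distances emulated are
depth-unrestricted. The Mantel test runs on `FST/(1−FST)` versus
kilometres, with the OLS R² reported alongside the Mantel r.

## Runs of homozygosity

The detector follows the PLINK `--homozyg` scheme: a window of 7 SNPs
passes with ≤ 1 heterozygous and ≤ 2 missing calls; each SNP's hit
fraction is the share of passing windows covering it, thresholded at 0.05
(the common default; not dictated by the emulated study); candidate SNPs
form stretches split at inter-SNP gaps > 400 kb and at heterozygous calls
beyond the ≤ 1-per-ROH allowance (greedy left-to-right, the offending het
excluded from both pieces); a stretch is a ROH when it spans ≥ 300 kb
with ≥ 10 SNPs. "Minimum density of 7 SNPs per window" is read as the
scanning-window size and "maximum gap of 400" as kb; both are exposed as
parameters so alternative readings can be matched. Missing calls never
break a segment. FRoH divides the summed length of segments above 1 Mb
(or 5 Mb) by the corresponding genome denominator (defaults 229.6 and
228.4 Mb; the attainable-coverage denominator is 240.2 Mb — the eelgrass
assembly with scaffolds < 300 kb excluded). Genome coverage converts all
calls to homozygous and reruns the detector, bounding what FRoH can see
at the given SNP density. An exhaustive-interval oracle in the test suite
verifies the scan on fully specified fixtures, and tightening
`hit_fraction` or `min_snps_per_roh` provably never increases total ROH
length.

## Effective population size

`ld_ne` is the classical bias-corrected LD method with the reporting
surface of contemporary tools: Burrows composite correlations between
loci on *different* chromosomes (physical linkage excluded), loci with
minor-allele frequency < 0.05 removed (rare alleles inflate r²), the
sampling correction `1/S` (or `1/S + 3.19/S²` below S = 30) subtracted
from the mean r², and Ne from inverting
`r2_drift = 1/(3Ne) + 0.69/Ne²`, i.e.
`Ne = (1/3 + sqrt(1/9 − 2.76·r2_drift)) / (2·r2_drift)`. Non-positive
corrected r² flags Ne as infinite rather than erroring. Confidence
intervals come from a leave-one-chromosome-out jackknife on the corrected
mean r², transformed through the same inversion. The neural-network-
assisted, sibling-corrected estimator used in some recent software is a
different method; this package deliberately implements the fully
specified classical estimator instead, with under-powered guards
(≥ 10 samples, ≥ 200 usable loci, ≥ 2 chromosomes).

Nc for a meadow is `size_ha × 10⁴ × plants_per_m2` with a default of 55
plants per m² (550 shoots/m² at 10 shoots per plant); the hectare-to-m²
conversion is made explicit here because plant density is a per-m²
quantity. The GBF indicators are the fraction of units with point Ne
above 500 (or with CI reaching 500 in `ci_overlap` mode — point mode can
never exceed it) and the proportion of populations maintained,
`1 − lost/assessed`, with loss defined as areal reduction beyond 99%.
With 18 assessed units the one-exceedance indicator reports 1/18 = 0.06
at two decimals (the whole-survey denominator is used, not the
17-meadow clustered subset). Correlations of per-meadow metrics with
areal change report both Pearson and Spearman statistics because the
underlying relationships are often monotone but non-linear.

## The synthetic-data generator

`simulate_dataset` draws cluster allele frequencies from a
Balding–Nichols beta around beta-distributed ancestral frequencies
(`FST` between clusters, a second level within), genet genotypes under
Hardy–Weinberg with autozygous tracts forced homozygous, ramets as
genet copies with somatic mutations, and technical replicates as ramet
re-calls with genotyping error only. The defaults are the survey-like
conditions the package is calibrated against: 18 meadows in 5 clusters,
between-cluster FST 0.10, 20 shoots and 13 genets per meadow (richness
0.63), genotyping error 0.5%, somatic rate 1e-4, two replicates per
meadow, autozygosity F = 0.75 with 2 Mb mean tract length on a 6 × 40 Mb
genome, and a Beta(0.2, 2.3) ancestral spectrum, which together give
per-site Ho ≈ 0.023–0.025 (`expected_ho` returns the analytic value).
Areal change is drawn normal with a configurable correlation to meadow
inbreeding (default −0.7, declining areas more inbred).

Ground truth covers genet membership, cluster labels, realized
autozygosity, realized richness and tract coordinates, so every recovery
test scores against exact truth: clone calling by adjusted Rand index,
FST against the Balding–Nichols target, ROH by bp-level Jaccard, K
selection against the simulated cluster count, and LD-Ne against a
Wright–Fisher simulation (`simulate_wf_ld`: random union of gametes,
unlinked loci, 20 generations to equilibrate drift LD).

What the generator does *not* emulate: linkage and recombination within
chromosomes (loci are exchangeable given the frequencies), selection,
spatially continuous habitat, pedigree-based inbreeding (tracts are
literal forced-homozygous intervals, chosen precisely because they give
exact bp-level truth), or the read-level error processes of a sequencing
pipeline. Passing recovery tests therefore demonstrates correctness of
the estimators under their own assumptions, not robustness to artefacts
such as batch effects or allele-dropout structure in real libraries.

Two regimes matter for test design. The *survey-like* regime
(rare-allele spectrum, high autozygosity) is right for clone calling and
diversity, but leaves most sites uninformative for ROH boundaries — in
that regime homozygous runs occur everywhere by construction. ROH
recovery is therefore calibrated in an *informative-marker* regime
(Beta(2, 2) spectrum, F = 0.30, 3000 SNPs on a 60 Mb genome), where
non-autozygous regions carry frequent heterozygotes and tract boundaries
are identifiable. Problem sizes in the tests (2000–5000 loci, tens of
samples, 10–20 seeds per property) are chosen so each recovery property
runs in about a minute on a single core while leaving comfortable
statistical margin.

## Numerical choices and degenerate inputs

Distances error on pairs with zero shared loci (naming the pair), and
threshold prediction errors on fewer than three merge heights or a
heightless (all-identical) tree. Cross-entropy uses an epsilon clip at
1e-6 to keep held-out likelihoods finite. The FST estimator skips loci
not called in every population of the pair; AMOVA imputes nothing —
distances are rescaled by shared-locus counts. The LD-Ne inversion
clamps a negative discriminant to zero (the estimate then degrades
gracefully to `1/(6·r2_drift)`) and flags non-positive drift r² as
infinite. All simulation and permutation entry points take explicit
seeds; the pipeline stamps every CSV with a hash of the parameter blocks
and the seed (file paths deliberately excluded so the same analysis run
elsewhere hashes identically).

## Known limitations

The MLL threshold assumes a detectable bimodality; continuous distance
distributions (e.g. pervasive half-sib structure with high error) leave
the largest-gap heuristic unstable, which is why replicate validation and
the gap diagnostics are surfaced rather than hidden. F_IS from the
ratio-of-means definition is not comparable to per-locus-averaged F_IS
from other software at low diversity. The AMOVA permutation scheme tests
each level against a standard label-permutation null; methods that
compare against expectations under alternative nulls will report
different significance for the same components. LD-Ne assumes random
mating and unlinked marker pairs; residual family structure biases it
downward, and the package does not attempt the sibling-purging
corrections of specialised tools. In-water distances depend on the grid
resolution; paths through single-cell straits appear or disappear with
the mask, so the snapped coordinates and resolution are logged with the
result.
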