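---
title: "Methods: mtDNA haplogroup association analysis for PSP and CBD"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: mtDNA haplogroup association analysis for PSP and CBD}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mthaplotau)
```

## The analysis problem

Progressive supranuclear palsy (PSP) and corticobasal degeneration (CBD)
are autopsy-confirmed 4-repeat tauopathies. Because mitochondrial
dysfunction is implicated in tauopathy and mitochondrial DNA (mtDNA)
haplogroups differ in bioenergetic behaviour, a natural epidemiological
question is whether maternal mtDNA background modifies disease risk or
the severity of tau pathology. `mthaplotau` implements the full
computational chain such a study needs:

1. a curated European mtDNA phylogeny with branch-defining SNPs and a
   39-locus typing panel;
2. quality control of raw panel genotype calls (signal-intensity
   acceptance, sample call-rate filter);
3. rule-based haplogroup assignment by sequential descent with
   disjoint-clade conflict detection, super-haplogroup grouping and
   removal of non-European lineages;
4. aggregation of semi-quantitative regional tau lesion scores into
   per-subject burden measures with group-mean imputation;
5. covariate-adjusted logistic (risk) and linear (tau burden, onset,
   duration) association models with a minimum-carrier rule and
   per-family Bonferroni thresholds;
6. a synthetic cohort generator with known ground truth, so that every
   stage — and the chain end to end — is testable without access to any
   individual-level data.

## The haplogroup phylogeny and typing panel

The tree is data, not code: a YAML document
(`inst/extdata/phylotree_european.yaml`) with one record per haplogroup
node carrying the defining SNPs of the branch leading to it (rCRS
position, ancestral and derived allele on the heavy strand, optional
rsID and gene label). The shipped document encodes the European
macro-topology — N at the root; N1/I, W and X; R with R0 → HV → H
(H1–H4) and HV0a → V; JT with the J and T lineages; U (U1, U3, U5, U6)
and K — with 39 panel loci in total.

The exact 39 loci of the original two-assay typing design are not
public. The shipped panel is therefore a *reconstruction*: one to two
canonical PhyloTree-style variants per branch, with the three branches
whose defining variants are published pinned exactly — H4 by rs41419549
(m.5004T>C, *MT-ND2*), HV by rs193302980 (m.14766T>C, *MT-CYB*), and
HV0a by rs35788393 (m.15904C>T, tRNA-Thr). Any user with the true assay
design can substitute their own document; `load_tree()` validates
structure (single root, acyclicity, resolvable parents, unique panel
positions, defining SNPs inside the declared panel) and reports all
violations at once.

`defining_path()` concatenates branch SNPs from root to node;
`disjoint_clades()` returns the nodes that are neither ancestors nor
descendants. Both are deliberately simple, exhaustively testable
primitives on which the caller's correctness rests.

## Genotype quality control

Raw calls carry a signal intensity and a baseline intensity. A call is
accepted only when the called allele is a real base and the intensity
exceeds baseline by **strictly more than 5** units (an excess of exactly
5 is still noise); a sample is accepted when its call rate is
**strictly greater than 95%**. Both cut-offs are configurable but
default to these strict readings. Two choices deserve note:

* the call-rate denominator is the full declared panel (39), not the
  number of attempted calls — a sample with no data at a locus has, for
  assignment purposes, no call there;
* the call-rate rule is evaluated *after* intensity filtering. Whether
  intensity rejection should count against the call rate is not
  determinable from the study description; filtering first is the
  conservative order and is the package's documented assumption.

An optional VCF reader maps variant records onto the panel; VCFs carry
no assay intensities, so mapped calls are auto-accepted (given a
nominal intensity above the threshold) and, by default, panel loci
absent from the VCF are treated as homoplasmic reference calls.

## Haplogroup assignment

The caller implements a sequential-descent rule: a sample belongs to a
haplogroup only if the derived allele is present at *every* SNP on the
defining path from the root, and the assignment is the deepest such
node. Two deliberate strictnesses:

* a **no-call blocks descent** — a missing call is not "present", so
  the sample falls back to the deepest fully-called ancestor rather
  than being guessed downward;
* after a candidate is found, every accepted call is checked against
  the defining SNPs of **disjoint clades**; any derived hit there is a
  contradiction and the sample is flagged `conflict` rather than
  assigned. Two equally deep fully-matching candidates (impossible with
  clean data on a bifurcating panel) are likewise a conflict.

Samples assigned exactly to an internal node (e.g. `H` with no sub-H
branch called) are legitimate outputs, mirroring how both `H` and its
sub-haplogroups appear as separate analysis rows. Super-haplogroups are
a configurable map in the tree document; the shipped map pools only the
two groupings with published evidence (JT = J* + T*, UK = U* + K) and
maps every other node to itself, because the full grouping scheme used
in the original secondary analyses is not public. The European filter
is flag-driven (a per-node `european` flag, inherited from the nearest
flagged ancestor when unstated) rather than a hard-coded lineage list,
because the published exclusion clause ("non-N, A, F, and B") is
ambiguous about the intended set.

The caller is verified three ways: perfect-data round-trip over every
node; equivalence with an unpruned brute-force oracle on 1,000 noisy
simulated samples; and invariance to node ordering in the tree
document.

## Tau burden aggregation

Each subject is scored 0–3 (none/mild/moderate/severe) per region and
lesion measure (CB, NFT, TA, AP, NT) over 20 regions in PSP and 17 in
CBD. (The published region name lists are supplementary material that is
not public; the shipped lists are documented placeholders with the
correct counts and are configuration, not biology.) Aggregation
follows three rules:

* **imputation**: a missing (subject, measure, region) score is
  replaced by the mean of the observed scores of the same disease
  group, measure and region. Means are computed from all subjects with
  observed values, regardless of those subjects' own inclusion status,
  and in a single pass — they are not recomputed after exclusions;
* **exclusion**: a subject missing strictly more than 50% of regions
  for a measure contributes nothing to analyses of that measure (10 of
  20 missing is still included; 11 is not);
* the burden is the mean over the full region list after imputation,
  so it is bounded in [0, 3] and equals the plain arithmetic mean when
  data are complete.

Group-mean imputation is a fixed point of the cell means (imputing and
recomputing changes nothing), which the tests verify on synthetic
cohorts.

## Association models

Every analysis row is a **one-vs-rest indicator**: carriers of the
row's haplogroup set versus everyone else in the analysis. Nested rows
(e.g. the pooled H lineage and `H1` alone) are separate tests, as in
the published tables. The families are:

| family | model | covariates |
|---|---|---|
| PSP risk, CBD risk | logistic (case vs control) | age, sex |
| PSP tau, CBD tau | OLS per measure | age at death, sex, Braak, Thal |
| PSP duration | OLS | age of onset, sex |
| PSP onset | OLS | sex |
| super-haplogroup (secondary) | logistic | age, sex |

Rows with fewer than 10 carriers among the analysed subjects are not
tested; an explicit per-analysis override list can force-test a row
(used for H4 in the CBD tau family, which the original analysis
examined at 8 carriers because of its risk association). Estimates are
Wald: the exponentiated indicator coefficient with a normal-quantile CI
for odds ratios, the raw coefficient with a t-quantile CI for linear
models; p-values are two-sided. The CI/p method is not stated in the
study description, so Wald is the documented default; separation-prone
logistic fits are flagged `unstable` (with the Wald output retained)
rather than silently dropped. Sex enters as a binary covariate; age
linearly; Braak and Thal as linear ordinal scores — all unstated in the
original and therefore documented package defaults.

Each family's Bonferroni threshold is `alpha / m` with `m` the number
of *distinct tested haplogroup rows* (a tau family tests each row for
four measures but counts it once), rounded to 4 decimal places;
significance is `p <= threshold` against the rounded value. Secondary
super-haplogroup families use `alpha = 0.05` unadjusted. From the
published carrier counts these rules reproduce the printed thresholds
exactly: 0.0021 (PSP risk, m = 24), 0.0024 (CBD risk, m = 21), 0.0024
(PSP tau, m = 21), 0.0045 (CBD tau, m = 11 with the H4 override). The
published onset/duration threshold (0.0026) implies m = 19, but the
per-row carrier counts of that subset are not public, so that family's
m cannot be verified against printed data.

One consequence of counting haplogroups rather than (haplogroup ×
measure) results is that a tau family's chance of *any* false flag
under the null is bounded by roughly 4α, not α — each of the m rows is
tested four times against a threshold of α/m. The package's null
calibration therefore compares observed false-flag counts against the
Bonferroni expectation implied by the thresholds (the sum of the
threshold over all tested results), which is the quantity the
correction actually controls; in the shipped 100-replicate experiment
the pipeline runs slightly below that expectation.

## The synthetic cohort generator

The generator's defaults *are* the study conditions: group sizes 1042 /
171 / 910; per-node haplogroup frequencies from the published control
column (the two rows printed only in combined form are split evenly
across their members); age, sex, onset availability (606 of 1042 PSP
cases lack onset/duration), Braak and Thal distributions calibrated to
the published characteristics table; tau scoring restricted to the
published subsets (764 PSP, 150 CBD); a 0.5% no-call rate and a signal
model (mean 12 over baseline 3, SD 1) under which accepted calls clear
the intensity threshold in expectation while a small fraction fail —
values chosen once as realistic for a high-quality targeted assay, since
the original per-assay noise profile is not published.

Disease effects are injected as log odds ratios. Internally the
generator uses the case–control sampling identity: controls draw
haplogroups from the base frequencies *f*, cases from
*f* · exp(log OR), renormalised. This is exactly the haplogroup
distribution a prospective logistic model induces once sampling is
conditioned on case status (covariates being independent of
haplogroup), and it gives fixed group sizes and an exactly known truth
for the adjusted logistic estimate.

Tau scores are generated on a latent continuous scale — a per-region
baseline spread around the measure's published median, plus the
carrier's injected shift, mild Braak/Thal/age effects and Gaussian
noise (SD 0.8) — then rounded and clamped to the 0–3 grid. The latent
construction reproduces the fractional per-subject means of the real
instrument while honouring its ordinal range; note that rounding and
clamping attenuate an injected latent shift slightly, which is why
recovery of the −0.35 NT shift is asserted as sign recovery plus CI
behaviour rather than exact equality.

Randomness is one seeded stream split per subject by counter, so
growing the cohort never reshuffles earlier subjects. The per-subject
seeds are produced by a 32-bit avalanche hash of (seed, counter):
affinely related seeds give correlated Mersenne Twister streams, which
in an early version of the generator leaked spurious
genotype–phenotype association into null simulations — a hazard worth
recording.

### What the generator does and does not emulate

It emulates the *structure* of the study's data: panel call patterns
with no-calls and intensity noise, the published haplogroup frequency
spectrum, covariate distributions, ordinal regional tau scores with
missingness, and known injected effects. It does not emulate
population-genetic reality (no coalescent, no recurrent mutation, no
heteroplasmy), genotype–covariate dependence (so adjusted and crude
effects coincide by construction), non-European admixture, or
correlated regional missingness. Passing tests therefore demonstrate
that the pipeline recovers what it is supposed to recover under the
study's stated conditions — not that the pipeline would be robust to
artefacts the generator does not model.

## Numerical choices and degenerate inputs

* Strict inequalities at every published cut-off (`> 5`, `> 95%`,
  `> 50%` missing, `< 10` carriers).
* Thresholds rounded to 4 decimals before the `<=` significance
  comparison, reproducing printed behaviour.
* Constant covariates: dropped with a message in logistic risk fits
  (so a no-covariate synthetic fit reduces exactly to the crude
  cross-product OR), but an error naming the covariate in linear fits,
  where a rank-deficient design more likely signals an input mistake.
* Empty families (nothing reaches 10 carriers) are reported with
  `m_tests = 0` by the family runners; `bonferroni_family()` itself
  refuses them.
* Zero-observation imputation cells raise an error naming the regions
  rather than imputing from nothing.
* The example file-mode cohort and all simulation outputs are
  byte-reproducible from their seeds.

## Problem sizes used in the shipped experiments

The package's own verification experiments run at the published study
scale: OR-coverage uses 200 replicate case–control studies of
171 + 910 subjects; null calibration uses 100 replicate full studies
(1042 + 171 + 910, with tau scoring of the published subsets); tau
shift recovery uses 30 replicates of 764 scored cases; the caller
oracle runs on 1,000 noisy samples. These sizes give Monte-Carlo error
comfortably below the tolerances being checked (e.g. binomial SD ≈ 1.5
percentage points for 95% coverage over 200 replicates).

## Known limitations

* The shipped panel is a reconstruction; haplogroup calls on real data
  depend on the true assay design, which users must supply for exact
  replication.
* Wald inference can be unstable in near-separated cells; such fits
  are flagged, and a profile-likelihood alternative is a natural
  extension.
* The region lists and the full super-haplogroup scheme are
  placeholders pending the non-public supplementary definitions.
* Braak/Thal enter linearly; a categorical coding would be a
  one-line change in the model formula but is not exposed as a switch.
* The published adjusted headline estimates (e.g. OR 4.51 for H4/CBD)
  are not exactly reproducible without individual-level covariates;
  the package instead verifies the crude printed-count consistency
  (4.54, within 1%) and simulation-based CI coverage of the injected
  truth.
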