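---
title: "Proteoform-specific label-free quantification of homologous protein families"
author: "mupquant"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Proteoform-specific label-free quantification of homologous protein families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mupquant)
```

## The problem

Mouse major urinary proteins (MUPs) are a family of lipocalins encoded by
a cluster of *Mup* loci. Central cluster members differ by only a handful
of residues over a ~157-residue mature protein (>97% identity), while
peripheral members sit at 82–94% identity. Gel bands, antibodies and
standard protein-inference heuristics cannot tell these proteoforms apart.
Bottom-up mass spectrometry can — but only through *proteotypic* peptides,
peptides whose sequence occurs in exactly one proteoform of the search
database. Two consequences shape the whole analysis:

1. **Uniqueness is context-dependent.** The same peptide may be unique
   within a designated family database yet shared once a background
   proteome is added. Enlarging a database can only remove proteotypic
   status (a monotonicity this package tests explicitly), so proteoform
   identifiability must be re-derived per database context.
2. **The targets drive the denominator.** MUPs make up most of the
   urinary protein mass, so upregulating them raises total protein
   concentration. Intensity-based normalization (total area sums) then
   absorbs part of the real signal, and unregulated proteins appear
   downregulated. Normalizing by an external concentration measurement
   avoids this circularity.

## Sequence model and digestion

`tryptic_digest()` cleaves C-terminal to K or R, suppressed when the next
residue is proline, and enumerates products with up to `max_missed`
internal missed cleavages (default 2, a common search setting;
configurable via `digest_params()`). A brute-force substring oracle in the
test-suite confirms the enumeration over random sequences.

Peptide masses are monoisotopic residue sums plus one water, with cysteine
carried as the carbamidomethylated residue (+57.02146 Da, matching
iodoacetamide alkylation as a fixed modification). No variable
modifications are modelled; oxidation and similar are search-engine
concerns outside this package's scope.

A peptide is *admissible* for quantification if its length lies in 6–30
residues and at least one considered charge state puts
(m + z·1.00728)/z inside the inclusive scan window m/z 250–1500. Charges
2–4 are considered throughout; charge 1 is additionally considered for
peptides of at most 7 residues, since short peptides fall below the lower
m/z bound at charge 2 and the wide scan window exists precisely to retain
short unique peptides. All of these are `digest_params()` fields.

**I/L equivalence.** Isoleucine and leucine are isobaric and
indistinguishable by the precursor and most fragment masses, so by default
two peptides differing only by I↔L substitutions are treated as the same
sequence when deciding uniqueness (`il_equivalent = TRUE`). This is the
conservative choice: it can only demote peptides from proteotypic status,
never promote them. The flag can be disabled for workflows that trust
differentiating fragments.

**Redundancy clearing.** Database entries that share an identical
(optionally signal-peptide-trimmed) sequence are collapsed into one entry
with all accessions recorded — mature urinary proteins are secreted
without their signal peptide, so precursor-level differences are not
observable.

**Pairwise identity** uses global Needleman–Wunsch alignment (BLOSUM62,
gap open 10, gap extension 0.5) with identity defined as identical
columns over alignment length. For the generated families alignments are
gapless, so identity reduces to Hamming distance over length; the
alignment route matters for real sequences of unequal length.

## Quantification model

The ion library (`build_library()`) is the set of admissible proteotypic
peptides of a context, optionally restricted to peptides observed in at
least one identification run. Proteoform intensity is the **sum** of the
library peptides' areas per sample (`rollup = "sum"`; mean available for
sensitivity analysis — upstream vendor software does not document its
aggregation, and sum is the linear choice under which MS1 and MS2 roll-ups
coincide when fragment areas sum to peptide areas). At MS2 level,
fragment rows are summed to peptide areas first.

Missing detections are **absent, not zero**: a proteoform undetected in a
sample stays `NA`, is excluded from that sample's pairs, and never pulls
a mean toward zero. This matches presence/absence genetics of the family
(an individual without the gene product has no peptides at either time
point) rather than a limit-of-detection censoring model.

## Normalization and testing

With per-sample totals \(T_s\) and mean total \(\bar T\):

* none: \(x_{ps} \mapsto x_{ps}\);
* TAS: \(x_{ps} \mapsto x_{ps}\,\bar T/T_s\);
* manual: \(x_{ps} \mapsto x_{ps}/c_s\) with \(c_s\) the measured protein
  concentration (µg/µL).

Differential expression uses a two-sided **paired t-test** per proteoform
over individuals present at both time points (at least `min_pairs = 3`
complete pairs; fewer excludes the proteoform with a logged reason; zero
variance of differences is flagged rather than given a fabricated p).
The test runs on the raw area scale by default, with a `log2_transform`
option; the fold change is the ratio of group means (t2/t1), not the mean
of per-pair ratios, matching group-comparison conventions of the vendor
statistics tools. Significance requires both p < α/k (Bonferroni–Dunn,
k = number of proteoforms tested) and a better-than-two-fold change;
downregulation uses the reciprocal rule (fold < 0.5).

Detection frequencies are rounded to integer percent and binned
ubiquitous = 100, common = 50–70, uncommon = 30–49, rare < 10. The gaps
(10–29, 71–99) are intentional: the published classes leave them
unspecified, and the package maps such values to `"unclassified"` with a
warning rather than guessing intent.

## Relative composition

The 100% method assumes equal ionization efficiencies of family-derived
peptides — defensible because the proteoforms are near-identical — and
scores each proteoform by its summed unique-peptide area divided by its
number of unique peptides, normalizing scores to 100%. Shares below 5%
pool into "Others". Areas are summed across all samples before
normalization (population-level composition); a `per_sample` option
returns sample-wise shares. Violating the equal-efficiency assumption
biases shares proportionally to the efficiency ratio; this is documented
behaviour, not corrected, and a test demonstrates it. The family fraction
of total MS intensity uses *all* family peptides, shared ones included,
divided by the total of all quantified peptides.

## What the synthetic data emulate

Because no public raw data exist for the original study design, the
generator produces matrices whose *statistical structure* matches what the
analysis assumes:

* a family derived from one random base sequence by point substitutions
  placed inside admissible tryptic peptides, with disjoint private
  substitution sets per proteoform (guaranteeing ≥1 proteotypic peptide
  each) and a shared "core" divergence for peripheral members so central
  pairs stay above 97% identity and peripheral pairs fall in 82–94%;
  substitutions never touch K/R or cleavage-suppressing prolines, so all
  family members share one cleavage pattern, as true paralogs largely do;
* a constant background proteome audited to share no tryptic peptide with
  the family;
* a paired design (13 individuals × t1/t2 by default) with per-individual
  Bernoulli detection spanning ubiquitous/common/uncommon/rare classes;
* multiplicative lognormal noise: biological (CV 0.2, per proteoform and
  sample, averaged over 2 pooled samplings at t1 and 3 at t2), technical
  (CV 0.1 per peptide measurement) and fragment-level (CV 0.05). The
  original pilot reported only "high technical reproducibility", so these
  CVs are assumed values, chosen in the range routinely reported for
  label-free intensities, and all are design fields;
* per-peptide ionization-efficiency factors (lognormal, CV 0.5) drawn once
  and shared across samples — the component TAS normalization absorbs but
  concentration normalization does not;
* six fragment rows per peptide with Dirichlet(2) weights; with fragment
  noise disabled the fragments sum exactly to the peptide area, which
  pins the MS1 = MS2 consistency property;
* total protein concentration proportional to total simulated protein
  amount, scaled so the t1 average equals 1.4 µg/µL; with the default
  (computed) family fold the t2 average lands at ≈2.6 µg/µL, so family
  upregulation raises concentration exactly as in the motivating system.
  When `fold_changes` is not supplied, a uniform family fold is derived
  from the 2.6/1.4 concentration ratio; the expected family share of
  MS intensity at t1 is set by `family_share` (default 0.85), computed on
  the peptide map so that peptides shared by several family members count
  all their parents.

The generator does **not** emulate retention-time structure, co-eluting
interferences, saturation, limit-of-detection censoring (absence is
genetic, not intensity-dependent), shared peptides between family and
background, or search-engine scoring variability. Passing tests therefore
validate the arithmetic and the statistical behaviour of the pipeline
under its own assumptions — not robustness to the full messiness of real
acquisitions.

A note on the recovery tests: the `family_share` and fold parameters
define *expectations over the detection process*. With a handful of
family members at realistic detection frequencies, a single 13-individual
draw scatters the realized family share several points around its
expectation, so the recovery tests hold detection at 1 while leaving the
noise model at defaults; what they certify is the intensity estimator,
not the detection sampling variance.

## Numerical choices and degenerate inputs

* Absent values propagate as `NA` end to end; zero imputation is never
  silent.
* TAS requires positive sample totals; manual factors must be positive
  and cover every sample — both fail loudly otherwise.
* `bonferroni_dunn()` refuses k = 0; `concordance()` requires ≥3 shared
  proteoforms and returns r = 1 explicitly for identical degenerate
  (zero-variance) inputs.
* Frequencies are rounded to integer percent *before* binning, so the
  printed class boundaries are reproduced exactly.
* Family generation retries placement (bounded, default 25) and errors
  for infeasible identity bands instead of silently relaxing them.
* Seeded routines save and restore the caller's RNG state.

## Problem sizes used by the tests

The packaged checks run a 6-proteoform family (4 central, 2 peripheral)
with 8 background proteins; the digestion oracle covers 1,000 random
sequences up to 60 residues, superset monotonicity 100 random contexts,
and the type-I/power checks 200 simulations each at n = 13 — sizes at
which the whole suite completes in well under a minute while the binomial
margins on the measured rates stay tight. The default family size
(15 central, 5 peripheral) mirrors the ~20–34 published family members
and is used where a single simulation suffices.

## Known limitations

* Identity bands are enforced by construction (substitution counts), so
  generated identities sit at discrete values inside the bands rather
  than sampling them continuously.
* The paired t-test on raw areas is the documented default even though
  intensity data are right-skewed; `log2_transform = TRUE` is available
  and recommended when noise CVs are large.
* Composition shares inherit the equal-ionization assumption; for
  proteins less homologous than this family the 100% method is biased.
* `screen_long_forms()` equates "extension-region peptides" with peptides
  unique to the long form within the database, which is exact when the
  long form differs from its mature counterpart only by the extension.
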