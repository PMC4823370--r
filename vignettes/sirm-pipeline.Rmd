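---
title: "Stable-isotope-resolved metabolomics with sirmtools: models, choices, and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stable-isotope-resolved metabolomics with sirmtools}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sirmtools)
```

# The experimental design this package analyzes

Three motor neuronal cell lines — the untransfected NSC-34 hybrid line and
its stable transfectants expressing human wild-type SOD1 (WT-NSC) or the
ALS-causing G93A mutant (G93A-NSC) — are cultured for 22 h without serum in
medium containing either [U-¹³C₆]glucose (25 mM) or [U-¹³C₅]glutamine
(1 mM), with 1 mM pyruvate and no FBS. Three kinds of measurements follow:

1. **¹H NMR of spent media** against a TSP internal standard: metabolite
   concentrations, and ¹³C satellite integrals that report the fraction of
   each molecule carrying ¹³C at the observed proton's carbon.
2. **GC-MS of intracellular extracts** after TBDMS derivatization: raw
   isotopologue ion intensities M+0…M+K per metabolite fragment, from which
   mass isotopomer distributions (MIDs) and ¹³C fractional enrichments are
   obtained after natural-abundance correction.
3. **GC-MS profiling** (TMS derivatization) of pool sizes, normalized to
   internal standards and protein, summarized as percent of the NSC-34
   reference line.

The package implements each analysis stage, an exact positional
label-propagation simulator encoding the pathway diagnostics used to
interpret the isotopologue patterns, the group statistics (one-way ANOVA,
Tukey HSD, Benjamini–Hochberg FDR), and a seeded synthetic-data generator
that emulates the whole study so every stage can be validated end to end
without any deposited raw data.

# Natural-abundance correction of MIDs

A silylated GC-MS fragment contains, besides the metabolite backbone,
derivatization carbon and silicon whose heavy isotopes (²⁹Si 4.7%, ³⁰Si
3.1%, ¹³C 1.07% per atom) dominate the M+1/M+2 background. For a fragment
with elemental formula $F$ and $n$ tracer-traceable backbone carbons, the
correction matrix $C$ has columns $j = 0 \dots n$:

$$ C_{\cdot j} = \mathrm{shift}_j\!\left(\mathrm{natural}\left(F - j\,\mathrm{C}\right)\right), $$

the natural isotope pattern of the formula with $j$ carbons fixed as ¹³C
(those contribute a deterministic shift of $j$; the remaining atoms,
including the other backbone carbons, keep natural abundance). The measured
intensity vector $y$ over M+0…M+K then satisfies $y \approx C x$ with $x$
the true MID, and $x$ is recovered by **non-negative least squares**
(`pracma::lsqnonneg`) followed by renormalization to the simplex. NNLS is
used instead of matrix inversion because inversion can return negative
fractions on noisy data; the NNLS residual norm is reported per fit.

Numerical choices:

* Isotope abundances are a versioned constant table (¹³C 0.0107, ²H
  0.000115, ¹⁵N 0.00364, ¹⁷O 0.00038, ¹⁸O 0.00205, ²⁹Si 0.04685, ³⁰Si
  0.03092, ³³S 0.0075, ³⁴S 0.0425); every `CorrectionMatrix` records the
  table version it was built from. Phosphorus is monoisotopic and therefore
  omitted from fragment formulas.
* The observed shift range defaults to $K = n + 3$: enough to capture the
  Si-driven tail without requiring the full scan range.
* Patterns are truncated at $K$, so they sum to at most 1; columns of $C$
  are truncated natural patterns, never renormalized.
* All-zero intensity vectors are rejected rather than silently zero-filled.

Two enrichment conventions are implemented, because "percent of the pool
enriched with ¹³C" can mean either. The default, used everywhere a single
number is reported, is the **carbon-atom fraction**
$\sum_i i\,m_i / n$; the alternative `labeled-fraction` convention
$1 - m_0$ (fraction of molecules carrying any label) is available by
argument. For the synthetic study the two give similar recovered values
because the generator's truths are defined on the atom convention; on real
data the molecule-level convention is systematically larger.

The shipped fragment library covers the measured panel with TBDMS M−57
fragments (the isotope-analysis derivatization); its formulas were
assembled from the metabolite formula plus one C₆H₁₄Si per silylation site
minus the C₄H₉ of the M−57 loss, with methoximation adding CH₃N at keto
groups.

# The positional label-propagation simulator

Interpreting citrate isotopologue patterns requires knowing *which* carbons
are lost as CO₂, not just how many are labeled — a shift-only bookkeeping
model cannot express why oxidative glutamine entry can never produce
citrate M+3, or why glucose entry via PDH alone produces no citrate M+1 in
early turns. The simulator therefore tracks, for every pool of $n \le 6$
carbons, a full probability distribution over the $2^n$ positional labeling
vectors (state spaces stay ≤ 64).

Reactions are atom maps: each product carbon comes from exactly one
substrate carbon or from an external unlabeled source (the CO₂ fixed by
pyruvate carboxylase or reductive IDH), and released carbons are listed
explicitly, so label is conserved per application — a property the test
suite checks for every reaction against random distributions. Key mapping
conventions (standard biochemistry):

* PDH releases pyruvate C1; acetyl-CoA carbons become citrate C5–C6.
* Aconitase/IDH stereospecificity: the CO₂ released at IDH is the
  oxaloacetate-derived C4 carboxyl; α-ketoglutarate dehydrogenase releases
  α-ketoglutarate C1 (the other oxaloacetate carboxyl). Acetyl-CoA carbon
  therefore survives the first turn.
* Succinate and fumarate are symmetric: each labeling vector is averaged
  with its end-to-end reversal after every update ("scrambling"), which
  preserves the MID but randomizes position.
* Aspartate mirrors oxaloacetate; glutamate mirrors α-ketoglutarate through
  transamination; cystathionine's serine-derived carbons track serine with
  the homocysteine moiety unlabeled (reported at the MID level since the
  molecule has 7 carbons).
* The CO₂ pool is fixed unlabeled: the culture is an open system, and
  ¹³CO₂ refixation is modeled only through the explicit external carbons of
  pyruvate carboxylase and reductive IDH.

`PathwayConfig` holds the tracer choice and the flux splits at each branch
(PDH vs pyruvate carboxylase at oxaloacetate production, oxidative
glutamine entry vs IDH at α-ketoglutarate, citrate synthase vs reductive
carboxylation, glutamine synthetase vs uptake, de novo serine synthesis vs
import, glycolytic vs unlabeled pyruvate). All splits are fractions in
[0, 1] whose producing routes sum to 1.

**Turn semantics.** Propagation is a deterministic fixed-point iteration.
One *turn* is one Gauss–Seidel sweep over the pools in canonical metabolic
order (glycolytic chain, then glutaminolysis, then the TCA segment, then
the condensation), so a single turn carries label from the tracer through
one full pass of the pathway: turn 1 equals "the first condensation". The
number of cycles the original interpretation assumed is not recoverable, so
the turn limit is an explicit parameter rather than a guessed default.
Steady-state mode (`turns = NA`) iterates sweeps until the largest absolute
probability change falls below `tol` (default 1e−12, cap 500 sweeps, error
with the residual on non-convergence). At the fixed point the result is
independent of the update order, which the suite verifies by permuting it.
The turn-limited recursion is cross-checked against an independent
Monte-Carlo ancestry-sampling oracle.

The four encoded diagnostics, each an exact structural statement:

| tracer, route | citrate pattern |
|---|---|
| glucose via PDH, first condensation | M+2 only |
| glucose via PDH, repeated cycling | even shifts up to M+6, no M+1 through two turns |
| glutamine, oxidative entry, unlabeled acetyl-CoA | M+4 first turn; M+3 exactly zero at any depth |
| glutamine, reductive carboxylation | M+5 appears |

Deep cycling (> 2 turns) under glucose/PDH does eventually produce trace
odd citrate shifts through the scrambled succinate segment once labeled
carboxyls are lost; the simulator reports whatever the atom maps imply
rather than suppressing it.

# NMR source attribution and media exchange

¹³C satellites flank a ¹H resonance when the attached carbon is ¹³C, so
`satelliteFraction` computes $f_{13} = S/(C+S)$ and subtracts single-site
natural abundance, $(f_{13} - 0.0107)/(1 - 0.0107)$, clipped to [0, 1].
The subtraction uses the single observed carbon's 1.07%, not a
molecule-wide correction, because the satellites report one position. Both
the raw and corrected fractions are returned, since reported "~80%" values
may follow either convention; the corrected one is the default summary.

Concentrations come from integral ratios against TSP (9 protons, 0.967 mM
in the tube after 50 µL of 11.6 mM stock into 600 µL, dilution factor
600/550). Net exchange is $(c_{end} - c_{fresh}) \cdot V / m_{protein}$ in
µmol/mg, negative for consumption; lactate, alanine, formate and glutamate
are absent from fresh medium and are pure release. Per-glucose molar ratios
divide release by |glucose consumption| and are undefined (error) when
glucose is not net-consumed. Medium volume is a required configuration
quantity (default 2 mL/well) because flux normalization needs it even
though figure legends do not print it.

# Profiling normalization and group summaries

Profiling intensities are divided by the internal-standard intensity and
protein mass, which makes the pipeline scale-invariant per sample. Missing
cells are back-filled per metabolite with half the minimum observed value,
and every fill is logged on the returned table. This is a behavioral
substitute for re-integration of the quantitation ion from raw
chromatograms, which is impossible without raw data; half-minimum is the
conventional floor imputation for values below detection. Group summaries
are reported as mean percent of the NSC-34 reference ± SEM, with the SEM of
the ratio propagated by the delta method for independent means.

# Statistics

One-way fixed-effects ANOVA (`stats::oneway.test` with `var.equal = TRUE`),
Tukey HSD pairwise contrasts (`TukeyHSD` on the `aov` fit), and
Benjamini–Hochberg FDR (`stats::p.adjust`) across metabolites. Whether FDR
should apply before or after the post hoc contrasts is genuinely ambiguous
in this design; the package applies FDR to the ANOVA p-values across
metabolites within one measurement family (pool sizes, enrichments,
exchanges) and leaves the Tukey contrasts adjusted only within metabolite —
the choice is stated in the output so readers can re-adjust. Significance
stars are rendered at 0.05/0.01/0.001 on the FDR-adjusted values. The suite
checks the F statistic against explicit sums of squares, Tukey at $k = 2$
against the pooled t-test, BH against the step-up definition, and the
empirical type-I rate under a simulated null (0.05 ± 0.01 at α = 0.05).
Note that the BH adjustment is *not* idempotent as a transformation —
re-adjusting adjusted values inflates them — so the suite asserts the
definition and monotonicity, not idempotence.

# The synthetic-data generator

The generator exists so the full pipeline can be exercised and its
estimators validated against known truths. Its defaults (in
`defaultStudyConfig()`, every entry annotated with the reported quantity it
encodes) are the study's printed values: replicate counts per assay family
(media n = 4, MIDs n = 5, pools n = 6; the medium-lactate assay used
n = 8), tracer concentrations, the +46% G93A-vs-WT medium lactate contrast
without serum, +37% glucose consumption, ~80% lactate/alanine from glucose,
the enrichment panel (90% PEP; 60%/80% pyruvate–lactate–alanine;
glutamine 32/18/24% from glucose and 39/67/56% from glutamine), and the
pool-size percentages (serine +164% in WT-NSC, etc.). Quantities printed
only as ranges (TCA enrichments 40–55% from glucose, 10–20% from glutamine,
succinate 20–25%) were fixed once at in-range values. Two defaults are the
package's own: baseline absolute magnitudes (pool sizes are arbitrary
units; media baselines are chosen so that lactate+alanine release never
exceeds the stoichiometric 2 per glucose, and glutamine consumption stays
within what 1 mM glutamine in 2 mL can supply), and the noise model —
multiplicative mean-preserving lognormal, CV 5% for intensities and 10%
for protein, since only SEM bars are reported and replicate-level variance
is not recoverable.

**True MIDs.** For each metabolite the generator takes the positional
simulator's *labeled-material* MID $L$ — the pure product of the tracer-fed
route, run for four turns with tracer purity 0.99 per position applied to
the tracer input (finite turnover over 22 h; four turns give realistic
mixed isotopologue ladders rather than the fully-labeled infinite-cycling
limit) — and mixes it with unlabeled molecules, $x = dL + (1-d)\,\delta_0$,
solving $d$ so the carbon-atom enrichment equals the configured truth.
Tracer purity thus lives in the forward model only; the correction matrix
never sees it. Where the network has no route from tracer to metabolite
(e.g. glutamine-tracer carbon in glycolytic pools, which in cells would
arrive via malic enzyme — not modeled), the generator falls back to
independent per-carbon labeling at the target fraction. Raw GC-MS
intensities are then the forward convolution $C x$ times channel-wise
noise; NMR integrals split a total at
$f_{13} = s + (1-s) \cdot 0.0107$ for configured source fraction $s$.

**What the generator does not emulate** — and therefore what passing tests
do and do not show: chromatographic artifacts (co-elution, detector
saturation, retention-time drift), fragment-specific ion statistics,
between-batch derivatization efficiency, compartmentation (one well-mixed
pool per metabolite), and isotopic non-steady-state kinetics within the
22 h window. Recovery results validate the estimators under the stated
error model, not the instruments.

**Validation scales.** The suite recovers every configured truth: exactly
at CV 0, and within 3 SEM of a single study estimate at the study
replicate counts when averaged over seeds (the NNLS enrichment estimator
carries a small O(CV²) bias, ≈ 0.3% relative at CV 5%, which sits well
inside single-study precision). The end-to-end recovery checks average 200
seeded studies; the heavier Monte-Carlo cross-checks (ancestry-sampling
oracle at 20 000 samples, 10 000-replicate null calibration, 500-trial
noisy-correction sweep) were sized to run comfortably on one CPU while
keeping Monte-Carlo error far below the tested tolerances.

# Known limitations

* No flux estimation: the simulator predicts isotopologue patterns from
  assumed flux splits; it does not fit fluxes to measured MIDs (no
  EMU/cumomer least squares).
* Nominal-mass correction only: ¹³C and ²⁹Si at the same nominal shift are
  not separated (no high-resolution mode).
* The exact correction algorithm used with the original in-house software
  is unpublished; NNLS is this package's choice.
* No raw-signal processing: AMDIS deconvolution, FID phasing/baseline and
  spectral assignment are upstream of the package's inputs.
* d/l-serine cannot be distinguished, matching the underlying method.

# A worked example

```{r example, eval = FALSE}
library(sirmtools)

## simulate the labeling experiment used to interpret citrate patterns
net <- buildDefaultNetwork()
midOf(propagateLabels(net, pathwayConfig("glutamine", oxGln = 1,
                                         turns = 1))$citrate)

## generate a synthetic study and recover enrichments
cfg <- defaultStudyConfig()
d <- generateTracerDataset(cfg, seed = 1, tracers = "glucose",
                           lines = "NSC-34")
enr <- correctMidTable(d$gcms)$enrichments
aggregate(enrichmentAtom ~ metabolite, enr, mean)

## media fluxes and group statistics
m <- mediaExchangeTable(generateMediaDataset(cfg, seed = 1))
p <- generatePoolDataset(cfg, seed = 1)
p$value <- normalizeAbundance(p$quant_ion_intensity, p$is_intensity,
                              p$protein_mg)
head(metaboliteStats(p))
```
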