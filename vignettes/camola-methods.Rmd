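---
title: "Methods: carbon-module labeling analysis of GC-MS volatiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: carbon-module labeling analysis of GC-MS volatiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(camola)
```

## The measurement model

A carbon-module labeling (CAMOLA) experiment reacts fully ¹³C-labeled
glucose together with unlabeled precursors (cysteine, (E)-2-nonenal) and
repeats the reaction with unlabeled glucose as a control. For an n-carbon
product, electron-impact GC-MS at unit-mass resolution records the
molecular-ion window M+0..M+n; a product molecule that incorporated k
glucose carbons appears k mass units above the monoisotopic ion. The data
object is therefore a short vector of ion abundances per compound, and
the quantity of interest is the isotopomer distribution p₀..pₙ — the
fractions of product molecules carrying 0..n labeled carbons.

Two views of that distribution are implemented, and the distinction
matters:

* **Raw isotope ratios** (`normalize_cluster()`): pₖ = aₖ / Σaⱼ. This is
  the convention of the published isotope-ratio tables — no correction for
  naturally occurring heavy isotopes is applied. It is the package
  default, because reproducing reported values requires reproducing their
  convention.
* **Natural-abundance deconvolution** (`deconvolve()`, opt-in): the
  observed window is modelled as b = M·x, where column k of the correction
  matrix M is the theoretical isotope envelope of the k-labeled species —
  a binomial over the C−k unlabeled carbons at 1.07% ¹³C, convolved with
  the isotope polynomials of the molecule's H, N, O and S atoms (²H
  0.0115%, ¹⁵N 0.364%, ¹⁷O 0.038%, ¹⁸O 0.205%, ³³S 0.75%, ³⁴S 4.25%, ³⁶S
  0.01%), shifted by k and truncated to the window. Tracer carbons are
  treated as isotopically pure ¹³C. The system is solved for x ≥ 0 by
  non-negative least squares and x is renormalized. Non-negativity is
  enforced inside the solver rather than by inverting M and clipping,
  because clipping biases small fractions upward; the residual norm is
  attached so users can see when the linear model fits poorly. A condition
  number above 1e8 aborts with a conditioning error — for these small
  lower-triangular-dominant matrices (diagonal near 1) conditioning is in
  practice excellent, so hitting the guard indicates a malformed matrix,
  not a hard inverse problem.

For sulfur-bearing compounds the raw and corrected views differ
noticeably (³⁴S alone puts >4% of each species two mass units up), which
is why the isotope-ratio tables of thiophenes show several percent at
M+2 even in control runs.

## Identification and quantitation

Retention indices use the linear (van den Dool) convention, appropriate
for temperature-programmed runs: RI = 100·(n + (t−tₙ)/(tₙ₊₁−tₙ)) between
bracketing ladder alkanes, exactly 100·n at a node, and no extrapolation
beyond C6/C30 — compounds eluting before the first alkane are a censored
category, not a number. The default library-match tolerance is 10 RI
units, a typical inter-laboratory spread on DB-5-type phases. Isothermal
(logarithmic) Kovats indices and spectral-similarity scoring are
deliberately out of scope.

Semi-quantitation assumes unit response and full recovery:
Wᵢ = f′·Aᵢ·mₛ/(Aₛ·m). The units contract is fixed — mₛ in µg, m in g — so
concentrations emerge in µg/g; both masses are explicit arguments rather
than assumed from any particular protocol. Odor activity values divide by
the odor threshold and are reported half-up to one decimal. All report
rounding in the package is half-up (never banker's), matching the
one-decimal precision of the published tables.

## Origin attribution

The attribution model treats a product skeleton as assembled from
precursor *carbon modules*: labeled glucose fragments C1–C6, unlabeled
cysteine fragments C1–C3, unlabeled aldehyde fragments C1–C9 (the
inventory is configurable per reaction system). `enumerate_hypotheses()`
lists every multiset of at most `max_modules` modules (default 3) summing
to the product's carbons; each hypothesis predicts a single label count.
`fit_mixture()` finds non-negative weights summing to one that minimize
the squared distance between predicted and observed label-count
distributions. Because hypotheses sharing a label count are spectrally
indistinguishable, the optimum over totals is the Euclidean projection of
the observed fractions onto the simplex; each total is then assigned to
the first hypothesis with that label count in enumeration order — the
minimum-support exact fit, with a deterministic tie-break. The weights
are descriptive pathway proportions; no kinetic meaning is claimed.

Qualitative origin calls discretize the label summary. The defaults are
interpretive — the narrative language ("obviously derived from",
"mainly originated from") comes with no printed thresholds — and were
fixed once so that every published call is reproduced:

* unlabeled-precursor-derived when M+0 ≥ 85% (published unlabeled calls
  sit at 89% and above);
* glucose-derived when the fully-labeled fraction exceeds 50% **or** the
  summed labeled fraction exceeds 80%. The 80% value is deliberate: the
  most weakly labeled compound the narrative still assigns to glucose
  carries 80.8% labeled signal after normalization, while the strongest
  "mixed" compound carries 74%, so any cutoff in (74, 80.8) reproduces
  the calls and 80 is the round value in that interval;
* mixed otherwise. Glucose checks are strict inequalities so that an
  even 50/50 split stays "mixed".

The unlabeled check has precedence, making the call monotone: adding M+0
mass can never move a compound away from the unlabeled category.

Label summaries list a label count when its share reaches
`min_report_fraction` (default 2%) — the published proportion tables list
values down to about 4% and omit smaller ones, so 2% is the loosest
threshold consistent with them.

## The synthetic-data generator

`generate_cluster()` and `generate_experiment()` forward-simulate the
whole measurement: true isotopomer fractions are pushed through the
correction matrix (so simulated spectra carry realistic natural-abundance
shoulders), scaled to a total signal (default 1e6 area units), and
perturbed by noise. The default noise model is multiplicative log-normal
with CV 5% and unit mean — EI peak-area repeatability is proportional —
with a Poisson "counting" mode for low-signal scenarios and "none" for
exact closed-loop checks. Seeds are explicit everywhere and the global
RNG state is never consumed; each (system, replicate, compound) in an
experiment bundle derives its own sub-seed from the master seed.

The default panel and per-system true fractions mirror the three model
reaction systems and the labeling splits they produce (three replicates,
the usual GC-MS triplicate). Retention times are placed by inverting the
RI interpolation on a C6–C30 ladder whose times approximate a 4 °C/min
program on a 60 m column.

What the simulator does *not* emulate: chromatographic peak shapes,
co-elution, fragment ions below the molecular-ion window, detector
saturation, and retention-time drift. Passing the closed-loop tests
therefore demonstrates that the numerical chain (extraction,
normalization, deconvolution, summarization, classification) is correct
and unbiased under the stated noise model — not that peak integration of
real chromatograms is solved, which is upstream of this package.

## Numerical choices and degenerate inputs

* Nominal-mass binning sums abundances within each unit-mass bin
  (round-to-nearest); binning is idempotent. Unit-resolution quadrupole
  data carry no sub-dalton information worth preserving.
* All-zero clusters, missing molecular ions, zero internal-standard
  areas, and retention times outside the ladder raise typed errors
  (`camola_data_error` / `camola_numeric_error` / `camola_config_error`)
  that the CLI maps to exit codes 3, 4 and 2.
* Windows that would cross the 400 u acquisition limit are truncated with
  a warning and a reduced n.
* Deconvolution accuracy: on noiseless forward-generated clusters the
  solver recovers fractions to better than 1e-6 for formulas up to C12;
  at 5% proportional noise the per-coordinate mean absolute error over
  200 replicates stays below 0.02 with vanishing bias. These sizes (1000
  random identity checks, 25 random formulas, 200–800 Monte-Carlo
  replicates) keep the full suite under a minute while leaving the
  estimates' standard errors far below the tolerances tested.
* Analyzed-ion subsets: some compounds are evaluated on a narrower ion
  window than their carbon count (e.g. M+0/M+1 only); the pipeline
  supports a per-compound override with renormalization over the subset,
  which is also how printed summaries that do not sum to 100 are handled
  — they are renormalized before classification.

## Known limitations

* No vendor/raw-format or mzML parsing, no peak picking: inputs are
  integrated peak lists (MSP or CSV).
* High-resolution isotopologue analysis and fragment-ion labeling are out
  of scope; the model is strictly molecular-ion, unit-mass.
* Positional isotopomers are invisible to this measurement; only counts
  of labeled carbons are inferred.
* The origin thresholds are calibrated to one family of model systems;
  other chemistries may need different cutoffs, which is why they are
  plain configuration.
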