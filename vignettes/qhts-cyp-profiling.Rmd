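---
title: "From raw 1536-well plates to CYP inhibition profiles: the methods behind qhtscyp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From raw 1536-well plates to CYP inhibition profiles}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qhtscyp)
```

`qhtscyp` implements the analysis chain of a quantitative high-throughput
screen (qHTS) for cytochrome P450 inhibition: raw luminescence plates are
normalized against on-plate controls, corrected for spatial background,
pivoted into 15-point concentration-response series, fit with a
four-parameter Hill model, classified into Tox21-style curve classes and
ranks, aggregated over triplicate runs into reproducibility calls and
activity outcomes, and finally analyzed for structural-class enrichment via
a self-organizing map (SOM) and Fisher's exact test. Because the deposited
screen data are too large for routine testing, the package ships a
synthetic screen generator with known ground truth; every stage of the
pipeline is validated against that truth.

## The screen design being emulated

A screen consists of 1536-well plates (32 rows x 48 columns). Columns 1-2
carry duplicate 16-point titrations of a positive-control inhibitor,
columns 3-4 carry DMSO (vehicle) wells, and columns 5-48 carry test
compounds. Each concentration level of the 15-point test titration
(0.7 nM to 58 µM, geometric spacing, step ratio about 2.25) occupies one
plate, so a library of up to 1408 compounds fits one plate stack per run.
The screen is run three times with compounds re-randomized to different
wells, which is what makes the triplicate reproducibility analysis
informative about positional artifacts. A DMSO-only plate (control columns
plus an all-DMSO test area) accompanies each run for background-pattern
estimation, mirroring the practice of placing vehicle plates at the head of
the compound stack.

The generator's signal model for a well with true signed activity $a$ (in
percent, inhibition negative) is

$$ V \;=\; \Big[\, bg + (B - bg)\,(1 + a/100) \,\Big]\cdot \varepsilon \;+\; P(r,c), $$

where $B$ is the DMSO baseline (default 10 000 RLU), $bg = 0.05\,B$ the
fully-inhibited background (setting the assay window S/B at 20, the order
of magnitude reported for these luminescent CYP assays),
$\varepsilon$ multiplicative lognormal noise with CV 3% (default), and
$P(r,c)$ an additive spatial background: separable linear row/column
gradients plus an optional edge ring, scaled to a 5% default amplitude and
held fixed within a run. True activities follow the same four-parameter
Hill model the pipeline fits.

Generator choices that the source design left open, fixed here once:

* **Control split within columns 1-4.** The design says controls occupy
  columns 1-4 and that the positive control is plated as duplicate 16-point
  titrations; the split (titrations in columns 1-2, DMSO in columns 3-4) is
  a convention of this package.
* **Inhibitor efficacy.** True inhibitors draw maximal inhibition uniformly
  from -100% to -80%: enzymatic inhibitors of a single reporter reaction
  typically drive the signal to the assay floor at saturating dose.
  Activators (positive cooperativity) draw +40% to +100% at a 2% default
  rate, echoing the observation that activation is real but much rarer than
  inhibition.
* **Per-assay hits.** An inhibitor affects each of the five CYP channels
  independently with probability 0.7 (at least one guaranteed), yielding a
  realistic mixture of pan-CYP (about 17% of actives) and selective
  compounds. True AC50s are log-uniform over the central portion of the
  tested range (`[3 conc_min, conc_max/3]`), Hill slopes uniform on
  [0.8, 2].
* **Saturating control.** The positive-control titration (midpoint 20 nM,
  slope 2) is pinned to exactly -100% activity at doses at least 100x its
  midpoint. A real screen chooses its control to reach full effect at the
  top doses; without the pin, the Hill asymptote is never reached at finite
  dose and the normalization anchor would carry a small systematic bias,
  which would make exact round-trip checks meaningless.
* **Duplicate samples.** 5% of samples are duplicate preparations of
  earlier compounds (same parent, fingerprint, truth), so the
  unique-compound reduction in the reporting stage has something to do.
* **Fingerprints** are abstract 256-bit vectors: one archetype per
  structural class (bit density 0.3), members differing by independent 5%
  bit flips. They model class structure, not chemistry.

## Normalization, pattern correction, and QC

Raw wells are converted to signed percent activity with
$100\,(V_{\mathrm{compound}} - V_{\mathrm{DMSO}})/(V_{\mathrm{DMSO}} -
V_{\mathrm{pos}})$, using per-plate *medians* of the DMSO wells and of the
positive-control wells at the top four titration concentrations (the lower
part of the control titration spans partial effects and would dilute the
anchor). DMSO wells thus center at 0 and full inhibition maps to -100;
activation is positive. Means and SDs of the same control wells feed the
plate QC statistics: S/B, CV, and Z' = 1 - 3(sigma_pos +
sigma_dmso)/|mu_dmso - mu_pos|, with the conventional pass rule S/B > 2,
CV < 10%, Z' > 0.5.

The spatial background is estimated per run from the normalized DMSO-only
plates: per-well medians across plates, a Tukey median polish into row and
column effects, and loess smoothing of each marginal profile. Two details
matter:

* The first and last position of each marginal keep their raw (unsmoothed)
  estimates. Plate-edge effects are step-like and real; a smoother would
  flatten them, and the raw edge estimates already pool ~45 wells.
* The surface is recentered to zero plate-wide median, and applying it
  preserves each plate's median activity exactly. A median-preserving
  correction can remove *well-position-dependent* bias but, by
  construction, not a *plate-level* offset. Such an offset arises when the
  spatial gradient makes the DMSO anchor columns (3-4) unrepresentative of
  the plate; it is absorbed downstream by the free baseline of the Hill
  fit and by the classifier judging "points above background" relative to
  that fitted baseline, not relative to zero.

With the 5% gradient and 3% noise defaults, the property tests require the
estimated surface to cut the spatial (plate-median-centered) systematic
bias of test wells by several fold against the known injected pattern, to
correlate above 0.9 with an injected linear gradient, and to be essentially
zero when no pattern is injected.

## Hill fitting

The four-parameter model is
$y(c) = \mathrm{baseline} + \mathrm{efficacy}\,/\,(1 + (\mathrm{AC_{50}}/c)^{h})$,
with the IC50 reported as the fitted AC50 (in µM) for inhibition-direction
curves. Fitting uses profiled least squares: for a candidate
$(\log \mathrm{AC_{50}}, \log h)$ the two linear parameters have a
closed-form constrained solution, so the optimizer works in two dimensions
only. A log-spaced start grid (14 AC50 values x 5 slopes, including the
slope bound, where sharp-transition optima hide) is scanned and the four
best starts are polished with L-BFGS-B. Bounds confine AC50 to one decade
beyond the tested range, the slope to [0.3, 8], |efficacy| to 150 and
|baseline| to 30 — standard qHTS practice that keeps extrapolation honest.
A fit counts as converged only when it beats the best flat (constant)
model; flat series return efficacy 0. The property suite requires the fit
never to lose to a dense 50 x 20 grid-search oracle by more than 0.1% RSS,
to recover noiseless curves to 1% in AC50, and to keep the median
|log10 AC50 error| at or below 0.1 across 200 noisy curves (5% activity
noise). Weighting and convergence criteria are not prescribed by the
source protocol; unweighted least squares with the above multi-start is
this package's choice.

## Curve classes, ranks, outcomes

Classification uses efficacy, the number of data points beyond the
background band, and fit quality. The background band is `3 x` the SD of
normalized DMSO-well activity of the run (measured, not assumed). A curve
qualifies as class 1.x/2.x when the fit converged, |efficacy| >= 30%, and
at least two points lie beyond the band in the curve's direction — measured
both from zero (the plate background) and from the fitted baseline, so that
neither plate-level offsets nor fits that park their baseline at a bound
below all the data can manufacture activity; class 1.x additionally
requires the fitted response
at the two highest tested concentrations to come within 10% of the top
asymptote (both asymptotes observed). Subclass .1 needs |efficacy| >= 80%
and r^2 >= 0.9. A non-qualifying series whose top-concentration response
alone exceeds the band is class +-3; otherwise class 4 (inactive). Signs
encode direction throughout. The numeric thresholds stand in for a
protocol reference that the source text cites but does not reproduce; all
are exposed in `class_config()` so an alternative table can be swapped in.

Curve ranks map class magnitude to evidence strength (1.1 -> 8, 2.1 -> 7,
1.2 -> 6, 2.2 -> 4, 3 -> 2, 4 -> 0), add a +1 bonus (capped at 9) for
|efficacy| >= 90%, and copy the class sign. Triplicate ranks are averaged;
an |average rank| of at least 5 together with an *active match*
reproducibility call yields a definite inhibitor/activator outcome, weaker
direction-consistent evidence an inconclusive-directional outcome,
conflicting directions or a mismatch an inconclusive one, and all-class-4
triples inactive.

## Reproducibility calls

Each run is first collapsed to active / inactive / inconclusive (classes
+-1.1 … +-2.2 / 4 / everything else) with a direction. Outcomes are scored
+-5 (active), +-2.5 (inconclusive, 0 if directionless), 0 (inactive) — the
published rule states the thresholds but not the scores, and these values
make any active/inactive disagreement exceed the mismatch threshold while
keeping active/inconclusive mixtures in the inconclusive band. The mean
absolute pairwise score difference and the inactive fraction then decide:
active match (< 1.1 and < 25% inactive), inactive match (< 1.1 and > 50%),
mismatch (> 2.5), inconclusive otherwise. All-inconclusive triples satisfy
the literal active-match rule while containing no active run; they are
rerouted to inconclusive. The whole rule is verified by exhaustive
enumeration of all 216 signed run-outcome triples against an independent
restatement of the thresholds.

On the default synthetic screen the mismatch rate stays below 1% per
channel, the range reported for well-behaved triplicate screens of this
design; most mass sits in inactive match, with active match rates set by
the library's active fraction.

## Clustering and enrichment

Compounds are clustered by fingerprint with an online SOM on a hexagonal
grid (Gaussian neighborhood on hex distances, geometrically decaying
learning rate 0.5 -> 0.02 and radius, codebook initialized from jittered
data rows, deterministic in the seed; the inner loop is compiled). Cluster
ids follow the `k<row>.<col>` convention. SOM hyperparameters are not
stated in the source; 20 epochs with the above schedules are the package
default, and the analysis grid (6 x 5 for the 1000-compound default
library, about 30 compounds per occupied cell, a few cells per generated
class) is sized so clusters correspond to structural classes. Per cluster,
a 2 x 2 table (in/out of cluster x active/inactive) is tested with the
one-sided hypergeometric tail P(X >= k) — the "greater" Fisher exact test —
and called significant at raw p < 0.01 with no multiple-testing correction,
matching the screen's convention (a Benjamini-Hochberg column is available
but off by default). The deficiency tail is computed separately for the
blue side of the signed -log10(p) heatmap. The tests require exact
agreement (1e-12) with a brute-force tail sum, a false-enrichment rate at
or below 2% on null libraries (the discreteness of the hypergeometric makes
the raw-p rule conservative), and recovery of all three enriched classes'
dominant clusters in at least 95% of 20 independent screens.

## Reporting

Per compound: potency (IC50 < 1 µM in any CYP channel with an inhibitor
call), selectivity (inhibitor whose IC50 is more than 10-fold below *every*
other channel — the stricter reading of ">10-fold compared to other CYPs";
non-inhibitor channels count as infinite), pan-inhibition (inhibitor in all
five channels), and a luciferase flag (inhibitor in the counter-screen with
IC50 <= 20 µM; weaker or inactive counter-screen responses count as clean).
Duplicate samples collapse to their parent compound by worst case — a
parent inhibits a channel if any of its samples does — which matches
"inhibited at least one" semantics; percentages are relative to unique
compounds.

## Problem sizes and runtime

The test suite and acceptance script run everything at desk scale: screens
of 1000 compounds in 10 classes for one channel (about 3000 Hill fits per
screen, ~20 s each), 20 such screens for the end-to-end recovery
properties, 25 null libraries of 400 compounds for enrichment calibration,
and one full five-CYP + luciferase screen (18 000 fits) for the
screen-level summaries. These sizes were chosen to keep a full run in the
tens of minutes on one core while leaving the statistical checks
well-powered.

## Known limitations

* The synthetic generator models noise as well-independent lognormal plus a
  smooth separable gradient; it has no liquid-handling streaks, dispense
  dropouts, or plate-to-plate drift, so passing tests say nothing about
  robustness to those artifacts.
* Fingerprints are abstract bit vectors; enrichment results demonstrate the
  machinery, not chemistry. The real screen's proprietary structural
  fingerprints (and hence its specific cluster count) are out of scope.
* The curve-class decision table and reproducibility scores are documented
  conventions standing in for an unpublished reference table; absolute
  class frequencies will differ from pipelines using the original table.
* The luciferase counter-screen is modeled as an independent interference
  channel; correlated artifacts (a compound interfering in both the CYP and
  luciferase channel through the same mechanism) are not simulated.
* Plate-level offsets induced by strong gradients are absorbed by fit
  baselines rather than removed, as discussed above; with gradients well
  above the 5% default this approximation degrades.
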