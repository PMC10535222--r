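---
title: "Local versus systemic virtual bioequivalence: model and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Local versus systemic virtual bioequivalence: model and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lumenvbe)
```

## Why this package exists

For a gut-locally-acting drug, the plasma concentration profile is
*downstream* of the site of action. Two formulations can deliver
indistinguishable plasma exposure while delivering very different amounts of
drug to, say, the duodenal mucosa. `lumenvbe` makes that discordance
quantifiable: it simulates an enteric-coated controlled-release budesonide
formulation through a segmented gastrointestinal absorption model, runs
replicated 2x2 crossover virtual bioequivalence (VBE) trials on virtual
healthy and Crohn's-disease populations, and classifies every gut site as
concordant or discordant with the plasma bioequivalence verdict.

## Dissolution model

Release is empirical Weibull,

$$F(t) = F_\max\left(1 - e^{-\,(t - T_{lag})^{\beta}/\alpha}\right),$$

with $F_\max$ in percent, $\alpha$ a scale in $h^\beta$, $\beta$ a shape, and
$T_{lag}$ a lag (default 0 everywhere; the tabulated parameter sets carry no
lag). The reference product has $(F_\max, \alpha, \beta) = (100, 3.12, 0.94)$
and a coating trigger pH of 5.5. Virtual variants come in two families:

* **Release shifts**: the sampled reference curve moved by a constant
  $\Delta$ percentage points at every sampling time, capped at 100%, with
  completion standardized to 100% at 12 h (at 7 h for $\Delta = +20$, which
  reaches the cap early), then refitted to the Weibull form with
  $F_\max = 100$ fixed.
* **Trigger-pH variants**: identical release curve, different coating
  trigger (5.0, 6.0).

Similarity between two curves sampled on one grid is the f2 factor,

$$f_2 = 50\,\log_{10}\!\frac{100}{\sqrt{1 + \tfrac1n\sum_t (R_t - T_t)^2}},$$

computed over **all** sampled points: we deliberately do not apply the
convention of discarding points after both curves pass 85% release, because
the anchor identity used throughout — a constant 10-point offset gives
$f_2 = 50$ at any $n$ — presumes all points count. The cutoff is available as
an argument (`drop_after_85`) for users who want the regulatory variant.
The default sampling grid is 0.5, 1, 2, ..., 12 h; it is an assumption (the
source dissolution assay grid is not published) and therefore configurable.
Tabulated f2 values attached to the formulation library are treated as
stored inputs of those formulations, not as quantities the package claims to
regenerate from the (unpublished) raw assay.

`bootstrap_f2()` resamples formulation *units* (vessels) with replacement on
each side and reports the median and 5th/95th percentile interval of the f2
of resampled means. Resampling units (rather than time points) was chosen
because the unit is the natural exchangeable entity of a dissolution assay.
`generate_dissolution_replicates()` supplies synthetic units: multiplicative,
mean-preserving lognormal noise on the Weibull curve, clipped to [0, 100] and
monotonized by cumulative maximum — the cumulative-max step encodes that
cumulative release cannot decrease within a unit.

## Gut absorption model

Nine compartments — stomach plus eight absorbing segments (duodenum, two
jejunum, four ileum, colon) — each carry three drug states: intact pellets,
dissolved drug in lumen, and drug in the enterocyte layer.

**Transit.** Pellets and fluid move by first-order chains. Pellet mean
residence is 0.8 h gastric and 3 h small-intestinal, the SI share split over
the seven SI segments in proportion to length; fluid residence is 0.27 h
gastric, 3.4 h SI, and sex-specific whole-colon values (37.5 h male,
55.75 h female). Pellets reaching the end of the colon leave as fecal loss
of undissolved drug. Pellet residence in the colon is not separately
published; pellets are assumed to move with colonic contents.

**pH-triggered release.** The enteric coating opens only at segment pH
*strictly above* the trigger pH. A shared release clock advances at the rate
of the solid fraction currently past its trigger; released drug enters the
local lumen at the Weibull hazard $F'(\tau) / (100 - F(\tau))$ evaluated on
that clock (capped at 50 h$^{-1}$ for numerical safety near the lag). This
construction makes the population of pellets release with exactly the
Weibull cumulative profile once triggered, makes a trigger of 9 release
nothing, and guarantees that lowering the trigger never delays release.
With the default fasted pH ladder (stomach 1.5; duodenum 6.0; jejunum
6.2/6.4; ileum 6.8-7.4; colon 6.4), a 5.5 trigger opens in the duodenum, a
5.0 trigger behaves identically to 5.5 (both open at the duodenum), and a
6.0 trigger opens first in the jejunum — so the pH-6 variant is release-
delayed and its duodenum sees no drug at all, which the bioequivalence layer
records as non-BE with undefined statistics rather than dropping the cell.

**Absorption and gut wall.** Lumen-to-enterocyte flux is apical
transcellular plus paracellular permeability times segment cylinder area,
scaled by the regional absorption scalars 0.06 (duodenum), 0.12 (jejunum),
0.54 (ileum), 1.44 (colon). The enterocyte loses drug to CYP3A4 metabolism
(per-segment abundance shares of the 65.4 nmol SI total; 1.99 nmol in colon;
intrinsic clearance 4.1 uL/min/pmol) and to basolateral transfer into portal
blood, and pumps drug back to the lumen by Michaelis-Menten P-gp efflux
(Jmax 93, Km 9.4 uM; the source cites Jmax without units, so it is plain
configuration). Portal drug passes a well-stirred first-pass liver,
$E_H = f_{u,b} CL_{int} / (Q_H + f_{u,b} CL_{int})$, before the central
compartment; systemic elimination is hepatic ($Q_H E_H$) plus renal
($f_u \cdot$ GFR). Disposition is a two-compartment lumped model with
$V_{ss} = 0.8 \times 2.69$ L/kg $\times$ weight; central volume 25% of
$V_{ss}$ and 40 L/h distribution clearance were chosen once to give the
observed biphasic decline.

**Calibrated geometry.** Anatomical cylinder areas overstate the area
effectively wetted by the sparse fasted fluid pockets, so apical exchange
uses 5% of anatomical area and basolateral exchange 25%. These two
accessibility fractions are calibrations, fixed once so that (i) the
simulated enterocyte:lumen concentration ratio falls near the observed ~1%
(package default run: 0.2-7% across segments), (ii) lumen concentrations run
2+ orders of magnitude above plasma, and (iii) absorption of the enteric
formulation is predominantly ileo-colonic (~88% of the absorbed dose in the
default run). Enterocyte volume is 1% of segment fluid volume; it sets the
response time of the enterocyte layer, not its quasi-steady concentration.

**Numerics.** The rate laws are compiled C evaluated by the BDF solver
(`deSolve::vode`) at rtol 1e-8 / atol 1e-10 nmol, output every 0.25 h over
0-24 h by default. Every flux appears symmetrically in a source and a sink,
so the ledger identity (solid + lumen + enterocyte + central + peripheral +
metabolized + excreted + fecal = dose) holds to solver precision at every
output time; the suite enforces 1e-6 relative across randomized parameter
sweeps. Sub-nanomole negative undershoots from the solver are clamped to
zero on output. A reduced configuration (instant release into one absorbing
segment, direct lumen-to-portal absorption, one-compartment disposition, no
first pass) is maintained as a permanent closed-form check against the
Bateman solution and agrees to ~1e-8 relative.

## Virtual populations

The healthy specification holds the tabulated means (liver CYP3A4
137 pmol/mg; SI CYP3A4 65.4 nmol; colon CYP3A4 1.99 nmol; albumin
50.34/49.38 g/L M/F; GFR 172.42 mL/min for the 70-kg representative, scaled
allometrically with weight). The Crohn's specification overrides exactly
liver CYP3A4 (55.4 M / 80.5 F), SI CYP3A4 (8.6), colon CYP3A4 (0.2) and
albumin (30.13 M / 25.2 F). With less CYP3A4 at every site, the disease
representative clears less drug pre-systemically and systemically, so the
same dose yields roughly twice the plasma exposure — the suite asserts the
direction by simulation.

Between-subject variability is lognormal with the median pinned at the
specification mean, clamped to physiological bounds. The source simulator's
internal CVs are not published; the defaults here — 30% on enzyme
abundances, 20% on residence times, flows and masses, 15% on albumin and
weight — are stated assumptions, configurable per population. Unbound
fraction is re-derived per subject from albumin by proportional
binding-site scaling, $f_u' = (1 + \frac{1-f_u}{f_u}\frac{HSA'}{HSA})^{-1}$,
a documented stand-in for a dissociation-constant model.

Within-subject (occasion) variability applies to the three fluid residence
times only (gastric 38.217%, SI 21.132%, colon 44.962% CV), clamped to
their published limits, drawn independently per period — period 2 is an
independent redraw rather than a correlated deviate because only CVs and
limits are published. The single colon compartment uses the whole-colon
rows. A real crossover also varies enzymology and motility of the pellet
phase between occasions; because the published occasion model covers fluid
only, the null VBE run is tight around GMR 1 and the package's
bioequivalence conclusions are driven mostly by the deterministic
formulation effect. Passing the null-calibration check therefore shows the
trial machinery is unbiased and well-powered under the stated occasion
model, not that the model reproduces clinical between-occasion variance in
full.

## Trials, statistics, decisions

Each virtual trial is a two-sequence (TR/RT), two-treatment, two-period
crossover: a fresh cohort per trial, sequences assigned 50/50, occasion
physiology drawn per period and shared by whichever treatment that period
carries, complete washout (each period simulated from a drug-free state).
NCA (linear trapezoid to the last positive concentration; lin-up/log-down
available) yields AUC\_last and Cmax at 17 sites: plasma (sampled at a
clinical schedule out to 24 h) and the lumen and enterocyte layers of all
eight segments (dense solver grid — local sampling is a modelling construct,
not an assay).

The bioequivalence analysis is the classical log-scale mixed model with
sequence, period and treatment fixed and subject-within-sequence random.
For balanced complete data this is implemented in closed form: the
treatment contrast is the average over sequence groups of mean per-subject
log differences, with pooled within-sequence variance, $n-2$ degrees of
freedom, and a 90% t interval; BE iff the CI lies in [0.80, 1.25]. The suite
proves the closed form equals a brute-force REML fit to six decimals across
hundreds of simulated datasets. One caveat is stated rather than hidden: on
a small fraction of datasets the REML subject-variance estimate collapses to
its zero boundary, where the *constrained* fit deviates from the classical
contrast by construction; the equivalence claim covers interior solutions,
which is essentially all of them.

A formulation is bioequivalent at a site/metric when at least
$\lceil 0.8\,n_{trials}\rceil$ of the replicated trials conclude BE (8 of 10
at the default design). The combined metric is computed per trial (BE iff
both AUC and Cmax are BE) and then thresholded — combining before
thresholding was an open choice; combining per trial is the stricter and
more interpretable reading. Discordance classification treats plasma as the
test and the local site as the truth: plasma-BE/local-NBE is a false
positive (a substandard product passing on plasma), plasma-NBE/local-BE a
false negative. The heatmap encodes local non-BE in the cell border rather
than only in styling; all semantics round-trip through the CSV export.

## Problem sizes and determinism

The default study design is 10 trials x 12 subjects, which the acceptance
script runs for the null calibration and for the +/-10% discordance
experiments (about 240 subject-period simulations per study; a full study
runs in well under a minute on one core). The panel driver defaults to a
reduced 3 trials x 8 subjects x 3 formulations scale for quick end-to-end
runs, with the full eight-formulation panel available by configuration.
Every stochastic step (cohorts, occasions, bootstrap, trial replication)
descends from explicit integer seeds, and identical configurations
reproduce byte-identical result files.

## Known limitations

* The transit surrogate is a first-order compartment chain; it reproduces
  mean residence, not the full transit-time distribution of a segregated
  pellet-transit model.
* Fluid volumes, pH values and exchange-area accessibilities are explicit
  literature-typical configuration, not fitted to clinical profiles; only
  directional and order-of-magnitude agreement with reported local
  concentrations is claimed.
* No fed state, no bile-micelle solubilization or precipitation, no
  metabolite kinetics, no dropout or carryover in trials.
* Occasion variability covers fluid residence times only (see above), so
  simulated within-subject variance understates clinical variance; BE
  conclusions here isolate the formulation effect.
* Plasma binding in disease is rescaled from albumin proportionally; a
  measured dissociation constant would supersede it.

## A minimal session

```{r example, eval = FALSE}
lib <- formulation_library()
pop <- default_healthy_population()
pk <- run_vbe(lib$reference, lib$`+10%`, pop,
              trial_design(n_trials = 10, n_subjects = 12, seed = 7))
be <- be_results(pk)
dec <- discordance_table(be, formulation = "+10%", f2 = 50.8)
hm <- build_heatmap(dec, layer = "enterocyte", metric = "combined")
hm$plot
```
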