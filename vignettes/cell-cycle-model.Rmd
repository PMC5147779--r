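---
title: "A stochastic model of the budding-yeast cell-cycle control network"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A stochastic model of the budding-yeast cell-cycle control network}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`yeastcc` simulates the cyclin/CDK control network of *Saccharomyces
cerevisiae* as a mass-action system of elementary reactions — several
hundred of them once multisite phosphorylation chains and complexes are
expanded — inside a cell whose volume grows exponentially,
V(t) = V(0)·e^(μt), and divides asymmetrically. Because every step is an
elementary reaction, the same rate table drives both a deterministic
engine (mass-action ODEs, `simulate_deterministic()`) and an exact
stochastic engine (Gillespie's direct-method SSA, `simulate_cell()`); any
unit mismatch between the two is caught by a consistency test that
compares the ODE right-hand side with the stoichiometry-weighted
propensities.

The network contains 17 genes. Seven — *CLN1*, *CLN2*, *CLB5*, *CLB2*,
*SIC1*, *SWI5*, *CDC20* — are transcribed from discrete two-state
promoters driven by their transcription factors (SBF for the G1/S
cyclins, Fkh2 for the mitotic regulon, Swi5 for *SIC1*); the other ten
(*CLN3*, *WHI5*, *SBF*, *FKH2*, *APC*, *NET1*, *CDH1*, *CDC14*, *HBF*,
*HT1*) are constitutive. Following the field's convention, "Clb5" is the
composite of Clb5+Clb6, "Clb2" of Clb1+Clb2, and "Sic1" includes the
inhibitory domain of Cdc6; Cdc28 is not a variable (each cyclin count is
the count of its CDK heterodimer). *RAD27* represents the G1/S regulon as
a promoter-activity reporter only — no mRNA or protein species — since
only its gene activity is analyzed.

Ultrasensitivity comes from distributive multisite phosphorylation:
Whi5 (n = 10 sites, active with ≤ 2 phosphates), SBF (4, 0), Sic1 (9, 5),
Cdh1 (11, 0), Net1 (8, 3), Swi5 (3, 0), Fkh2 (2 sites, active only fully
phosphorylated) and the APC (11 sites). Sic1's chain is disordered —
count-resolved species with combinatorial multiplicities (n−k) on
phosphorylation and k on dephosphorylation, which is exactly the marginal
of the 2^9 site-resolved master equation under site-symmetric rates (a
test verifies this against a brute-force CME solve at n = 2). All other
chains are ordered. The APC does not use an activity mask: the form with
k phosphates binds Cdc20 at a rate scaled by β^(n−k), β = 0.525, n = 11,
so Cdc20:APC activity builds up slowly as mitotic CDK phosphorylates the
APC — the delay that prevents premature mitotic exit.

Stoichiometric inhibition is explicit: Whi5 with ≤ 2 phosphates binds
free active SBF; Sic1 with ≤ 5 phosphates binds Clb5 or Clb2; Net1 with
≤ 3 phosphates sequesters Cdc14 in the RENT complex. Kinases act on the
bound forms too, and crossing the activity boundary releases the partner
(e.g. phosphorylating Whi5P2:SBF frees SBF). Regulated degradation:
Cdc20:APC degrades Clb2, Clb5 and Ht1 (the Net1-directed phosphatase);
Cdh1:APC degrades Clb2 and Cdc20; Sic1 with ≥ 6 phosphates is destroyed
by the SCF route.

Size control enters through *CLN3*: every other protein's translation
propensity is proportional to cell volume (ribosome content), but Cln3's
is proportional to V², so its concentration grows with the cell and
trips the Whi5 switch at a threshold size. Transcription is constant per
active gene copy, so mRNA numbers stay at a few copies per cell
independent of size while protein concentrations are homeostatic. At
division, mother and daughter receive (1−f) and f of the volume and of
each molecular species — except Cln3, of which the daughter receives only
25%, producing the daughter-specific Start delay — and except the haploid
gene copies, which are carried (in their current promoter state) into
both progeny rather than split.

## Parameters

The model's reference parameter table is not available to this package,
so `default_params()` is this package's own calibration of the published
mechanism. The calibration targets, in order of priority:

* the deterministic wild-type limit cycle in glucose has period equal to
  the mass doubling time ln(2)/μ = 99 min (balanced growth makes this an
  attractor; the test checks convergence to 2%), with the event order
  Whi5 nuclear exit → budding → DNA-synthesis onset → division;
* mRNA half-lives of 5–10 min (3 min for *CLN1*, *CLN2*, *CLB5*) and
  means of a few copies per cell; protein levels of hundreds to
  thousands of molecules per cell (e.g. ~300 nM total Whi5 against the
  200 nM nuclear-exit threshold, free Clb2 peaking near 110 nM against
  the 12.5 nM division threshold);
* qualitatively correct mutant phenotypes: *clb5Δ clb6Δ* delays DNA
  onset (it must wait for Clb2); *cln1Δ cln2Δ* is viable but buds late
  and large (Cln3, whose level scales with size, substitutes for the
  missing feedback); *CLB2-dbΔ* arrests in mitosis with very high Clb2;
  *cdh1Δ* is only partially viable.

Medium objects carry μ, the daughter fraction f (0.40 / 0.36 / 0.35 for
glucose / galactose / glycerol-ethanol) and `clb2_factor`, a
medium-indexed multiplier on *CLB2* transcription (1.0 / 0.8 / 0.7).
The source model states that Clb2 synthesis depends on μ without giving
a functional form; a per-medium multiplier is the minimal commitment, it
is exposed in the medium table, and it is what lets stable-Clb2 strains
exit mitosis on poor carbon sources.

Thresholds (all configurable in `default_params()`): division when free
[Clb2] falls through 12.5 nM, armed at 25 nM; budding when the `bud_ss`
indicator rises to 25 nM; DNA onset at `dna_ss` = 30 nM; Whi5 nuclear
exit when the summed ≤ 2-phosphate Whi5 pool falls below 200 nM; gene
activity thresholds 0.15 (*CLN2*) and 0.2 (*CLB2*, *RAD27*); arrest
window 500 min (stretched to 3.5 mass-doubling times on slow media so
the long-but-finite G1 tail of tiny daughters is not misread as arrest).

## Numerical choices

**Time-varying volume in the SSA.** Propensities are volume-dependent
(bimolecular ∝ 1/V, translation ∝ V or V²). The SSA treats V as constant
between events and inserts a forced null event every Δ = 0.1 min at
which V, all propensities, the indicator variables and the event
detectors are refreshed. With μΔ ≈ 7·10⁻⁴ the per-step volume error is
below 0.1%. Δ is an argument (`dt_null`) for convergence checks.

**Indicators.** `bud_ss` and `dna_ss` are scoring devices, not
molecules: they relax with first-order kinetics toward an
efficiency-weighted cyclin sum (all G1/S cyclins for budding; B-type
cyclins only for DNA synthesis) and are integrated exactly (exponential
relaxation) at the null-event cadence, resetting to zero in both progeny
at division.

**Gene activity.** Activation times of *CLN2*, *RAD27* and *CLB2* are
scored against thresholds on a fractional activity signal. For a 1-copy
gene the promoter state is binary with ~0.4-min dwells, and a short
moving average of that signal crosses a 0.15–0.2 threshold spuriously
somewhere in any sufficiently long G1. The default activity is therefore
the promoter-occupancy function of the instantaneous transcription-factor
concentrations (a smooth function of species with thousands of
molecules), lightly smoothed with a 1-min exponential moving average;
the windowed binary average remains available via
`simulate_cell(activity = "window")`. With occupancy scoring the
wild-type *CLN2*/*RAD27* activation ages are tightly coupled, as they
should be when both genes read the same Cln1,2 surge.

**Division detection.** The detector arms when free [Clb2] exceeds twice
the division threshold and fires on the subsequent downward crossing —
arming prevents newborn G1 cells, whose Clb2 is already below threshold,
from re-triggering. Event location in the ODE engine uses `lsodar` root
finding; in the SSA engine events are located at the 0.1-min null-event
cadence.

**Random numbers.** Each cell draws from its own xoshiro256** stream
seeded by mixing (master seed, cell id) through splitmix64, so a culture
is bit-reproducible regardless of scheduling, and any cell can be
re-simulated in isolation. Division-fraction noise and binomial
partitioning draw from R's RNG re-seeded per division from the same pair.

**EM mixture fits** use 5 random restarts and stop when the
log-likelihood gain drops below 1e-8; model choice between one- and
two-component Poisson fits uses the small-sample-corrected information
criterion (AICc), since the source analyses state only that the mixture
"fit better". Sic1 decay is fitted on log counts from the pre-minimum
peak down to max(5 molecules, 1% of peak) — the cycle's Sic1 minimum
bounds the fit so that the telophase re-accumulation cannot hijack it.

**Size-control regression** uses equal-count bins (default 8–10) of
x = ln(V_bir/⟨V_bud⟩) against y = μ·T_unbud; only ratios enter, so the
slope is invariant to rescaling all volumes.

## What the simulations do and do not emulate

The generator reproduces intrinsic noise (molecule-number fluctuations
through exact SSA dynamics) and, optionally, two extrinsic sources:
binomial partitioning at division and Gaussian noise on the division
fraction f (mean f, CV 5–10%, truncated to (0.05, 0.95) by resampling).
It does not include checkpoint machinery (mitotic checkpoint complex,
securin/separase, FEAR/MEN), nutrient shifts, cell death beyond
permanent arrest, or the Whi5-dilution alternative size-control
mechanism. Passing tests therefore validate the control-network logic
under clean exponential growth, not those excluded layers.

Problem sizes in the shipped tests and acceptance script are chosen for
a single-CPU run: cultures of 40–110 cells, extant populations of tens
of cells, and fixture chains of 10³–10⁴ stationary samples. These give
stable qualitative orderings (verified against larger pilot runs) while
keeping the whole suite in the tens of minutes; the same functions scale
to the hundreds-of-cells populations of the original analyses by raising
`max_cells`.

## Known limitations

* The parameterization is a reconstruction: quantitative per-strain
  means (e.g. exact activation ages or arrest percentages) are in the
  right regime but not calibrated to the original table, and the
  wild-type coherence of *CLN2*/*RAD27* activation reaches r ≈ 0.95
  rather than 0.99.
* The *cdh1Δ* strain is much healthier here (arrest fractions in the
  percent range rather than ~45%): in this calibration Sic1 backs up Cdh1
  more effectively than in the original (a known sensitivity — the balance
  between Cdh1 and Sic1 as G1 stabilizers). Likewise *clb5Δ clb6Δ*
  daughters delay DNA onset only slightly, because their T_g1 is dominated
  by the Start delay rather than by Sic1-clearance decoherence.
* Deterministic runs use symmetric division only; asymmetric division
  and per-cell event ages live in the stochastic engine.
* The APC phospho-state is frozen while Cdc20 is bound; dephosphorylation
  acts on the free forms.
* Two population-level orderings are only partly reproduced: the galactose
  and glycerol-ethanol size-control slopes both saturate near the
  perfect-sizer value (media differ only by μ, f and the CLB2 factor here,
  which does not separate them), and the across-strain correlation of
  CV(T_div) with CV(T_bud) does not exceed that with CV(T_unbud), because
  this parameterization leaves more of the cycle-time variance in the
  unbudded phase than the original. The companion inequality for CV(V_bir)
  and the remaining orderings hold.
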