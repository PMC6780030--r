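---
title: "In silico drug trials with the cellular electromechanical window"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{In silico drug trials with the cellular electromechanical window}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the approach

Drug-induced Torsade de Pointes (TdP) is the arrhythmia that cardiac safety
pharmacology tries hardest to anticipate. The regulatory surrogates — hERG
(IKr) block and QT prolongation — are sensitive but unspecific: many
multichannel drugs block IKr *and* the L-type Ca2+ current (ICaL), and the
latter offsets much of the pro-arrhythmic burden of the former. This package
implements a human in silico drug-trial pipeline built around a cellular
surrogate of the *electromechanical window*,

$$\mathrm{EMw} = \mathrm{CTD}_{90} - \mathrm{APD}_{90},$$

the gap between the duration of the intracellular Ca2+ transient (mechanical
systole, at the cell level) and the duration of the action potential
(electrical systole). Pure IKr blockers prolong APD90 while barely moving
CTD90, so they *shorten* the EMw; drugs that also block ICaL prolong CTD90
along with APD90 and leave the EMw roughly unchanged. EMw shortening beyond
−10% is the risk flag, alongside outright repolarisation abnormalities (RA).

The pipeline has five stages, each an exported module surface:

1. **Cell model** — the O'Hara–Rudy dynamic (ORd) human ventricular model,
   endocardial variant, with multiplicative conductance scalings (one model of
   a population) and fractional pore block (drug action):
   `simulate_paced()`, `ord_rhs()`.
2. **Biomarkers** — APD40/50/90, triangulation, dV/dtMAX, Vpeak, RMP, CTD50/90,
   the EMw, and RA/DA flags: `trace_biomarkers()`, `detect_abnormalities()`.
3. **Population** — uniform sampling of nine conductances inside published
   variability ranges, pacing to steady state, calibration against
   experimental biomarker windows: `build_population()`.
4. **Drug trials** — IC50/Hill pore block at multiples of the therapeutic
   concentration EFTPCmax, and the exhaustive IKr/ICaL/INaL block grid:
   `run_drug_trial()`, `block_scan()`.
5. **Risk scoring** — RA-only and RA + ΔEMw classification, the
   concentration-weighted TdP score, and confusion-matrix metrics:
   `classify_risk()`, `tdp_score()`, `prediction_metrics()`.

## The cell model and its numerics

The ORd endocardial model (41 state variables; ms, mV, mM) is implemented in
C++ and integrated with the hybrid scheme that is standard in cardiac
simulators: Rush–Larsen exponential updates for the Hodgkin–Huxley-type gates
(plus the relaxation-form SR-release fluxes and the `nca` fraction) and
Heun's predictor–corrector (second order) for voltage, concentrations and
CaMK. No stiff ODE library is involved — this is a deliberate design choice,
not a fallback: the scheme is unconditionally stable in the gates,
bit-reproducible, and the step size adapts to the voltage derivative so that
each step changes V by at most `dv_step` (default 0.2 mV, bounded by
`dt_min` = 0.005 ms and `dt_max` = 1 ms). The upstroke is therefore resolved
at a few microseconds per step while diastole takes millisecond steps. The
second-order treatment of the concentrations matters: plain forward Euler at
these step sizes biases CTD90 by tens of milliseconds, because the slow
Ca2+ decay is unconstrained by the voltage-based step control and the 90%
decay threshold sits on a shallow tail. With Heun, halving all three
settings moves both APD90 and CTD90 by well under 1 ms (a test asserts
< 1 ms), and a plain forward-Euler integration driven through the exported
right-hand side at a tiny fixed step agrees with the production path to a
fraction of a millivolt (another test).

The cell subtype is endocardial — the ORd default, and consistent with the
undiseased-human calibration data — with the publication's stimulus
(−80 µA/µF for 0.5 ms at each cycle start, configurable). Control pacing is
500 beats at 1 Hz from the published resting state; drug runs are 150 beats
*restarted from the model's own control steady state*, mirroring a trial in
which each cell is its own control. A reduced-beat configuration is used in
the test suite.

One consequence of the endocardial choice deserves emphasis: **the baseline
endocardial model does not develop early afterdepolarisations at 85% IKr
block at 1 Hz** in this implementation. Repolarisation merely slows, and only
at considerably stronger block does 2:1-type repolarisation failure appear;
the original model's published EAD demonstrations used the M-cell variant at
slow pacing. Populations sampled with low repolarisation reserve (high sCaL,
low sKr — see below) do develop RA at 75% IKr block and above, which is where
all population-level RA statistics in this package come from. The
corresponding single-baseline acceptance check is retained and fails
deliberately rather than being weakened.

## Biomarker conventions

All durations start at the instant of maximum upstroke velocity. APDxx ends
at the first downward crossing of `Vpeak − (xx/100)·(Vpeak − RMP)`, with RMP
the pre-stimulus voltage of the same beat and linear interpolation between
samples. CTDxx ends when the Ca2+ transient has decayed xx% of the way from
its peak back to its own pre-stimulus diastolic level — the "decay" reading
of the duration; the alternative "fraction of initial base value" reading
coincides for a symmetric return to baseline and the decay reading is the one
consistent with describing CTD90 as "90% of decay". The EMw is undefined
(NA) whenever an abnormality is flagged or either duration is invalid.

RA detection: within the window from 50 ms after the upstroke (to skip the
notch) until 90% repolarisation, a voltage derivative above +0.01 V/s
sustained for ≥ 2 ms flags an EAD; failure to reach 90% repolarisation before
the next stimulus flags repolarisation failure. A beat that already *starts*
more than 20 mV above the control resting potential is counted as RA as well:
in last-beat analysis under strong IKr block, an elevated diastolic start is
the previous beat's repolarisation failure carried across the cycle boundary
(2:1 responses), and classifying it as a depolarisation abnormality would
halve the RA fractions the block-grid statistics measure. DA is reserved for
beats that fail to excite from a normal diastolic potential (dV/dtMAX <
10 V/s — an order of magnitude below the experimental lower bound — or
Vpeak < 0 mV). All thresholds are arguments.

Percent changes (ΔEMw, ΔAPD90, ΔCTD90) always use the same model's control
as denominator; models whose control |EMw| is below 1 ms are excluded from
median ΔEMw (degenerate denominator) and reported as NA.

## The population: a stated world

The nine scaling factors are drawn independently and uniformly (Latin
hypercube optionally) inside the published variability ranges: GNa and GK1
30–200%, GNaL, GNCX and GCaL 100–200%, Gto 0–200%, GKr 45–100%, GKs 0–100%,
GNaK 30–100%. These ranges are asymmetric on purpose — repolarising currents
can only be weakened, depolarising ones only strengthened — so accepted
populations have a *weak repolarisation reserve* by construction (the tests
assert median sKr < 1 and median sCaL > 1 across accepted models), which is
what makes them informative for drug-induced RA. Candidates are accepted when
all nine control biomarkers fall inside the experimental windows (APD40
85–320 ms, APD50 110–350 ms, APD90 180–440 ms, Tri90−40 50–150 ms, dV/dtMAX
100–1000 V/s, Vpeak 10–55 mV, RMP −95 to −80 mV, CTD50 120–420 ms, CTD90
220–785 ms) with no RA/DA in control. The reference draw is 150 candidates;
acceptance fractions around 70–85% are typical, with rejections dominated by
over-long APD90/triangulation and sub-threshold upstroke velocity (low-GNa
corners). Rejected candidates stay in the object with reason codes.

## Drug model and trials

Drug action is the simple pore-block model: at concentration $C$, the
remaining conductance of a channel with half-inhibitory concentration
$IC_{50}$ and Hill coefficient $h$ is $1/(1 + (C/IC_{50})^h)$, applied
multiplicatively on top of the population scaling
($G_X \to s_X(1-b_X)G_X$). Compounds are tested at 1, 3, 10, 30 and
100× EFTPCmax. The block-grid sensitivity analysis bypasses the IC50
conversion and applies fixed fractional blocks (0/25/50/75/100% on IKr, ICaL
and INaL; 125 combinations) through the same engine
(`population_block_response()`), so drug trials and the grid cannot drift
apart numerically. Undefined cells (no computable EMw anywhere, e.g. full
ICaL block abolishing the Ca2+ transient) are explicit NAs, never dropped
rows.

## Risk calls and the TdP score

At a given multiple, "RA only" calls a drug risky if ≥ 1 model shows RA;
"RA + ΔEMw" is the *disjunction* of RA occurrence and median ΔEMw < −10%
(strict inequality: a median of exactly −10% is safe). Drugs with RA in more
than 97% of models have no meaningful EMw median (three computable models or
fewer) and are risky by construction. A pure-threshold "EMw only" mode exists
for ablation. The disjunction reading was chosen because the combined
criterion is described as an extension of the RA criterion and because
saturated-RA compounds must remain classifiable; the threshold-only ablation
lets a user quantify how much the disjunction matters.

The concentration-weighted score integrates the five multiples:

$$\mathrm{score} = \frac{\sum_i w_i\,(nRA_i + nEMw_i)}{n_{tot} \sum_i w_i},
  \qquad w_i = \frac{EFTPC_{max}}{C_i},$$

bounded in [0, 1], monotone in every count, invariant to rescaling all
weights, and never smaller than the RA-only score on the same trial (all
asserted as properties). Truth labels map known/possible/conditional clinical
risk to "risky" and reviewed-but-not-classified or unlisted compounds to
"safe"; sensitivity, specificity, accuracy, PPV and NPV recompute exactly
from the integer confusion counts. Display of ΔEMw distributions uses the
log-modulus transform $L(x) = \mathrm{sign}(x)\log_{10}(|x|+1)$ (base 10 —
the transform's conventional form; the source material leaves the base
unstated).

## What the synthetic compendium does and does not emulate

Real IC50/Hill compendia are proprietary. `make_compendium()` generates
records with the same long-CSV schema from five pharmacological archetypes,
with potencies fixed by design (h = 1, EFTPCmax = 1 µM, seeded ±10% IC50
jitter):

| archetype | channels (IC50/EFTPCmax) | rationale |
|---|---|---|
| `pure_hERG` | IKr: 1 | 50% block at 1×, 91% at 10× — a potent selective hERG blocker |
| `hERG_plus_CaL` | IKr: 9, ICaL: 4.5 | calibrated to ~25% IKr / ~40% ICaL block at 3×, the verapamil-like balance |
| `NaL_mitigated` | IKr: 2, INaL: 2 | hERG block with late-Na mitigation of APD prolongation |
| `Na_dominant` | INa: 10 | fast-Na block, labelled safe; at high multiples Na⁺ unloading shortens CTD90 and the EMw criterion flags it — the biomarker's classic false-positive mode (mexiletine-like) |
| `inert` | — | no-block control |

These reproduce the *qualitative* contrasts — hERG-driven compounds risky,
inert/Na-dominant safe, ICaL co-block attenuating the EMw signal — robustly
on desk-scale populations. They are not the 40 reference compounds: green
end-to-end tests establish that the pipeline separates the archetypes, not
that it reproduces any published per-compound call. A user holding a real
compendium loads it through `read_compendium()` and obtains the full
per-compound workflow unchanged.

## Known limitations

* Pore block is conformation-blind: no state-dependent or trafficking-level
  hERG pharmacology, so open-state-trapped blockers (mexiletine-like) will
  overestimate IKr block.
* The EMw surrogate sees only electrophysiology. Positive inotropes acting
  through cAMP or myofilament Ca2+ affinity shorten the in vivo EMw without
  touching ion currents and are outside this model class.
* Single endocardial cell at 1 Hz only: no transmural heterogeneity, rate
  dependence, or tissue-level QT/pressure read-outs.
* The baseline endocardial model's resistance to EADs at 85% IKr block
  (above) means single-model RA screening is insensitive; RA statistics
  should always be read at the population level here.
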