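# emwtrials

Human in silico drug trials for cardiac safety pharmacology, built around the
cellular **electromechanical window**

> EMw = CTD90 − APD90,

the difference between the durations of the intracellular Ca²⁺ transient and
of the action potential at 90%. Pure hERG (IKr) blockers prolong APD90 with
little effect on CTD90 and therefore *shorten* the EMw; multichannel
compounds that also block the L-type Ca²⁺ current prolong both and leave the
EMw nearly unchanged. Drug-induced EMw shortening beyond −10%, together with
outright repolarisation abnormalities (RA), is the Torsade-de-Pointes risk
flag this package computes.

The package is aimed at safety pharmacologists and cardiac modellers who
have per-channel IC50/Hill data for a compound set and want
population-of-models risk predictions at therapeutic-concentration multiples.
It implements:

* the O'Hara–Rudy dynamic human ventricular model (endocardial variant) in
  C++ with conductance scaling and fractional pore block
  (`simulate_paced()`, `ord_rhs()`);
* AP and Ca²⁺-transient biomarker extraction, EMw, and automatic RA/DA
  detection (`trace_biomarkers()`, `detect_abnormalities()`);
* experimentally calibrated control populations: nine conductances sampled
  uniformly in published variability ranges, paced 500 beats at 1 Hz,
  filtered against experimental biomarker windows (`build_population()`);
* IC50/Hill pore-block drug trials at 1–100× EFTPCmax with per-model control
  restarts (`run_drug_trial()`), and the exhaustive IKr/ICaL/INaL block-grid
  sensitivity analysis (`block_scan()`);
* TdP risk classification ("RA only" and "RA + ΔEMw"), the
  concentration-weighted TdP score
  `score = Σᵢ wᵢ(nRAᵢ + nEMwᵢ) / (n_tot Σᵢ wᵢ)` with `wᵢ = EFTPCmax/Cᵢ`,
  and confusion-matrix metrics (`classify_risk()`, `tdp_score()`,
  `prediction_metrics()`);
* a synthetic compendium generator emulating the standard IC50 table schema
  and its pharmacological archetypes (`make_compendium()`), so the whole
  pipeline is testable without proprietary data.

## Worked example

```r
library(emwtrials)

## baseline model: pace to steady state, score the final beat
ctrl <- simulate_paced(protocol = stimulus_protocol(beats = 500))
bm0  <- trace_biomarkers(ctrl)
round(bm0[, c("APD90", "CTD90", "EMw")], 1)
#>   APD90 CTD90   EMw
#> 1 268.7 572.5 303.8

## 50% IKr block, 150 beats restarted from the control steady state
drugged <- simulate_paced(blocks = block_fractions(IKr = 0.5),
                          protocol = stimulus_protocol(beats = 150),
                          init = ctrl$final_state)
bm1 <- trace_biomarkers(drugged, control_rmp = bm0$RMP)
round(100 * (bm1$APD90 - bm0$APD90) / bm0$APD90, 1)   # % APD90 prolongation
#> [1] 43.6
round(100 * (bm1$EMw - bm0$EMw) / bm0$EMw, 1)         # % EMw change
#> [1] -38
```

The baseline beat's APD90 is 268.7 ms against a 572.5-ms Ca²⁺ transient, an
EMw of ~304 ms. A pure IKr block prolongs APD90 by +43.6% while CTD90 moves
only +0.3%, so the EMw shortens by more than a third — the signature the
risk criteria are built on. A population workflow looks like:

```r
pop  <- build_population(n = 150, seed = 1)        # ~5 min; ~70-85% accepted
acc  <- accepted_models(pop)
drug <- make_compendium(seed = 1)[["pure_hERG_1"]] # or read_compendium(csv)
trial <- run_drug_trial(acc, drug)                 # 1,3,10,30,100x EFTPCmax
classify_risk(trial, "RA_plus_EMw", multiple = 10)
trial_tdp_score(trial)
```

## Acceptance script

`scripts/acceptance.R` recomputes the pipeline's headline quantities from
scratch with the installed package: it paces the baseline model and measures
the APD90 prolongation under 50% IKr block; samples and calibrates a
150-candidate control population (500-beat pre-pacing) and reports the
acceptance percentage and the Pearson correlations of control EMw with APD90
and CTD90; and applies the 50%/50% IKr/ICaL and 75%/25% block-grid cells to
every accepted model (150 drugged beats each), reporting the median ΔEMw and
ΔAPD90 and the RA fraction. Run it from the repository root:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

It takes roughly ten minutes on one CPU and writes one JSON object with one
`{value, n}` entry per quantity.

## Layout

```
R/            module surfaces: cell model, biomarkers, population,
              drug trials, risk scoring, synthetic data, io/config
src/          ORd equations + Rush-Larsen adaptive integrator (Rcpp)
tests/        testthat suite, including end-to-end acceptance checks
vignettes/    methods vignette: model, conventions, numerics, limitations
scripts/      acceptance.R (see above)
```
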