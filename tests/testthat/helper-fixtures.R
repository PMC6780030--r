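# Shared, lazily built fixtures. Simulated objects are cached for the test
# run so the expensive ones (steady-state pacing, population calibration) are
# computed once and reused across files.

.cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.cache[[key]])) .cache[[key]] <- force(expr)
  .cache[[key]]
}

# reduced-accuracy solver for tests where sub-ms biomarker precision is not
# under scrutiny (roughly 2x faster than the default settings)
fast_solver <- function() solver_settings(dt_min = 0.01, dt_max = 2, dv_step = 0.4)

# baseline endocardial model paced close to steady state (reduced pre-pacing)
baseline_control <- function() {
  cached("baseline_control",
         simulate_paced(protocol = stimulus_protocol(beats = 300)))
}

baseline_biomarkers <- function() {
  cached("baseline_biomarkers", trace_biomarkers(baseline_control()))
}

# an accepted-range model with deliberately weak repolarisation reserve,
# paced to approximate steady state: the EAD substrate used by the
# abnormality-detection tests
ead_prone_model <- function() {
  cached("ead_prone_model", {
    s <- ionic_scalings(sKr = 0.5, sCaL = 2.0, sNCX = 2.0, sNaL = 2.0,
                        sNaK = 0.5)
    tr <- simulate_paced(scalings = s,
                         protocol = stimulus_protocol(beats = 200),
                         solver = fast_solver())
    list(scalings = s, control = tr, biomarkers = trace_biomarkers(tr))
  })
}

# the shared calibrated population: 150 candidates paced to steady state with
# the reference 500-beat control protocol, default ranges and windows,
# fixed seed
shared_population <- function() {
  cached("shared_population",
         build_population(n = 150,
                          protocol = stimulus_protocol(beats = 500),
                          seed = 20190904))
}

# deterministic subsample of accepted models, for the drug-trial and
# block-grid tests (desk-scale population)
population_subset <- function(n_models = 30) {
  pop <- accepted_models(shared_population())
  n <- length(pop$accepted)
  keep <- seq_len(min(n_models, n))
  structure(list(scalings = pop$scalings[keep, , drop = FALSE],
                 biomarkers = pop$biomarkers[keep, , drop = FALSE],
                 states = pop$states[keep, , drop = FALSE],
                 accepted = pop$accepted[keep],
                 reject_reason = pop$reject_reason[keep],
                 provenance = pop$provenance),
            class = "ap_population")
}

# a small calibrated population for cheap end-to-end runs
tiny_population <- function() {
  cached("tiny_population", population_subset(10))
}
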