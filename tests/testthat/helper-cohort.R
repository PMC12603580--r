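# shared fixture builders for the test suite

# small synthetic cohort; proportions default to term-only for trend tests
small_cohort <- function(n = 80L, seed = 101L,
                         proportions = c(term = 1, preterm = 0, loss = 0),
                         ...) {
  generate_cohort(cohort_config(n_pregnancies = n,
                                outcome_proportions = proportions,
                                seed = seed, ...))
}

# a noise-free cohort: deterministic trajectories (tiny SDs keep z-scores
# defined), every day recorded, every sleep episode nocturnal
noiseless_cohort <- function(n = 5L, seed = 1L,
                             proportions = c(term = 1, preterm = 0, loss = 0)) {
  sds <- function(v) stats::setNames(rep(v, length(gravida:::.generated_metrics)),
                                     gravida:::.generated_metrics)
  generate_cohort(cohort_config(n_pregnancies = n,
                                outcome_proportions = proportions,
                                missing_day_rate = 0, nap_rate = 0,
                                random_intercept_sd = sds(1e-9),
                                residual_sd = sds(1e-9),
                                seed = seed))
}

# minimal profiles table for timeline/preprocess fixtures
make_profiles <- function(ids, lmp, due = as.Date(NA), end,
                          outcome = "term") {
  data.frame(participant_id = ids, age = 32, height_m = 1.65, weight_kg = 65,
             lmp_date = as.Date(lmp), due_date = as.Date(due),
             end_date = as.Date(end), outcome = outcome,
             stringsAsFactors = FALSE)
}
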