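# Shared fixtures, built in code at load time. Sizes are kept small; the
# full-scale study geometry is exercised in the acceptance tests.

fixture_env <- new.env()

small_world <- function(n_resp = 40, seed = 11, model = "I") {
  key <- paste(n_resp, seed, model, sep = "_")
  if (is.null(fixture_env[[key]])) {
    plan <- generate_omep(seed = seed)
    coh <- simulate_respondents(n_resp, seed = seed)
    truth <- finnish_carer_estimates(model)
    choices <- simulate_dataset(coh, plan, truth, seed = seed)
    fixture_env[[key]] <- list(plan = plan, cohort = coh, truth = truth,
                               choices = choices)
  }
  fixture_env[[key]]
}

# one exploded task with known picks, for occasion-level checks
one_task <- function(profile = c(1, 4, 2, 3, 1, 4, 2),
                     picks = c(1, 2, 5, 6), display_order = 1:7) {
  explode_task(profile, picks, display_order)
}

# the published normalised column of the final model (Table-style published
# values, used as frozen expectations)
published_normalized <- function() {
  c(occu1 = 0.976, occu2 = 0.971, occu3 = 0.463, occu4 = 0.088,
    cont1 = 1.000, cont2 = 0.941, cont3 = 0.467, cont4 = 0.000,
    perc1 = 0.802, perc2 = 0.810, perc3 = 0.272, perc4 = 0.185,
    safe1 = 0.770, safe2 = 0.490, safe3 = 0.236, safe4 = 0.177,
    soci1 = 0.803, soci2 = 0.710, soci3 = 0.461, soci4 = 0.196,
    spac1 = 0.968, spac2 = 0.917, spac3 = 0.445, spac4 = 0.083,
    supp1 = 0.776, supp2 = 0.775, supp3 = 0.469, supp4 = 0.232)
}

# the published preference-based index values (perc1/perc2 switch applied)
published_index <- function() {
  list(
    OCCU = c(0.163, 0.162, 0.063, -0.010),
    CONT = c(0.168, 0.156, 0.064, -0.027),
    PERC = c(0.131, 0.129, 0.026, 0.009),
    SAFE = c(0.123, 0.069, 0.019, 0.008),
    SOCI = c(0.129, 0.111, 0.063, 0.011),
    SPAC = c(0.162, 0.152, 0.060, -0.011),
    SUPP = c(0.124, 0.124, 0.065, 0.018)
  )
}

# the published normalised values with the perc1/perc2 switch applied
published_normalized_switched <- function() {
  x <- published_normalized()
  x[c("perc1", "perc2")] <- x[c("perc2", "perc1")]
  x
}
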