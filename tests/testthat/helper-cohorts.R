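# Builders for small in-code fixtures.

# Noiseless cohort on a fixed nonnegative day design.
make_noiseless_cohort <- function(lam = log(2) / 8, c = 0.3,
                                  Bis = c(5, 10, 15, 20, 25),
                                  days = c(0, 7, 30, 86),
                                  endpoint = "SUVMAX") {
  obs <- do.call(rbind, lapply(seq_along(Bis), function(i) {
    data.frame(patient_id = sprintf("P%02d", i), day = days,
               endpoint = endpoint,
               value = model_value(lam, c, Bis[i], days),
               stringsAsFactors = FALSE)
  }))
  adjust_cohort(as_observation_table(obs, provenance = "noiseless fixture"))
}

# Same design with additive Gaussian noise (fixed seed responsibility of the
# caller).
make_noisy_cohort <- function(lam = log(2) / 8, c = 0.3,
                              Bis = c(5, 10, 15, 20, 25),
                              days = c(0, 7, 30, 86),
                              sd = 0.5, endpoint = "SUVMAX") {
  tab <- make_noiseless_cohort(lam, c, Bis, days, endpoint)
  tab$value <- pmax(tab$value + rnorm(nrow(tab), 0, sd), 0)
  tab
}

# Write a small CSV fixture and return its path.
write_csv_fixture <- function(lines) {
  path <- tempfile(fileext = ".csv")
  writeLines(lines, path)
  path
}
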