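# Shared fixtures built in code.

# Noiseless calibrator table on the line ratio = slope * conc + intercept.
exact_calibrators <- function(slope = 0.01, intercept = 0,
                              levels = c(5, 10, 50, 250, 750, 1000)) {
  data.frame(nominal_concentration = levels,
             area_ratio = slope * levels + intercept)
}

# The worked three-point profile: exact monoexponential with a 60-min
# half-life sampled at 120/180/240 min, i.e. C0' = 800 mg/L.
worked_profile <- function() {
  list(t = c(120, 180, 240), conc = c(200, 100, 50),
       dose = 5 * 647.1,
       beta = log(2) / 60, c0 = 800)
}

# A complete in-memory test order for compute_mgfr.
make_order <- function(patient_id = "P1", dose_mg = 3235.5, bsa = 1.73,
                       elapsed_min = c(120, 180, 240),
                       t0 = as.POSIXct("2024-03-01 08:00:00", tz = "UTC")) {
  list(patient_id = patient_id, dose_mg = dose_mg, bsa_m2 = bsa,
       injection_time = t0, draw_times = t0 + elapsed_min * 60)
}

# Write a study to temp CSVs; returns the three paths.
write_study_files <- function(study, dir = tempfile("study-")) {
  dir.create(dir)
  paths <- list(batch = file.path(dir, "batch.csv"),
                orders = file.path(dir, "orders.csv"),
                results = file.path(dir, "results.csv"))
  write_instrument_csv(study$batch, paths$batch)
  utils::write.csv(study$orders, paths$orders, row.names = FALSE, na = "")
  paths
}
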