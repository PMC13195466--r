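# Shared fixtures, built once per test run and memoised.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# The default study conditions: 30x30 grid at 12 km, 120 days across 2021.
default_study <- function() memo("default", function() synthetic_study(seed = 1))

# A desk-scale study for fast unit tests.
small_study <- function() memo("small", function() {
  synthetic_study(seed = 7, n_rows = 12, n_cols = 12,
                  dates = seq(as.Date("2021-01-05"), as.Date("2021-12-20"), by = 6),
                  mean_daily_events = 4,
                  n_total = 12, n_speciation = 4, n_near_road = 1)
})

# Noise-free study whose "model" is the truth itself (unit biases, no
# displacement): fusion identity fixtures.
exact_study <- function() memo("exact", function() {
  synthetic_study(seed = 11, n_rows = 12, n_cols = 12,
                  dates = seq(as.Date("2021-01-05"), as.Date("2021-12-20"), by = 6),
                  mean_daily_events = 4, noise_sd = 0,
                  model_bias = c(PM25_TOT = 1, EC = 1, OC = 1, NO3 = 1,
                                 SO4 = 1, OTHER = 1),
                  model_wind_shift_km = c(0, 0), model_day_error_sd = 0,
                  n_total = 12, n_speciation = 4, n_near_road = 1)
})

events_df <- function(date, row = 1L, col = 1L, area = 10,
                      source = "truth", burn_type = "prescribed",
                      ownership = "private", ...) {
  data.frame(date = as.Date(date), row = row, col = col, area = area,
             source = source, burn_type = burn_type, ownership = ownership,
             ..., stringsAsFactors = FALSE)
}

rel_diff <- function(a, b) max(abs(a - b)) / max(abs(b), 1e-12)

with_seed_local <- function(seed, expr) pfsmoke:::with_seed(seed, expr)
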