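# shared fixtures and comparison helpers

tab1 <- kinetic_params()
pop1L <- population_model(vout = 1)

per_ml <- function(x) x * 1e3  # cells/mL -> cells/L

rel_dev <- function(a, b) abs(a - b) / abs(b)

# round to the precision a printed value carries
round_nM1 <- function(x_M) round(x_M * 1e9, 1)   # nM, one decimal
round_nM <- function(x_M) round(x_M * 1e9)       # nM, nearest integer

# minimal hand-built single-strain trajectory for metric unit tests
fake_trajectory <- function(times, internal, external = internal * 0,
                            label = "s") {
  df <- data.frame(time_s = times, h2o2_out_M = external)
  df[[paste0("h2o2_in_M.", label)]] <- internal
  df[[paste0("superoxide_M.", label)]] <- 0
  df[[paste0("density_per_L.", label)]] <- 1e10
  structure(df, class = c("ros_trajectory", "data.frame"),
            strain_labels = label,
            meta = list(scenario = "fake", rtol = NA, atol = NA,
                        quasi_steady = NA))
}

stress_step <- function(amount, time = 0) data.frame(time = time,
                                                     amount = amount)
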