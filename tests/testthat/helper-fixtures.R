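# Shared fixtures: tiny cohorts/protocols built in code at test time.

tiny_config <- function(cohort = "mouse", n_subjects = 2, slices = 10,
                        seed = 42L, ...) {
  msti_cohort_config(cohort, n_subjects = n_subjects,
                     slices_per_thrombus = slices, seed = seed, ...)
}

default_tis <- function() exp(seq(log(100), log(5000), length.out = 8))

# Noiseless simulated subject with maps fitted inside the thrombus.
noiseless_subject <- function(cohort = "mouse", group = "lysed", seed = 42L,
                              slices = 10) {
  cc <- tiny_config(cohort, slices = slices, seed = seed)
  sub <- simulate_subject(cc, group, 1, msti_protocol(), noiseless = TRUE)
  maps <- suppressMessages(compute_maps(sub$stack, sub$mask_thrombus))
  list(sub = sub, maps = maps, truth = sub$truth_table)
}

# Ideal-inversion IR signal (B/A = 2, magnitude).
ir_signal <- function(ti, t1, A = 1000) abs(A - 2 * A * exp(-ti / t1))
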