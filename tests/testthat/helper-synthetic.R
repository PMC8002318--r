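# Shared fixtures, built in code.

# Parameter set fitted on the 2015 pilot-scale dataset, with b4 re-solved so
# the seconds constraint holds exactly (printed values are rounded to two
# decimals) and b6 = b3 + b4.
kumar2015_truth <- function() {
  b2 <- 0.99; b3 <- 0.65
  b4 <- 1 + b2 - b3
  model_parameters(0.33, b2, b3, b4, 5.35, b3 + b4)
}

# Random-uniform synthetic table in the pilot-scale factor ranges, simulated
# from given true parameters with multiplicative lognormal noise.
make_synthetic_table <- function(n = 60, seed = 11, cv = 0,
                                 truth = kumar2015_truth()) {
  spec <- preset_dataset("kumar2015-like", n_runs = n, seed = seed)
  simulate_observations(generate_doe(spec), truth,
                        noise_spec(mrt_cv = cv, var_cv = cv, seed = seed + 1))
}

# Small gridded design for main-effects style checks.
make_grid_table <- function(truth = kumar2015_truth(), cv = 0, seed = 21) {
  spec <- doe_spec(fr_kg_h = c(10, 25), rpm = c(500, 900), ls_pct = 11.5,
                   nk = c(2, 6, 12), sa_deg = c(30, 60, 90),
                   design = "full-factorial", seed = seed)
  simulate_observations(generate_doe(spec), truth,
                        noise_spec(mrt_cv = cv, var_cv = cv, seed = seed))
}

default_geom <- function() screw_geometry(0.0125, 0.00625, 0.025, 0.3, 0.001)
default_config <- function() screw_configuration(6, 3, 2, 60)
default_cond <- function() process_condition(10, 600, 0.115, 600, 1000)
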