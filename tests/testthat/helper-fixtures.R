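# Shared fixtures: all test data are generated in code.

# A minimal hand-built plate: 4 solvent controls plus treated wells with
# exactly known signals, for arithmetic identities.
tiny_plate <- function(red_trt = c(1000, 500, 0),
                       dose_trt = c(1e-6, 2e-6, 4e-6)) {
  n <- length(red_trt)
  ctrl <- data.frame(
    plate_id = "p1", well_id = paste0("A", 1:4), treatment_id = "DMSO",
    treatment_kind = "solvent_control", dose = 0, dose_unit = "none",
    red_signal = 1000, green_signal = 500, cell_count = 10000,
    luminescence = 4000, run_id = "run1", stringsAsFactors = FALSE)
  trt <- data.frame(
    plate_id = "p1", well_id = paste0("B", seq_len(n)), treatment_id = "chemX",
    treatment_kind = "chemical", dose = dose_trt, dose_unit = "M",
    red_signal = red_trt, green_signal = 500, cell_count = 10000,
    luminescence = 4000, run_id = "run1", stringsAsFactors = FALSE)
  rbind(ctrl, trt)
}

# Construct a log-logistic fit object directly from known parameters
# (bypasses fitting; used to test inversion and masking rules).
manual_fit <- function(top, ec50, hill, bottom = 0, endpoint = "mmp",
                       active = TRUE, effect_conc = NA_real_) {
  structure(list(treatment_id = "manual", endpoint = endpoint,
                 model = "loglogistic4",
                 params = c(bottom = bottom, top = top, ec50 = ec50,
                            hill = hill),
                 effect_conc = effect_conc, active = active,
                 reason = NA_character_,
                 mask_info = list(excluded_doses = numeric(0),
                                  reason = NA_character_),
                 n_points = 0L, runs_used = 0L, converged = TRUE,
                 sse = 0), class = "mitotox_fit")
}

# Noise-free variants for exact-recovery checks.
no_noise <- function() noise_model(signal_cv = 0, count_dispersion = 0)

# Simulate one chemical and fit one endpoint, returning the fit.
fit_endpoint <- function(chem, endpoint = "mmp", noise = noise_model(),
                         seed = 1, design = plate_design()) {
  wells <- simulate_plate(list(chem), design, noise, seed = seed)
  m <- quantify_plate(wells)
  fit_loglogistic(m[m$endpoint == endpoint & m$dose > 0, ],
                  treatment_id = chem$chem_id, endpoint = endpoint)
}
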