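# shared fixture builders; everything is generated in code, no stored data

# instrument config for standard runs: 0.3 counts/pM, baseline 100 counts
std_config <- function(k = 0.0282, noise_sd = 0, duration_s = 120,
                       seed = NA_integer_) {
  sim_config(decay_k = k, noise_sd = noise_sd, duration_s = duration_s,
             sampling_rate_hz = 0.5, sensitivity = 0.3,
             baseline_counts = 100, seed = seed)
}

# a four-phase field session plan: reagent blank, seawater background,
# coral surface, SOD check; production chosen so P/k gives the target
# steady-state concentrations
field_plan <- function(k, sw_nM = 5, coral_nM = 125, phase_s = 1200) {
  data.frame(
    label = c("reagent_blank", "background_sw_surface", "coral_surface",
              "sod_check"),
    duration_s = c(phase_s, phase_s, phase_s, phase_s / 2),
    production_nM_s = c(0, sw_nM * k, coral_nM * k, coral_nM * k))
}

# noiseless calibration built from simulated standard runs, as a user would:
# run each secondary standard, fit its decay, extrapolate back to injection
simulated_calibration <- function(cfg, concs = c(3, 8, 15, 25, 38),
                                  blanks = c(-0.08, 0, 0.08)) {
  pts <- do.call(rbind, lapply(concs, function(cc) {
    tr <- simulate_standard_run(cc, cfg$decay_k, cfg,
                                baseline_duration_s = 60)
    t0 <- tr$metadata$injection_time_s
    fit <- fit_decay(tr, t0 + 2, t0 + 60, baseline = cfg$baseline_counts)
    calibration_point(cc, extrapolate_luminescence(fit, t0, t0 + 2),
                      extrapolation_time_s = 2)
  }))
  build_calibration(pts, blanks, matrix_k = cfg$decay_k)
}

# brute-force ANOSIM oracle: recompute R from first principles for every
# way of assigning n1 samples to group 1 (two-group designs only)
anosim_exhaustive_oracle <- function(d, labels) {
  d <- as.matrix(d)
  n <- nrow(d)
  stopifnot(length(unique(labels)) == 2)
  g1 <- unique(labels)[1]
  n1 <- sum(labels == g1)
  lower <- lower.tri(d)
  rk <- rank(d[lower])
  ri <- row(d)[lower]; rj <- col(d)[lower]
  stat_for <- function(members1) {
    in1 <- seq_len(n) %in% members1
    w <- in1[ri] == in1[rj]
    (mean(rk[!w]) - mean(rk[w])) / (n * (n - 1) / 4)
  }
  sets <- utils::combn(n, n1)
  all_R <- apply(sets, 2, stat_for)
  obs <- stat_for(which(labels == g1))
  list(R = obs, p = mean(all_R >= obs - 1e-12), all_R = all_R)
}
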