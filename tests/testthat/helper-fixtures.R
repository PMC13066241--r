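# Shared fixtures, built in code at test time.

quick_config <- function(...) {
  cfg <- default_config()
  mods <- list(...)
  for (nm in names(mods)) cfg[[nm]] <- utils::modifyList(cfg[[nm]], mods[[nm]])
  cfg
}

# minimal hand-built trial result for closed-form outcome-measure tests
fake_result <- function(n = 101, a_sim = 0, a_ref = 0, stance_frac = 0.6,
                        markers_foot = NULL, markers_shank = NULL,
                        res_force = NULL, reserve = NULL, grf_peak = 800) {
  time <- seq(0, 1, length.out = n)
  zero <- matrix(0, n, 3, dimnames = list(NULL, c("x", "y", "z")))
  grf <- ifelse(time <= stance_frac, grf_peak * sin(pi * time / stance_frac), 0)
  structure(list(
    time = time, phase = 100 * time,
    q = matrix(0, n, 6), qdot = matrix(0, n, 6),
    act = cbind(pf = rep_len(a_sim, n), df = 0),
    a_cmd = matrix(0, n, 2),
    a_ref = rep_len(a_ref, n),
    tau_req = numeric(n), tau_muscle = numeric(n),
    reserve = if (is.null(reserve)) numeric(n) else rep_len(reserve, n),
    support = numeric(n), saturated = logical(n),
    grf_v = grf,
    res_force = if (is.null(res_force)) zero else res_force,
    markers = list(foot = if (is.null(markers_foot)) zero else markers_foot,
                   shank = if (is.null(markers_shank)) zero else markers_shank),
    elements = NULL, failure = NULL,
    meta = list(level = "PF25", speed = "slow", direction = "zero",
                seed = 1L, grf_peak = grf_peak, T = 1,
                stance_fraction = stance_frac, config_hash = "x")),
    class = "afo_trial_result")
}
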