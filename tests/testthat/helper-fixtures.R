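# Shared fixtures: small parameter bundles used across test files.

# threshold-linear channel with hand-set small weights, no noise
tl_params <- function(noise_sd = 0, w_self = 0.4, w_inh = 0.3,
                      g_d = 1, g_i = 1, dt = 1, tau = 50) {
  channel_params(tau = tau, w_self = w_self, w_inh = w_inh,
                 g_d = g_d, g_i = g_i,
                 activation = activation_threshold_linear(),
                 noise_sd = noise_sd, dt = dt)
}

# the bistable logistic channel used for attractor and go/no-go behaviour
bi <- channel_preset("bistable")

# quick decision parameters with a short deadline for cheap tests
quick_dp <- function(deadline = 800, threshold = 1, t0 = 100)
  decision_params(threshold = threshold, deadline = deadline,
                  evidence_gain = 0.005, t0 = t0)

# build a synthetic trajectory object without running the integrator
synthetic_trajectory <- function(times, d_rate, i_rate, seed = 0L) {
  structure(list(times = times, d_rate = d_rate, i_rate = i_rate,
                 seed = as.integer(seed), params_fingerprint = "synthetic"),
            class = "bg_trajectory")
}

# hand-built go/no-go trial set (bypasses the simulator)
new_trials_for_test <- function(rt, labels) {
  df <- data.frame(trial = seq_along(rt), condition = "hand", label = labels,
                   rt_ms = rt, crossed = labels == "go",
                   seed = seq_along(rt), stringsAsFactors = FALSE)
  bgcompete:::new_bg_trials(df, params_fingerprint = "hand", base_seed = 0L,
                            kind = "gonogo")
}

# input pair with a given direct:indirect ratio at fixed total drive
ratio_input <- function(ratio, total = 1.2, I_m = 0, I_lambda = 0) {
  channel_input(I_d = total * ratio / (1 + ratio),
                I_i = total / (1 + ratio), I_m = I_m, I_lambda = I_lambda)
}
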