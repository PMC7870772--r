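# shared fixtures, built in code at test time

# a small behavioural cohort (deterministic)
small_cohort <- function(P = 8, n_pc = 20, seed = 42, dt = 1e-3, ...) {
  cfg <- sim_config(n_participants = P, n_trials_per_condition = n_pc,
                    seed = seed, ...)
  gen_behavior(cfg, dt = dt)
}

# triangular waveform on a ms grid
triangle_wave <- function(t_ms, peak_t, rise_from, fall_to, peak = 10) {
  ifelse(t_ms < rise_from | t_ms > fall_to, 0,
         ifelse(t_ms <= peak_t,
                peak * (t_ms - rise_from) / (peak_t - rise_from),
                peak * (fall_to - t_ms) / (fall_to - peak_t)))
}

# minimal epochs object wrapping a given trials x electrodes x samples array
toy_epochs <- function(data, sample_rate = 500, t0_ms = -600,
                       locked = "response") {
  E <- dim(data)[2]
  layout <- make_net_layout(E)
  step <- 1000 / sample_rate
  eeg_epochs(data,
             time_ms = seq(t0_ms, by = step, length.out = dim(data)[3]),
             channel_names = layout$channel_names,
             neighbours = layout$neighbours, sample_rate = sample_rate,
             positions = layout$positions, perimeter = layout$perimeter,
             locked = locked)
}

# cosine similarity up to sign
cosim <- function(a, b) abs(sum(a * b)) / sqrt(sum(a^2) * sum(b^2))
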