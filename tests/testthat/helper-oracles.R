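# Independent oracles and small fixture builders used across tests.

# analytic-signal (Hilbert) envelope via the frequency domain; an
# independent, non-causal reference for the lock-in amplitude estimates
hilbert_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# mean ERD of a trace over [from, to] seconds
steady_mean <- function(tr, from, to) {
  mean(tr$erd[tr$time >= from & tr$time <= to])
}

# one rest + one task block with a noiseless amplitude-scaled carrier
noiseless_fixture <- function(depth, foi = 11, rest = 8, task = 8,
                              rate = 1000, phase = 0) {
  sch <- block_schedule(1, rest = rest, task = task)
  synth_eeg(synth_eeg_config(sch, rate = rate, foi = foi, erd_depth = depth,
                             noise = "none", phase = phase))
}
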