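# Independent oracles and small fixtures used across the suite.

# Small, fast design for simulation-heavy tests.
small_design <- function(fs = 256, sweeps = 20, ...) {
  acc_design(fs = fs, sweeps = sweeps, ...)
}

quiet_profile <- function(...) {
  participant_profile(latency_jitter_ms = 0, artifact_rate = 0, ...)
}

cond1 <- function(snr = 15, rep = 1) {
  list(frequency_hz = 1000, snr_db = snr, repetition = rep)
}

# Literal re-statement of the threshold rule, written as a direct scan so it
# can serve as an independent check of estimate_threshold(): threshold = the
# lowest level L with outcome present at L, present at L+step (when that
# level exists and is classifiable), and absent at L-step (same proviso).
brute_force_threshold <- function(outcomes, grid, step = 3) {
  grid <- sort(grid)
  at <- function(l) {
    if (!l %in% grid) return(NA_character_)
    outcomes[match(l, grid)]
  }
  classifiable <- function(s) !is.na(s) && s %in% c("present", "absent")
  for (l in grid) {
    s0 <- at(l)
    if (!classifiable(s0) || s0 != "present") next
    up <- at(l + step)
    if (classifiable(up) && up != "present") next
    dn <- at(l - step)
    if (classifiable(dn) && dn != "absent") next
    return(l)
  }
  NA_real_
}

# Stationary mean level of the staircase Markov chain for a listener with
# psychometric function p(level). States are (level, consecutive-correct);
# levels live on a lattice of gcd(up, down) around the threshold.
staircase_equilibrium <- function(p_fun, down = 4, up = 2,
                                  lo = -30, hi = 30) {
  g <- gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)
  step <- g(down, up)
  levels <- seq(lo, hi, by = step)
  nl <- length(levels)
  idx <- function(level, cc) (cc * nl) + match(level, levels)
  P <- matrix(0, 2 * nl, 2 * nl)
  clamp <- function(l) min(max(l, lo), hi)
  for (i in seq_len(nl)) {
    l <- levels[i]
    p <- p_fun(l)
    # cc = 0: correct -> (l, 1); incorrect -> (l + up, 0)
    P[idx(l, 0), idx(l, 1)] <- P[idx(l, 0), idx(l, 1)] + p
    P[idx(l, 0), idx(clamp(l + up), 0)] <- P[idx(l, 0), idx(clamp(l + up), 0)] + 1 - p
    # cc = 1: correct -> (l - down, 0); incorrect -> (l + up, 0)
    P[idx(l, 1), idx(clamp(l - down), 0)] <- P[idx(l, 1), idx(clamp(l - down), 0)] + p
    P[idx(l, 1), idx(clamp(l + up), 0)] <- P[idx(l, 1), idx(clamp(l + up), 0)] + 1 - p
  }
  e <- eigen(t(P))
  v <- Re(e$vectors[, which.min(abs(e$values - 1))])
  pi_s <- v / sum(v)
  occupancy <- pi_s[seq_len(nl)] + pi_s[nl + seq_len(nl)]
  sum(levels * occupancy)
}
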