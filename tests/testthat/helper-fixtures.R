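# Shared fixtures, built in code at test time.

# A small clean panel with exact conservation (no artifacts).
make_clean_panel <- function(days = 400, seed = 42) {
  cfg <- hospital_config(days = days, lag_mean = 20)
  simulate_hospital(cfg, seed = seed)$series
}

# Exhaustive-enumeration oracle for the runs-test tail probabilities:
# every arrangement of n1 'above' among n positions, equally likely.
runs_enum_oracle <- function(n1, n2, r_obs) {
  n <- n1 + n2
  pos <- utils::combn(n, n1)
  counts <- apply(pos, 2, function(idx) {
    s <- rep(-1L, n); s[idx] <- 1L
    length(rle(s)$lengths)
  })
  c(p_lower = mean(counts <= r_obs), p_upper = mean(counts >= r_obs))
}
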