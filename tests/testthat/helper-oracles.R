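## Independent brute-force oracles shared across test files.

oracle_bar_row <- function(y, t, p) {
  a <- (y - p$offset_um - p$speed_um_per_h * t / 3600) %% p$period_um
  as.numeric(a < p$duty * p$period_um)
}

oracle_phase <- function(y, t, p) {
  ## enumerate bar centres near y and take the signed offset of smallest
  ## magnitude; exact half-offsets map to -0.5
  c0 <- p$offset_um + p$speed_um_per_h * t / 3600 + p$duty * p$period_um / 2
  k <- round((y - c0) / p$period_um)
  cand <- c0 + (k + -2:2) * p$period_um
  off <- (y - cand) / p$period_um
  best <- off[which.min(abs(off))]
  if (best >= 0.5) best - 1 else if (best < -0.5) best + 1 else best
}
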