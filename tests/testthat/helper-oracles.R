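# Independent oracles shared by the unit and acceptance suites. These are
# deliberately naive implementations that do not share code with the
# package.

# Adjusted Rand index via literal pair counting.
ari_oracle <- function(a, b) {
  n <- length(a)
  ss <- sd_ <- ds_ <- dd <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    sa <- a[i] == a[j]
    sb <- b[i] == b[j]
    if (sa && sb) ss <- ss + 1
    else if (sa && !sb) sd_ <- sd_ + 1
    else if (!sa && sb) ds_ <- ds_ + 1
    else dd <- dd + 1
  }
  total <- ss + sd_ + ds_ + dd
  exp_index <- (ss + sd_) * (ss + ds_) / total
  max_index <- ((ss + sd_) + (ss + ds_)) / 2
  if (max_index == exp_index) return(1)
  (ss - exp_index) / (max_index - exp_index)
}

# One-sided signed-rank p-value via literal 2^n sign-pattern enumeration.
wilcox_enum_oracle <- function(a, b) {
  d <- a - b
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- signs %*% r
  mean(w_all >= w_obs - 1e-9)
}
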