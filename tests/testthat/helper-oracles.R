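# Brute-force two-sided Mann-Whitney p by enumerating every assignment of
# the combined observations to group 1 (symmetric-tail definition, which
# coincides with the doubled one-tail value for the tie-free null).
mw_enumerate_p <- function(x, y) {
  nx <- length(x)
  vals <- c(x, y)
  n <- length(vals)
  u_of <- function(idx) {
    xx <- vals[idx]
    yy <- vals[-idx]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_of(seq_len(nx))
  mu <- nx * (n - nx) / 2
  us <- apply(utils::combn(n, nx), 2, u_of)
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# clearance parameters of the first epicardial reference subject
ref_epi1_params <- function() {
  clearance_params(a = 37.9, b = 0.3712, c = 62.1, d = 0.0012930)
}

# random resolvable biexponential parameters within the reference ranges
random_clearance_params <- function() {
  a <- stats::runif(1, 16, 63)
  b <- stats::runif(1, 0.16, 1.2)
  d <- stats::runif(1, 2e-4, 1.5e-3)
  clearance_params(a, b, 100 - a, d)
}
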