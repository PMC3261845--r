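# Shared fixtures: small configs and the default neoplasia contrast.

neoplasia_contrast <- function() {
  define_contrast("neoplasia", c("normal", "IBD"), c("adenoma", "cancer"))
}

small_config <- function(...) {
  defaults <- list(
    n_probesets = 300,
    samples_per_class = c(normal = 8, IBD = 4, adenoma = 4, cancer = 8),
    n_de_up = 10, n_de_down = 10, de_effect = 1,
    n_onoff_on = 5, n_onoff_off = 5,
    within_class_sd = 0.5, seed = 42L
  )
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

# Independent brute-force Benjamini-Hochberg step-up: sort ascending, take
# cumulative minima of m*p/i from the largest rank down.
bh_stepup_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- pmin(1, m * p[o] / seq_len(m))
  adj <- rev(cummin(rev(adj)))
  out <- numeric(m)
  out[o] <- adj
  out
}

# Independent exact Mann-Whitney oracle: enumerate every assignment of the
# pooled values to group x and count pairwise wins directly.
mw_enumeration_oracle <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">"))
  U_obs <- u_of(x, y)
  combos <- utils::combn(length(pooled), nx)
  u_all <- apply(combos, 2, function(ix) {
    u_of(pooled[ix], pooled[-ix])
  })
  list(U = U_obs,
       p = min(1, 2 * min(mean(u_all <= U_obs), mean(u_all >= U_obs))))
}
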