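# Shared fixtures: small generation configs and a deterministic toy table.

gen_small <- function(n = 12, ...) gen_config(n = n, ...)

# noise-free generator: y is exactly the fixed-effect surface
gen_exact <- function(n = 6, betaA_star = 0) {
  gen_config(n = n, sigma_c0 = 0, sigma_c1 = 0, sigma_e = 0,
             betaA_star = betaA_star)
}

# a small complete collapsed table
small_table <- function(n = 12, seed = 101, gen = gen_small(n)) {
  collapse_runin(simulate_trial(gen, seed))
}

# hand-built table: `npid` participants, weeks 0..24, linear outcomes
toy_table <- function(npid = 4, slope = 10, base = 5000) {
  weeks <- 0:24
  do.call(rbind, lapply(seq_len(npid), function(i) {
    data.frame(pid = i, week = weeks, age = 20 + (i * 7) %% 13 + weeks / 52,
               arm = i %% 2L, y = base + i * 100 + slope * weeks,
               observed = 1L)
  }))
}

expect_monotone_nondecreasing <- function(x) {
  expect_true(all(diff(x) >= -1e-12))
}
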