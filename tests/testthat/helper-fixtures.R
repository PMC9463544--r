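# Shared fixture builders; everything is generated in code, nothing on disk.

with_seed <- ewdrs:::with_seed
trapz <- ewdrs:::trapz

master_grid <- function() 500:1500

# Flat-property material for physics checks.
flat_material <- function(mu_a = 0.01, mu_s_prime = 1, g = 0.9, n = 1.34,
                          name = "flat") {
  g_nm <- master_grid()
  optical_properties(g_nm, rep(mu_a, length(g_nm)), rep(mu_s_prime, length(g_nm)),
                     g = g, n = n, name = name)
}

# Small probe-and-models bundle used across MC tests.
quick_probe <- function() probe_geometry()

# A deterministic smooth positive test spectrum on an arbitrary grid.
smooth_spectrum <- function(grid = seq(500, 1000, 5), band = "visnir") {
  spectrum(grid, 1 + 0.5 * sin((grid - 500) / 120), band)
}

expect_ledger_closed <- function(result, tol = 1e-6) {
  expect_lt(abs(ledger_total(result) - 1), tol)
}
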