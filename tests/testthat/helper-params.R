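# Shared fixtures: the study's central parameter set and common protocols.


# Printed study inputs used by the deterministic chains.
STUDY <- list(E = 11.3, A = 0.6, L0 = 36.47, R0 = 65.60,
              short_slope = 189.5, comp_slope = 177.4, long_slope = 104.9,
              alpha = 0.64, rate = 1.5e-3)

expect_rel_equal <- function(object, expected, tol) {
  expect_lt(abs(object / expected - 1), tol)
}
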