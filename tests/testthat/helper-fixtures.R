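# shared fixtures: small deterministic datasets built in code

small_dataset <- function(S = 4, K = 2, m = 5, icc = 0.1, cac = 0.8,
                          theta = 0.15, seed = 101) {
  simulate_staircase(staircase_design(S, K, m),
                     variance_components(icc, cac), theta, seed = seed)
}

# the design-factor grid of the factorial study (variance formulas do not
# depend on theta)
variance_grid <- function() {
  expand.grid(S = c(4, 10), K = c(1, 5, 10), m = c(10, 50, 100),
              icc = c(0.01, 0.05, 0.1, 0.2), cac = c(1, 0.95, 0.8, 0.5),
              KEEP.OUT.ATTRS = FALSE)
}
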