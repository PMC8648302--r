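# Shared fixtures: noiseless configurations and small helpers used across the
# unit tests. All expected values in the tests were computed by independent
# direct arithmetic (or the stated brute-force oracle) and frozen.

quiet_cfg <- function(seed = 1, ...) {
  sim_config(seed = seed, sigma_A = 0, sigma_delta = 0, sigma_F = 0,
             sigma_OD = 0, ...)
}

# closed-form slope, written out independently of the package implementation
oracle_slope <- function(gm, Vpmax = 250, Kp = 82) (gm * Vpmax) / (gm * Kp + Vpmax)
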