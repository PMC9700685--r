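# Shared oracles and small builders used across the test files.

# brute-force pixel counting for the overlap metrics, via an explicit loop
# (independent of the package's vectorized counting)
bf_counts <- function(gt, pred) {
  ng <- np <- ni <- 0L
  for (i in seq_len(nrow(gt)))
    for (j in seq_len(ncol(gt))) {
      g <- gt[i, j]; p <- pred[i, j]
      ng <- ng + (g == 1)
      np <- np + (p == 1)
      ni <- ni + (g == 1 && p == 1)
    }
  list(ng = ng, np = np, ni = ni)
}

random_mask <- function(nr, nc, p) matrix(rbinom(nr * nc, 1, p), nr, nc)

# one phantom with a fixed geometry, for mask-invariance checks
fixed_patch <- function(type = "well_circumscribed", seed = 7) {
  synth_patch(nodule_spec(type, center = c(30, 34), radius_px = 7,
                          contrast = 0.5, noise_sd = 0.03, seed = seed))
}

# closed-form trainable-parameter count of one inverted residual block
# (hand arithmetic per stage, independent of the engine)
ir_params_closed_form <- function(i, o, t, k = 3, se_ratio = 0.25) {
  e <- t * i
  s <- ceiling(se_ratio * i)
  expand  <- 1 * 1 * i * e + 2 * e        # 1x1 conv (no bias) + BN
  dw      <- k * k * e + 2 * e            # depth-wise conv + BN
  se      <- e * s + s * e                # two bias-free dense layers
  project <- 1 * 1 * e * o + 2 * o        # 1x1 conv + BN
  expand + dw + se + project
}
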