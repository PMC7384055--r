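# Independent brute-force oracles used to cross-check closed forms.

# forward-Euler integration of piecewise inversion recovery
euler_bgs <- function(t1_ms, inversion_times_ms, t_ms, mz0 = 1, dt = 0.1) {
  mz <- mz0
  t <- 0
  inv_left <- inversion_times_ms
  while (t < t_ms - 1e-9) {
    if (length(inv_left) > 0 && t >= inv_left[1] - dt / 2) {
      mz <- -mz
      inv_left <- inv_left[-1]
    }
    step <- min(dt, t_ms - t)
    mz <- mz + step * (1 - mz) / t1_ms
    t <- t + step
  }
  mz
}

# numeric quadrature of the laminar velocity average of the plug response
quad_laminar <- function(v_mean, vs, n_bins = 1e4) {
  if (v_mean == 0) return(1)
  v <- (seq_len(n_bins) - 0.5) / n_bins * 2 * v_mean
  mean(plug_flow_response(v, vs))
}

# naive double-loop evaluation of the outlier-rejection rule
naive_reject <- function(mat, frac = 0.2, sd_thresh = 1.5) {
  R <- ncol(mat)
  n <- nrow(mat)
  kept <- integer(0)
  for (r in seq_len(R)) {
    deviant <- 0
    for (v in seq_len(n)) {
      mu <- mean(mat[v, ])
      sdv <- stats::sd(mat[v, ])
      if (abs(mat[v, r] - mu) > sd_thresh * sdv) deviant <- deviant + 1
    }
    if (deviant / n <= frac) kept <- c(kept, r)
  }
  kept
}

# wrap a voxels x pairs matrix as a subtraction stack
stack_from_matrix <- function(mat) {
  structure(list(dm = array(mat, c(nrow(mat), 1, 1, ncol(mat))),
                 n_pairs = ncol(mat)),
            class = "subtraction_stack")
}
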