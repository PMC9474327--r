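# Random valid parameter sets for property-style tests. Draw ranges keep
# every object inside the model's validity region (e_plus > e_minus where a
# positive mean gap is assumed, alpha_r * e_r in [0, 1]).

random_group_params <- function(positive_gap = TRUE) {
  e_minus <- runif(1, -2, 3)
  gap <- if (positive_gap) runif(1, 0.2, 3) else runif(1, -3, 3)
  e_r <- runif(1, 0.05, 0.95)
  group_params(e_plus = e_minus + gap, e_minus = e_minus, e_r = e_r,
               v_plus = runif(1, 0, 2), v_minus = runif(1, 0, 2),
               v_r = runif(1, 0, 0.05))
}

random_shift_params <- function(gp) {
  shift_params(d_plus = runif(1, -1, 2), d_minus = runif(1, -1, 2),
               alpha_r = runif(1, 0, 1 / gp$e_r))
}

# within-cluster sum of squares of a full assignment, for decomposition oracles
wss2 <- function(values, in_plus) {
  ss <- function(v) if (length(v) == 0) 0 else sum((v - mean(v))^2)
  ss(values[in_plus]) + ss(values[!in_plus])
}

# exhaustive best 2-partition over ALL assignments (not only thresholds);
# feasible for length <= 12
best_partition_wss <- function(values) {
  n <- length(values)
  best <- Inf
  for (code in 1:(2^n - 2)) {
    in_plus <- as.logical(bitwAnd(rep(code, n), 2^(0:(n - 1))))
    best <- min(best, wss2(values, in_plus))
  }
  best
}
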