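# Sweep over (d+, d-, alpha_r) producing paired sign maps of the bulk mean
# difference and bulk variance difference — the DE vs DV contrast: the two
# maps are generally not the same, so mean-based and variance-based tests see
# different features of the same single-cell change.

#' Baseline parameters for the DE/DV sign-map sweep
#'
#' The reference donor population used for the worked sweep:
#' \eqn{E_+ = 2, E_- = 1, E_r = 0.5, V_+ = 0.3, V_- = 0.1, V_r = 0.05}.
#'
#' @return A [group_params()] object.
#' @export
sweep_baseline <- function() {
  group_params(e_plus = 2, e_minus = 1, e_r = 0.5,
               v_plus = 0.3, v_minus = 0.1, v_r = 0.05)
}

#' Grid sweep of bulk mean and variance differences
#'
#' Evaluates [mean_difference()] and the change in [variance_bulk()] over a
#' grid of shift parameters: every combination of `d_values` for `d_plus` and
#' `d_minus` crossed with `alpha_values` for `alpha_r`. The default axes are
#' the worked 11 x 11 x 3 grid (\eqn{d_\pm \in \{0, 0.1, \ldots, 1\}},
#' \eqn{\alpha_r \in \{0.2, 0.5, 0.8\}}). Measurement error is additive and
#' group-invariant, so it cancels from the variance difference; the default
#' noise is therefore zero.
#'
#' Grid points where the shifted proportion leaves `[0, 1]` are recorded as
#' invalid (`NA` differences) and the sweep continues; the number of invalid
#' cells is attached as an attribute.
#'
#' @param gp Reference-group [group_params()]; defaults to
#'   [sweep_baseline()].
#' @param noise A [measurement_noise()] object.
#' @param d_values Grid values used for both `d_plus` and `d_minus`.
#' @param alpha_values Grid values for `alpha_r`.
#' @param tol Magnitudes below `tol` are classified as `"boundary"` rather
#'   than forced into a sign.
#' @return A data frame of class `"grid_result"` in long format: `d_plus`,
#'   `d_minus`, `alpha_r`, `delta_mean`, `delta_var`, `sign_mean`,
#'   `sign_var` (each `"increase"`, `"decrease"` or `"boundary"`) and
#'   `valid`. Attribute `n_invalid` counts skipped cells.
#' @examples
#' g <- sweep_grid()
#' subset(g, d_plus == 1 & d_minus == 0 & alpha_r == 0.2)
#' @export
sweep_grid <- function(gp = sweep_baseline(),
                       noise = measurement_noise(0),
                       d_values = seq(0, 1, by = 0.1),
                       alpha_values = c(0.2, 0.5, 0.8),
                       tol = 1e-12) {
  check_group_params(gp)
  base_var <- variance_bulk(gp, noise)
  grid <- expand.grid(d_plus = d_values, d_minus = d_values,
                      alpha_r = alpha_values,
                      KEEP.OUT.ATTRS = FALSE)
  n <- nrow(grid)
  delta_mean <- rep(NA_real_, n)
  delta_var <- rep(NA_real_, n)
  valid <- rep(TRUE, n)
  for (i in seq_len(n)) {
    s <- shift_params(grid$d_plus[i], grid$d_minus[i], grid$alpha_r[i])
    shifted <- tryCatch(apply_shift(gp, s), error = function(e) NULL)
    if (is.null(shifted)) {
      valid[i] <- FALSE
      next
    }
    delta_mean[i] <- mean_difference(gp, s)
    delta_var[i] <- variance_bulk(shifted, noise) - base_var
  }
  classify <- function(x) {
    out <- rep(NA_character_, length(x))
    ok <- !is.na(x)
    out[ok & abs(x) <= tol] <- "boundary"
    out[ok & x > tol] <- "increase"
    out[ok & x < -tol] <- "decrease"
    out
  }
  res <- data.frame(grid, delta_mean = delta_mean, delta_var = delta_var,
                    sign_mean = classify(delta_mean),
                    sign_var = classify(delta_var),
                    valid = valid, stringsAsFactors = FALSE)
  structure(res, class = c("grid_result", "data.frame"),
            n_invalid = sum(!valid), group_params = gp, noise = noise)
}
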