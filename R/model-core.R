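# Closed-form model of bulk expression under a two-subset cell mixture.
#
# A gene's single-cell distribution in one donor is a two-component mixture:
# subset "+" cells with mean mu+ (proportion r) and subset "-" cells with mean
# mu- (proportion 1 - r). The bulk value is Y = r*mu+ + (1-r)*mu- + e. Across
# donors, (mu+, mu-, r) are independent random variables with population means
# (E+, E-, Er) and variances (V+, V-, Vr); e has mean 0 and variance Verr.

#' Population-level parameters of the donor distribution
#'
#' Bundles the means and variances of the donor-level mixture parameters: the
#' subset means \eqn{\mu_+} and \eqn{\mu_-} and the subset-+ proportion
#' \eqn{r}. These six numbers fully determine the closed-form bulk mean
#' ([expected_bulk()]) and variance ([variance_bulk()]).
#'
#' @param e_plus Expected subset-+ mean expression, \eqn{E_+ = E[\mu_+]}.
#' @param e_minus Expected subset-- mean expression, \eqn{E_- = E[\mu_-]}.
#' @param e_r Expected subset-+ proportion, \eqn{E_r = E[r]}, in `[0, 1]`.
#' @param v_plus Across-donor variance of \eqn{\mu_+} (\eqn{V_+ \ge 0}).
#' @param v_minus Across-donor variance of \eqn{\mu_-} (\eqn{V_- \ge 0}).
#' @param v_r Across-donor variance of \eqn{r} (\eqn{V_r \ge 0}).
#' @return An object of class `"group_params"`.
#' @examples
#' gp <- group_params(e_plus = 2, e_minus = 1, e_r = 0.9,
#'                    v_plus = 1, v_minus = 0.1, v_r = 0.001)
#' expected_bulk(gp)
#' @export
group_params <- function(e_plus, e_minus, e_r, v_plus = 0, v_minus = 0, v_r = 0) {
  vals <- c(e_plus = e_plus, e_minus = e_minus, e_r = e_r,
            v_plus = v_plus, v_minus = v_minus, v_r = v_r)
  if (!all(is.finite(vals)))
    stop("group_params: all fields must be finite numbers", call. = FALSE)
  if (e_r < 0 || e_r > 1)
    stop(sprintf("group_params: e_r must lie in [0, 1], got %g", e_r),
         call. = FALSE)
  for (nm in c("v_plus", "v_minus", "v_r"))
    if (vals[[nm]] < 0)
      stop(sprintf("group_params: %s must be >= 0, got %g", nm, vals[[nm]]),
           call. = FALSE)
  structure(as.list(vals), class = "group_params")
}

#' @export
print.group_params <- function(x, ...) {
  cat("Donor population parameters (two-subset mixture)\n")
  cat(sprintf("  E+ = %g  E- = %g  Er = %g\n", x$e_plus, x$e_minus, x$e_r))
  cat(sprintf("  V+ = %g  V- = %g  Vr = %g\n", x$v_plus, x$v_minus, x$v_r))
  invisible(x)
}

#' Group-difference (shift) parameters
#'
#' Parametrizes how a second group ("D") differs from a reference group ("C"):
#' the subset means shift by \eqn{\Delta\mu_\pm = d_\pm (E_+ - E_-)} and the
#' expected subset proportion is multiplied by \eqn{\alpha_r}. `d_plus` and
#' `d_minus` are stored in the normalized convention (shift divided by the
#' reference mean gap \eqn{E_+ - E_-}); pass `normalized = FALSE` together
#' with `gp` to supply absolute shifts instead.
#'
#' @param d_plus,d_minus Expression shifts for subsets + and -. Normalized by
#'   the reference gap \eqn{E_+ - E_-} unless `normalized = FALSE`.
#' @param alpha_r Multiplicative change in the expected subset-+ proportion
#'   (\eqn{\ge 0}); when applied to a group, \eqn{\alpha_r E_r} must stay in
#'   `[0, 1]`.
#' @param normalized If `FALSE`, interpret `d_plus`/`d_minus` as absolute
#'   shifts \eqn{\Delta\mu_\pm} and convert using `gp`.
#' @param gp Reference [group_params()]; required when `normalized = FALSE`.
#' @return An object of class `"shift_params"` (normalized convention).
#' @examples
#' shift_params(0.5, 0.5, alpha_r = 4 / 9)
#' @export
shift_params <- function(d_plus = 0, d_minus = 0, alpha_r = 1,
                         normalized = TRUE, gp = NULL) {
  vals <- c(d_plus = d_plus, d_minus = d_minus, alpha_r = alpha_r)
  if (!all(is.finite(vals)))
    stop("shift_params: all fields must be finite numbers", call. = FALSE)
  if (alpha_r < 0)
    stop(sprintf("shift_params: alpha_r must be >= 0, got %g", alpha_r),
         call. = FALSE)
  if (!normalized) {
    if (is.null(gp))
      stop("shift_params: gp is required to normalize absolute shifts",
           call. = FALSE)
    stopifnot(inherits(gp, "group_params"))
    gap <- gp$e_plus - gp$e_minus
    if (gap == 0)
      stop("shift_params: cannot normalize absolute shifts when e_plus == e_minus",
           call. = FALSE)
    d_plus <- d_plus / gap
    d_minus <- d_minus / gap
  }
  structure(list(d_plus = d_plus, d_minus = d_minus, alpha_r = alpha_r),
            class = "shift_params")
}

#' @export
print.shift_params <- function(x, ...) {
  cat(sprintf("Group shift: d+ = %g, d- = %g (normalized), alpha_r = %g\n",
              x$d_plus, x$d_minus, x$alpha_r))
  invisible(x)
}

#' Additive measurement-error variance
#'
#' Variance of the error term added to the bulk value on top of the cell-mean
#' component (the last term of the bulk variance decomposition).
#'
#' @param v_err Variance of the additive measurement error (\eqn{\ge 0}).
#' @return An object of class `"measurement_noise"`.
#' @export
measurement_noise <- function(v_err = 0) {
  if (!is.finite(v_err) || v_err < 0)
    stop(sprintf("measurement_noise: v_err must be a finite number >= 0, got %s",
                 format(v_err)), call. = FALSE)
  structure(list(v_err = v_err), class = "measurement_noise")
}

check_group_params <- function(gp) {
  if (!inherits(gp, "group_params"))
    stop("expected a 'group_params' object; build one with group_params()",
         call. = FALSE)
  invisible(gp)
}

check_shift_params <- function(shift) {
  if (!inherits(shift, "shift_params"))
    stop("expected a 'shift_params' object; build one with shift_params()",
         call. = FALSE)
  invisible(shift)
}

#' Expected bulk expression value
#'
#' Closed form for the population mean of the bulk value:
#' \deqn{E[Y] = E_r E_+ + (1 - E_r) E_-.}
#'
#' @param gp A [group_params()] object.
#' @return The expected bulk expression (scalar).
#' @examples
#' expected_bulk(group_params(2, 1, 0.5))  # 1.5
#' @export
expected_bulk <- function(gp) {
  check_group_params(gp)
  gp$e_r * gp$e_plus + (1 - gp$e_r) * gp$e_minus
}

#' Bulk expression variance and its five-term decomposition
#'
#' Closed form for the across-donor variance of the bulk value:
#' \deqn{V[Y] = (E_+ - E_-)^2 V_r + E_r^2 V_+ + (1 - E_r)^2 V_-
#'   + (V_+ + V_-) V_r + V_{err}.}
#' Cell-to-cell variability within a donor does not appear: with many cells
#' per sample it averages out of the bulk value. `variance_terms()` returns
#' the five additive terms separately for reporting; `variance_bulk()` returns
#' their sum.
#'
#' @param gp A [group_params()] object.
#' @param noise A [measurement_noise()] object (default: no error).
#' @return `variance_bulk()`: the total variance (scalar).
#'   `variance_terms()`: a named numeric vector of the five terms
#'   (`gap_sq_vr`, `er_sq_vplus`, `comp_sq_vminus`, `vplus_vminus_vr`,
#'   `v_err`) summing to the total.
#' @examples
#' gp <- group_params(2, 1, 0.9, 1, 0.1, 0.001)
#' variance_bulk(gp, measurement_noise(0.1))   # 0.9131
#' variance_terms(gp, measurement_noise(0.1))
#' @export
variance_bulk <- function(gp, noise = measurement_noise(0)) {
  sum(variance_terms(gp, noise))
}

#' @rdname variance_bulk
#' @export
variance_terms <- function(gp, noise = measurement_noise(0)) {
  check_group_params(gp)
  if (!inherits(noise, "measurement_noise"))
    stop("expected a 'measurement_noise' object", call. = FALSE)
  c(gap_sq_vr = (gp$e_plus - gp$e_minus)^2 * gp$v_r,
    er_sq_vplus = gp$e_r^2 * gp$v_plus,
    comp_sq_vminus = (1 - gp$e_r)^2 * gp$v_minus,
    vplus_vminus_vr = (gp$v_plus + gp$v_minus) * gp$v_r,
    v_err = noise$v_err)
}

#' Apply a group shift to reference-group parameters
#'
#' Produces the shifted-group parameters: subset means move by
#' \eqn{\Delta\mu_\pm = d_\pm (E_+ - E_-)} and the expected proportion becomes
#' \eqn{\alpha_r E_r}. Variances are unchanged (the shift model moves only the
#' donor-level means). The shifted proportion must stay in `[0, 1]`; values
#' outside are rejected rather than clamped.
#'
#' @param gp Reference-group [group_params()].
#' @param shift A [shift_params()] object.
#' @return A new `group_params` object for the shifted group.
#' @examples
#' gp <- group_params(2, 1, 0.5, 0.3, 0.1, 0.05)
#' apply_shift(gp, shift_params(1, 0, 0.2))  # E+ = 3, E- = 1, Er = 0.1
#' @export
apply_shift <- function(gp, shift) {
  check_group_params(gp)
  check_shift_params(shift)
  new_er <- shift$alpha_r * gp$e_r
  if (new_er < 0 || new_er > 1)
    stop(sprintf(
      "apply_shift: shifted proportion alpha_r * e_r = %g lies outside [0, 1]",
      new_er), call. = FALSE)
  gap <- gp$e_plus - gp$e_minus
  group_params(e_plus = gp$e_plus + shift$d_plus * gap,
               e_minus = gp$e_minus + shift$d_minus * gap,
               e_r = new_er,
               v_plus = gp$v_plus, v_minus = gp$v_minus, v_r = gp$v_r)
}

#' Closed-form bulk mean difference between shifted and reference groups
#'
#' \deqn{E[Y_D] - E[Y_C] = (E_+ - E_-)\,(E_r(\alpha_r - 1)
#'   + \alpha_r E_r d_+ + (1 - \alpha_r E_r) d_-).}
#' Identically equal to
#' `expected_bulk(apply_shift(gp, shift)) - expected_bulk(gp)`; the closed
#' form makes explicit how a positive expression shift (\eqn{d_\pm > 0}) can
#' be cancelled, or even reversed, by a proportion decrease
#' (\eqn{\alpha_r < 1}).
#'
#' @inheritParams apply_shift
#' @return The bulk mean difference (scalar).
#' @examples
#' gp <- group_params(2, 1, 0.5)
#' mean_difference(gp, shift_params(1, 0, 0.2))  # -0.3: negative despite d+ > 0
#' @export
mean_difference <- function(gp, shift) {
  check_group_params(gp)
  check_shift_params(shift)
  new_er <- shift$alpha_r * gp$e_r
  if (new_er < 0 || new_er > 1)
    stop(sprintf(
      "mean_difference: shifted proportion alpha_r * e_r = %g lies outside [0, 1]",
      new_er), call. = FALSE)
  (gp$e_plus - gp$e_minus) *
    (gp$e_r * (shift$alpha_r - 1) +
       shift$alpha_r * gp$e_r * shift$d_plus +
       (1 - shift$alpha_r * gp$e_r) * shift$d_minus)
}

#' Proportion change at which a positive expression shift cancels exactly
#'
#' For nonnegative shifts `d_plus`, `d_minus`, returns the value of
#' \eqn{\alpha_r} at which the bulk mean difference is exactly zero:
#' \deqn{\alpha_r = \frac{E_r - d_-}{E_r (1 + d_+ - d_-)},}
#' the unique root of the mean-difference closed form in \eqn{\alpha_r}.
#' Smaller \eqn{\alpha_r} gives a nonpositive mean difference: the gene's
#' single-cell activation is invisible to, or reversed in, a bulk DE test.
#' Requires the assumptions `e_plus > e_minus`, `e_r > 0` and
#' `1 + d_plus - d_minus > 0`; each is validated and a violation is named.
#'
#' @param gp Reference-group [group_params()].
#' @param d_plus,d_minus Nonnegative normalized expression shifts.
#' @return The cancelling \eqn{\alpha_r} (scalar).
#' @examples
#' cancellation_alpha_bound(group_params(2, 1, 0.9), 0.5, 0.5)  # 4/9
#' @export
cancellation_alpha_bound <- function(gp, d_plus, d_minus) {
  check_group_params(gp)
  if (!is.finite(d_plus) || !is.finite(d_minus))
    stop("cancellation_alpha_bound: d_plus and d_minus must be finite",
         call. = FALSE)
  if (d_plus < 0 || d_minus < 0)
    stop("cancellation_alpha_bound: requires d_plus >= 0 and d_minus >= 0",
         call. = FALSE)
  if (gp$e_plus <= gp$e_minus)
    stop("cancellation_alpha_bound: requires e_plus > e_minus", call. = FALSE)
  if (gp$e_r <= 0)
    stop("cancellation_alpha_bound: requires e_r > 0", call. = FALSE)
  if (1 + d_plus - d_minus <= 0)
    stop("cancellation_alpha_bound: requires 1 + d_plus - d_minus > 0",
         call. = FALSE)
  alpha <- (gp$e_r - d_minus) / (gp$e_r * (1 + d_plus - d_minus))
  if (alpha < 0)
    stop(sprintf(
      paste0("cancellation_alpha_bound: d_minus = %g exceeds e_r = %g, ",
             "so no nonnegative alpha_r cancels the shift"),
      d_minus, gp$e_r), call. = FALSE)
  alpha
}
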