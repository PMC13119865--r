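#' Method-of-moments Gamma parameterisation
#'
#' Fits a Gamma distribution to a printed mean and standard error, the
#' standard convention for cost parameters in probabilistic sensitivity
#' analysis. The fitted distribution reproduces the input moments exactly:
#' `shape = (mean/se)^2`, `scale = se^2/mean`.
#'
#' @param mean Mean cost (GBP), strictly positive.
#' @param se Standard error (GBP), strictly positive.
#' @param name Item label used in error messages.
#' @return A list of class `gamma_spec` with elements `shape` and `scale`.
#' @examples
#' gamma_from_moments(29.00, 5.80)  # shape 25, scale 1.16
#' @export
gamma_from_moments <- function(mean, se, name = "cost item") {
  if (!is.finite(mean) || mean <= 0)
    stop(sprintf("'%s': Gamma fit requires mean > 0 (got %s)", name, format(mean)),
         call. = FALSE)
  if (!is.finite(se) || se <= 0)
    stop(sprintf("'%s': Gamma fit requires se > 0 (got %s)", name, format(se)),
         call. = FALSE)
  structure(list(shape = (mean / se)^2, scale = se^2 / mean),
            class = "gamma_spec")
}

#' Method-of-moments Beta parameterisation
#'
#' Fits a Beta distribution to a mean and standard error for probability and
#' utility parameters. Writing `nu = mean(1-mean)/se^2 - 1`, the fit is
#' `alpha = mean * nu`, `beta = (1-mean) * nu`, valid only when
#' `se^2 < mean(1-mean)`. An infeasible standard error is handled according
#' to `policy`: `"raise"` signals an error; `"clamp"` (the default) shrinks
#' the standard error to `0.95 * sqrt(mean(1-mean))` and emits a warning, so
#' that a single implausible printed value does not abort a whole run.
#'
#' @param mean Mean, strictly inside (0, 1).
#' @param se Standard error, strictly positive.
#' @param name Item label used in messages.
#' @param policy `"clamp"` or `"raise"` for infeasible standard errors.
#' @return A list of class `beta_spec` with elements `alpha`, `beta`, and
#'   `clamped` (logical; `TRUE` when the clamp was applied, in which case
#'   `se_used` carries the clamped value).
#' @examples
#' beta_from_moments(0.05, 0.0101)      # alpha ~ 23.2, beta ~ 441
#' beta_from_moments(0.5, sqrt(1 / 12)) # ~ uniform
#' @export
beta_from_moments <- function(mean, se, name = "probability item",
                              policy = c("clamp", "raise")) {
  policy <- match.arg(policy)
  if (!is.finite(mean) || mean <= 0 || mean >= 1)
    stop(sprintf("'%s': Beta fit requires 0 < mean < 1 (got %s)", name, format(mean)),
         call. = FALSE)
  if (!is.finite(se) || se <= 0)
    stop(sprintf("'%s': Beta fit requires se > 0 (got %s)", name, format(se)),
         call. = FALSE)
  vmax <- mean * (1 - mean)
  clamped <- FALSE
  if (se^2 >= vmax) {
    if (policy == "raise")
      stop(sprintf("'%s': se^2 = %.4g >= mean(1-mean) = %.4g; no Beta distribution has these moments",
                   name, se^2, vmax), call. = FALSE)
    se <- 0.95 * sqrt(vmax)
    clamped <- TRUE
    warning(sprintf("'%s': infeasible Beta standard error clamped to %.4g", name, se),
            call. = FALSE)
  }
  nu <- vmax / se^2 - 1
  structure(list(alpha = mean * nu, beta = (1 - mean) * nu,
                 clamped = clamped, se_used = se),
            class = "beta_spec")
}

#' @export
print.gamma_spec <- function(x, ...) {
  cat(sprintf("Gamma(shape = %.6g, scale = %.6g)  mean = %.6g, sd = %.6g\n",
              x$shape, x$scale, x$shape * x$scale, sqrt(x$shape) * x$scale))
  invisible(x)
}

#' @export
print.beta_spec <- function(x, ...) {
  m <- x$alpha / (x$alpha + x$beta)
  s <- sqrt(x$alpha * x$beta / ((x$alpha + x$beta)^2 * (x$alpha + x$beta + 1)))
  cat(sprintf("Beta(alpha = %.6g, beta = %.6g)  mean = %.6g, sd = %.6g%s\n",
              x$alpha, x$beta, m, s, if (isTRUE(x$clamped)) "  [se clamped]" else ""))
  invisible(x)
}

# Moments implied by a fitted spec; used by round-trip validators and tests.
spec_moments <- function(spec) {
  if (inherits(spec, "gamma_spec")) {
    list(mean = spec$shape * spec$scale, sd = sqrt(spec$shape) * spec$scale)
  } else if (inherits(spec, "beta_spec")) {
    s <- spec$alpha + spec$beta
    list(mean = spec$alpha / s,
         sd = sqrt(spec$alpha * spec$beta / (s^2 * (s + 1))))
  } else stop("unknown distribution spec", call. = FALSE)
}

# One random draw set from a fitted spec.
draw_spec <- function(spec, n = 1L) {
  if (inherits(spec, "gamma_spec")) stats::rgamma(n, shape = spec$shape, scale = spec$scale)
  else if (inherits(spec, "beta_spec")) stats::rbeta(n, spec$alpha, spec$beta)
  else stop("unknown distribution spec", call. = FALSE)
}
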