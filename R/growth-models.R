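#' Candidate growth-model parameter sets
#'
#' Constructors for the closed-form model families used throughout the
#' package.  `params_2d()` describes dry weight as a function of cultivation
#' time only (one light level at a time); `params_3d()` describes it as a
#' joint function of time and light intensity; `params_light_response()`
#' describes the sigmoid net-photosynthetic-rate light-response curve.
#'
#' Families and their coefficients (canonical units: t in days, I in
#' umol/(m^2 s), DW in mg/seedling):
#'
#' * 2D `linear`: `DW0 + A * t` (`DW0` mg, `A` mg/d) — the straight-line
#'   control.
#' * 2D `logistic`: `A / (1 + exp(-k2 * (t - tc)))`; `A` is the maximal DW
#'   achievable, `tc` the time to half-maximum, `k2` (1/d) the rate.
#' * 2D `gompertz`: `A * exp(-exp(-k * (t - tc)))`; equals `A/e` at `t = tc`.
#' * 2D `exponential`: `DW0 + A * exp(R0 * t)`.
#' * 3D `plane`: `DW0 + kt * t + kI * I` — affine control/saturated-region
#'   model.
#' * 3D `logistic_cum`: product-of-logistics cumulative surface
#'   `DW0 + DWmax / ((1 + exp((t_m4 - t)/k3)) * (1 + exp((I_m4 - I)/k4)))`;
#'   at `(t_m4, I_m4)` the surface reaches `DW0 + DWmax/4` (a quarter of the
#'   asymptotic gain).
#' * 3D `exponential2d`: `DW0 + B * exp(t/C + I/D)` (signs carried by the
#'   fitted `C`, `D`).
#' * 3D `gauss_cum`: `DW0 + 0.25 * B * (1 + erf((t - C)/(sqrt(2) D))) *
#'   (1 + erf((I - E)/(sqrt(2) F)))`.
#'
#' @param family Model family name (see above).
#' @param ... Named numeric coefficients for the family.
#' @return An object of class `ltbr_params` (and `ltbr_params_2d`,
#'   `ltbr_params_3d` or `ltbr_params_lr`), a named list with elements
#'   `family` and `coef` (named numeric vector in canonical order).
#' @examples
#' p <- params_2d("logistic", A = 419.5, k2 = 0.49, tc = 13.5)
#' eval_2d(p, t = 13.5)  # half of A
#' @export
params_2d <- function(family, ...) {
  family <- match.arg(family, names(.families_2d))
  new_params(family, c(...), .families_2d[[family]], "ltbr_params_2d")
}

#' @rdname params_2d
#' @export
params_3d <- function(family, ...) {
  family <- match.arg(family, names(.families_3d))
  new_params(family, c(...), .families_3d[[family]], "ltbr_params_3d")
}

#' @rdname params_2d
#' @param P_max Maximal net photosynthetic rate, ug/(m^2 s).
#' @param I_m2 Intensity at which half of `P_max` is reached, umol/(m^2 s).
#' @param k1 Rate coefficient, m^2 s/umol.
#' @export
params_light_response <- function(P_max, I_m2, k1) {
  new_params("sigmoid_lr", c(P_max = P_max, I_m2 = I_m2, k1 = k1),
             c("P_max", "I_m2", "k1"), "ltbr_params_lr")
}

# coefficient order per family; length is the parameter count p used by AIC
.families_2d <- list(
  linear      = c("DW0", "A"),
  logistic    = c("A", "k2", "tc"),
  gompertz    = c("A", "k", "tc"),
  exponential = c("DW0", "A", "R0")
)

.families_3d <- list(
  plane         = c("DW0", "kt", "kI"),
  logistic_cum  = c("DW0", "DWmax", "t_m4", "k3", "I_m4", "k4"),
  exponential2d = c("DW0", "B", "C", "D"),
  gauss_cum     = c("DW0", "B", "C", "D", "E", "F")
)

new_params <- function(family, coefs, wanted, subclass) {
  if (!all(is.finite(coefs)))
    stop("non-finite parameter for family '", family, "'", call. = FALSE)
  missing <- setdiff(wanted, names(coefs))
  if (length(missing))
    stop("family '", family, "' needs coefficients: ",
         paste(missing, collapse = ", "), call. = FALSE)
  coefs <- coefs[wanted]
  if (family %in% c("logistic", "gompertz") && coefs[["A"]] <= 0)
    stop("asymptote A must be > 0 for the ", family, " family", call. = FALSE)
  if (family == "logistic_cum" &&
      (coefs[["k3"]] <= 0 || coefs[["k4"]] <= 0))
    stop("logistic_cum requires k3 > 0 and k4 > 0", call. = FALSE)
  structure(list(family = family, coef = coefs),
            class = c(subclass, "ltbr_params"))
}

#' @export
print.ltbr_params <- function(x, ...) {
  cat(x$family, "model:",
      paste(names(x$coef), signif(x$coef, 6), sep = " = ", collapse = ", "),
      "\n")
  invisible(x)
}

#' Number of free parameters of a model family
#'
#' Used as `p` in the AIC penalty `2p`.
#' @param family Family name (2D or 3D).
#' @return Integer parameter count.
#' @export
n_params <- function(family) {
  all <- c(.families_2d, .families_3d)
  if (is.null(all[[family]])) stop("unknown family '", family, "'")
  length(all[[family]])
}

erf <- function(x) 2 * pnorm(x * sqrt(2)) - 1

#' Evaluate a time-based (2D) growth model
#'
#' @param params An `ltbr_params_2d` object from [params_2d()].
#' @param t Cultivation time, days (vectorised).
#' @return Dry weight, mg/seedling.
#' @export
eval_2d <- function(params, t) {
  stopifnot(inherits(params, "ltbr_params_2d"))
  if (!all(is.finite(t))) stop("t must be finite")
  cf <- params$coef
  switch(params$family,
    linear      = cf[["DW0"]] + cf[["A"]] * t,
    logistic    = cf[["A"]] / (1 + exp(-cf[["k2"]] * (t - cf[["tc"]]))),
    gompertz    = cf[["A"]] * exp(-exp(-cf[["k"]] * (t - cf[["tc"]]))),
    exponential = cf[["DW0"]] + cf[["A"]] * exp(cf[["R0"]] * t)
  )
}

#' Evaluate a light-time (3D) growth model
#'
#' No domain clamping happens here: evaluation is the pure closed form and
#' extrapolates freely.  Domain enforcement lives in the surface layer
#' ([predict.ltbr_surface()]).
#'
#' @param params An `ltbr_params_3d` object from [params_3d()].
#' @param t Cultivation time, days (vectorised, recycled against `I`).
#' @param I Light intensity, umol/(m^2 s).
#' @return Dry weight, mg/seedling.
#' @export
eval_3d <- function(params, t, I) {
  stopifnot(inherits(params, "ltbr_params_3d"))
  if (!all(is.finite(t)) || !all(is.finite(I))) stop("t and I must be finite")
  cf <- params$coef
  switch(params$family,
    plane = cf[["DW0"]] + cf[["kt"]] * t + cf[["kI"]] * I,
    logistic_cum =
      cf[["DW0"]] + cf[["DWmax"]] /
        ((1 + exp((cf[["t_m4"]] - t) / cf[["k3"]])) *
         (1 + exp((cf[["I_m4"]] - I) / cf[["k4"]]))),
    exponential2d =
      cf[["DW0"]] + cf[["B"]] * exp(t / cf[["C"]] + I / cf[["D"]]),
    gauss_cum =
      cf[["DW0"]] + 0.25 * cf[["B"]] *
        (1 + erf((t - cf[["C"]]) / (sqrt(2) * cf[["D"]]))) *
        (1 + erf((I - cf[["E"]]) / (sqrt(2) * cf[["F"]])))
  )
}

#' Evaluate the sigmoid light-response curve for net photosynthetic rate
#'
#' `Pn(I) = P_max / (1 + exp(-k1 * (I - I_m2)))`: bounded in `(0, P_max)`,
#' monotone increasing in `I` for `k1 > 0`, and equal to `P_max / 2` at
#' `I = I_m2`.
#'
#' @param params An `ltbr_params_lr` object from [params_light_response()].
#' @param I Light intensity, umol/(m^2 s) (vectorised), must be >= 0.
#' @return Net photosynthetic rate, ug/(m^2 s).
#' @export
eval_light_response <- function(params, I) {
  stopifnot(inherits(params, "ltbr_params_lr"))
  if (!all(is.finite(I)) || any(I < 0)) stop("I must be finite and >= 0")
  cf <- params$coef
  cf[["P_max"]] / (1 + exp(-cf[["k1"]] * (I - cf[["I_m2"]])))
}

# unchecked evaluator used inside the optimizer's hot loop: positional
# coefficient vector (canonical order) -> predictions; identical closed
# forms to eval_2d()/eval_3d(), minus S3 dispatch and validation
model_fun <- function(family) {
  switch(family,
    linear      = function(th, d) th[1] + th[2] * d$t,
    logistic    = function(th, d) th[1] / (1 + exp(-th[2] * (d$t - th[3]))),
    gompertz    = function(th, d) th[1] * exp(-exp(-th[2] * (d$t - th[3]))),
    exponential = function(th, d) th[1] + th[2] * exp(th[3] * d$t),
    plane       = function(th, d) th[1] + th[2] * d$t + th[3] * d$I,
    logistic_cum = function(th, d)
      th[1] + th[2] / ((1 + exp((th[3] - d$t) / th[4])) *
                       (1 + exp((th[5] - d$I) / th[6]))),
    exponential2d = function(th, d)
      th[1] + th[2] * exp(d$t / th[3] + d$I / th[4]),
    gauss_cum = function(th, d)
      th[1] + 0.25 * th[2] *
        (1 + erf((d$t - th[3]) / (sqrt(2) * th[4]))) *
        (1 + erf((d$I - th[5]) / (sqrt(2) * th[6]))),
    stop("unknown family '", family, "'"))
}

is_family_3d <- function(family) family %in% names(.families_3d)

# does the family expose an explicit maximal-DW (asymptote) parameter?
has_explicit_asymptote <- function(family) {
  family %in% c("logistic", "gompertz", "logistic_cum")
}
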