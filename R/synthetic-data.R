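# Seeded simulation of the sextuplicate measurement design, so the whole
# pipeline (fit -> select -> surface -> validate -> robustness) is testable
# without any external data.

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sampling-day schedule keyed to leaf developmental stages
#'
#' Seedlings develop faster under stronger light, so the measurement design
#' samples each intensity level at its own 1-, 2- and 3-leaf-stage days,
#' plus the fixed transplantation days 14 and 16.  Stage-day anchors:
#' 1-leaf on day 5 at >= 350 umol/(m^2 s) and day 6 at <= 300; 2-leaf on
#' day 6 at >= 350; 3-leaf on day 8 at >= 450, day 9 between 250 and 400,
#' day 10 at 100-200 and day 13 at 50.  Between anchors the schedule is
#' linearly interpolated and rounded; the unstated low-light 2-leaf day is
#' taken as the rounded midpoint of the 1- and 3-leaf days.
#'
#' @param I Light intensity, umol/(m^2 s), within `[50, 500]`.
#' @return Integer-ish vector `c(one_leaf, two_leaf, three_leaf, 14, 16)`.
#' @export
leaf_stage_days <- function(I) {
  stopifnot(length(I) == 1, I >= 50, I <= 500)
  rnd <- function(x) floor(x + 0.5)
  interp <- function(anchors_I, anchors_d)
    rnd(approx(anchors_I, anchors_d, xout = I, rule = 2)$y)
  s1 <- interp(c(300, 350), c(6, 5))
  s3 <- interp(c(50, 100, 200, 250, 400, 450, 500),
               c(13, 10, 10, 9, 9, 8, 8))
  s2 <- if (I >= 350) 6 else rnd((s1 + s3) / 2)
  c(s1, s2, s3, 14, 16)
}

#' Measurement-grid design
#'
#' The default design mirrors the study layout: 10 intensity levels from 50
#' to 500 umol/(m^2 s) in steps of 50, each sampled on day 0 plus its
#' leaf-stage days plus days 14 and 16, with 6 replicates per cell and a
#' seed dry weight of 0.5 mg on day 0.
#'
#' @param intensities Intensity levels, umol/(m^2 s).
#' @param replicates Replicates per (day, intensity) cell (>= 2).
#' @param seed_dw Average seed dry weight, mg (day-0 level).
#' @return Object of class `ltbr_design`: list with `intensities`,
#'   `replicates`, `seed_dw` and `days` (named list of sampling days per
#'   level, each starting at day 0).
#' @export
grid_design <- function(intensities = seq(50, 500, by = 50),
                        replicates = 6, seed_dw = 0.5) {
  stopifnot(replicates >= 2, all(intensities >= 50 & intensities <= 500))
  days <- lapply(intensities,
                 function(I) sort(unique(c(0, leaf_stage_days(I)))))
  names(days) <- as.character(intensities)
  structure(list(intensities = intensities, replicates = replicates,
                 seed_dw = seed_dw, days = days), class = "ltbr_design")
}

#' Intensity-dependent multiplicative noise model
#'
#' Replicate dry weights scatter more under stronger light; the generator
#' realises this with multiplicative Gaussian noise whose relative standard
#' deviation grows linearly with intensity: `rel_sd(I) = a + b * I / 500`
#' (defaults a = b = 0.05), truncated so no weight goes below zero.
#'
#' @param a Baseline relative SD. @param b Intensity-slope of the relative
#'   SD over the 0-500 range.
#' @return Object of class `ltbr_noise` with a `rel_sd(I)` function.
#' @export
noise_model <- function(a = 0.05, b = 0.05) {
  stopifnot(a >= 0, b >= 0)
  structure(list(a = a, b = b,
                 rel_sd = function(I) a + b * I / 500),
            class = "ltbr_noise")
}

#' Generate replicate-level growth data from a known surface
#'
#' Each record is `DW = truth(t, I) * (1 + eps)` with
#' `eps ~ N(0, rel_sd(I)^2)`, truncated at zero; deterministic given
#' `seed`.  Day-0 records are by default also drawn from the surface
#' (`day0 = "model"`, the coherent choice for parameter-recovery studies);
#' `day0 = "seed"` instead centres them on the design's measured seed dry
#' weight (0.5 mg), emulating how the real experiment anchors day 0 on
#' weighed seeds rather than on the fitted surface.
#'
#' @param design An [grid_design()].
#' @param truth An `ltbr_surface` ground truth
#'   (default [reference_surface()]).
#' @param noise An [noise_model()].
#' @param seed Integer RNG seed.
#' @param day0 `"model"` or `"seed"` (see above).
#' @return Data frame with columns `intensity`, `day`, `replicate`,
#'   `dw_mg` and fitting aliases `t`, `I`, `dw`.
#' @export
generate_growth <- function(design = grid_design(),
                            truth = reference_surface(),
                            noise = noise_model(), seed = 1,
                            day0 = c("model", "seed")) {
  day0 <- match.arg(day0)
  stopifnot(inherits(design, "ltbr_design"), inherits(noise, "ltbr_noise"))
  grid <- do.call(rbind, lapply(design$intensities, function(I)
    data.frame(intensity = I, day = design$days[[as.character(I)]])))
  with_seed(seed, {
    rows <- lapply(seq_len(nrow(grid)), function(i) {
      I <- grid$intensity[i]; t <- grid$day[i]
      mu <- if (t == 0 && day0 == "seed") design$seed_dw
            else predict(truth, t, I)
      eps <- rnorm(design$replicates, 0, noise$rel_sd(I))
      data.frame(intensity = I, day = t,
                 replicate = seq_len(design$replicates),
                 dw_mg = pmax(mu * (1 + eps), 0))
    })
    out <- do.call(rbind, rows)
    out$t <- out$day; out$I <- out$intensity; out$dw <- out$dw_mg
    out
  })
}

# white-LED band photon fluxes at the 400 umol/(m^2 s) level, used as the
# reference spectral shape for all synthetic levels
.reference_bands <- c(uv = 0.28, blue = 117.86, green = 181.02,
                      red = 101.54, far_red = 8.11)

#' Generate per-band LED spectra for a set of intensity levels
#'
#' Band photon fluxes proportional to the reference white-LED spectral
#' shape (measured at the 400 umol/(m^2 s) level), rescaled so the band
#' total equals each requested level.  The green band is the largest at
#' every level, as in the measured spectra.
#'
#' @param levels Intensity levels, umol/(m^2 s), within `[0, 500]`.
#' @return Data frame with columns `intensity`, `band`, `flux`.
#' @export
generate_spectrum <- function(levels = seq(50, 500, by = 50)) {
  stopifnot(all(levels >= 0 & levels <= 500))
  props <- .reference_bands / sum(.reference_bands)
  do.call(rbind, lapply(levels, function(lv)
    data.frame(intensity = lv, band = names(props),
               flux = unname(lv * props))))
}

#' The ten validation growth conditions
#'
#' Randomly chosen (in the original experiment) off-grid conditions used to
#' validate the surface: six in Region 1 and four in Region 2.
#'
#' @return Data frame with columns `t` (days) and `I` (umol/(m^2 s)).
#' @export
validation_conditions <- function() {
  data.frame(
    t = c(8.10, 8.05, 11.05, 11.10, 15.10, 15.20,
          14.05, 15.10, 15.05, 15.20),
    I = c(120, 345, 235, 440, 172, 340,
          411, 420, 453, 480))
}

#' Generate replicate validation measurements from a known surface
#'
#' Draws `replicates` dry weights per condition from the surface prediction
#' with multiplicative Gaussian noise of fixed relative SD, truncated at
#' zero.  Out-of-domain conditions raise an error.
#'
#' @param surface An `ltbr_surface` (also defines the domain).
#' @param conditions Data frame with columns `t`, `I`
#'   (default [validation_conditions()]).
#' @param rel_sd Relative standard deviation of the measurement noise.
#' @param replicates Replicates per condition.
#' @param seed Integer RNG seed.
#' @return Replicate-level data frame with columns `t`, `I`, `replicate`,
#'   `dw`.
#' @export
generate_validation_set <- function(surface = reference_surface(),
                                    conditions = validation_conditions(),
                                    rel_sd = 0.05, replicates = 6,
                                    seed = 1) {
  classify_region(conditions$t, conditions$I, surface)  # domain check
  pred <- predict(surface, conditions$t, conditions$I)
  with_seed(seed, {
    do.call(rbind, lapply(seq_len(nrow(conditions)), function(i) {
      eps <- rnorm(replicates, 0, rel_sd)
      data.frame(t = conditions$t[i], I = conditions$I[i],
                 replicate = seq_len(replicates),
                 dw = pmax(pred[i] * (1 + eps), 0))
    }))
  })
}
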