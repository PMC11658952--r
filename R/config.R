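#' Model configuration
#'
#' Collects every constant of the energy-balance weight-loss model in one
#' validated object: the tissue energy density, the diet-induced
#' thermogenesis (DIT) coefficient, the adaptive-thermogenesis (AT) ceiling,
#' the fat-free-mass (FFM) percentage shift and its saturation thresholds,
#' the resting-energy-expenditure (REE) equation and its coefficients, and
#' the lean-reference anchors used to predict baseline body composition.
#'
#' Two model variants are supported. The `"original"` variant pairs the
#' Cunningham REE equation with an exponential FFM% rise saturating at 10%
#' relative weight loss. The `"refined"` variant pairs the FFM-based Mifflin
#' REE equation with a linear FFM% rise saturating at 20% relative loss.
#' AT saturates at 10% relative loss in both variants.
#'
#' @param variant `"original"` or `"refined"`; presets `ree_equation` and
#'   `ffm_trajectory` jointly. Individual fields may still be overridden.
#' @param energy_density kcal per kg of body tissue (default 7700).
#' @param dit_coeff DIT as a fraction of energy intake (default 0.05, the
#'   overweight/obese value; lean populations use 0.10).
#' @param at_ceiling AT at saturation, as a fraction of REE (default 0.15).
#' @param ffm_shift rise in FFM% at saturation, percentage points
#'   (default 10).
#' @param sat_threshold_original fractional weight loss at which the
#'   exponential FFM% trajectory and AT saturate (default 0.10).
#' @param sat_threshold_refined fractional weight loss at which the linear
#'   FFM% trajectory saturates (default 0.20).
#' @param ree_equation `"cunningham"` or `"mifflin"` (both FFM-based).
#' @param ffm_trajectory `"exponential_original"` or `"linear_refined"`.
#' @param cunningham_intercept,cunningham_slope Cunningham coefficients:
#'   REE = intercept + slope * FFM(kg). Defaults 500 and 22.
#' @param mifflin_intercept,mifflin_slope FFM-based Mifflin coefficients.
#'   Defaults 413 and 19.7.
#' @param lean_ref_weight_female,lean_ref_weight_male reference body weight
#'   of a lean adult, kg.
#' @param lean_ref_ffm_frac_female,lean_ref_ffm_frac_male FFM fraction of
#'   the lean reference subject.
#' @param excess_ffm_frac fraction of weight above the lean reference that
#'   is FFM (default 0.25; the remaining 0.75 is fat mass).
#' @param exp_saturation_frac fraction of saturation the unnormalised
#'   exponential trajectories reach at their threshold; sets the shape
#'   parameter k = -log(1 - exp_saturation_frac) / threshold. The curves
#'   are then rescaled so the endpoint anchors are exact.
#'
#' @return An object of class `eb_model_config` (a validated named list).
#' @seealso [read_model_config()], [write_model_config()]
#' @examples
#' cfg <- model_config()
#' cfg$energy_density
#' refined <- model_config("refined")
#' refined$ree_equation
#' @export
model_config <- function(variant = c("original", "refined"),
                         energy_density = 7700,
                         dit_coeff = 0.05,
                         at_ceiling = 0.15,
                         ffm_shift = 10,
                         sat_threshold_original = 0.10,
                         sat_threshold_refined = 0.20,
                         ree_equation = NULL,
                         ffm_trajectory = NULL,
                         cunningham_intercept = 500,
                         cunningham_slope = 22,
                         mifflin_intercept = 413,
                         mifflin_slope = 19.7,
                         lean_ref_weight_female = 60,
                         lean_ref_ffm_frac_female = 0.72,
                         lean_ref_weight_male = 70,
                         lean_ref_ffm_frac_male = 0.85,
                         excess_ffm_frac = 0.25,
                         exp_saturation_frac = 0.99) {
  variant <- match.arg(variant)
  if (is.null(ree_equation)) {
    ree_equation <- if (variant == "original") "cunningham" else "mifflin"
  }
  if (is.null(ffm_trajectory)) {
    ffm_trajectory <- if (variant == "original") {
      "exponential_original"
    } else {
      "linear_refined"
    }
  }
  cfg <- list(
    energy_density = energy_density,
    dit_coeff = dit_coeff,
    at_ceiling = at_ceiling,
    ffm_shift = ffm_shift,
    sat_threshold_original = sat_threshold_original,
    sat_threshold_refined = sat_threshold_refined,
    ree_equation = ree_equation,
    ffm_trajectory = ffm_trajectory,
    cunningham_intercept = cunningham_intercept,
    cunningham_slope = cunningham_slope,
    mifflin_intercept = mifflin_intercept,
    mifflin_slope = mifflin_slope,
    lean_ref_weight_female = lean_ref_weight_female,
    lean_ref_ffm_frac_female = lean_ref_ffm_frac_female,
    lean_ref_weight_male = lean_ref_weight_male,
    lean_ref_ffm_frac_male = lean_ref_ffm_frac_male,
    excess_ffm_frac = excess_ffm_frac,
    exp_saturation_frac = exp_saturation_frac
  )
  class(cfg) <- "eb_model_config"
  validate_model_config(cfg)
}

#' @export
print.eb_model_config <- function(x, ...) {
  cat("Energy-balance model configuration\n")
  cat(sprintf("  REE equation:    %s\n", x$ree_equation))
  cat(sprintf("  FFM trajectory:  %s\n", x$ffm_trajectory))
  cat(sprintf("  energy density:  %g kcal/kg\n", x$energy_density))
  cat(sprintf("  DIT coefficient: %g\n", x$dit_coeff))
  cat(sprintf(
    "  AT ceiling:      %g x REE (saturates at %g%% loss)\n",
    x$at_ceiling, 100 * x$sat_threshold_original
  ))
  cat(sprintf(
    "  FFM%% shift:      +%g pp (saturates at %g%% / %g%% loss)\n",
    x$ffm_shift, 100 * x$sat_threshold_original,
    100 * x$sat_threshold_refined
  ))
  invisible(x)
}

model_config_fields <- function() {
  names(unclass(model_config()))
}

validate_model_config <- function(cfg) {
  stopifnot(inherits(cfg, "eb_model_config"))
  num1 <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
  chk <- function(ok, msg) if (!ok) stop(msg, call. = FALSE)
  chk(num1(cfg$energy_density) && cfg$energy_density > 0,
      "energy_density must be a positive number (kcal/kg)")
  chk(num1(cfg$dit_coeff) && cfg$dit_coeff >= 0 && cfg$dit_coeff <= 1,
      "dit_coeff must lie in [0, 1]")
  chk(num1(cfg$at_ceiling) && cfg$at_ceiling >= 0 && cfg$at_ceiling < 1,
      "at_ceiling must lie in [0, 1)")
  chk(num1(cfg$ffm_shift) && cfg$ffm_shift >= 0,
      "ffm_shift must be >= 0 percentage points")
  chk(num1(cfg$sat_threshold_original) && cfg$sat_threshold_original > 0 &&
        cfg$sat_threshold_original < 1,
      "sat_threshold_original must lie in (0, 1)")
  chk(num1(cfg$sat_threshold_refined) && cfg$sat_threshold_refined > 0 &&
        cfg$sat_threshold_refined < 1,
      "sat_threshold_refined must lie in (0, 1)")
  chk(is.character(cfg$ree_equation) &&
        cfg$ree_equation %in% c("cunningham", "mifflin"),
      "ree_equation must be 'cunningham' or 'mifflin'")
  chk(is.character(cfg$ffm_trajectory) &&
        cfg$ffm_trajectory %in% c("exponential_original", "linear_refined"),
      "ffm_trajectory must be 'exponential_original' or 'linear_refined'")
  for (f in c("cunningham_intercept", "cunningham_slope",
              "mifflin_intercept", "mifflin_slope")) {
    chk(num1(cfg[[f]]) && cfg[[f]] >= 0, paste(f, "must be >= 0"))
  }
  for (f in c("lean_ref_weight_female", "lean_ref_weight_male")) {
    chk(num1(cfg[[f]]) && cfg[[f]] > 0, paste(f, "must be > 0 kg"))
  }
  for (f in c("lean_ref_ffm_frac_female", "lean_ref_ffm_frac_male")) {
    chk(num1(cfg[[f]]) && cfg[[f]] > 0 && cfg[[f]] < 1,
        paste(f, "must lie in (0, 1)"))
  }
  chk(num1(cfg$excess_ffm_frac) && cfg$excess_ffm_frac >= 0 &&
        cfg$excess_ffm_frac < 1,
      "excess_ffm_frac must lie in [0, 1)")
  chk(num1(cfg$exp_saturation_frac) && cfg$exp_saturation_frac > 0 &&
        cfg$exp_saturation_frac < 1,
      "exp_saturation_frac must lie in (0, 1)")
  cfg
}

#' Subject baseline description
#'
#' Baseline inputs of the model: starting weight, sex (selects the
#' lean-reference anchors of the body-composition predictor), physical
#' activity level (PAL, the ratio of total to resting energy expenditure)
#' and the prescribed baseline energy intake.
#'
#' @param w0 starting body weight, kg (> 0).
#' @param sex `"female"` or `"male"`.
#' @param pal physical activity level, in the PAL index range 1.2
#'   (chair-/bed-bound) to 2.4 (strenuous activity). Default 1.6, a
#'   moderately active lifestyle.
#' @param ei0 baseline prescribed energy intake, kcal/d (>= 0). Used as the
#'   default constant intake when no schedule is supplied.
#' @return An object of class `eb_subject`.
#' @examples
#' subject_baseline(93.31, "female", pal = 1.6, ei0 = 800)
#' @export
subject_baseline <- function(w0, sex = c("female", "male"), pal = 1.6,
                             ei0 = 800) {
  sex <- match.arg(sex)
  if (!is.numeric(w0) || length(w0) != 1 || !is.finite(w0) || w0 <= 0) {
    stop("w0 must be a single positive weight in kg", call. = FALSE)
  }
  if (!is.numeric(pal) || length(pal) != 1 || pal < 1.2 || pal > 2.4) {
    stop("pal must lie in the PAL index range [1.2, 2.4]", call. = FALSE)
  }
  if (!is.numeric(ei0) || length(ei0) != 1 || ei0 < 0) {
    stop("ei0 must be a non-negative energy intake in kcal/d",
         call. = FALSE)
  }
  structure(list(w0 = w0, sex = sex, pal = pal, ei0 = ei0),
            class = "eb_subject")
}

#' @export
print.eb_subject <- function(x, ...) {
  cat(sprintf("Subject: %.2f kg %s, PAL %.2f, baseline EI %g kcal/d\n",
              x$w0, x$sex, x$pal, x$ei0))
  invisible(x)
}
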