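#' Predict baseline fat-free mass fraction from starting weight
#'
#' Body composition at baseline is predicted from a linear relationship
#' between starting weight and FFM in kg: a lean reference subject of the
#' given sex carries `lean_ref_ffm_frac * lean_ref_weight` kg of FFM, and
#' each kg of weight above the reference adds `excess_ffm_frac` kg of FFM
#' (default 0.25, i.e. excess weight is 75% fat mass / 25% fat-free mass).
#' Dividing by starting weight yields the baseline FFM fraction, which
#' decreases with weight above the lean reference.
#'
#' @param w0 starting weight, kg (> 0). Vectorised.
#' @param sex `"female"` or `"male"`.
#' @param config an [model_config()] object.
#' @return Baseline FFM as a fraction of body weight (dimensionless).
#' @examples
#' baseline_ffm_fraction(93.31, "female")
#' @export
baseline_ffm_fraction <- function(w0, sex = c("female", "male"),
                                  config = model_config()) {
  sex <- match.arg(sex)
  validate_model_config(config)
  if (!is.numeric(w0) || any(!is.finite(w0)) || any(w0 <= 0)) {
    stop("w0 must be positive weight(s) in kg", call. = FALSE)
  }
  ref_w <- config[[paste0("lean_ref_weight_", sex)]]
  ref_frac <- config[[paste0("lean_ref_ffm_frac_", sex)]]
  ffm_kg <- ref_frac * ref_w + config$excess_ffm_frac * (w0 - ref_w)
  ffm_kg / w0
}

# Shape parameter of the exponential saturation curves: the unnormalised
# curve 1 - exp(-k x) reaches exp_saturation_frac at x = threshold.
exp_shape_k <- function(config, threshold) {
  -log(1 - config$exp_saturation_frac) / threshold
}

# Normalised exponential rise from 0 at x = 0 to 1 at x = x_sat, clamped
# at 1 beyond; endpoint anchors are exact.
exp_saturating <- function(x, x_sat, k) {
  frac <- (1 - exp(-k * pmin(x, x_sat))) / (1 - exp(-k * x_sat))
  pmin(frac, 1)
}

#' Fat-free mass fraction as a function of relative weight loss
#'
#' During energy restriction the fraction of remaining weight that is FFM
#' rises from its baseline value `c` and stabilises `ffm_shift` percentage
#' points higher. The original model uses an exponential rise saturating at
#' 10% relative weight loss; the refined model a linear rise saturating at
#' 20%. Both are continuous and non-decreasing, anchored exactly at `c`
#' when `rel_loss = 0` and at `c + ffm_shift/100` at and beyond saturation.
#'
#' @param rel_loss relative weight loss `(w0 - w)/w0`, in `[0, 1)`.
#'   Vectorised.
#' @param c baseline FFM fraction, from [baseline_ffm_fraction()].
#' @param config an [model_config()] object; `config$ffm_trajectory`
#'   selects the functional form.
#' @return FFM fraction of current weight (dimensionless).
#' @examples
#' cfg <- model_config()
#' ffm_fraction_at(c(0, 0.05, 0.10, 0.30), c = 0.55, cfg)
#' @export
ffm_fraction_at <- function(rel_loss, c, config = model_config()) {
  validate_model_config(config)
  if (!is.numeric(rel_loss) || any(!is.finite(rel_loss)) ||
      any(rel_loss < 0)) {
    stop("rel_loss must be >= 0: weight gain is outside model scope",
         call. = FALSE)
  }
  if (any(rel_loss >= 1)) {
    stop("rel_loss must be < 1", call. = FALSE)
  }
  if (!is.numeric(c) || any(c <= 0) || any(c >= 1)) {
    stop("baseline FFM fraction c must lie in (0, 1)", call. = FALSE)
  }
  shift <- config$ffm_shift / 100
  if (config$ffm_trajectory == "exponential_original") {
    x_sat <- config$sat_threshold_original
    k <- exp_shape_k(config, x_sat)
    c + shift * exp_saturating(rel_loss, x_sat, k)
  } else {
    x_sat <- config$sat_threshold_refined
    c + shift * pmin(rel_loss / x_sat, 1)
  }
}

#' Resting energy expenditure from fat-free mass
#'
#' Linear FFM-based prediction equations: Cunningham
#' (`500 + 22 * FFM`) or the FFM-based Mifflin form (`413 + 19.7 * FFM`),
#' with coefficients taken from `config` so they are never hard-coded.
#'
#' @param ffm_kg fat-free mass, kg (> 0). Vectorised.
#' @param config an [model_config()] object; `config$ree_equation` selects
#'   the equation.
#' @return REE in kcal/d.
#' @examples
#' ree(50)                                  # Cunningham: 1600
#' ree(50, model_config("refined"))         # Mifflin: 1398
#' @export
ree <- function(ffm_kg, config = model_config()) {
  validate_model_config(config)
  if (!is.numeric(ffm_kg) || any(!is.finite(ffm_kg)) || any(ffm_kg <= 0)) {
    stop("ffm_kg must be positive fat-free mass in kg", call. = FALSE)
  }
  switch(config$ree_equation,
    cunningham = config$cunningham_intercept +
      config$cunningham_slope * ffm_kg,
    mifflin = config$mifflin_intercept + config$mifflin_slope * ffm_kg
  )
}

#' Adaptive thermogenesis as a function of relative weight loss
#'
#' The underfeeding-associated fall in REE beyond what loss of tissue
#' explains. AT rises exponentially from zero at the onset of weight loss
#' and stabilises at `at_ceiling` (default 15%) of REE once relative weight
#' loss reaches `sat_threshold_original` (default 10%), in both model
#' variants.
#'
#' @param rel_loss relative weight loss `(w0 - w)/w0`, in `[0, 1)`.
#'   Vectorised (recycled against `ree_value`).
#' @param ree_value current REE in kcal/d (> 0).
#' @param config an [model_config()] object.
#' @return AT in kcal/d, in `[0, at_ceiling * ree_value]`.
#' @examples
#' adaptive_thermogenesis(c(0, 0.05, 0.10), 1600)
#' @export
adaptive_thermogenesis <- function(rel_loss, ree_value,
                                   config = model_config()) {
  validate_model_config(config)
  if (!is.numeric(rel_loss) || any(!is.finite(rel_loss)) ||
      any(rel_loss < 0)) {
    stop("rel_loss must be >= 0: weight gain is outside model scope",
         call. = FALSE)
  }
  if (any(rel_loss >= 1)) stop("rel_loss must be < 1", call. = FALSE)
  if (!is.numeric(ree_value) || any(ree_value <= 0)) {
    stop("ree_value must be > 0 kcal/d", call. = FALSE)
  }
  x_sat <- config$sat_threshold_original
  k <- exp_shape_k(config, x_sat)
  config$at_ceiling * ree_value * exp_saturating(rel_loss, x_sat, k)
}

#' Diet-induced thermogenesis
#'
#' The energy cost of digestion, a fixed fraction of energy intake
#' (`dit_coeff`, default 0.05 for an overweight/obese population; 0.10 is
#' typical for lean populations).
#'
#' @param ei energy intake, kcal/d (>= 0). Vectorised.
#' @param config an [model_config()] object.
#' @return DIT in kcal/d.
#' @examples
#' dit(800)   # 40 kcal/d at the default 5% coefficient
#' @export
dit <- function(ei, config = model_config()) {
  validate_model_config(config)
  if (!is.numeric(ei) || any(!is.finite(ei)) || any(ei < 0)) {
    stop("ei must be >= 0 kcal/d", call. = FALSE)
  }
  config$dit_coeff * ei
}

#' Body-composition state at a given weight
#'
#' Algebraic helper tying current weight back to the baseline: relative
#' loss, FFM fraction (via the configured trajectory) and FFM in kg.
#'
#' @param weight current body weight, kg. Vectorised.
#' @param subject an [subject_baseline()] object.
#' @param config an [model_config()] object.
#' @return A data.frame with columns `weight`, `rel_loss`, `ffm_frac`,
#'   `ffm_kg`.
#' @examples
#' s <- subject_baseline(93.31, "female")
#' composition_state(c(93.31, 88, 84), s)
#' @export
composition_state <- function(weight, subject, config = model_config()) {
  stopifnot(inherits(subject, "eb_subject"))
  if (!is.numeric(weight) || any(!is.finite(weight)) || any(weight <= 0)) {
    stop("weight must be > 0 kg", call. = FALSE)
  }
  rel_loss <- (subject$w0 - weight) / subject$w0
  if (any(rel_loss < 0)) {
    stop("weight above starting weight: weight gain is outside model scope",
         call. = FALSE)
  }
  c0 <- baseline_ffm_fraction(subject$w0, subject$sex, config)
  frac <- ffm_fraction_at(rel_loss, c0, config)
  data.frame(weight = weight, rel_loss = rel_loss, ffm_frac = frac,
             ffm_kg = frac * weight)
}

#' Total energy expenditure and its components
#'
#' Splits total daily energy expenditure into AT-adjusted resting
#' expenditure, physical activity and diet-induced thermogenesis:
#' `REE_net = REE(FFM) - AT`, `PAEE = (PAL - 1) * REE_net`,
#' `total = PAL * REE_net + DIT`. AT adjusts REE before the PAL product is
#' taken, so activity expenditure scales with the adapted resting rate.
#'
#' @param weight current body weight, kg. Vectorised.
#' @param ei energy intake, kcal/d (recycled).
#' @param subject an [subject_baseline()] object.
#' @param config an [model_config()] object.
#' @return A data.frame with columns `ree_gross`, `at`, `ree_net`, `paee`,
#'   `dit`, `total` (all kcal/d); components satisfy
#'   `total = ree_net + paee + dit`.
#' @examples
#' s <- subject_baseline(93.31, "female")
#' total_ee(93.31, ei = 800, s)
#' @export
total_ee <- function(weight, ei, subject, config = model_config()) {
  state <- composition_state(weight, subject, config)
  ree_gross <- ree(state$ffm_kg, config)
  at <- adaptive_thermogenesis(state$rel_loss, ree_gross, config)
  ree_net <- ree_gross - at
  paee <- (subject$pal - 1) * ree_net
  dit_v <- dit(ei, config)
  data.frame(
    ree_gross = ree_gross, at = at, ree_net = ree_net, paee = paee,
    dit = rep_len(dit_v, length(ree_net)),
    total = subject$pal * ree_net + dit_v
  )
}
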