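#' Rate of weight change (right-hand side of the weight ODE)
#'
#' The model treats weight as the single state variable: the rate of change
#' is the energy imbalance divided by the tissue energy density,
#' `dw/dt = (EI(t) - TEE(w)) / energy_density`, where total energy
#' expenditure composes the FFM trajectory, the REE equation, adaptive
#' thermogenesis, the PAL multiplier and DIT (see [total_ee()]).
#'
#' Relative loss is always computed against the pre-intervention weight
#' `w0`; tiny negative values arising from solver overshoot at baseline are
#' clamped to zero.
#'
#' @param t time, days.
#' @param w current weight, kg (> 0).
#' @param subject an [subject_baseline()] object.
#' @param schedule an intake schedule ([intake_schedule]).
#' @param config an [model_config()] object.
#' @return dw/dt in kg/d.
#' @examples
#' s <- subject_baseline(93.31, "female")
#' rhs(0, 93.31, s, constant_intake(800))
#' @export
rhs <- function(t, w, subject, schedule, config = model_config()) {
  if (any(w <= 0)) {
    stop("simulation diverged: weight reached zero", call. = FALSE)
  }
  w <- pmin(w, subject$w0)  # guard solver overshoot above baseline
  ei <- ei_at(pmax(t, 0), schedule)
  ee <- total_ee(w, ei, subject, config)
  (ei - ee$total) / config$energy_density
}

# Scalar derivative with all constants precomputed; the hot path of the
# integrator (the exported rhs() re-validates its inputs on every call).
make_deriv <- function(subject, config) {
  w0 <- subject$w0
  pal <- subject$pal
  c0 <- baseline_ffm_fraction(w0, subject$sex, config)
  shift <- config$ffm_shift / 100
  exp_ffm <- config$ffm_trajectory == "exponential_original"
  xs_f <- if (exp_ffm) config$sat_threshold_original else
    config$sat_threshold_refined
  k_f <- exp_shape_k(config, config$sat_threshold_original)
  xs_a <- config$sat_threshold_original
  k_a <- exp_shape_k(config, xs_a)
  ceil_a <- config$at_ceiling
  ri <- if (config$ree_equation == "cunningham") config$cunningham_intercept
        else config$mifflin_intercept
  rs <- if (config$ree_equation == "cunningham") config$cunningham_slope
        else config$mifflin_slope
  dc <- config$dit_coeff
  ed <- config$energy_density
  function(w, ei) {
    if (w <= 0) {
      stop("simulation diverged: weight reached zero", call. = FALSE)
    }
    x <- max(0, (w0 - w) / w0)
    g_f <- if (exp_ffm) {
      min((1 - exp(-k_f * min(x, xs_f))) / (1 - exp(-k_f * xs_f)), 1)
    } else {
      min(x / xs_f, 1)
    }
    ree_v <- ri + rs * (c0 + shift * g_f) * min(w, w0)
    g_a <- min((1 - exp(-k_a * min(x, xs_a))) / (1 - exp(-k_a * xs_a)), 1)
    (ei - (pal * ree_v * (1 - ceil_a * g_a) + dc * ei)) / ed
  }
}

#' Simulate a weight-loss trajectory
#'
#' Integrates the weight ODE over the intervention with an adaptive
#' multistep solver (`deSolve::ode`, lsoda), restarting the integration at
#' every intake-schedule discontinuity so step changes in prescribed intake
#' do not degrade the adaptive stepper. Output is on a daily grid; weekly
#' weigh-in values are the rows at days 7, 14, ... (end-of-week
#' convention).
#'
#' @param subject an [subject_baseline()] object.
#' @param schedule an intake schedule; defaults to a constant schedule at
#'   the subject's baseline intake `ei0`.
#' @param weeks intervention duration in weeks (> 0; validation of the
#'   model used 6-12 week programmes, but any positive duration is
#'   accepted).
#' @param config an [model_config()] object.
#' @param rtol,atol relative and absolute solver tolerances.
#' @return An `eb_trajectory`: a data.frame with one row per day and
#'   columns `t` (days), `weight`, `ffm_kg` (kg), `ree_net`, `at`, `paee`,
#'   `dit`, `ei`, `deficit` (kcal/d; `deficit = TEE - EI`, positive during
#'   restriction).
#' @examples
#' s <- subject_baseline(93.31, "female", pal = 1.6, ei0 = 800)
#' traj <- simulate_weight(s, weeks = 8)
#' tail(traj, 3)
#' @export
simulate_weight <- function(subject, schedule = NULL, weeks,
                            config = model_config(),
                            rtol = 1e-8, atol = 1e-8) {
  stopifnot(inherits(subject, "eb_subject"))
  validate_model_config(config)
  if (!is.numeric(weeks) || length(weeks) != 1 || weeks <= 0) {
    stop("weeks must be a single positive duration", call. = FALSE)
  }
  if (is.null(schedule)) schedule <- constant_intake(subject$ei0)
  stopifnot(inherits(schedule, "eb_intake"))

  t_end <- weeks * 7
  breaks <- intake_break_days(schedule, t_end)
  seg_bounds <- c(0, breaks, t_end)

  deriv <- make_deriv(subject, config)
  times_all <- numeric(0)
  weights_all <- numeric(0)
  w_start <- subject$w0
  for (i in seq_len(length(seg_bounds) - 1)) {
    a <- seg_bounds[i]
    b <- seg_bounds[i + 1]
    # daily grid within the segment plus its exact endpoints
    grid <- sort(unique(c(a, seq(ceiling(a), floor(b)), b)))
    # evaluate intake just inside the segment (half-open switch convention)
    seg_ei <- ei_at(a, schedule)
    seg_deriv <- function(t, y, parms) list(deriv(y[[1]], seg_ei))
    sol <- deSolve::ode(y = c(w = w_start), times = grid, func = seg_deriv,
                        parms = NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
    if (attr(sol, "istate")[1] < 0) {
      stop(sprintf("simulation failed to converge near day %.1f",
                   sol[nrow(sol), "time"]), call. = FALSE)
    }
    if (any(sol[, "w"] <= 0)) {
      bad <- sol[which(sol[, "w"] <= 0)[1], "time"]
      stop(sprintf("simulation diverged: weight reached zero at day %.1f",
                   bad), call. = FALSE)
    }
    w_start <- unname(sol[nrow(sol), "w"])
    keep <- if (i < length(seg_bounds) - 1) {
      sol[, "time"] < b  # segment end re-emitted by the next segment
    } else {
      rep(TRUE, nrow(sol))
    }
    times_all <- c(times_all, sol[keep, "time"])
    weights_all <- c(weights_all, sol[keep, "w"])
  }

  # restrict to the daily grid (segment bounds are integers or t_end)
  on_grid <- times_all %in% unique(c(seq(0, floor(t_end)), t_end))
  t <- times_all[on_grid]
  w <- pmin(weights_all[on_grid], subject$w0)

  ei <- ei_at(t, schedule)
  ee <- total_ee(w, ei, subject, config)
  lean_ffm <- config[[paste0("lean_ref_ffm_frac_", subject$sex)]] *
    config[[paste0("lean_ref_weight_", subject$sex)]]
  state <- composition_state(w, subject, config)
  if (any(state$ffm_kg < lean_ffm)) {
    warning("trajectory crosses below the lean-reference fat-free mass; ",
            "predictions in this range are extrapolations", call. = FALSE)
  }
  traj <- data.frame(
    t = t, weight = w, ffm_kg = state$ffm_kg,
    ree_net = ee$ree_net, at = ee$at, paee = ee$paee, dit = ee$dit,
    ei = ei, deficit = ee$total - ei
  )
  class(traj) <- c("eb_trajectory", "data.frame")
  attr(traj, "subject") <- subject
  traj
}

#' Weekly weigh-in weights from a daily trajectory
#'
#' @param traj an `eb_trajectory` from [simulate_weight()].
#' @return A data.frame with columns `week` and `weight` (kg), read at days
#'   7, 14, ... (end-of-week convention).
#' @export
weekly_weights <- function(traj) {
  stopifnot(inherits(traj, "eb_trajectory"))
  wk_days <- seq(7, max(traj$t), by = 7)
  idx <- match(wk_days, traj$t)
  data.frame(week = wk_days / 7, weight = traj$weight[idx])
}

#' Static 3500-kcal-rule weight-loss prediction
#'
#' The clinical heuristic that a cumulative 3500 kcal deficit equals 1 lb
#' of weight loss, i.e. a constant 500 kcal/d deficit loses about 0.45 kg
#' per week. Energy expenditure is assumed fixed, so the prediction is
#' linear in both deficit and duration; the dynamic model predicts less
#' loss because expenditure falls as weight is lost.
#'
#' @param deficit daily energy deficit, kcal/d (>= 0). Vectorised.
#' @param weeks duration in weeks (>= 0). Vectorised.
#' @return Predicted weight loss in kg.
#' @examples
#' static_prediction(500, 1)    # ~0.45 kg, the "1 lb per week" rule
#' @export
static_prediction <- function(deficit, weeks) {
  if (!is.numeric(deficit) || any(deficit < 0)) {
    stop("deficit must be >= 0 kcal/d", call. = FALSE)
  }
  if (!is.numeric(weeks) || any(weeks < 0)) {
    stop("weeks must be >= 0", call. = FALSE)
  }
  deficit * 7 * weeks / 3500 * 0.45359237
}

#' Energy-conservation closure of a trajectory
#'
#' The ODE guarantees that the time-integral of the daily deficit equals
#' the energy density times the total weight lost; this function measures
#' the relative discrepancy of that identity on the daily output grid, a
#' quick check that integration and component bookkeeping agree. The
#' resting + activity expenditure (continuous in weight) is integrated by
#' trapezoid; intake and DIT, piecewise constant with switches on grid
#' points, are integrated exactly by their left values.
#'
#' @param traj an `eb_trajectory` from [simulate_weight()].
#' @param config the [model_config()] used to produce it.
#' @return Relative error (dimensionless); near zero for a well-resolved
#'   trajectory.
#' @export
energy_closure <- function(traj, config = model_config()) {
  stopifnot(inherits(traj, "eb_trajectory"))
  n <- nrow(traj)
  if (n < 2) stop("trajectory too short", call. = FALSE)
  dt <- diff(traj$t)
  rest <- traj$ree_net + traj$paee
  integral <- sum(dt * (rest[-n] + rest[-1]) / 2) +
    sum(dt * (traj$dit[-n] - traj$ei[-n]))
  lost <- traj$weight[1] - traj$weight[n]
  if (lost == 0 && integral == 0) return(0)
  (integral - config$energy_density * lost) /
    (config$energy_density * max(abs(lost), .Machine$double.eps))
}
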