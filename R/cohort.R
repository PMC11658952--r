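#' Synthetic-cohort specification
#'
#' Parameters of a simulated very-low-energy total-diet-replacement cohort
#' with the statistical structure of a commercial weight-loss programme:
#' female clients with baseline weight ~ truncated Normal(93.31, 19.18) kg,
#' interventions of 6-12 weeks with weekly weigh-ins, an early
#' glycogen-water weight loss the energy model does not capture, and a late
#' compliance drift (extra intake) in longer enrolments.
#'
#' @param n number of subjects (>= 1).
#' @param weight_mean,weight_sd baseline weight distribution, kg.
#' @param weight_min truncation: baseline weights are redrawn until
#'   >= `weight_min` kg.
#' @param age_mean mean age in years (recorded for realism; the energy
#'   model itself is age-free).
#' @param length_weights named numeric vector of enrolment probabilities
#'   over intervention lengths in weeks (names are the weeks; must sum
#'   to 1). The default spans 6-12 weeks with the mode at 8 weeks and the
#'   smallest mass at 12.
#' @param glycogen_bolus_range range (kg) of the per-subject glycogen-water
#'   loss, drawn uniformly; the observed weight falls below the energy
#'   model by this amount, approached with half-life
#'   `glycogen_halflife`.
#' @param glycogen_halflife half-life in days of the approach to full
#'   glycogen-water depletion (default 5 d, so the bolus is essentially
#'   spent within the first 7-10 d).
#' @param compliance_onset_week week from which subjects consume
#'   `compliance_extra_kcal` above prescription (default week 8).
#' @param compliance_extra_kcal extra intake, kcal/d, from the onset week
#'   (a fixture magnitude, not an estimate from data).
#' @param obs_noise_sd SD (kg) of i.i.d. weigh-in measurement noise.
#' @param seed integer seed making the cohort fully reproducible.
#' @return An object of class `eb_cohort_spec`.
#' @examples
#' cohort_spec(n = 10, seed = 1)
#' @export
cohort_spec <- function(n = 100,
                        weight_mean = 93.31,
                        weight_sd = 19.18,
                        weight_min = 45,
                        age_mean = 47,
                        length_weights = c(
                          "6" = 0.13, "7" = 0.15, "8" = 0.18, "9" = 0.16,
                          "10" = 0.15, "11" = 0.145, "12" = 0.085
                        ),
                        glycogen_bolus_range = c(1.5, 2.0),
                        glycogen_halflife = 5,
                        compliance_onset_week = 8,
                        compliance_extra_kcal = 200,
                        obs_noise_sd = 0.3,
                        seed = 1L) {
  if (!is.numeric(n) || length(n) != 1 || n < 1) {
    stop("n must be >= 1", call. = FALSE)
  }
  if (weight_sd < 0) stop("weight_sd must be >= 0", call. = FALSE)
  if (is.null(names(length_weights)) ||
      any(is.na(as.numeric(names(length_weights))))) {
    stop("length_weights must be named by intervention length in weeks",
         call. = FALSE)
  }
  if (any(length_weights < 0) || abs(sum(length_weights) - 1) > 1e-8) {
    stop("length_weights probabilities must be >= 0 and sum to 1",
         call. = FALSE)
  }
  if (length(glycogen_bolus_range) != 2 ||
      glycogen_bolus_range[1] > glycogen_bolus_range[2] ||
      any(glycogen_bolus_range < 0)) {
    stop("glycogen_bolus_range must be a non-negative (low, high) pair",
         call. = FALSE)
  }
  if (glycogen_halflife <= 0) {
    stop("glycogen_halflife must be > 0 days", call. = FALSE)
  }
  if (obs_noise_sd < 0) stop("obs_noise_sd must be >= 0", call. = FALSE)
  if (weight_sd > 0 &&
      weight_min > weight_mean + 6 * weight_sd) {
    stop("infeasible truncation: weight_min far above the distribution",
         call. = FALSE)
  }
  structure(list(
    n = as.integer(n), weight_mean = weight_mean, weight_sd = weight_sd,
    weight_min = weight_min, age_mean = age_mean,
    length_weights = length_weights,
    glycogen_bolus_range = glycogen_bolus_range,
    glycogen_halflife = glycogen_halflife,
    compliance_onset_week = compliance_onset_week,
    compliance_extra_kcal = compliance_extra_kcal,
    obs_noise_sd = obs_noise_sd, seed = as.integer(seed)
  ), class = "eb_cohort_spec")
}

# fraction of the glycogen-water bolus realised by day t: 0 at baseline,
# -> 1 with the configured half-life
bolus_fraction <- function(t, halflife) {
  1 - 2^(-t / halflife)
}

#' Generate a synthetic observed cohort
#'
#' For each subject: draw the starting weight from the truncated normal,
#' draw the intervention length, simulate the latent "true" trajectory with
#' the dynamic model — intake follows `schedule`, plus
#' `compliance_extra_kcal` from `compliance_onset_week` — then overlay a
#' glycogen-water loss (uniform in `glycogen_bolus_range`, approached with
#' half-life `glycogen_halflife`) and i.i.d. weigh-in noise on the weekly
#' observations. The glycogen-water term is an observed-weight offset, not
#' a change to the energy model: it is water, not an energy store.
#'
#' The result is the observed arm only (`predicted_weight` is `NA`); pair
#' it with [add_predictions()] to fill in the nominal model's predictions
#' for evaluation.
#'
#' @param spec a [cohort_spec()].
#' @param config an [model_config()]; the latent truth and (later) the
#'   predictions use the same model, so with all perturbations at zero the
#'   pipeline returns zero error identically.
#' @param schedule the prescribed intake schedule (default: 800 kcal/d,
#'   stepping to 1200 kcal/d at week 10 for food reintroduction).
#' @return A cohort table: one row per subject-week with columns
#'   `subject_id`, `week`, `observed_weight`, `predicted_weight` (`NA`),
#'   `w0`, `intervention_length`. Subject-level draws (age, bolus, length)
#'   are attached as the `"subjects"` attribute.
#' @examples
#' tab <- generate_cohort(cohort_spec(n = 3, seed = 7))
#' head(tab)
#' @export
generate_cohort <- function(spec, config = model_config(),
                            schedule = step_intake()) {
  stopifnot(inherits(spec, "eb_cohort_spec"))
  validate_model_config(config)
  stopifnot(inherits(schedule, "eb_intake"))

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  w0 <- draw_truncated_normal(spec$n, spec$weight_mean, spec$weight_sd,
                              spec$weight_min)
  lengths_avail <- as.numeric(names(spec$length_weights))
  len <- sample(lengths_avail, spec$n, replace = TRUE,
                prob = spec$length_weights)
  age <- round(stats::rnorm(spec$n, spec$age_mean, 10))
  bolus <- stats::runif(spec$n, spec$glycogen_bolus_range[1],
                        spec$glycogen_bolus_range[2])

  rows <- vector("list", spec$n)
  for (i in seq_len(spec$n)) {
    subj <- subject_baseline(w0[i], "female",
                             ei0 = ei_at(0, schedule))
    latent_sched <- perturbed_schedule(schedule, spec, len[i])
    traj <- simulate_weight(subj, latent_sched, weeks = len[i],
                            config = config)
    wk <- weekly_weights(traj)
    observed <- wk$weight -
      bolus[i] * bolus_fraction(wk$week * 7, spec$glycogen_halflife) +
      stats::rnorm(nrow(wk), 0, spec$obs_noise_sd)
    rows[[i]] <- data.frame(
      subject_id = sprintf("S%04d", i), week = wk$week,
      observed_weight = observed, predicted_weight = NA_real_,
      w0 = w0[i], intervention_length = len[i]
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "subjects") <- data.frame(
    subject_id = sprintf("S%04d", seq_len(spec$n)), w0 = w0, age = age,
    intervention_length = len, glycogen_bolus_kg = bolus
  )
  out
}

# Latent-truth intake: prescription plus compliance drift from the onset
# week. With zero drift the nominal schedule object is returned unchanged so
# the noise-free round trip is bit-exact.
perturbed_schedule <- function(schedule, spec, weeks) {
  extra <- spec$compliance_extra_kcal
  onset <- spec$compliance_onset_week
  if (extra == 0 || onset >= weeks + 1) return(schedule)
  breaks <- sort(unique(c(schedule$switch_weeks, onset)))
  levels <- ei_at(pmax(c(0, breaks) * 7, 0), schedule) +
    extra * (c(0, breaks) >= onset)
  piecewise_intake(levels, breaks)
}

draw_truncated_normal <- function(n, mean, sd, min) {
  if (sd == 0) {
    if (mean < min) {
      stop("infeasible truncation: point mass below weight_min",
           call. = FALSE)
    }
    return(rep(mean, n))
  }
  p_keep <- 1 - stats::pnorm(min, mean, sd)
  if (p_keep < 1e-6) {
    stop("infeasible truncation: weight_min above the distribution mass",
         call. = FALSE)
  }
  out <- numeric(0)
  while (length(out) < n) {
    draw <- stats::rnorm(ceiling((n - length(out)) / p_keep * 1.1) + 8,
                         mean, sd)
    out <- c(out, draw[draw >= min])
  }
  out[seq_len(n)]
}

#' Fill in model predictions for an observed cohort
#'
#' Simulates the nominal dynamic model (prescribed schedule, no
#' perturbations) for each subject from their recorded starting weight and
#' writes the weekly predicted weights into `predicted_weight`.
#'
#' @param table a cohort table (from [generate_cohort()] or
#'   [read_cohort_csv()]).
#' @param config an [model_config()].
#' @param schedule the prescribed intake schedule used for prediction.
#' @param sex subject sex assumed for the whole cohort (the validation
#'   cohort is female).
#' @return The table with `predicted_weight` filled.
#' @export
add_predictions <- function(table, config = model_config(),
                            schedule = step_intake(), sex = "female") {
  table <- validate_cohort_table(table, need_predicted = FALSE)
  ids <- unique(table$subject_id)
  for (id in ids) {
    sel <- table$subject_id == id
    w0 <- table$w0[sel][1]
    weeks <- table$intervention_length[sel][1]
    subj <- subject_baseline(w0, sex, ei0 = ei_at(0, schedule))
    wk <- weekly_weights(simulate_weight(subj, schedule, weeks = weeks,
                                         config = config))
    table$predicted_weight[sel] <-
      wk$weight[match(table$week[sel], wk$week)]
  }
  table
}

# internal: save/restore the global RNG state so cohort generation does not
# disturb the caller's random stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
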