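# Independent oracles, written as direct scalar transcriptions of the model
# equations. They deliberately share no code with the package's solver path.

# Fixed-step Euler integration of the weight ODE for a female subject.
# ei_fun(t) gives intake in kcal/d at day t; variant selects the REE
# equation / FFM trajectory pairing.
euler_oracle <- function(w0, pal, ei_fun, days, dt = 0.01,
                         variant = c("original", "refined")) {
  variant <- match.arg(variant)
  c0 <- (0.72 * 60 + 0.25 * (w0 - 60)) / w0
  k <- -log(1 - 0.99) / 0.10
  sat_exp <- function(x, xs) {
    min((1 - exp(-k * min(x, xs))) / (1 - exp(-k * xs)), 1)
  }
  w <- w0
  n <- round(days / dt)
  for (i in seq_len(n)) {
    t <- (i - 1) * dt
    x <- max(0, (w0 - w) / w0)
    frac <- if (variant == "original") {
      c0 + 0.10 * sat_exp(x, 0.10)
    } else {
      c0 + 0.10 * min(x / 0.20, 1)
    }
    ree_v <- if (variant == "original") {
      500 + 22 * frac * w
    } else {
      413 + 19.7 * frac * w
    }
    at_v <- 0.15 * ree_v * sat_exp(x, 0.10)
    ei <- ei_fun(t)
    tee <- pal * (ree_v - at_v) + 0.05 * ei
    w <- w + dt * (ei - tee) / 7700
  }
  w
}

# Intake of the very-low-energy programme: 800 kcal/d before day 70,
# 1200 kcal/d from day 70 (week 10) onwards.
ll_ei <- function(t) if (t < 70) 800 else 1200

# Reference subject used across tests: the cohort-mean female client.
ref_subject <- function(ei0 = 800) {
  subject_baseline(93.31, "female", pal = 1.6, ei0 = ei0)
}

# Energy intake that exactly balances baseline expenditure, so the
# trajectory should stay flat: EI = pal*REE0 / (1 - dit_coeff).
balancing_intake <- function(subject, config = model_config()) {
  c0 <- baseline_ffm_fraction(subject$w0, subject$sex, config)
  ree0 <- ree(c0 * subject$w0, config)
  subject$pal * ree0 / (1 - config$dit_coeff)
}

# Intake giving a prescribed baseline deficit (positive = restriction).
intake_for_deficit <- function(subject, deficit,
                               config = model_config()) {
  balancing_intake(subject, config) -
    deficit / (1 - config$dit_coeff)
}
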