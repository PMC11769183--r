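#' Beat morphology template
#'
#' Describes one PQRST heartbeat as five Gaussian bumps. Each wave has a center
#' offset in seconds relative to the R peak, an amplitude in mV-scaled arbitrary
#' units, and a Gaussian width (standard deviation) in seconds. The defaults
#' sketch a textbook-like upright sinus beat: a small P wave, a sharp dominant
#' R with narrow Q and S deflections, and a broader T wave.
#'
#' @param p,q,r,s,t Numeric vectors `c(center, amplitude, width)` per wave.
#' @return A tibble of class `beat_template` with columns `wave`, `center`,
#'   `amplitude`, `width`.
#' @examples
#' beat_template()
#' @export
beat_template <- function(p = c(-0.20, 0.15, 0.040),
                          q = c(-0.045, -0.10, 0.015),
                          r = c(0.00, 1.00, 0.020),
                          s = c(0.045, -0.25, 0.015),
                          t = c(0.30, 0.35, 0.060)) {
  waves <- list(P = p, Q = q, R = r, S = s, T = t)
  for (w in names(waves)) {
    assert_that(length(waves[[w]]) == 3 && all(is.finite(waves[[w]])),
                paste0("wave ", w, " must be c(center, amplitude, width)"))
  }
  out <- tibble(
    wave = names(waves),
    center = map_dbl(waves, 1),
    amplitude = map_dbl(waves, 2),
    width = map_dbl(waves, 3)
  )
  assert_that(all(out$width > 0), "wave widths must be strictly positive")
  assert_that(out$amplitude[out$wave == "R"] > 0, "R amplitude must be strictly positive")
  class(out) <- c("beat_template", class(out))
  out
}

#' RR-interval model
#'
#' Parameterizes the beat-to-beat interval distribution that encodes a
#' subject's autonomic state: mean RR interval and SDNN (the standard
#' deviation of RR intervals), the two first-order heart-rate-variability
#' summaries. Intervals are drawn i.i.d. Gaussian by default; an AR(1) option
#' introduces serial correlation while preserving the marginal mean/SDNN.
#'
#' @param mean_rr Mean RR interval in seconds (> 0).
#' @param sdnn Standard deviation of RR intervals in seconds (>= 0).
#' @param method `"iid"` (default) or `"ar1"`.
#' @param ar AR(1) coefficient in (-1, 1); used when `method = "ar1"`.
#' @param floor Positive lower bound for sampled intervals (s); draws below it
#'   are clipped so no interval can be non-positive.
#' @param seed Optional default seed used by [generate_rr_series()].
#' @return A list of class `rr_model`.
#' @export
rr_model <- function(mean_rr = 0.8, sdnn = 0.06, method = c("iid", "ar1"),
                     ar = 0.4, floor = 0.3, seed = NULL) {
  method <- match.arg(method)
  assert_that(is_number(mean_rr) && mean_rr > 0, "mean_rr must be a positive number")
  assert_that(is_number(sdnn) && sdnn >= 0, "sdnn must be a non-negative number")
  assert_that(is_number(floor) && floor > 0, "floor must be positive")
  assert_that(is_number(ar) && abs(ar) < 1, "ar must lie in (-1, 1)")
  structure(list(mean_rr = mean_rr, sdnn = sdnn, method = method, ar = ar,
                 floor = floor, seed = seed),
            class = "rr_model")
}

#' Generate a seeded RR-interval series
#'
#' @param model An [rr_model()].
#' @param n_beats Number of intervals to draw (>= 1).
#' @param seed Integer seed; defaults to the model's own seed. The function is
#'   a pure function of `(model, n_beats, seed)`.
#' @return Numeric vector of `n_beats` strictly positive intervals in seconds.
#' @examples
#' generate_rr_series(rr_model(0.8, 0.05), 5, seed = 1)
#' @export
generate_rr_series <- function(model, n_beats, seed = model$seed) {
  assert_that(inherits(model, "rr_model"), "model must be an rr_model")
  assert_that(is_count(n_beats), "n_beats must be a positive integer")
  with_seed(seed, {
    z <- if (model$method == "iid") {
      rnorm(n_beats)
    } else {
      e <- rnorm(n_beats)
      out <- numeric(n_beats)
      out[1] <- e[1]
      if (n_beats > 1) {
        a <- model$ar
        s <- sqrt(1 - a^2)
        for (i in 2:n_beats) out[i] <- a * out[i - 1] + s * e[i]
      }
      out
    }
    rr <- model$mean_rr + model$sdnn * z
    pmax(rr, model$floor)
  })
}

#' Render a clean ECG waveform from RR intervals
#'
#' Places one template beat at each cumulative RR time and sums the Gaussian
#' wave bumps on a uniform sampling grid. The output is deterministic; total
#' duration is `sum(rr)` seconds, floored to whole samples.
#'
#' @param rr Numeric vector of positive RR intervals (s).
#' @param template A [beat_template()].
#' @param fs Sampling rate in Hz (default 130, the target device rate).
#' @return Numeric vector of `floor(sum(rr) * fs)` samples.
#' @export
render_ecg <- function(rr, template = beat_template(), fs = 130) {
  assert_that(is.numeric(rr) && length(rr) >= 1, "rr must be a non-empty numeric vector")
  assert_that(all(rr > 0), "all RR intervals must be positive")
  assert_that(is_number(fs) && fs > 0, "fs must be positive")
  n <- floor(sum(rr) * fs)
  x <- numeric(n)
  centers <- cumsum(rr)
  for (ci in centers) {
    for (wi in seq_len(nrow(template))) {
      c0 <- ci + template$center[wi]
      w <- template$width[wi]
      lo <- max(1L, floor((c0 - 5 * w) * fs) + 1L)
      hi <- min(n, ceiling((c0 + 5 * w) * fs) + 1L)
      if (lo > hi) next
      tt <- (seq(lo, hi) - 1) / fs
      x[lo:hi] <- x[lo:hi] + template$amplitude[wi] * exp(-(tt - c0)^2 / (2 * w^2))
    }
  }
  x
}

#' Additive noise specification
#'
#' Three noise sources routinely present in wearable ECG: broadband white
#' noise, low-frequency baseline wander (respiration/electrode drift), and
#' powerline interference.
#'
#' @param white_sd Standard deviation of Gaussian white noise.
#' @param wander_amp,wander_freq Amplitude and frequency (Hz) of a sinusoidal
#'   baseline wander component.
#' @param powerline_amp,powerline_freq Amplitude and frequency (Hz) of the
#'   mains interference sinusoid (50 Hz default).
#' @return A list of class `noise_spec`.
#' @export
noise_spec <- function(white_sd = 0.05, wander_amp = 0.15, wander_freq = 0.3,
                       powerline_amp = 0.05, powerline_freq = 50) {
  vals <- c(white_sd, wander_amp, wander_freq, powerline_amp, powerline_freq)
  assert_that(all(is.finite(vals)) && all(vals >= 0),
              "all noise amplitudes and frequencies must be non-negative")
  structure(list(white_sd = white_sd, wander_amp = wander_amp,
                 wander_freq = wander_freq, powerline_amp = powerline_amp,
                 powerline_freq = powerline_freq),
            class = "noise_spec")
}

#' Add seeded noise to a clean signal
#'
#' @param clean Numeric sample vector.
#' @param spec A [noise_spec()]. An all-zero spec returns the input unchanged.
#' @param fs Sampling rate in Hz.
#' @param seed Integer seed (white noise and sinusoid phases).
#' @return Numeric vector of the same length as `clean`.
#' @export
add_noise <- function(clean, spec = noise_spec(), fs = 130, seed = NULL) {
  assert_that(inherits(spec, "noise_spec"), "spec must be a noise_spec")
  assert_that(is.numeric(clean), "clean must be numeric")
  n <- length(clean)
  with_seed(seed, {
    phases <- runif(2, 0, 2 * pi)
    tt <- (seq_len(n) - 1) / fs
    out <- clean +
      spec$wander_amp * sin(2 * pi * spec$wander_freq * tt + phases[1]) +
      spec$powerline_amp * sin(2 * pi * spec$powerline_freq * tt + phases[2])
    if (spec$white_sd > 0) out <- out + rnorm(n, 0, spec$white_sd)
    out
  })
}

# Monotone VAS trajectory over the session's rating points; fatigue subjects
# end above the 80% threshold, non-fatigue subjects stay at or below it.
vas_trajectory <- function(class, n_points = 7, seed = NULL) {
  with_seed(seed, {
    start <- runif(1, 5, 20)
    final <- if (class == "F") runif(1, 85, 97) else runif(1, 35, 72)
    mid <- sort(runif(n_points - 2))
    c(start, start + (final - start) * mid, final)
  })
}

#' Default class-conditional RR models
#'
#' Fixture defaults for the two label classes: the fatigue class is slower and
#' less variable (mean RR 0.90 s, SDNN 0.02 s) than the non-fatigue class
#' (mean RR 0.80 s, SDNN 0.06 s), giving a learnable, physiologically
#' plausible HRV contrast. These are synthetic-fixture parameters, not
#' estimates from any real cohort.
#'
#' @return Named list with elements `F` and `N`, each an [rr_model()].
#' @export
default_class_params <- function() {
  list(F = rr_model(mean_rr = 0.90, sdnn = 0.02),
       N = rr_model(mean_rr = 0.80, sdnn = 0.06))
}

#' Generate a labeled synthetic cohort
#'
#' Produces one ECG record per subject: a clean rendered waveform driven by the
#' subject's class-conditional RR model, plus configurable additive noise, a
#' monotone VAS trajectory (crossing the 80% fatigue threshold for F
#' subjects), and demographics drawn to mirror a young athletic cohort (ages
#' uniform on 18--27, male:female 2:1).
#'
#' @param n_subjects Number of subjects (>= 2; both classes are represented).
#' @param class_params Named list `list(F = rr_model(...), N = rr_model(...))`.
#' @param duration_s Record duration per subject in seconds; the default
#'   300 s mirrors a five-minute resting ECG collection window.
#' @param noise A [noise_spec()].
#' @param template A [beat_template()].
#' @param seed Integer seed; the whole cohort is a pure function of the
#'   arguments including this seed.
#' @param fs Sampling rate (Hz).
#' @return A tibble of class `fatigue_cohort`, one row per record, with
#'   list-columns `clean` (noise-free reference), `ecg` (observed signal) and
#'   `vas_trajectory`.
#' @examples
#' cohort <- generate_cohort(n_subjects = 2, duration_s = 20, seed = 1)
#' cohort[, c("subject_id", "class", "age", "gender", "vas")]
#' @export
generate_cohort <- function(n_subjects = 20,
                            class_params = default_class_params(),
                            duration_s = 300,
                            noise = noise_spec(),
                            template = beat_template(),
                            seed = 1,
                            fs = 130) {
  assert_that(is_count(n_subjects) && n_subjects >= 2,
              "n_subjects must be an integer >= 2 (both classes must be represented)")
  assert_that(all(c("F", "N") %in% names(class_params)) &&
                all(map_lgl_(class_params[c("F", "N")], inherits, "rr_model")),
              "class_params must name rr_models for classes F and N")
  assert_that(is_number(duration_s) && duration_s > 0, "duration_s must be positive")
  classes <- rep(c("F", "N"), length.out = n_subjects)
  n_target <- floor(duration_s * fs)
  rows <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    cls <- classes[i]
    model <- class_params[[cls]]
    s_demo <- derive_seed(seed, i, "demo")
    demo <- with_seed(s_demo, {
      list(age = sample(18:27, 1),
           gender = sample(c("male", "female"), 1, prob = c(2, 1) / 3))
    })
    n_beats <- ceiling(duration_s / model$mean_rr) + 8L
    rr <- generate_rr_series(model, n_beats, seed = derive_seed(seed, i, "rr"))
    clean <- render_ecg(rr, template = template, fs = fs)
    if (length(clean) < n_target) clean <- c(clean, numeric(n_target - length(clean)))
    clean <- clean[seq_len(n_target)]
    noisy <- add_noise(clean, noise, fs = fs, seed = derive_seed(seed, i, "noise"))
    vtraj <- vas_trajectory(cls, seed = derive_seed(seed, i, "vas"))
    rows[[i]] <- tibble(
      subject_id = sprintf("S%02d", i),
      class = cls,
      age = as.integer(demo$age),
      gender = demo$gender,
      vas = vtraj[length(vtraj)],
      vas_trajectory = list(vtraj),
      fs = fs,
      n_samples = n_target,
      clean = list(clean),
      ecg = list(noisy)
    )
  }
  out <- bind_rows(rows)
  class(out) <- c("fatigue_cohort", class(out))
  out
}

# vapply wrapper (avoids importing purrr::map_lgl under a clashing name)
map_lgl_ <- function(x, f, ...) vapply(x, f, logical(1), ...)

#' Detect R peaks by threshold and local maximum
#'
#' A deliberately simple detector: candidate samples exceed a fraction of the
#' signal's maximum and are local maxima; detections closer than a refractory
#' interval keep only the larger peak. Adequate for clean or denoised synthetic
#' signals; used to recover per-record mean RR.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate (Hz).
#' @param threshold Fraction of `max(x)` a peak must exceed.
#' @param refractory_s Minimum separation between peaks in seconds.
#' @return Integer vector of 1-based peak sample indices.
#' @export
detect_rpeaks <- function(x, fs = 130, threshold = 0.5, refractory_s = 0.25) {
  n <- length(x)
  if (n < 3) return(integer(0))
  thr <- threshold * max(x)
  cand <- which(x[2:(n - 1)] > thr &
                  x[2:(n - 1)] >= x[1:(n - 2)] &
                  x[2:(n - 1)] >= x[3:n]) + 1L
  if (length(cand) == 0) return(integer(0))
  min_gap <- round(refractory_s * fs)
  keep <- integer(0)
  for (i in cand) {
    if (length(keep) == 0 || i - keep[length(keep)] >= min_gap) {
      keep <- c(keep, i)
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i
    }
  }
  keep
}
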