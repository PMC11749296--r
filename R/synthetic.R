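#' Configure the synthetic PBH-CGM generator
#'
#' The generator emulates the CGM signature of post-bariatric
#' hypoglycaemia: a stable basal profile, rapid meal-induced rises, and —
#' after a fraction of meals — a sharp drop below 54 mg/dL arriving 90–150
#' minutes after the meal, plus first-order sensor noise and random data
#' gaps. Defaults are calibrated to the cohort statistics the pipeline is
#' designed for: mean glucose near 107 mg/dL, roughly 4 Level-2 episodes
#' per 10 monitoring days with median duration 25 min, and about 1% of
#' time below 54 mg/dL.
#'
#' @param n_subjects cohort size.
#' @param days_per_subject monitoring days per subject.
#' @param meals_per_day meals per day, placed in evenly spaced daytime
#'   windows (no overnight meals).
#' @param pbh_prob_per_meal probability that a meal ends in a
#'   hypoglycaemic dip.
#' @param basal_mean,basal_sd basal glucose level and the SD of the
#'   mean-reverting fluctuation around it (mg/dL).
#' @param basal_halflife_min reversion half-life of the basal process.
#' @param rise_amplitude,time_to_peak ranges for the meal excursion
#'   height (mg/dL) and rise time (min).
#' @param dip_delay range of dip onset, minutes after the meal.
#' @param dip_depth range of the dip's depth below 54 mg/dL.
#' @param dip_duration range of time spent below 54 mg/dL, minutes.
#' @param noise_sd,noise_ar1 marginal SD and AR(1) coefficient of the
#'   sensor noise.
#' @param gap_rate expected data gaps per day.
#' @param gap_length range of gap lengths, minutes.
#' @param seed master seed; per-subject seeds are `seed + subject index`.
#' @return a validated `sim_config`.
#' @export
sim_config <- function(n_subjects = 47, days_per_subject = 39, meals_per_day = 4,
                       pbh_prob_per_meal = 0.10,
                       basal_mean = 100, basal_sd = 5, basal_halflife_min = 120,
                       rise_amplitude = c(60, 140), time_to_peak = c(30, 60),
                       dip_delay = c(90, 150), dip_depth = c(5, 15),
                       dip_duration = c(15, 35),
                       noise_sd = 3, noise_ar1 = 0.7,
                       gap_rate = 0.3, gap_length = c(10, 120),
                       seed = 1L) {
  cfg <- list(
    n_subjects = n_subjects, days_per_subject = days_per_subject,
    meals_per_day = meals_per_day, pbh_prob_per_meal = pbh_prob_per_meal,
    basal_mean = basal_mean, basal_sd = basal_sd,
    basal_halflife_min = basal_halflife_min,
    rise_amplitude = rise_amplitude, time_to_peak = time_to_peak,
    dip_delay = dip_delay, dip_depth = dip_depth, dip_duration = dip_duration,
    noise_sd = noise_sd, noise_ar1 = noise_ar1,
    gap_rate = gap_rate, gap_length = gap_length, seed = as.integer(seed)
  )
  stopifnot(
    n_subjects >= 0, days_per_subject > 0, meals_per_day >= 0,
    pbh_prob_per_meal >= 0, pbh_prob_per_meal <= 1,
    basal_sd >= 0, noise_sd >= 0, abs(noise_ar1) < 1,
    gap_rate >= 0, all(dip_duration > 0), all(dip_depth > 0),
    all(dip_delay >= 0)
  )
  structure(cfg, class = "sim_config")
}

#' Simulate one subject's CGM trace with ground truth
#'
#' Builds a deterministic glucose curve (basal mean-reverting process plus
#' per-meal excursion kernels and, for dip meals, a forced excursion below
#' 54 mg/dL), records the intended episodes from that curve, then adds
#' AR(1) sensor noise, clips to the sensor range [40, 400] mg/dL and masks
#' random gaps. Fully reproducible from `subject_seed`.
#'
#' @param config a [sim_config()].
#' @param subject_seed integer seed for this subject.
#' @param subject_id trace label.
#' @return list with elements `trace` (a [cgm_trace()]) and `truth` (list
#'   with `meal_min` and tibble `episodes`: the below-54 runs of the
#'   noise-free curve).
#' @export
simulate_subject <- function(config, subject_seed, subject_id = paste0("S", subject_seed)) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(as.integer(subject_seed), {
    step <- 5
    n <- config$days_per_subject * 288L
    t_min <- (seq_len(n) - 1) * step

    # basal mean-reverting fluctuation around basal_mean
    determ <- rep(config$basal_mean, n)
    if (config$basal_sd > 0) {
      phi <- 2^(-step / config$basal_halflife_min)
      innov <- stats::rnorm(n, 0, config$basal_sd * sqrt(1 - phi^2))
      x0 <- stats::rnorm(1, 0, config$basal_sd)
      determ <- determ + as.numeric(stats::filter(innov, phi, "recursive", init = x0))
    }

    # meal excursions and dips
    meal_min <- numeric(0)
    dips <- list()
    if (config$meals_per_day > 0) {
      win_h <- seq(7, 19, length.out = config$meals_per_day)
      for (day in seq_len(config$days_per_subject) - 1) {
        for (h in win_h) {
          m <- day * 1440 + (h + stats::runif(1)) * 60
          meal_min <- c(meal_min, m)
          amp <- stats::runif(1, config$rise_amplitude[1], config$rise_amplitude[2])
          tpk <- stats::runif(1, config$time_to_peak[1], config$time_to_peak[2])
          determ <- determ + meal_kernel(t_min, m, amp, tpk)
          if (stats::runif(1) < config$pbh_prob_per_meal) {
            delay <- stats::runif(1, config$dip_delay[1], config$dip_delay[2])
            depth <- stats::runif(1, config$dip_depth[1], config$dip_depth[2])
            dur <- 5 * max(1, round(stats::runif(1, config$dip_duration[1], config$dip_duration[2]) / 5))
            dips[[length(dips) + 1L]] <- list(start_min = round((m + delay) / 5) * 5,
                                              depth = depth, dur = dur)
          }
        }
      }
    }
    for (dp in dips) {
      i0 <- dp$start_min / 5 + 1
      i1 <- i0 + dp$dur / 5 - 1
      if (i0 > n) next
      i1 <- min(i1, n)
      determ[i0:i1] <- 54 - dp$depth
      if (i0 > 1) determ[i0 - 1] <- (max(determ[i0 - 1], 54) + 54) / 2
      if (i1 < n) determ[i1 + 1] <- (max(determ[i1 + 1], 54) + 54) / 2
    }

    truth_runs <- run_bounds(determ < 54)
    episodes <- tibble::tibble(
      subject_id = subject_id,
      onset = truth_runs$start, end = truth_runs$end,
      onset_min = t_min[truth_runs$start],
      duration_min = (truth_runs$end - truth_runs$start + 1L) * step
    )

    # AR(1) sensor noise
    glucose <- determ
    if (config$noise_sd > 0) {
      if (abs(config$noise_ar1) > 0) {
        innov <- stats::rnorm(n, 0, config$noise_sd * sqrt(1 - config$noise_ar1^2))
        e0 <- stats::rnorm(1, 0, config$noise_sd)
        glucose <- glucose + as.numeric(stats::filter(innov, config$noise_ar1, "recursive", init = e0))
      } else {
        glucose <- glucose + stats::rnorm(n, 0, config$noise_sd)
      }
    }
    glucose <- pmin(pmax(glucose, 40), 400)

    # random data gaps
    status <- rep("observed", n)
    n_gaps <- stats::rpois(1, config$gap_rate * config$days_per_subject)
    if (n_gaps > 0) {
      for (g in seq_len(n_gaps)) {
        len <- max(1, round(stats::runif(1, config$gap_length[1], config$gap_length[2]) / 5))
        start <- sample.int(n, 1)
        idx <- start:min(start + len - 1, n)
        glucose[idx] <- NA_real_
        status[idx] <- "missing"
      }
    }

    list(
      trace = cgm_trace(subject_id, glucose, status),
      truth = list(meal_min = meal_min, episodes = episodes)
    )
  })
}

# smooth rise to `amp` over `tpk` minutes, symmetric fall back to baseline
meal_kernel <- function(t_min, m, amp, tpk) {
  s <- t_min - m
  k <- numeric(length(t_min))
  up <- s >= 0 & s <= tpk
  down <- s > tpk & s <= 2 * tpk
  k[up] <- amp / 2 * (1 - cos(pi * s[up] / tpk))
  k[down] <- amp / 2 * (1 + cos(pi * (s[down] - tpk) / tpk))
  k
}

#' Simulate a cohort
#'
#' Independent subjects with seeds `config$seed + 1, ..., config$seed + n`;
#' permuting subject order never changes an individual subject's trace.
#'
#' @param config a [sim_config()].
#' @return tibble with one row per subject: `subject_id`, list-columns
#'   `trace` and `truth`.
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  if (config$n_subjects == 0) {
    return(tibble::tibble(subject_id = character(0), trace = list(), truth = list()))
  }
  ids <- sprintf("S%02d", seq_len(config$n_subjects))
  sims <- purrr::map2(seq_len(config$n_subjects), ids, function(k, id) {
    simulate_subject(config, config$seed + k, id)
  })
  tibble::tibble(
    subject_id = ids,
    trace = purrr::map(sims, "trace"),
    truth = purrr::map(sims, "truth")
  )
}

#' Bind a cohort's traces into one multi-subject trace
#'
#' @param cohort tibble from [simulate_cohort()].
#' @return a [cgm_trace()] stacking all subjects.
#' @export
cohort_trace <- function(cohort) {
  new_cgm_trace(dplyr::bind_rows(cohort$trace))
}

#' Clairvoyant (perfect-information) forecaster
#'
#' An oracle forecaster for end-to-end testing: its "prediction" at origin
#' `t` is the true future value, `yhat(t + 5k | t) = y(t + 5k)`. On a
#' noiseless simulated cohort it bounds what any real forecaster can
#' achieve (MAE 0, recall 100%, no false alarms).
#'
#' @return object of class `clairvoyant_model` usable with
#'   [forecast_stream()].
#' @export
clairvoyant_model <- function() {
  structure(list(), class = "clairvoyant_model")
}

#' @rdname forecast_stream
#' @export
forecast_stream.clairvoyant_model <- function(model, trace, steps = 6, ...) {
  assert_trace(trace)
  out <- list()
  for (id in unique(trace$subject_id)) {
    y <- trace$glucose[trace$subject_id == id]
    tm <- trace$time_min[trace$subject_id == id]
    if (anyNA(y)) stop("clairvoyant forecaster needs a fully observed trace")
    n <- length(y)
    if (n <= steps) next
    origins <- seq_len(n - steps)
    pred <- vapply(seq_len(steps), function(k) y[origins + k], numeric(length(origins)))
    if (length(origins) == 1) pred <- matrix(pred, nrow = 1)
    out[[id]] <- forecast_tibble(id, origins, tm[origins], pred)
  }
  dplyr::bind_rows(out)
}
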