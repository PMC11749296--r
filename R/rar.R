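#' Recursive first-order autoregressive glucose forecaster
#'
#' The run-to-run forecaster at the centre of the package: a first-order
#' autoregressive model `y(t) = a * y(t-1) + e(t)` whose coefficient is
#' re-estimated online by exponentially-weighted recursive least squares
#' every time a new CGM sample arrives. The forgetting factor `mu` in
#' (0, 1) discounts a sample that is `tau` steps old by `mu^tau`, giving an
#' effective memory of `tau = 1/(1 - mu)` samples; at the default
#' `mu = 0.675` that is about 3 samples (15 min), which is what lets the
#' model track the very fast post-meal glucose drops that characterise
#' post-bariatric hypoglycaemia.
#'
#' Multi-step forecasts are produced by iterating the one-step prediction:
#' `yhat(t + k | t) = a^k * y(t)`.
#'
#' @param mu forgetting factor in (0, 1).
#' @param a0 initial AR coefficient. 1 (persistence) is the safe cold
#'   start for CGM: before any evidence arrives the forecast is flat.
#' @param p0 initial estimation covariance; large values make the prior
#'   weak.
#' @param burn_in number of updates required before the model will issue a
#'   forecast.
#' @return an object of class `rar_model` holding the adaptive state.
#' @export
rar_model <- function(mu = 0.675, a0 = 1, p0 = 1e3, burn_in = 3) {
  stopifnot(mu > 0, mu < 1, p0 > 0, burn_in >= 0)
  structure(
    list(mu = mu, a = a0, P = p0, a0 = a0, p0 = p0, burn_in = burn_in, n_updates = 0L),
    class = "rar_model"
  )
}

#' One recursive least-squares update of the rAR coefficient
#'
#' Exponentially-weighted RLS for the scalar regression of `y_new` on
#' `y_prev`. The textbook gain form
#' \preformatted{
#'   k <- P * y_prev / (mu + y_prev^2 * P)
#'   a <- a + k * (y_new - a * y_prev)
#'   P <- (P - k * y_prev * P) / mu
#' }
#' is carried out in information form (tracking `R = 1/P`, which stays
#' bounded where `P` grows like `mu^-t`), an algebraically identical
#' update that is numerically exact against the batch weighted
#' least-squares solution. After any sequence of updates the coefficient
#' equals the minimiser of the exponentially-discounted squared one-step
#' prediction error (with the ridge prior implied by `a0`, `p0`).
#'
#' @param model an [rar_model()].
#' @param y_prev,y_new consecutive glucose samples (mg/dL).
#' @return the updated model.
#' @export
rar_update <- function(model, y_prev, y_new) {
  stopifnot(inherits(model, "rar_model"))
  if (!is.finite(y_prev) || !is.finite(y_new)) {
    stop("rar_update: non-finite input")
  }
  r <- model$mu / model$P + y_prev^2
  model$a <- model$a + y_prev * (y_new - model$a * y_prev) / r
  model$P <- 1 / r
  model$n_updates <- model$n_updates + 1L
  model
}

#' Multi-step rAR forecast from the current sample
#'
#' @param model an [rar_model()] that has seen at least `burn_in` updates.
#' @param y_t current glucose (mg/dL).
#' @param steps number of 5-min steps ahead (1..6, i.e. up to 30 min).
#' @return numeric vector of length `steps`; entry `k` is
#'   `yhat(t + 5k | t) = a^k * y_t`.
#' @export
rar_forecast <- function(model, y_t, steps = 6) {
  stopifnot(inherits(model, "rar_model"), steps >= 1, steps <= 6)
  if (model$n_updates < model$burn_in) {
    stop(insufficient_history("rAR forecaster has not met its burn-in"))
  }
  model$a^seq_len(steps) * y_t
}

insufficient_history <- function(msg) {
  structure(
    class = c("pbh_insufficient_history", "error", "condition"),
    list(message = msg, call = sys.call(-1))
  )
}

# reset adaptive state, keeping the configuration
rar_reset <- function(model) {
  model$a <- model$a0
  model$P <- model$p0
  model$n_updates <- 0L
  model
}

#' Effective memory of a forgetting factor
#'
#' `tau = 1/(1 - mu)`: samples older than `tau` steps carry weight below
#' `mu^tau` and have little influence on the estimate. `floor(tau)` is the
#' number of most recent samples that dominate the fit.
#'
#' @param mu forgetting factor in (0, 1).
#' @return `tau` in samples.
#' @export
rar_effective_memory <- function(mu) {
  stopifnot(mu > 0, mu < 1)
  1 / (1 - mu)
}

#' Select the rAR forgetting factor on training data
#'
#' Grid search over `mu`, scoring each candidate by the sum of squared
#' one-step-ahead prediction errors accumulated in a left-to-right pass
#' over the training traces (prediction-error method). Errors during each
#' model's burn-in are not scored. One population-wise `mu` is returned;
#' the coefficient itself always adapts per subject at run time.
#'
#' @param trace a training [cgm_trace()] (gaps already interpolated).
#' @param mu_grid candidate forgetting factors.
#' @param ... passed to [rar_model()] (`a0`, `p0`, `burn_in`).
#' @return an [rar_model()] with the selected `mu`; attribute `"scores"`
#'   holds the per-candidate tibble.
#' @export
fit_rar <- function(trace, mu_grid = seq(0.1, 0.9, by = 0.025), ...) {
  assert_trace(trace)
  sse <- vapply(mu_grid, function(mu) rar_sse(trace, rar_model(mu = mu, ...)), numeric(1))
  scores <- tibble::tibble(mu = mu_grid, sse = sse)
  best <- rar_model(mu = mu_grid[which.min(sse)], ...)
  attr(best, "scores") <- scores
  best
}

rar_sse <- function(trace, model) {
  total <- 0
  for (id in unique(trace$subject_id)) {
    y <- trace$glucose[trace$subject_id == id]
    st <- model
    gap_run <- 0L
    for (t in seq_along(y)[-1]) {
      if (is.na(y[t]) || is.na(y[t - 1])) {
        gap_run <- gap_run + is.na(y[t])
        if (gap_run >= 6L) st <- rar_reset(st)
        next
      }
      gap_run <- 0L
      if (st$n_updates >= st$burn_in) {
        total <- total + (y[t] - st$a * y[t - 1])^2
      }
      st <- rar_update(st, y[t - 1], y[t])
    }
  }
  total
}

#' @exportS3Method generics::tidy
tidy.rar_model <- function(x, ...) {
  tibble::tibble(term = c("a", "mu"), estimate = c(x$a, x$mu))
}

#' @exportS3Method generics::glance
glance.rar_model <- function(x, ...) {
  tibble::tibble(
    mu = x$mu,
    effective_memory = rar_effective_memory(x$mu),
    a = x$a,
    P = x$P,
    n_updates = x$n_updates
  )
}
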