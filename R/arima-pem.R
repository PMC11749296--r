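#' Fit a population ARIMA glucose model by the prediction-error method
#'
#' Fits one ARIMA(p, d, q) coefficient set to the pooled training segments
#' of all subjects by minimising the conditional sum of squared
#' one-step-ahead prediction errors. Each maximal run of contiguous
#' non-missing samples is treated as an independent realisation: the
#' error recursion restarts at every segment, so no prediction-error term
#' ever spans a data gap or a subject boundary.
#'
#' The default order (3, 1, 1) means the last three differenced samples
#' and one lagged innovation drive the one-step prediction — an effective
#' memory similar to the rAR forecaster's.
#'
#' @param trace a training [cgm_trace()].
#' @param order integer vector `c(p, d, q)`.
#' @param min_total minimum pooled sample count required to fit.
#' @return object of class `arima_pem` with elements `phi`, `theta`,
#'   `order`, `sigma2`, `n_obs`, `convergence`.
#' @export
fit_arima_pem <- function(trace, order = c(3, 1, 1), min_total = 500) {
  assert_trace(trace)
  p <- order[1]; d <- order[2]; q <- order[3]
  stopifnot(p >= 0, d >= 0, q >= 0, p + q > 0)
  segs <- trace_segments(trace, min_len = p + d + q + 5L)
  w <- lapply(segs, function(y) diff_d(y, d))
  n_obs <- sum(lengths(w))
  if (n_obs < min_total) {
    stop("pooled training data too short to fit ARIMA (", n_obs, " < ", min_total, " samples)")
  }
  # with no differencing the process has a level: fit around the pooled mean
  level <- if (d == 0) mean(unlist(w)) else 0
  if (d == 0) w <- lapply(w, function(x) x - level)
  fit <- css_fit(w, p, q)
  if (fit$convergence != 0) {
    stop(
      "ARIMA prediction-error fit did not converge (optim code ",
      fit$convergence, "): ", fit$message
    )
  }
  check_roots(fit$phi, "AR (model not causal)")
  check_roots(fit$theta, "MA (model not invertible)")
  structure(
    list(
      phi = fit$phi, theta = fit$theta, order = c(p = p, d = d, q = q),
      mean = level, sigma2 = fit$sse / n_obs, n_obs = n_obs,
      convergence = fit$convergence
    ),
    class = "arima_pem"
  )
}

# maximal runs of non-NA glucose per subject, as numeric vectors
trace_segments <- function(trace, min_len = 1L) {
  out <- list()
  for (id in unique(trace$subject_id)) {
    y <- trace$glucose[trace$subject_id == id]
    r <- rle(!is.na(y))
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$lengths)) {
      if (r$values[i] && r$lengths[i] >= min_len) {
        out[[length(out) + 1L]] <- y[starts[i]:ends[i]]
      }
    }
  }
  out
}

diff_d <- function(y, d) {
  if (d > 0) for (i in seq_len(d)) y <- diff(y)
  y
}

# Conditional-sum-of-squares residuals of an ARMA(p, q) on one segment,
# conditioning on the first p values (e = 0 there). Sign convention as in
# stats::arima: w_t = sum(phi_i w_{t-i}) + sum(theta_j e_{t-j}) + e_t.
css_residuals <- function(w, phi, theta) {
  p <- length(phi); q <- length(theta)
  n <- length(w)
  if (n <= p) return(numeric(0))
  rhs <- w
  if (p > 0) {
    for (i in seq_len(p)) rhs <- rhs - phi[i] * dplyr::lag(w, i, default = 0)
  }
  rhs <- rhs[(p + 1):n]
  if (q > 0) {
    e <- stats::filter(rhs, filter = -theta, method = "recursive")
    as.numeric(e)
  } else {
    rhs
  }
}

css_sse <- function(par, segs, p, q) {
  phi <- par[seq_len(p)]
  theta <- par[p + seq_len(q)]
  sum(vapply(segs, function(w) sum(css_residuals(w, phi, theta)^2), numeric(1)))
}

# Hannan-Rissanen style starting values plus a small set of restarts.
css_fit <- function(segs, p, q) {
  starts <- list(rep(0, p + q))
  long <- segs[[which.max(lengths(segs))]]
  ar0 <- tryCatch(
    stats::ar(long, order.max = max(p, 1L), aic = FALSE, method = "ols")$ar,
    error = function(e) NULL
  )
  if (p > 0 && !is.null(ar0) && all(is.finite(ar0))) {
    starts <- c(starts, list(c(ar0[seq_len(p)] * 0.9, rep(0, q))))
  }
  if (q > 0) {
    starts <- c(starts, lapply(c(-0.3, 0.3), function(th) {
      s <- rep(0, p + q)
      s[p + 1] <- th
      s
    }))
  }
  best <- NULL
  for (s0 in starts) {
    res <- tryCatch(
      stats::optim(s0, function(par) css_sse(par, segs, p, q), method = "BFGS",
                   control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL
    )
    if (is.null(res)) next
    if (is.null(best) || res$value < best$value) best <- res
  }
  if (is.null(best)) {
    return(list(phi = rep(NA_real_, p), theta = rep(NA_real_, q),
                sse = Inf, convergence = 1L, message = "all starts failed"))
  }
  list(
    phi = best$par[seq_len(p)], theta = best$par[p + seq_len(q)],
    sse = best$value, convergence = best$convergence,
    message = if (is.null(best$message)) "" else best$message
  )
}

check_roots <- function(coef, what) {
  if (length(coef) == 0) return(invisible())
  roots <- polyroot(c(1, -coef))
  if (any(Mod(roots) <= 1 + 1e-8)) {
    stop("fitted ", what, ": root(s) inside the unit circle")
  }
  invisible()
}

#' Iterated multi-step forecast from a fitted ARIMA
#'
#' Runs the conditional prediction-error recursion over the supplied
#' history to obtain the lagged innovations, then iterates the one-step
#' prediction `steps` times with future innovations set to zero, and
#' integrates `d` times back to the glucose scale.
#'
#' @param model an `arima_pem` fit.
#' @param history numeric vector of recent glucose values (most recent
#'   last), of length at least `p + d + q`.
#' @param steps forecast steps ahead (1..6).
#' @return numeric vector of length `steps`.
#' @export
arima_forecast <- function(model, history, steps = 6) {
  stopifnot(inherits(model, "arima_pem"), steps >= 1)
  p <- model$order["p"]; d <- model$order["d"]; q <- model$order["q"]
  if (length(history) < p + d + q || anyNA(history)) {
    stop(insufficient_history("ARIMA forecaster needs a longer contiguous history"))
  }
  level <- model_level(model)
  w <- diff_d(history, d)
  if (d == 0) w <- w - level
  e <- css_residuals(w, model$phi, model$theta)
  w_ext <- w
  e_ext <- c(rep(0, length(w) - length(e)), e)
  for (k in seq_len(steps)) {
    nw <- 0
    if (p > 0) for (i in seq_len(p)) nw <- nw + model$phi[i] * w_ext[length(w_ext) + 1 - i]
    if (q > 0) for (j in seq_len(q)) {
      idx <- length(e_ext) + 1 - j
      if (idx > length(w)) next  # future innovations are zero
      nw <- nw + model$theta[j] * e_ext[idx]
    }
    w_ext <- c(w_ext, nw)
    e_ext <- c(e_ext, 0)
  }
  wf <- w_ext[length(w) + seq_len(steps)]
  if (d == 0) wf + level else undiff(wf, history, d)
}

model_level <- function(model) {
  if (is.null(model$mean)) 0 else model$mean
}

# integrate d-times-differenced forecasts back to the level scale
undiff <- function(wf, history, d) {
  if (d == 0) return(wf)
  lasts <- numeric(d + 1)
  y <- history
  lasts[1] <- y[length(y)]
  for (i in seq_len(d)) {
    y <- diff(y)
    lasts[i + 1] <- y[length(y)]
  }
  # reconstruct: repeatedly cumulative-sum, starting from the deepest diff
  out <- wf
  for (i in d:1) {
    out <- lasts[i] + cumsum(out)
  }
  out
}

#' @exportS3Method generics::tidy
tidy.arima_pem <- function(x, ...) {
  tibble::tibble(
    term = c(paste0("ar", seq_along(x$phi)), if (length(x$theta)) paste0("ma", seq_along(x$theta))),
    estimate = c(x$phi, x$theta)
  )
}

#' @exportS3Method generics::glance
glance.arima_pem <- function(x, ...) {
  tibble::tibble(
    p = x$order[["p"]], d = x$order[["d"]], q = x$order[["q"]],
    sigma2 = x$sigma2, n_obs = x$n_obs
  )
}

#' @export
print.arima_pem <- function(x, ...) {
  cat(sprintf(
    "<arima_pem (%d,%d,%d): phi = %s; theta = %s; fit on %d samples>\n",
    x$order[["p"]], x$order[["d"]], x$order[["q"]],
    paste(sprintf("%.3f", x$phi), collapse = ", "),
    paste(sprintf("%.3f", x$theta), collapse = ", "),
    x$n_obs
  ))
  invisible(x)
}
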