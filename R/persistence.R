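#' Save and load linear forecasters as JSON
#'
#' The rAR and ARIMA forecasters are small coefficient sets; they are
#' persisted as plain JSON so a fitted population model can travel between
#' machines and be inspected by eye. Windowed tree/network models are
#' runtime objects and are not covered.
#'
#' @param model an [rar_model()] or `arima_pem` fit.
#' @param path output file.
#' @return `write_model()` returns `path` invisibly; `read_model()`
#'   returns the reconstructed model.
#' @export
write_model <- function(model, path) {
  payload <- if (inherits(model, "rar_model")) {
    list(type = "rar", mu = model$mu, a = model$a, P = model$P,
         a0 = model$a0, p0 = model$p0, burn_in = model$burn_in,
         n_updates = model$n_updates)
  } else if (inherits(model, "arima_pem")) {
    list(type = "arima_pem", order = as.list(model$order),
         phi = model$phi, theta = model$theta, mean = model_level(model),
         sigma2 = model$sigma2, n_obs = model$n_obs)
  } else {
    stop("write_model supports rar_model and arima_pem objects")
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(p$type, "rar")) {
    m <- rar_model(mu = p$mu, a0 = p$a0, p0 = p$p0, burn_in = p$burn_in)
    m$a <- p$a
    m$P <- p$P
    m$n_updates <- as.integer(p$n_updates)
    m
  } else if (identical(p$type, "arima_pem")) {
    structure(
      list(
        phi = as.numeric(p$phi), theta = as.numeric(p$theta),
        order = c(p = p$order$p, d = p$order$d, q = p$order$q),
        mean = if (is.null(p$mean)) 0 else p$mean,
        sigma2 = p$sigma2, n_obs = p$n_obs, convergence = 0L
      ),
      class = "arima_pem"
    )
  } else {
    stop("unrecognised model file: ", path)
  }
}
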