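#' Build a supervised (window, 6-step target) dataset from traces
#'
#' Slides a window of `input_window` past samples over each subject's
#' trace and pairs it with the next `output_steps` samples. A pair is
#' emitted only when all `input_window + output_steps` samples are
#' contiguous non-missing grid samples; no pair straddles a missing run or
#' a subject boundary.
#'
#' @param trace a [cgm_trace()].
#' @param input_window number of past samples per input (default 12,
#'   i.e. 60 min).
#' @param output_steps target length (6 steps = 30 min).
#' @return list with matrix `x` (`n_pairs x input_window`, oldest sample
#'   first), matrix `y` (`n_pairs x output_steps`), and tibble `origins`
#'   (`subject_id`, `origin` = 1-based index of the last input sample).
#' @export
make_supervised <- function(trace, input_window = 12, output_steps = 6) {
  assert_trace(trace)
  stopifnot(input_window >= 3, output_steps >= 1)
  xs <- list(); ys <- list(); metas <- list()
  for (id in unique(trace$subject_id)) {
    y <- trace$glucose[trace$subject_id == id]
    n <- length(y)
    span <- input_window + output_steps
    if (n < span) next
    ok_run <- ok_window(!is.na(y), span)
    origins <- which(ok_run) + input_window - 1L
    if (!length(origins)) next
    xs[[id]] <- t(vapply(origins, function(o) y[(o - input_window + 1):o], numeric(input_window)))
    ys[[id]] <- t(vapply(origins, function(o) y[(o + 1):(o + output_steps)], numeric(output_steps)))
    metas[[id]] <- tibble::tibble(subject_id = id, origin = origins)
  }
  if (!length(xs)) {
    return(list(
      x = matrix(numeric(0), 0, input_window),
      y = matrix(numeric(0), 0, output_steps),
      origins = tibble::tibble(subject_id = character(0), origin = integer(0))
    ))
  }
  list(x = do.call(rbind, xs), y = do.call(rbind, ys), origins = dplyr::bind_rows(metas))
}

# logical vector: TRUE at positions starting a run of `span` TRUEs
ok_window <- function(ok, span) {
  n <- length(ok)
  if (n < span) return(logical(0))
  cs <- cumsum(ok)
  out <- (cs[span:n] - c(0, cs)[1:(n - span + 1)]) == span
  out
}

#' Configure a windowed multi-step regressor
#'
#' One configuration object per model family, all behind the same
#' fit/forecast contract. Families:
#' \describe{
#'   \item{`"rf"`}{random forest; 100 trees, depth limit 15, at least 10
#'     samples per split; one independent forest per output step.}
#'   \item{`"lgb"`}{leaf-wise gradient-boosted trees; 200 rounds, 31
#'     leaves per tree, learning rate 0.02; one booster per step.}
#'   \item{`"nn"`}{feed-forward network with hidden layers of 32 (ELU)
#'     and 16 (linear) neurons and a 6-neuron linear output, trained with
#'     RMSprop on mean squared error, batch 32, up to 300 epochs with
#'     early stopping after 30 epochs without validation improvement.}
#'   \item{`"lstm"`, `"cnnlstm"`}{recurrent families reserved in the
#'     contract; fitting them is not supported in this implementation and
#'     errors with a clear message.}
#' }
#' Inputs (and, for the network, targets) are standardised by the
#' training-set global mean/SD, stored with the fitted model.
#'
#' @param family model family, see above.
#' @param input_window input window length in samples.
#' @param output_steps number of forecast steps (6 = 30-min horizon).
#' @param learning_rate,epochs,patience,batch_size network training
#'   controls (ignored by the tree families).
#' @param seed integer seed making fits reproducible.
#' @param ... family-specific overrides: `num_trees`, `max_depth`,
#'   `min_node_size` (rf); `nrounds`, `num_leaves`, `eta` (lgb);
#'   `hidden` (nn, default `c(32, 16)`).
#' @return a `windowed_spec`.
#' @export
windowed_spec <- function(family = c("rf", "lgb", "nn", "lstm", "cnnlstm"),
                          input_window = 12, output_steps = 6,
                          learning_rate = 1e-5, epochs = 300, patience = 30,
                          batch_size = 32, seed = 1L, ...) {
  family <- match.arg(family)
  stopifnot(input_window >= 3, output_steps == 6 || output_steps >= 1)
  opts <- list(...)
  defaults <- switch(family,
    rf = list(num_trees = 100, max_depth = 15, min_node_size = 10),
    lgb = list(nrounds = 200, num_leaves = 31, eta = 0.02),
    nn = list(hidden = c(32, 16)),
    list()
  )
  defaults[names(opts)] <- opts
  structure(
    list(
      family = family, input_window = input_window, output_steps = output_steps,
      learning_rate = learning_rate, epochs = epochs, patience = patience,
      batch_size = batch_size, seed = as.integer(seed), opts = defaults
    ),
    class = "windowed_spec"
  )
}

#' Fit a windowed regressor
#'
#' @param spec a [windowed_spec()].
#' @param train supervised dataset from [make_supervised()].
#' @param validation optional supervised dataset used for network early
#'   stopping.
#' @return a `windowed_fit` wrapping one sub-model per output step plus
#'   the standardisation constants.
#' @export
fit_windowed <- function(spec, train, validation = NULL) {
  stopifnot(inherits(spec, "windowed_spec"))
  if (spec$family %in% c("lstm", "cnnlstm")) {
    stop("family '", spec$family, "' is not supported in this implementation; ",
         "supply its predictions through the forecast-stream contract instead")
  }
  if (nrow(train$x) == 0) stop("empty training dataset")
  mu <- mean(train$x)
  sdv <- stats::sd(as.numeric(train$x))
  if (!is.finite(sdv) || sdv == 0) sdv <- 1
  xs <- (train$x - mu) / sdv
  fit <- switch(spec$family,
    rf = fit_rf(spec, xs, train$y),
    lgb = fit_lgb(spec, xs, train$y),
    nn = fit_nn(spec, xs, (train$y - mu) / sdv,
                if (!is.null(validation) && nrow(validation$x) > 0) {
                  list(x = (validation$x - mu) / sdv, y = (validation$y - mu) / sdv)
                })
  )
  structure(
    list(spec = spec, fit = fit, center = mu, scale = sdv),
    class = "windowed_fit"
  )
}

fit_rf <- function(spec, x, y) {
  colnames(x) <- paste0("l", seq_len(ncol(x)))
  lapply(seq_len(ncol(y)), function(k) {
    ranger::ranger(
      x = as.data.frame(x), y = y[, k],
      num.trees = spec$opts$num_trees, max.depth = spec$opts$max_depth,
      min.node.size = spec$opts$min_node_size,
      seed = spec$seed + k, num.threads = 1
    )
  })
}

fit_lgb <- function(spec, x, y) {
  lapply(seq_len(ncol(y)), function(k) {
    xgboost::xgb.train(
      params = list(
        objective = "reg:squarederror", eta = spec$opts$eta,
        tree_method = "hist", grow_policy = "lossguide",
        max_leaves = spec$opts$num_leaves, max_depth = 0,
        nthread = 1, seed = spec$seed + k
      ),
      data = xgboost::xgb.DMatrix(x, label = y[, k]),
      nrounds = spec$opts$nrounds, verbose = 0
    )
  })
}

#' Predict from a fitted windowed regressor
#'
#' @param object a `windowed_fit`.
#' @param newdata matrix of input windows (`n x input_window`, raw mg/dL).
#' @param ... unused.
#' @return matrix `n x output_steps` of predicted glucose (mg/dL).
#' @export
predict.windowed_fit <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata), ncol(newdata) == object$spec$input_window)
  xs <- (newdata - object$center) / object$scale
  out <- switch(object$spec$family,
    rf = {
      colnames(xs) <- paste0("l", seq_len(ncol(xs)))
      df <- as.data.frame(xs)
      do.call(cbind, lapply(object$fit, function(m) stats::predict(m, df, num.threads = 1)$predictions))
    },
    lgb = do.call(cbind, lapply(object$fit, function(m) stats::predict(m, xgboost::xgb.DMatrix(xs)))),
    nn = nn_predict(object$fit, xs) * object$scale + object$center
  )
  unname(as.matrix(out))
}

#' @export
print.windowed_fit <- function(x, ...) {
  cat(sprintf(
    "<windowed_fit: family %s, window %d samples -> %d steps>\n",
    x$spec$family, x$spec$input_window, x$spec$output_steps
  ))
  invisible(x)
}
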