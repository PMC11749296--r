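#' Construct a CGM trace
#'
#' A CGM trace is a tibble holding one or more subjects' sensor glucose
#' series on a uniform 5-minute grid. Columns:
#' \describe{
#'   \item{subject_id}{character, opaque subject label.}
#'   \item{time_min}{minutes since the subject's trace start; multiples of
#'     the grid step, starting at 0 for every subject.}
#'   \item{glucose}{sensor glucose in mg/dL; `NA` where the slot is missing.}
#'   \item{status}{per-sample provenance, one of `"observed"`,
#'     `"interpolated"`, `"zoh_filled"`, `"missing"`.}
#' }
#' All operations in the package accept multi-subject traces and treat each
#' subject independently (no window, forecast or episode ever crosses a
#' subject boundary).
#'
#' @param subject_id character scalar or vector of subject labels.
#' @param glucose numeric vector of glucose values (mg/dL), `NA` allowed.
#' @param status character vector of per-sample provenance flags; defaults
#'   to `"observed"` where glucose is present, `"missing"` otherwise.
#' @param step_min grid step in minutes (fixed at 5 in this package's
#'   pipeline; kept explicit for clarity).
#' @return a `cgm_trace` tibble.
#' @export
cgm_trace <- function(subject_id, glucose, status = NULL, step_min = 5) {
  n <- length(glucose)
  subject_id <- if (length(subject_id) == 1L) rep(as.character(subject_id), n) else as.character(subject_id)
  stopifnot(length(subject_id) == n)
  if (is.null(status)) {
    status <- ifelse(is.na(glucose), "missing", "observed")
  }
  stopifnot(length(status) == n)
  bad <- !status %in% c("observed", "interpolated", "zoh_filled", "missing")
  if (any(bad)) {
    stop("unknown status value(s): ", paste(unique(status[bad]), collapse = ", "))
  }
  if (any(is.na(glucose) & status != "missing")) {
    stop("non-missing status with NA glucose")
  }
  ok <- !is.na(glucose)
  if (any(glucose[ok] < 20 | glucose[ok] > 500)) {
    stop("glucose outside plausible sensor range [20, 500] mg/dL")
  }
  out <- dplyr::mutate(
    tibble::tibble(subject_id = subject_id, glucose = as.numeric(glucose), status = status),
    time_min = (dplyr::row_number() - 1) * step_min,
    .by = "subject_id"
  )
  out <- dplyr::select(out, "subject_id", "time_min", "glucose", "status")
  new_cgm_trace(out, step_min = step_min)
}

new_cgm_trace <- function(df, step_min = 5) {
  df <- tibble::as_tibble(df)
  class(df) <- c("cgm_trace", class(tibble::tibble()))
  attr(df, "step_min") <- step_min
  df
}

#' @export
print.cgm_trace <- function(x, ...) {
  ns <- dplyr::summarise(x, n = dplyr::n(), .by = "subject_id")
  cat(sprintf(
    "<cgm_trace: %d subject%s, %d samples on a %g-min grid>\n",
    nrow(ns), if (nrow(ns) == 1L) "" else "s", nrow(x), trace_step(x)
  ))
  NextMethod()
}

trace_step <- function(trace) {
  s <- attr(trace, "step_min")
  if (is.null(s)) 5 else s
}

# Apply `f(one_subject_df, ...)` per subject, preserving subject order, and
# row-bind results back into a cgm_trace.
map_subjects <- function(trace, f, ...) {
  ids <- unique(trace$subject_id)
  parts <- lapply(ids, function(id) f(trace[trace$subject_id == id, , drop = FALSE], ...))
  new_cgm_trace(dplyr::bind_rows(parts), step_min = trace_step(trace))
}

assert_trace <- function(trace) {
  need <- c("subject_id", "time_min", "glucose", "status")
  miss <- setdiff(need, names(trace))
  if (length(miss)) {
    stop("not a CGM trace: missing column(s) ", paste(miss, collapse = ", "))
  }
  invisible(trace)
}

#' Plot a CGM trace
#'
#' Glucose against time, coloured by sample provenance, with reference
#' lines at the 54 and 70 mg/dL hypoglycaemia thresholds. Subjects are
#' facetted.
#'
#' @param object a `cgm_trace`.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cgm_trace <- function(object, ...) {
  assert_trace(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time_min / 60, y = .data$glucose)) +
    ggplot2::geom_hline(yintercept = c(54, 70), linetype = "dashed", colour = "grey50") +
    ggplot2::geom_line(colour = "grey70", na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$status), size = 0.4, na.rm = TRUE) +
    ggplot2::facet_wrap(~subject_id, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "time (h)", y = "glucose (mg/dL)", colour = NULL)
}
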