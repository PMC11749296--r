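#' Read raw CGM samples from a delimited text file
#'
#' Reads one subject's raw sensor export: a CSV/TSV file with a header
#' naming a timestamp column (`timestamp`, ISO-8601 or seconds) and a
#' glucose column (`glucose_mgdl` or `glucose`, mg/dL). Rows are sorted by
#' time; duplicate timestamps are collapsed to their mean; glucose outside
#' the plausible sensor range [20, 500] mg/dL is rejected.
#'
#' @param path file path.
#' @return a tibble of raw samples with columns `time_s` (seconds since the
#'   first sample) and `glucose`, sorted and strictly increasing in time.
#' @export
read_cgm <- function(path) {
  raw <- readr::read_delim(
    path,
    delim = detect_delim(path),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  if (nrow(raw) == 0L) stop("empty CGM file: ", path)
  ts_col <- intersect(c("timestamp", "time_s", "time"), names(raw))[1]
  gl_col <- intersect(c("glucose_mgdl", "glucose"), names(raw))[1]
  if (is.na(ts_col) || is.na(gl_col)) {
    stop("CGM file must have a timestamp column and a glucose column (glucose_mgdl)")
  }
  ts <- parse_timestamps(raw[[ts_col]])
  gl <- suppressWarnings(as.numeric(raw[[gl_col]]))
  bad <- which(is.na(ts) | is.na(gl))
  if (length(bad)) {
    stop("unparsable CGM rows: ", paste(bad, collapse = ", "))
  }
  out_of_range <- which(gl < 20 | gl > 500)
  if (length(out_of_range)) {
    stop(
      "glucose outside [20, 500] mg/dL at row(s): ",
      paste(out_of_range, collapse = ", ")
    )
  }
  samples <- tibble::tibble(time_s = ts - min(ts), glucose = gl)
  samples <- dplyr::summarise(samples, glucose = mean(.data$glucose), .by = "time_s")
  dplyr::arrange(samples, .data$time_s)
}

detect_delim <- function(path) {
  header <- readLines(path, n = 1L)
  if (grepl("\t", header)) "\t" else ","
}

parse_timestamps <- function(x) {
  num <- suppressWarnings(as.numeric(x))
  if (!anyNA(num)) return(num)
  dt <- suppressWarnings(as.POSIXct(x, tz = "UTC", tryFormats = c(
    "%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d %H:%M", "%Y-%m-%d"
  )))
  as.numeric(dt)
}

#' Align raw samples to a uniform 5-minute grid
#'
#' Each grid slot takes the raw sample nearest in time within half the grid
#' step (±150 s for the 5-min grid); slots with no sample in tolerance are
#' flagged `missing`. A sample exactly halfway between two slots is
#' assigned to the earlier slot, and when two samples are equidistant from
#' a slot the earlier sample wins.
#'
#' @param samples tibble with columns `time_s` and `glucose`, as returned
#'   by [read_cgm()].
#' @param subject_id label for the resulting trace.
#' @param step_min grid step in minutes.
#' @return a single-subject [cgm_trace()].
#' @export
align_cgm <- function(samples, subject_id = "S1", step_min = 5) {
  stopifnot(nrow(samples) >= 2L)
  step_s <- step_min * 60
  ts <- samples$time_s
  # nearest slot; exact halfway point floors to the earlier slot
  slot <- ceiling(ts / step_s - 0.5)
  dist <- abs(ts - slot * step_s)
  cand <- tibble::tibble(slot = slot, dist = dist, time_s = ts, glucose = samples$glucose)
  cand <- dplyr::arrange(cand, .data$slot, .data$dist, .data$time_s)
  cand <- dplyr::slice_head(cand, n = 1L, by = "slot")
  n_slots <- max(cand$slot) + 1L
  glucose <- rep(NA_real_, n_slots)
  glucose[cand$slot + 1L] <- cand$glucose
  cgm_trace(subject_id, glucose, step_min = step_min)
}

#' Interpolate short interior gaps (training preprocessing)
#'
#' Interior runs of missing samples strictly shorter than `max_gap_min` are
#' filled by linear (first-order polynomial) interpolation between the
#' flanking non-missing values and flagged `interpolated`. Runs of
#' `max_gap_min` or longer, and leading/trailing runs, are left missing.
#' This fill consults future samples, so it is applied to training data
#' only; real-time segments use [causal_fill()].
#'
#' @param trace a [cgm_trace()].
#' @param max_gap_min gaps shorter than this many minutes are filled.
#' @return the trace with short gaps filled.
#' @export
interpolate_gaps <- function(trace, max_gap_min = 30) {
  assert_trace(trace)
  step <- trace_step(trace)
  map_subjects(trace, function(df) {
    miss <- is.na(df$glucose)
    if (!any(miss)) return(df)
    r <- rle(miss)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (i in seq_along(r$lengths)) {
      if (!r$values[i]) next
      if (starts[i] == 1L || ends[i] == nrow(df)) next    # no anchor on one side
      if (r$lengths[i] * step >= max_gap_min) next
      lo <- starts[i] - 1L
      hi <- ends[i] + 1L
      idx <- starts[i]:ends[i]
      df$glucose[idx] <- stats::approx(
        x = df$time_min[c(lo, hi)], y = df$glucose[c(lo, hi)], xout = df$time_min[idx]
      )$y
      df$status[idx] <- "interpolated"
    }
    df
  })
}

#' Causal zero-order-hold fill (real-time preprocessing)
#'
#' Every missing sample with at least one earlier non-missing sample takes
#' the most recent non-missing value (last observation carried forward) and
#' is flagged `zoh_filled`. Samples before the first observation stay
#' missing. No future sample is ever consulted, so the fill is usable in a
#' simulated real-time pass; applying it twice is a no-op.
#'
#' @param trace a [cgm_trace()].
#' @return the causally filled trace.
#' @export
causal_fill <- function(trace) {
  assert_trace(trace)
  map_subjects(trace, function(df) {
    miss <- is.na(df$glucose)
    if (!any(miss)) return(df)
    filled <- locf(df$glucose)
    newly <- miss & !is.na(filled)
    df$glucose <- filled
    df$status[newly] <- "zoh_filled"
    df
  })
}

# last observation carried forward; leading NAs preserved
locf <- function(x) {
  idx <- cumsum(!is.na(x))
  obs <- x[!is.na(x)]
  out <- rep(NA_real_, length(x))
  out[idx > 0L] <- obs[idx[idx > 0L]]
  out
}

#' Split a trace chronologically into train / validation / test
#'
#' Contiguous chronological slices per subject; boundary indices are the
#' floor of the cumulative fraction times the subject's grid length, so a
#' 101-sample trace splits 70/15/16 under the default 70/15/15 fractions.
#'
#' @param trace a [cgm_trace()].
#' @param fractions length-3 numeric summing to 1.
#' @return a `cgm_split`: a named list with elements `train`, `validation`,
#'   `test`, each a [cgm_trace()] (possibly zero-row).
#' @export
split_cgm <- function(trace, fractions = c(0.70, 0.15, 0.15)) {
  assert_trace(trace)
  stopifnot(length(fractions) == 3L, abs(sum(fractions) - 1) < 1e-8, all(fractions >= 0))
  parts <- list(train = list(), validation = list(), test = list())
  for (id in unique(trace$subject_id)) {
    df <- trace[trace$subject_id == id, , drop = FALSE]
    n <- nrow(df)
    if (n < 3L) stop("trace for subject ", id, " shorter than 3 samples")
    b <- floor(cumsum(fractions) * n)
    b[3] <- n
    parts$train[[id]] <- df[seq_len(b[1]), , drop = FALSE]
    parts$validation[[id]] <- if (b[2] > b[1]) df[(b[1] + 1):b[2], , drop = FALSE] else df[0, , drop = FALSE]
    parts$test[[id]] <- if (b[3] > b[2]) df[(b[2] + 1):b[3], , drop = FALSE] else df[0, , drop = FALSE]
  }
  out <- lapply(parts, function(p) new_cgm_trace(dplyr::bind_rows(p), step_min = trace_step(trace)))
  structure(out, class = "cgm_split")
}

#' @export
print.cgm_split <- function(x, ...) {
  cat(sprintf(
    "<cgm_split: train %d / validation %d / test %d samples>\n",
    nrow(x$train), nrow(x$validation), nrow(x$test)
  ))
  invisible(x)
}

#' Prepare a split for model fitting and real-time evaluation
#'
#' Applies the asymmetric preprocessing used throughout the package: the
#' training slice gets short interior gaps linearly interpolated (an
#' acausal fill is acceptable offline), while the validation and test
#' slices are causally zero-order-hold filled only, as a deployed system
#' would see them.
#'
#' @param split a `cgm_split` from [split_cgm()].
#' @param max_gap_min passed to [interpolate_gaps()].
#' @return the split with preprocessing applied.
#' @export
prepare_split <- function(split, max_gap_min = 30) {
  stopifnot(inherits(split, "cgm_split"))
  split$train <- interpolate_gaps(split$train, max_gap_min = max_gap_min)
  split$validation <- causal_fill(split$validation)
  split$test <- causal_fill(split$test)
  split
}

#' Subject eligibility by CGM availability
#'
#' A subject is eligible when the observed (not filled, not missing)
#' monitoring time strictly exceeds `min_days` days.
#'
#' @param trace a [cgm_trace()].
#' @param min_days eligibility threshold in days.
#' @return named logical vector, one element per subject.
#' @export
cgm_eligible <- function(trace, min_days = 10) {
  assert_trace(trace)
  step <- trace_step(trace)
  tab <- dplyr::summarise(
    tibble::as_tibble(trace),
    observed_min = sum(.data$status == "observed") * step,
    .by = "subject_id"
  )
  stats::setNames(tab$observed_min > min_days * 1440, tab$subject_id)
}

#' Write a trace back to delimited text
#'
#' One CSV per subject (`<subject_id>.csv` under `dir`) with columns
#' `timestamp` (seconds), `glucose_mgdl` and `status`, plus a JSON sidecar
#' `<subject_id>.json` with grid metadata and per-status counts.
#'
#' @param trace a [cgm_trace()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cgm <- function(trace, dir) {
  assert_trace(trace)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (id in unique(trace$subject_id)) {
    df <- trace[trace$subject_id == id, , drop = FALSE]
    csv <- file.path(dir, paste0(id, ".csv"))
    readr::write_csv(
      tibble::tibble(
        timestamp = df$time_min * 60,
        glucose_mgdl = df$glucose,
        status = df$status
      ),
      csv
    )
    meta <- list(
      subject_id = id,
      step_min = trace_step(trace),
      n_samples = nrow(df),
      counts = as.list(table(df$status))
    )
    js <- file.path(dir, paste0(id, ".json"))
    jsonlite::write_json(meta, js, auto_unbox = TRUE, pretty = TRUE)
    paths <- c(paths, csv, js)
  }
  invisible(paths)
}
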