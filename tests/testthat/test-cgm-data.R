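write_cgm_file <- function(lines, ext = ".csv") {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("read_cgm reads, sorts and averages duplicate timestamps", {
  p <- write_cgm_file(c("timestamp,glucose_mgdl", "600,110", "0,100", "300,105"))
  s <- read_cgm(p)
  expect_equal(s$time_s, c(0, 300, 600))
  expect_equal(s$glucose, c(100, 105, 110))

  p2 <- write_cgm_file(c("timestamp,glucose_mgdl", "0,100", "0,102", "300,95"))
  s2 <- read_cgm(p2)
  expect_equal(nrow(s2), 2L)
  expect_equal(s2$glucose[1], 101)
})

test_that("read_cgm accepts ISO-8601 timestamps and tab delimiters", {
  p <- write_cgm_file(c(
    "timestamp\tglucose_mgdl",
    "2024-01-01T00:00:00\t100",
    "2024-01-01T00:05:00\t104"
  ), ext = ".tsv")
  s <- read_cgm(p)
  expect_equal(s$time_s, c(0, 300))
})

test_that("read_cgm rejects bad rows with their row numbers", {
  p <- write_cgm_file(c("timestamp,glucose_mgdl", "0,100", "300,-5"))
  expect_error(read_cgm(p), "\\[20, 500\\].*2")
  p2 <- write_cgm_file(c("timestamp,glucose_mgdl", "0,100", "300,abc"))
  expect_error(read_cgm(p2), "unparsable.*2")
  p3 <- write_cgm_file("timestamp,glucose_mgdl")
  expect_error(read_cgm(p3), "empty")
})

test_that("align_cgm snaps samples within half a grid step", {
  s <- tibble::tibble(time_s = c(0, 298, 603), glucose = c(100, 105, 110))
  tr <- align_cgm(s)
  expect_equal(tr$status, rep("observed", 3))
  expect_equal(tr$glucose, c(100, 105, 110))

  s2 <- tibble::tibble(time_s = c(0, 900), glucose = c(100, 120))
  tr2 <- align_cgm(s2)
  expect_equal(tr2$status, c("observed", "missing", "missing", "observed"))
})

test_that("align_cgm breaks slot ties toward the earlier slot and sample", {
  # 150 s is equidistant between slots 0 and 300 -> earlier slot
  s <- tibble::tibble(time_s = c(150, 600), glucose = c(100, 110))
  tr <- align_cgm(s)
  expect_equal(tr$glucose[1], 100)
  expect_equal(tr$status[2], "missing")

  # two samples equidistant from slot 300 -> earlier sample wins
  s2 <- tibble::tibble(time_s = c(0, 240, 360), glucose = c(90, 100, 110))
  tr2 <- align_cgm(s2)
  expect_equal(tr2$glucose[2], 100)
})

test_that("interpolate_gaps fills interior gaps under 30 min linearly", {
  # observed 25 min apart (100, 125), 4 missing slots between
  y <- c(100, NA, NA, NA, NA, 125)
  tr <- interpolate_gaps(make_trace(y))
  expect_equal(tr$glucose, c(100, 105, 110, 115, 120, 125))
  expect_equal(tr$status[2:5], rep("interpolated", 4))
})

test_that("a 30-min gap and edge gaps are left missing", {
  y6 <- c(100, rep(NA, 6), 120)
  tr6 <- interpolate_gaps(make_trace(y6))
  expect_true(all(is.na(tr6$glucose[2:7])))
  expect_equal(tr6$status[2:7], rep("missing", 6))

  # 5 missing slots (25 min) does get filled
  y5 <- c(100, rep(NA, 5), 120)
  expect_false(anyNA(interpolate_gaps(make_trace(y5))$glucose))

  lead <- make_trace(c(NA, NA, 100, 105))
  expect_true(all(is.na(interpolate_gaps(lead)$glucose[1:2])))
  trail <- make_trace(c(100, 105, NA))
  expect_true(is.na(interpolate_gaps(trail)$glucose[3]))
})

test_that("causal_fill holds the last value forward and is idempotent", {
  tr <- causal_fill(make_trace(c(100, NA, NA, 90)))
  expect_equal(tr$glucose, c(100, 100, 100, 90))
  expect_equal(tr$status, c("observed", "zoh_filled", "zoh_filled", "observed"))

  lead <- causal_fill(make_trace(c(NA, NA, 100)))
  expect_true(all(is.na(lead$glucose[1:2])))

  full <- make_trace(c(90, 95, 100))
  expect_identical(causal_fill(full)$glucose, full$glucose)

  once <- causal_fill(make_trace(c(NA, 100, NA, 80, NA, NA)))
  expect_identical(causal_fill(once), once)
})

test_that("gap filling never alters observed or interpolated samples", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      y <- runif(60, 60, 200)
      y[sample(60, 15)] <- NA
      tr <- make_trace(y)
      ti <- interpolate_gaps(tr)
      tc <- causal_fill(ti)
      obs <- tr$status == "observed"
      expect_identical(ti$glucose[obs], tr$glucose[obs])
      expect_identical(tc$glucose[!is.na(ti$glucose)], ti$glucose[!is.na(ti$glucose)])
      expect_identical(tc$status[obs], tr$status[obs])
    }
  })
})

test_that("causal_fill output never depends on future samples", {
  y <- c(100, NA, NA, 120, NA, 110, NA, NA)
  base <- causal_fill(make_trace(y))
  for (j in 4:8) {
    y2 <- y
    y2[j] <- if (is.na(y[j])) y2[j] else 400  # sentinel in the future
    pert <- causal_fill(make_trace(y2))
    expect_identical(pert$glucose[seq_len(j - 1)], base$glucose[seq_len(j - 1)])
  }
})

test_that("split_cgm slices chronologically by floored cumulative fractions", {
  tr <- make_trace(seq(80, by = 0.5, length.out = 100))
  sp <- split_cgm(tr)
  expect_equal(sapply(sp, nrow), c(train = 70, validation = 15, test = 15))

  sp101 <- split_cgm(make_trace(rep(100, 101)))
  expect_equal(sapply(sp101, nrow), c(train = 70, validation = 15, test = 16))

  all_train <- split_cgm(tr, c(1, 0, 0))
  expect_equal(nrow(all_train$train), 100)
  expect_equal(nrow(all_train$validation), 0)

  expect_error(split_cgm(make_trace(c(100, 100))), "shorter than 3")
})

test_that("split slices concatenate back to the original trace", {
  tr <- dplyr::bind_rows(
    make_trace(runif(53, 70, 200), id = "A"),
    make_trace(runif(87, 70, 200), id = "B")
  )
  tr <- pbhcast:::new_cgm_trace(tr)
  sp <- split_cgm(tr)
  back <- dplyr::bind_rows(lapply(c("A", "B"), function(id) {
    dplyr::bind_rows(
      sp$train[sp$train$subject_id == id, ],
      sp$validation[sp$validation$subject_id == id, ],
      sp$test[sp$test$subject_id == id, ]
    )
  }))
  expect_equal(as.data.frame(back), as.data.frame(tr))
})

test_that("eligibility needs strictly more than min_days of observed data", {
  expect_true(unname(cgm_eligible(make_trace(rep(100, 2881)))))
  expect_false(unname(cgm_eligible(make_trace(rep(100, 2880)))))
  expect_false(unname(cgm_eligible(make_trace(rep(NA_real_, 50)))))
})

test_that("prepare_split applies asymmetric preprocessing", {
  y <- rep(100, 200)
  y[c(50, 51, 180)] <- NA   # gaps inside the train and test slices
  sp <- prepare_split(split_cgm(make_trace(y)))
  expect_true("interpolated" %in% sp$train$status)
  expect_false("zoh_filled" %in% sp$train$status)
  expect_true("zoh_filled" %in% sp$test$status)
})
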