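test_that("generated recordings have the requested shape and are seed-deterministic", {
  rec <- simulate_recording("happy", 15, seed = 7)
  expect_equal(dim(rec), c(1920L, 14L)) # 15 s x 128 Hz, 14 channels
  expect_equal(colnames(rec), emotiv_montage()$channel_names)
  expect_true(all(is.finite(as.matrix(rec))))

  again <- simulate_recording("happy", 15, seed = 7)
  expect_identical(as.data.frame(rec), as.data.frame(again))

  other_seed <- simulate_recording("happy", 15, seed = 8)
  expect_false(identical(as.data.frame(rec), as.data.frame(other_seed)))

  short <- simulate_recording("calm", 1.5, seed = 1)
  expect_equal(nrow(short), 192L)
  expect_identical(
    as.data.frame(short),
    as.data.frame(simulate_recording("calm", 1.5, seed = 1))
  )
})

test_that("invalid generator arguments are rejected", {
  expect_error(simulate_recording("happy", 0, seed = 1), "duration")
  expect_error(simulate_recording("happy", -3, seed = 1), "duration")
  expect_error(simulate_recording("bored", 3, seed = 1), "label")
})

test_that("generation does not disturb the caller's RNG stream", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  invisible(simulate_recording("sad", 2, seed = 3))
  expect_identical(runif(1), before)
})

test_that("calm carries more frontal alpha than scared under default profiles", {
  fs <- 128
  calm <- simulate_recording("calm", 60, seed = 3)
  scared <- simulate_recording("scared", 60, seed = 3)
  frac <- function(rec, ch) {
    x <- rec[[ch]]
    band_power_oracle(x, fs, 8, 13) / band_power_oracle(x, fs, 0.5, 30)
  }
  for (ch in c("AF3", "F3", "F4", "AF4")) {
    expect_gt(frac(calm, ch), frac(scared, ch))
  }
})

test_that("every pair of classes is separable in some band power (3x standard error)", {
  fs <- 128
  bands <- eeg_bands()
  channels <- emotiv_montage()$channel_names
  n_rec <- 20
  powers <- lapply(emotion_labels(), function(lab) {
    per_rec <- vapply(seq_len(n_rec), function(r) {
      rec <- simulate_recording(lab, 4, seed = 1000 + r)
      as.vector(vapply(channels, function(ch) {
        vapply(seq_len(nrow(bands)), function(b) {
          log(band_power_oracle(rec[[ch]], fs, bands$low_hz[b], bands$high_hz[b]))
        }, numeric(1))
      }, numeric(nrow(bands))))
    }, numeric(nrow(bands) * length(channels)))
    list(mean = rowMeans(per_rec), se = apply(per_rec, 1, sd) / sqrt(n_rec))
  })
  names(powers) <- emotion_labels()
  pairs <- utils::combn(emotion_labels(), 2)
  for (j in seq_len(ncol(pairs))) {
    a <- powers[[pairs[1, j]]]
    b <- powers[[pairs[2, j]]]
    z <- abs(a$mean - b$mean) / sqrt(a$se^2 + b$se^2)
    expect_gte(max(z), 3)
  }
})

test_that("CSV round-trip preserves rate, channel order, and samples", {
  rec <- simulate_recording("sad", 2, seed = 11)
  path <- withr::local_tempfile(fileext = ".csv")
  write_recording_csv(rec, path)
  back <- read_recording_csv(path)
  expect_equal(sampling_rate(back), 128)
  expect_equal(colnames(back), colnames(rec))
  expect_equal(as.matrix(back), as.matrix(rec), tolerance = 1e-6)
})

test_that("malformed recording files raise parse errors naming the line", {
  path <- withr::local_tempfile(fileext = ".csv")
  ch <- emotiv_montage()$channel_names

  writeLines(c("# fs=128", paste(ch[1:13], collapse = ","), "1,2,3"), path)
  expect_error(read_recording_csv(path), "line 2")

  writeLines(c("# fs=128", paste(ch, collapse = ",")), path)
  expect_error(read_recording_csv(path), "data")

  writeLines(c(
    "# fs=128", paste(ch, collapse = ","),
    paste(rep("0.5", 14), collapse = ","),
    paste(c("oops", rep("0.5", 13)), collapse = ",")
  ), path)
  expect_error(read_recording_csv(path), "line 4")

  writeLines(c(
    "# fs=128", paste(ch, collapse = ","),
    paste(rep("0.5", 13), collapse = ",")
  ), path)
  expect_error(read_recording_csv(path), "line 3")

  writeLines(c("not a header", paste(ch, collapse = ","), "1"), path)
  expect_error(read_recording_csv(path), "line 1")
})
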