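test_that("CSV recordings round-trip exactly", {
  set.seed(42)
  rec <- eeg_recording(matrix(rnorm(30), 3), 100, c("C3", "Cz", "P3"))
  p <- withr::local_tempfile(fileext = ".csv")
  write_recording(rec, p)
  r2 <- read_recording(p)
  expect_equal(r2$samples, rec$samples, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_identical(r2$channel_names, rec$channel_names)
  expect_equal(r2$rate, rec$rate)
})

test_that("unreadable or malformed recordings raise informative errors", {
  expect_error(read_recording("/nonexistent/rec.csv"), "no such file")
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("time,C3,Cz", "0,1,2", "0.01,3"), p)
  expect_error(read_recording(p), "malformed|format")
  p2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("C3,Cz", "1,2"), p2)  # missing the time column
  expect_error(read_recording(p2), "time")
})

test_that("EDF round-trips within 16-bit quantization, names in order", {
  set.seed(7)
  rec <- eeg_recording(matrix(rnorm(3 * 2000, sd = 20), 3), 1000,
                       c("C3", "Cz", "P3"))
  p <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, p)
  r2 <- read_recording(p)
  expect_identical(r2$channel_names, rec$channel_names)
  expect_equal(r2$rate, rec$rate)
  quant <- max(apply(rec$samples, 1, function(v) diff(range(v)))) / 65535
  expect_lt(max(abs(r2$samples - rec$samples)), quant)
})

test_that("EDF handles non-integer durations via a single record", {
  rec <- eeg_recording(matrix(sin(1:1500), 1), 1000, "C3")
  p <- withr::local_tempfile(fileext = ".edf")
  write_recording(rec, p)
  r2 <- read_recording(p)
  expect_equal(ncol(r2$samples), 1500)
  expect_equal(r2$rate, 1000)
})

test_that("recording constructor enforces its invariants", {
  expect_error(eeg_recording(matrix(0, 2, 5), 0, c("a", "b")), "rate")
  expect_error(eeg_recording(matrix(0, 2, 5), 100, c("a", "a")), "unique")
  expect_error(eeg_recording(matrix(0, 2, 5), 100, "a"), "channel")
})

test_that("large Laplacian subtracts the neighbor mean", {
  m <- montage_1020()
  n <- 50
  s <- sin(2 * pi * 10 * (0:(n - 1)) / 100)
  noise <- cos(2 * pi * 3 * (0:(n - 1)) / 100)

  # spatially uniform recording: identically zero output
  rec_u <- eeg_recording(matrix(5, 5, n), 100, c("C3", "F3", "Cz", "P3", "T7"))
  expect_true(all(large_laplacian(rec_u, m) == 0))

  # center carries s(t), neighbors silent: passthrough
  rec_s <- eeg_recording(rbind(s, 0, 0, 0, 0), 100,
                         c("C3", "F3", "Cz", "P3", "T7"))
  expect_equal(as.numeric(large_laplacian(rec_s, m)), s)

  # additive common-mode on all electrodes is removed exactly
  rec_c <- eeg_recording(rbind(s + noise, noise, noise, noise, noise), 100,
                         c("C3", "F3", "Cz", "P3", "T7"))
  expect_equal(as.numeric(large_laplacian(rec_c, m)), s, tolerance = 1e-12)
})

test_that("Laplacian is linear and reports missing channels", {
  m <- montage_1020()
  chans <- c("C3", "F3", "Cz", "P3", "T7")
  set.seed(11)
  for (i in 1:5) {
    x <- matrix(rnorm(5 * 20), 5); y <- matrix(rnorm(5 * 20), 5)
    a <- rnorm(1); b <- rnorm(1)
    lx <- large_laplacian(eeg_recording(x, 100, chans), m)
    ly <- large_laplacian(eeg_recording(y, 100, chans), m)
    lxy <- large_laplacian(eeg_recording(a * x + b * y, 100, chans), m)
    expect_equal(as.numeric(lxy), as.numeric(a * lx + b * ly),
                 tolerance = 1e-10)
  }
  rec <- eeg_recording(matrix(0, 2, 5), 100, c("C3", "F3"))
  expect_error(large_laplacian(rec, m), "Cz")
})

test_that("montage and schedule JSON round-trip and validate", {
  m <- montage_1020()
  p <- withr::local_tempfile(fileext = ".json")
  write_montage(m, p)
  m2 <- read_montage(p)
  expect_equal(m2$neighbors$C3, m$neighbors$C3)
  expect_equal(m2$center, "C3")
  expect_error(
    montage_layout(data.frame(name = "C3", x = 0, y = 0),
                   list(C3 = "Xx")), "Xx")

  sch <- block_schedule(2, rest = 5, task = 5, blank = 3)
  ps <- withr::local_tempfile(fileext = ".json")
  write_schedule(sch, ps)
  expect_equal(as.data.frame(unclass(read_schedule(ps))),
               as.data.frame(unclass(sch)))
  expect_error(task_schedule(data.frame(kind = "rest", onset = 0,
                                        duration = -1)), "positive")
  expect_error(task_schedule(data.frame(kind = c("rest", "task"),
                                        onset = c(0, 3), duration = c(5, 5))),
               "overlap")
})
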