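test_that("raw float32 recordings round-trip and apply metadata scaling", {
  set.seed(1)
  rec <- recording(matrix(rnorm(2 * 25000), nrow = 2), 25000, c("e1", "e2"))
  sp <- withr::local_tempfile(fileext = ".raw")
  mp <- withr::local_tempfile(fileext = ".json")
  write_recording(rec, sp, mp)
  back <- load_recording(sp, mp)
  expect_equal(recording_duration(back), 1.0)
  expect_equal(back$channel_ids, c("e1", "e2"))
  expect_equal(back$data, rec$data, tolerance = 1e-6)  # float32 precision

  # scale_uv applied to stored counts
  con <- file(sp, "wb")
  writeBin(c(10, -20, 5, 0), con, size = 4L, endian = "little")
  close(con)
  jsonlite::write_json(list(rate_hz = 2, channel_ids = list("a", "b"),
                            scale_uv = 0.1), mp, auto_unbox = TRUE)
  r2 <- load_recording(sp, mp)
  expect_equal(r2$data[1, ], c(1.0, -2.0))
})

test_that("truncated or corrupt signal files raise format errors naming the offset", {
  sp <- withr::local_tempfile(fileext = ".raw")
  mp <- withr::local_tempfile(fileext = ".json")
  con <- file(sp, "wb")
  writeBin(as.raw(rep(0, 10)), con)  # not a whole number of float32
  close(con)
  jsonlite::write_json(list(rate_hz = 25000, channel_ids = list("e1")), mp,
                       auto_unbox = TRUE)
  expect_error(load_recording(sp, mp), "byte offset")
  # whole floats but not divisible by channel count
  con <- file(sp, "wb"); writeBin(c(1, 2, 3), con, size = 4L); close(con)
  jsonlite::write_json(list(rate_hz = 25000, channel_ids = list("e1", "e2")),
                       mp, auto_unbox = TRUE)
  expect_error(load_recording(sp, mp), "format error")
  # non-finite samples name the offending channel
  con <- file(sp, "wb"); writeBin(c(1, NaN, 3, 4), con, size = 4L); close(con)
  expect_error(load_recording(sp, mp), "e1")
})

test_that("recording invariants are enforced", {
  expect_error(recording(matrix(0, 2, 10), 25000, c("a", "a")), "unique")
  expect_error(recording(matrix(0, 2, 10), -1, c("a", "b")), "positive")
  expect_error(recording(matrix(0, 2, 10), 25000, "a"), "channel_ids")
})

test_that("channel maps validate topology and default the electrode spacing", {
  el <- data.frame(id = c("e1", "e2"), x_um = c(0, 200), y_um = 0,
                   compartment = "tunnel")
  tn <- data.frame(tunnel_id = "T1", source_compartment = "DG",
                   target_compartment = "CA3",
                   upstream_electrode_id = "e1", downstream_electrode_id = "e2")
  expect_message(map <- channel_map(el, tn), "defaulting to 200")
  expect_equal(map$tunnels$electrode_spacing_um, 200)

  ff <- tunnel_electrodes(map, "DG", "CA3", "feedforward")
  expect_equal(c(ff$upstream, ff$downstream), c("e1", "e2"))
  fb <- tunnel_electrodes(map, "DG", "CA3", "feedback")
  expect_equal(c(fb$upstream, fb$downstream), c("e2", "e1"))

  bad <- tn; bad$downstream_electrode_id <- "e9"
  expect_error(suppressMessages(channel_map(el, bad)), "unknown electrode")
  dup <- rbind(el, el[1, ])
  expect_error(suppressMessages(channel_map(dup, tn)), "duplicate")
  wrongpair <- tn; wrongpair$target_compartment <- "CA1"
  expect_error(suppressMessages(channel_map(el, wrongpair)), "adjacent")
})

test_that("orientation flips are involutive and maps round-trip via JSON", {
  el <- data.frame(id = c("e1", "e2"), x_um = c(0, 200), y_um = 0,
                   compartment = "tunnel")
  tn <- data.frame(tunnel_id = "T1", source_compartment = "EC",
                   target_compartment = "DG",
                   upstream_electrode_id = "e1", downstream_electrode_id = "e2",
                   electrode_spacing_um = 200)
  map <- channel_map(el, tn)
  p <- withr::local_tempfile(fileext = ".json")
  write_channel_map(map, p)
  map2 <- load_channel_map(p)
  for (m in list(map, map2)) {
    ff <- tunnel_electrodes(m, "EC", "DG", "feedforward")
    fb <- tunnel_electrodes(m, "EC", "DG", "feedback")
    # one flip reverses the pair; flipping the flipped pair restores it
    expect_equal(c(fb$upstream, fb$downstream), c(ff$downstream, ff$upstream))
    expect_equal(rev(c(fb$upstream, fb$downstream)),
                 c(ff$upstream, ff$downstream))
    expect_equal(c(ff$upstream, ff$downstream), c("e1", "e2"))
    expect_equal(fb$spacing_um, 200)
  }
})

test_that("event tables round-trip through CSV at millisecond precision", {
  p <- withr::local_tempfile(fileext = ".csv")
  empty <- data.frame(channel_id = character(0), event_type = character(0),
                      start_s = numeric(0), end_s = numeric(0))
  write_events(empty, p)
  expect_equal(nrow(read_events(p)), 0L)

  one <- data.frame(channel_id = "e1", event_type = "spindle",
                    start_s = 1.000, end_s = 1.650)
  write_events(one, p)
  got <- read_events(p)
  expect_equal(got$end_s - got$start_s, 0.650, tolerance = 1e-9)

  set.seed(7)
  n <- 100
  st <- round(runif(n, 0, 300), 3)
  tbl <- data.frame(channel_id = sample(c("a", "b"), n, TRUE),
                    event_type = "spindle", start_s = st,
                    end_s = st + round(runif(n, 0.3, 2), 3))
  written <- write_events(tbl, p)
  back <- read_events(p)
  expect_equal(back$start_s, written$start_s, tolerance = 5e-4)
  expect_equal(back$end_s, written$end_s, tolerance = 5e-4)

  bad <- one; bad$end_s <- 0.5
  expect_error(write_events(bad, p), "start_s > end_s")
})
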