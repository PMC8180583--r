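test_that("gaze tables round-trip losslessly including NA gaze and metadata", {
  set.seed(7)
  n <- 1000
  x <- rnorm(n, 0, 5)
  y <- rnorm(n, 3, 4)
  pupil <- rep(3, n)
  blink <- 101:110
  pupil[blink] <- 0
  x[blink] <- NA
  y[blink] <- NA
  rec <- gaze_recording((0:(n - 1)) / 60, x, y, pupil,
                        participant_id = "P07", world = "RW")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gaze_table(rec, path)
  back <- read_gaze_table(path)
  expect_equal(back$samples$t, rec$samples$t, tolerance = 1e-9)
  expect_equal(back$samples$x, rec$samples$x, tolerance = 1e-9)
  expect_identical(is.na(back$samples$x), is.na(rec$samples$x))
  expect_identical(back$samples$valid, rec$samples$valid)
  expect_identical(back$participant_id, "P07")
  expect_identical(back$world, "RW")
  expect_identical(back$tracking_range, c(60, 46))
  # rewrite is byte-stable
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_gaze_table(back, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("empty recording writes a header-only file that reads back", {
  rec <- gaze_recording(numeric(0), numeric(0), numeric(0), numeric(0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gaze_table(rec, path)
  back <- read_gaze_table(path)
  expect_equal(nrow(back$samples), 0L)
})

test_that("invalid input tables are rejected with informative errors", {
  expect_error(gaze_recording(c(0, 1, 1), 1:3, 1:3),
               "strictly increasing.*3")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y,pupil", "0,1,2,3"), path)
  expect_error(read_gaze_table(path), "missing required column.*valid")
  # rows with non-finite time are dropped and counted
  path2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("t,x,y,pupil,valid", "0,1,2,3,TRUE", "NA,1,2,3,TRUE",
               "1,1,2,3,TRUE"), path2)
  expect_message(rec <- read_gaze_table(path2), "1 row")
  expect_equal(nrow(rec$samples), 2L)
})

test_that("schema mapping renames columns from foreign headers", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("timestamp,gx,gy,ps,ok", "0,1,2,3,TRUE", "0.1,1,2,3,TRUE"),
             path)
  rec <- read_gaze_table(path, schema = c(t = "timestamp", x = "gx",
                                          y = "gy", pupil = "ps",
                                          valid = "ok"))
  expect_equal(rec$samples$x, c(1, 1))
})

test_that("sector maps validate labels and overlap, and round-trip", {
  expect_error(sector_map(0, 10, "hallway"), "unknown sector label")
  expect_error(sector_map(c(0, 5), c(10, 15),
                          c("corridor", "ascending")), "overlap")
  m <- sector_map(c(0, 10, 3), c(10, 20, 4),
                  c("corridor", "ascending", "excluded"))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_sector_map(m, path)
  back <- read_sector_map(path)
  expect_equal(as.data.frame(back), as.data.frame(m))
})

test_that("slicing uses half-open intervals and drops excluded samples", {
  rec <- make_rec(rep(0, 200), rep(0, 200), rate = 10)  # t in [0, 19.9]
  map <- sector_map(0, 10, "corridor")
  segs <- slice_by_sector(rec, map, "corridor")
  expect_length(segs, 1L)
  expect_true(all(segs[[1]]$samples$t >= 0 & segs[[1]]$samples$t < 10))
  expect_equal(nrow(segs[[1]]$samples), 100L)
  # an exclusion window removes its samples from the slice
  map2 <- sector_map(c(0, 2), c(10, 4), c("corridor", "excluded"))
  segs2 <- slice_by_sector(rec, map2, "corridor")
  expect_equal(nrow(segs2[[1]]$samples), 80L)
  expect_false(any(segs2[[1]]$samples$t >= 2 & segs2[[1]]$samples$t < 4))
  # exclusion covering the whole interval drops the segment
  map3 <- sector_map(c(0, 0), c(10, 10), c("corridor", "excluded"))
  expect_length(slice_by_sector(rec, map3, "corridor"), 0L)
  # absent label is an empty list, not an error
  expect_length(slice_by_sector(rec, map, "descending"), 0L)
})

test_that("the study route plan has 6 corridors, 4 ascending and 2 descending segments", {
  for (w in c("VR", "RW")) {
    plan <- default_sector_plan(w)
    expect_equal(sum(plan$label == "corridor"), 6L)
    expect_equal(sum(plan$label == "ascending"), 4L)
    expect_equal(sum(plan$label == "descending"), 2L)
  }
})

test_that("sector labels partition every sample exactly once and slicing is idempotent", {
  rec <- make_rec(rnorm(500), rnorm(500), rate = 25)
  plan <- sector_map(c(0, 5, 8, 12, 6), c(5, 8, 12, 18, 7),
                     c("corridor", "ascending", "descending", "corridor",
                       "excluded"))
  lab <- sample_sector_labels(rec, plan)
  expect_length(lab, 500L)
  counts <- table(lab)
  segs_n <- sum(vapply(c("corridor", "ascending", "descending"), function(L) {
    sum(vapply(slice_by_sector(rec, plan, L), function(s) nrow(s$samples), 1L))
  }, 1))
  expect_equal(segs_n + sum(lab == "excluded") + sum(lab == "unclassified"),
               500L)
  # idempotence: re-slicing a segment with the same map returns it unchanged
  seg <- slice_by_sector(rec, plan, "corridor")[[1]]
  seg2 <- slice_by_sector(seg, plan, "corridor")[[1]]
  expect_equal(seg2$samples, seg$samples)
})
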