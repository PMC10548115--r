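test_that("needle-referenced maps are verbatim concatenations", {
  prof <- fake_profiles(matrix(rnorm(40 * 6), 40),
                        retardation = matrix(runif(40 * 6, 0, pi), 40))
  m <- needle_referenced_map(prof)
  expect_equal(ncol(m$intensity_db), 6)
  expect_identical(m$retardation[, 3], prof$retardation[, 3])
  expect_identical(m$intensity_db, prof$intensity_db)
})

test_that("stationary needles give identical canvas columns", {
  npx <- 30; n <- 12
  prof <- fake_profiles(matrix(rep(sin(1:npx), n), npx), tip_pixel = 2L)
  trk <- fake_track(rep(0, n), prof$time)
  cv <- build_surface_canvas(prof, trk)
  expect_true(all(cv$tip_row == 0))
  for (j in 2:n)
    expect_identical(cv$intensity_db[, j], cv$intensity_db[, 1])
})

test_that("frozen rows never change and tip rows follow the track", {
  npx <- 20; n <- 50; pitch <- 1.87
  # monotone insertion at 2 rows per column
  p <- (0:(n - 1)) * 2 * pitch
  prof <- fake_profiles(matrix(rnorm(npx * n), npx), tip_pixel = 3L,
                        pitch = pitch)
  trk <- fake_track(p, prof$time)
  cv <- build_surface_canvas(prof, trk)
  expect_equal(cv$tip_row, round(p / pitch))
  for (j in seq(5, n - 8, by = 9)) {
    frozen <- seq_len(cv$tip_row[j]) # rows strictly above the tip at column j
    for (j2 in seq(j + 1, n, by = 7))
      expect_identical(cv$intensity_db[frozen, j2],
                       cv$intensity_db[frozen, j])
  }
})

test_that("a fixed tissue boundary maps to a constant absolute-depth row", {
  npx <- 40; n <- 60; pitch <- 1.87; tip <- 0L
  p <- (0:(n - 1)) * pitch          # one row per column
  boundary_row <- 45                # absolute depth row of a step contrast
  img <- matrix(NA_real_, npx, n)
  for (j in 1:n) {
    abs_rows <- round(p[j] / pitch) + 0:(npx - 1)
    img[, j] <- ifelse(abs_rows >= boundary_row, 10, -10)
  }
  prof <- fake_profiles(img, tip_pixel = tip, pitch = pitch)
  trk <- fake_track(p, prof$time)
  cv <- build_surface_canvas(prof, trk)
  # in the canvas the step sits at the same row in every column that saw it
  # (the boundary is inside the imaged window for columns ~8..44)
  for (j in seq(8, 44, 6)) {
    col <- cv$intensity_db[, j]
    step_at <- which(diff(col > 0) == 1) # 1-based row of abs row (step_at - 1)
    expect_equal(step_at, boundary_row)
  }
  # whereas the needle-referenced map has it sloping at needle velocity
  nm <- needle_referenced_map(prof)
  steps <- apply(nm$intensity_db[, 8:44], 2,
                 function(c) which(diff(c > 0) == 1)[1])
  expect_equal(unique(diff(steps)), -1)
})

test_that("tip-boundary slope encodes the Doppler velocity within quantization", {
  npx <- 25; n <- 80; pitch <- 1.87
  p <- cumsum(runif(n, 0, 2.2))     # variable insertion speed
  prof <- fake_profiles(matrix(0, npx, n), tip_pixel = 0L, pitch = pitch)
  trk <- fake_track(p, prof$time)
  cv <- build_surface_canvas(prof, trk)
  dp <- diff(p)
  drow <- diff(cv$tip_row) * pitch
  expect_true(all(abs(drow - dp) <= pitch))
})

test_that("retraction resumes updates below the tip but keeps rows above frozen", {
  npx <- 20; pitch <- 1.87
  p <- c(seq(0, 20, by = 2), seq(18, 10, by = -2)) * pitch
  n <- length(p)
  img <- matrix(rep(1:n, each = npx), npx)   # column index as payload
  prof <- fake_profiles(img, tip_pixel = 0L, pitch = pitch)
  cv <- build_surface_canvas(prof, fake_track(p, prof$time))
  last <- n
  tip_last <- cv$tip_row[last]               # 10 rows, retracted from 20
  # rows above the current tip keep their frozen (insertion-time) payload
  expect_true(all(cv$intensity_db[seq_len(tip_last), last] < n - 5))
  # rows just below the tip carry the latest payload again
  expect_equal(cv$intensity_db[tip_last + 1, last], n)
})

test_that("rendered frames mirror around the needle with the tip line drawn", {
  npx <- 30; n <- 10; pitch <- 1.87
  p <- (0:(n - 1)) * pitch
  prof <- fake_profiles(matrix(rnorm(npx * n), npx),
                        retardation = matrix(runif(npx * n, 0, pi), npx),
                        tip_pixel = 0L, pitch = pitch)
  cv <- build_surface_canvas(prof, fake_track(p, prof$time))
  for (f in c(3, n)) {
    ras <- render_frame(cv, f, "retardation")
    expect_equal(dim(ras)[2], 2 * f + 1)
    # mirrored halves match
    expect_equal(ras[, f + 2, ], ras[, f, ])
    # tip boundary rows are black: rightmost column shows the latest tip,
    # the column just right of the separator shows the first column's tip
    expect_true(all(ras[cv$tip_row[f] + 1:3, 2 * f + 1, ] == 0))
    expect_true(all(ras[cv$tip_row[1] + 1:3, f + 2, ] == 0))
  }
})

test_that("exported frames round-trip losslessly with an ordered manifest", {
  npx <- 12; n <- 4
  prof <- fake_profiles(matrix(rnorm(npx * n), npx), tip_pixel = 0L)
  cv <- build_surface_canvas(prof, fake_track(rep(0, n), prof$time))
  frames <- lapply(1:3, function(f) render_frame(cv, f, "intensity_db"))
  dir <- withr::local_tempdir()
  paths <- export_frames(frames, dir)
  expect_length(paths, 3)
  expect_identical(basename(paths), sort(basename(paths)))
  back <- png::readPNG(paths[2])
  expect_lt(max(abs(back - frames[[2]])), 1.01 / 255) # 8-bit quantization
  manifest <- readLines(file.path(dir, "manifest.txt"))
  expect_identical(manifest, basename(paths))
  # zero frames -> empty manifest
  export_frames(list(), dir)
  expect_length(readLines(file.path(dir, "manifest.txt")), 0)
})
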