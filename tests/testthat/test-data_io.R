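test_that("force curves round-trip through the TSV + sidecar format", {
  fc <- gen_hertz_curve(K_true = 300, noise_sd = 1e-10, seed = 42)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_force_curve(fc, path)
  back <- read_force_curve(path)
  expect_equal(back$time_s, fc$time_s, tolerance = 1e-12)
  expect_equal(back$height_m, fc$height_m, tolerance = 1e-12)
  expect_equal(back$force_n, fc$force_n, tolerance = 1e-12)
  expect_identical(back$segment, fc$segment)
  m <- curve_meta(back)
  expect_equal(m$spring_constant, 0.03)
  expect_equal(m$bead_radius, 18.64e-6)
  # second read equals first (idempotence)
  again <- read_force_curve(path)
  expect_identical(as.data.frame(back), as.data.frame(again))
})

test_that("segment labels survive a round trip via the sidecar", {
  rec <- gen_creep_record(k_l = 0.1, k_a = 0.03, eta = 0.05)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_force_curve(rec, path)
  back <- read_force_curve(path)
  expect_identical(unique(back$segment), c("extend", "hold"))
  expect_equal(sum(back$segment == "hold"), sum(rec$segment == "hold"))
})

test_that("missing required columns raise a format error naming the column", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("time_s\theight_m", "0\t0", "0.001\t1e-9"), path)
  writeLines("spring_constant_n_per_m = 0.03\nbead_radius_m = 1e-5",
             paste0(path, ".meta"))
  expect_error(read_force_curve(path), "force", class = "tm_format_error")
})

test_that("unit dialects canonicalize to identical SI values", {
  # same 3-row curve in native SI and in the nN/um dialect
  si <- withr::local_tempfile(fileext = ".tsv")
  dial <- withr::local_tempfile(fileext = ".tsv")
  meta <- "spring_constant_n_per_m = 0.03\nbead_radius_m = 1.864e-05"
  writeLines(c("time_s\theight_m\tforce_n",
               "0\t0\t0",
               "0.001\t5e-09\t1e-10",
               "0.002\t1e-08\t2.5e-09"), si)
  writeLines(meta, paste0(si, ".meta"))
  writeLines(c("time_ms\theight_um\tforce_nn",
               "0\t0\t0",
               "1\t0.005\t0.1",
               "2\t0.01\t2.5"), dial)
  writeLines(meta, paste0(dial, ".meta"))
  a <- read_force_curve(si)
  b <- read_force_curve(dial)
  expect_equal(b$time_s, a$time_s)
  expect_equal(b$height_m, a$height_m)
  expect_equal(b$force_n, a$force_n)
})

test_that("non-monotonic time within a segment is a format error", {
  df <- data.frame(time_s = c(0, 2e-3, 1e-3), height_m = 1:3 * 1e-9,
                   force_n = 0, segment = "extend")
  expect_error(force_curve(df, 0.03, 1e-5), class = "tm_format_error")
})

test_that("stiffness maps round-trip exactly, including missing cells", {
  k <- matrix(c(100, 300, 200, NA), 2, 2)
  map <- stiffness_map(k, spacing = 25e-6)
  path <- withr::local_tempfile(fileext = ".csv")
  write_stiffness_map(map, path)
  back <- read_stiffness_map(path)
  expect_identical(back$k, k)
  expect_equal(back$spacing, 25e-6)
  # exactly three numeric cells in the file body
  body <- readLines(path)
  body <- body[!startsWith(body, "#")]
  cells <- unlist(strsplit(body, ","))
  expect_identical(sum(cells != "NA"), 3L)
  # all-missing map is valid
  m2 <- stiffness_map(matrix(NA_real_, 2, 3), spacing = 1e-5)
  p2 <- withr::local_tempfile()
  write_stiffness_map(m2, p2)
  expect_true(all(is.na(read_stiffness_map(p2)$k)))
})

test_that("ragged map rows are a format error", {
  path <- withr::local_tempfile()
  writeLines(c("# spacing_m = 1e-05", "1,2,3", "4,5"), path)
  expect_error(read_stiffness_map(path), "ragged", class = "tm_format_error")
})

test_that("map files preserve the lower-left origin convention", {
  # row 1 = bottom; the file is written top row first
  k <- matrix(c(1, 2, 3, 4), 2, 2)  # [1,1]=1 bottom-left, [2,1]=2 top-left
  path <- withr::local_tempfile()
  write_stiffness_map(stiffness_map(k), path)
  body <- readLines(path)
  body <- body[!startsWith(body, "#")]
  expect_identical(body[1], "2,4")  # top row first
  expect_identical(read_stiffness_map(path)$k, k)
})

test_that("vector fields round-trip with frame gaps preserved", {
  fld <- gen_displacement_frames(nx = 3, ny = 3, nz = 2, n_frames = 2)
  frames <- fld$frames
  frames$frame[frames$frame == 1L] <- 2L  # gap {0, 2}
  path <- withr::local_tempfile(fileext = ".tsv")
  write_vector_field(frames, path)
  back <- read_vector_field(path)
  expect_identical(sort(unique(back$frame)), c(0L, 2L))
  expect_equal(nrow(back), nrow(frames))
  expect_equal(back$ux_m, frames$ux_m[order(frames$frame)], tolerance = 1e-12)
})

test_that("vector field readers reject duplicates and non-finite coordinates", {
  fr <- make_frame(matrix(1e-6, 2, 3))
  fr$x_m[2] <- fr$x_m[1]  # duplicate node
  path <- withr::local_tempfile()
  write_vector_field(fr, path)
  expect_error(read_vector_field(path), "duplicate",
               class = "tm_format_error")
  fr2 <- make_frame(matrix(1e-6, 2, 3))
  fr2$x_m[2] <- NaN
  p2 <- withr::local_tempfile()
  write_vector_field(fr2, p2)
  expect_error(suppressMessages(read_vector_field(p2)),
               class = "tm_format_error")
})

test_that("TIFF stacks round-trip as matrices and arrays", {
  img <- matrix(runif(64), 8, 8)
  path <- withr::local_tempfile(fileext = ".tif")
  write_image_stack(img, path)
  back <- read_image_stack(path)
  expect_equal(back, img, tolerance = 1e-4)  # 16-bit quantization
  stack <- array(runif(8 * 8 * 3), c(8, 8, 3))
  write_image_stack(stack, path)
  expect_equal(dim(read_image_stack(path)), c(8, 8, 3))
})
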