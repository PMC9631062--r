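# Serialization, image composition and pixel-response correction.

test_that("spb serialization round-trips bit-exactly, including odd widths", {
  for (dims in list(c(4, 4, 3), c(3, 5, 7), c(9, 13, 4), c(1, 17, 2))) {
    s <- random_stack(dims[1], dims[2], dims[3], seed = sum(dims))
    path <- withr::local_tempfile(fileext = ".spb")
    write_stack(s, path)
    s2 <- read_stack(path)
    expect_identical(s2$planes, s$planes)
    expect_equal(s2$frame_rate_Hz, s$frame_rate_Hz)
    expect_equal(s2$metadata$note, "random fixture")
  }
})

test_that("spb file size follows the header + packed-payload arithmetic", {
  s <- random_stack(8, 10, 25, seed = 3)
  s$metadata <- list()
  path <- withr::local_tempfile(fileext = ".spb")
  write_stack(s, path)
  meta_len <- nchar(as.character(jsonlite::toJSON(list())))
  expect_equal(file.size(path), 32 + meta_len + 25 * ceiling(8 * 10 / 8))
})

test_that("malformed spb files are rejected with the failing offset", {
  s <- random_stack(4, 4, 2)
  path <- withr::local_tempfile(fileext = ".spb")
  write_stack(s, path)
  bad <- readBin(path, "raw", file.size(path))
  bad[1:4] <- charToRaw("NOPE")
  path2 <- withr::local_tempfile(fileext = ".spb")
  writeBin(bad, path2)
  expect_error(read_stack(path2), "bad magic at offset 0")
  good <- readBin(path, "raw", file.size(path))
  path3 <- withr::local_tempfile(fileext = ".spb")
  writeBin(good[1:(length(good) - 1)], path3)   # truncate last plane
  expect_error(read_stack(path3), "truncated plane")
})

test_that("TIFF interchange preserves the binary planes", {
  s <- random_stack(6, 7, 5, seed = 8)
  path <- withr::local_tempfile(fileext = ".tif")
  write_stack_tiff(s, path)
  s2 <- read_stack_tiff(path, frame_rate_Hz = s$frame_rate_Hz)
  expect_identical(s2$planes, s$planes)
})

test_that("compose_image sums planes and is additive over intervals", {
  planes <- array(0L, dim = c(2, 2, 3))
  planes[1, 1, ] <- c(1L, 1L, 0L)    # shared 1-pixel in planes 1 and 2
  planes[2, 2, 2] <- 1L
  s <- bit_plane_stack(planes, 9938.4)
  img <- compose_image(s)
  expect_equal(img$values[1, 1], 2)
  expect_equal(img$values[2, 2], 1)
  # additivity over disjoint intervals
  i12 <- compose_image(s, c(1, 2)); i3 <- compose_image(s, c(3, 3))
  expect_equal(i12$values + i3$values, img$values)
  # all-zero stack -> all-zero image
  z <- bit_plane_stack(array(0L, dim = c(2, 2, 2)), 100)
  z$planes[1, 1, 1] <- 1L; z$planes[1, 1, 1] <- 0L
  expect_true(all(compose_image(z)$values == 0))
  expect_error(compose_image(s, c(2, 1)), "invalid plane interval")
  expect_error(compose_image(s, c(1, 9)), "outside stack")
})

test_that("composed pixel sums match the binomial oracle", {
  lam <- 0.2; np <- 10000
  s <- constant_stack(lam, 8, 8, np, seed = 12)
  img <- compose_image(s)
  p <- -expm1(-lam)             # 0.18127; expected sum 1812.7
  se_mean <- sqrt(np * p * (1 - p) / 64)
  expect_lt(abs(mean(img$values) - np * p), 3 * se_mean)
})

test_that("occupancy inversion recovers the photon rate", {
  # exact inverse at a noiseless occupancy
  s <- constant_stack(0.5, 4, 4, 10)
  img <- compose_image(s)
  img$values[] <- round((1 - exp(-1)) * 10)  # craft p-hat = 1 - e^-1 ... n=10
  sensor0 <- sensor_model(width = 4, height = 4, dark_count_rate_cps = 0)
  # use an occupancy that is exactly representable: 6321/10000
  img$n_planes_summed <- 10000L
  img$values[] <- 6321
  cor <- correct_image(img, sensor0)
  expect_equal(unique(as.vector(cor$values)), 1.0, tolerance = 1e-3)
  # p-hat = 0 -> 0; p-hat = 1 -> documented cap
  img2 <- img; img2$corrected <- c(dark = FALSE, log = FALSE)
  img2$values[] <- 0
  expect_true(all(correct_image(img2, sensor0)$values == 0))
  img3 <- img; img3$corrected <- c(dark = FALSE, log = FALSE)
  img3$values[] <- 10000
  expect_equal(unique(as.vector(correct_image(img3, sensor0)$values)),
               -log(1 / (2 * 10000)))
  expect_error(correct_image(cor, sensor0), "already corrected")
})

test_that("dark-count subtraction recovers the true signal rate", {
  lam_true <- 0.5; dark <- 0.05; np <- 10000
  s <- constant_stack(lam_true, 8, 8, np, seed = 21, dark = dark)
  sensor <- sensor_model(width = 8, height = 8, frame_rate_Hz = 9938.4,
                         dark_count_rate_cps = dark * 9938.4)
  cor <- correct_image(compose_image(s), sensor)
  p <- -expm1(-(lam_true + dark))
  se <- sqrt(p * (1 - p) / np) / (1 - p) / sqrt(64)   # delta method, 64 px
  expect_lt(abs(mean(cor$values) - lam_true), 3 * se)
})
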