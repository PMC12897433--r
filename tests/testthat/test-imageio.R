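test_that("images round-trip losslessly through every format", {
  set.seed(1)
  m <- matrix(sample(0:65535, 100 * 100, replace = TRUE), 100, 100)
  img <- shg_image(m, image_id = "rt")
  for (fmt in c("tiff", "text")) {
    path <- tempfile(fileext = paste0(".", fmt))
    write_image(img, path, fmt)
    back <- read_image(path, fmt)
    expect_equal(back$counts, img$counts, ignore_attr = TRUE)
  }
  # png carries 8 bits
  m8 <- matrix(sample(0:255, 400, replace = TRUE), 20, 20)
  path <- tempfile(fileext = ".png")
  write_image(shg_image(m8), path)
  expect_equal(read_image(path)$counts, m8, ignore_attr = TRUE)
  expect_error(write_image(img, path, "png"), "8-bit")
})

test_that("multi-channel input is rejected", {
  path <- tempfile(fileext = ".png")
  png::writePNG(array(runif(20 * 20 * 3), c(20, 20, 3)), path)
  expect_error(read_image(path, "png"), "single-channel")
})

test_that("pixel coordinate convention survives a round-trip", {
  m <- matrix(0L, 30, 30)
  m[1, 30] <- 7L   # top-right corner
  img <- shg_image(m)
  path <- tempfile(fileext = ".tif")
  write_image(img, path)
  back <- read_image(path)
  expect_equal(back$counts[1, 30], 7)
  expect_equal(sum(back$counts), 7)
})

test_that("size and range invariants are enforced", {
  expect_error(shg_image(matrix(0, 5, 5)), "at least 20 x 20")
  # tiny text matrices parse when the minimum-size check is relaxed
  path <- tempfile(fileext = ".txt")
  writeLines(c("0 1", "2 3"), path)
  expect_error(read_image(path, "text"), "at least")
  small <- read_image(path, "text", min_size = 2)
  expect_equal(small$counts, matrix(0:3, 2, 2, byrow = TRUE),
               ignore_attr = TRUE)
  # negative text values rejected
  writeLines(c("0 -1", "2 3"), path)
  expect_error(read_image(path, "text", min_size = 2), "negative")
  # bit-depth overflow is an error on write, not a silent clip
  big <- shg_image(matrix(70000L, 20, 20))
  expect_error(write_image(big, tempfile(fileext = ".tif")), "65535")
  expect_error(write_image(big, tempfile(fileext = ".png")), "255")
  expect_silent(write_image(big, tempfile(fileext = ".txt"), "text"))
})

test_that("manifests round-trip and are validated", {
  dir <- tempfile()
  ds <- generate_dataset(seed = 3, dir = dir, format = "text")
  mf <- read_manifest(file.path(dir, "manifest.csv"))
  expect_equal(nrow(mf), 240)
  expect_equal(length(unique(mf$group)), 4)
  imgs <- load_images(mf[1:3, ])
  expect_equal(imgs[[1]]$counts, ds$images[[1]]$counts, ignore_attr = TRUE)
  expect_equal(imgs[[1]]$group, ds$manifest$group[1])

  # header-only manifest: empty dataset with a warning
  empty <- file.path(dir, "empty.csv")
  writeLines(paste(shgfib:::manifest_columns, collapse = ","), empty)
  expect_warning(e <- read_manifest(empty), "no rows")
  expect_equal(nrow(e), 0)

  # a row referencing a missing file names the row
  m2 <- mf
  m2$path[2] <- file.path(dir, "nope.txt")
  bad <- file.path(dir, "bad.csv")
  write_manifest(m2, bad)
  expect_error(read_manifest(bad), "row 2")

  # duplicate ids and unknown groups rejected
  m3 <- mf
  m3$image_id[2] <- m3$image_id[1]
  write_manifest(m3, bad)
  expect_error(read_manifest(bad), "duplicate")
  m4 <- mf
  m4$group[1] <- "X"
  write_manifest(m4, bad)
  expect_error(read_manifest(bad), "unknown group")
})
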