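test_that("PNG decoding is an exact identity on lossless fixtures", {
  p <- withr::local_tempfile(fileext = ".png")

  write_image(uniform_image(1, 1, 0, 255, 0), p)
  img <- load_image(p)
  expect_identical(img$R, matrix(0L, 1, 1))
  expect_identical(img$G, matrix(255L, 1, 1))
  expect_identical(img$B, matrix(0L, 1, 1))

  write_image(uniform_image(2, 2, 255, 255, 255), p)
  white <- load_image(p)
  expect_true(all(white$R == 255L) && all(white$G == 255L) && all(white$B == 255L))
  expect_equal(dim(white), c(2L, 2L))
})

test_that("a generated 64x64 image survives a write/read round trip element-wise", {
  gen <- generate_synthetic_image(height = 64, width = 64, seed = 11)
  p <- withr::local_tempfile(fileext = ".png")
  write_image(gen$image, p)
  back <- load_image(p)
  expect_identical(back$R, gen$image$R)
  expect_identical(back$G, gen$image$G)
  expect_identical(back$B, gen$image$B)
})

test_that("load_image rejects missing files, bad formats and greyscale rasters", {
  expect_error(load_image("no/such/file.png"), class = "icgquant_io_error")
  expect_error(load_image("no/such/file.png"), "no/such/file.png")
  bad <- withr::local_tempfile(fileext = ".txt")
  writeLines("not an image", bad)
  expect_error(load_image(bad), class = "icgquant_unsupported_format")
  grey <- withr::local_tempfile(fileext = ".png")
  png::writePNG(matrix(runif(16), 4, 4), grey)
  expect_error(load_image(grey), class = "icgquant_unsupported_format")
})

test_that("alpha channels are dropped with a warning", {
  p <- withr::local_tempfile(fileext = ".png")
  arr <- array(runif(4 * 4 * 4), dim = c(4, 4, 4))
  png::writePNG(arr, p)
  expect_warning(img <- load_image(p), "Alpha")
  expect_equal(dim(img), c(4L, 4L))
})

test_that("green dominance is strict: pure green in, white and ties out", {
  expect_true(green_dominance_mask(uniform_image(1, 1, 0, 255, 0))[1, 1])
  expect_false(green_dominance_mask(uniform_image(1, 1, 255, 255, 255))[1, 1])
  expect_false(green_dominance_mask(uniform_image(1, 1, 100, 100, 50))[1, 1])
  expect_false(green_dominance_mask(uniform_image(1, 1, 7, 7, 7))[1, 1])
})

test_that("dominance rule matches full enumeration of {0,100,255}^3", {
  combos <- expand.grid(r = c(0, 100, 255), g = c(0, 100, 255), b = c(0, 100, 255))
  img <- rgb_image(matrix(as.integer(combos$r), 27, 1),
                   matrix(as.integer(combos$g), 27, 1),
                   matrix(as.integer(combos$b), 27, 1))
  got <- green_dominance_mask(img)[, 1]
  want <- mapply(function(r, g, b) g > r && g > b, combos$r, combos$g, combos$b)
  expect_identical(got, unname(want))
})

test_that("masking is idempotent and never retains R=G=B pixels", {
  set.seed(42)
  img <- random_image(12, 9)
  m1 <- green_dominance_mask(img)
  m2 <- green_dominance_mask(img)
  expect_identical(m1, m2)
  equalpix <- img$R == img$G & img$G == img$B
  expect_false(any(m1[equalpix]))
})

test_that("extract_roi_values returns exactly the retained greens, row-major", {
  img <- uniform_image(20, 20, 0, 134, 0)
  vals <- extract_roi_values(img, roi(0, 0, 10, 10))
  expect_identical(vals, rep(134L, 100))

  # 40 white pixels scattered in the rectangle, 60 green ones
  img2 <- uniform_image(10, 10, 0, 150, 0)
  set.seed(7)
  white <- sample(100, 40)
  img2$R[white] <- 255L; img2$G[white] <- 255L; img2$B[white] <- 255L
  vals2 <- extract_roi_values(img2, roi(0, 0, 10, 10))
  expect_identical(vals2, rep(150L, 60))

  expect_identical(extract_roi_values(uniform_image(3, 3, 9, 9, 9), roi(1, 1, 1, 1)),
                   integer(0))
})

test_that("row-major ordering of extracted values follows the image layout", {
  G <- matrix(0L, 3, 4)
  G[2, ] <- c(10L, 20L, 30L, 40L)
  G[3, ] <- c(50L, 60L, 70L, 80L)
  img <- rgb_image(matrix(0L, 3, 4), G, matrix(0L, 3, 4))
  vals <- extract_roi_values(img, roi(1, 0, 2, 4))
  expect_identical(vals, c(10L, 20L, 30L, 40L, 50L, 60L, 70L, 80L))
})

test_that("ROI bounds are enforced with the offending coordinates named", {
  img <- uniform_image(10, 10, 0, 100, 0)
  expect_error(extract_roi_values(img, roi(5, 5, 10, 10)),
               class = "icgquant_roi_bounds")
  expect_error(extract_roi_values(img, roi(5, 5, 10, 10)), "\\[5, 15\\)")
})

test_that("roi_statistics computes the documented summary", {
  st <- roi_statistics(rep(134L, 100), 100)
  expect_equal(st$mean, 134)
  expect_equal(st$sd, 0)
  expect_equal(st$median, 134)
  expect_equal(st$histogram[135], 100L)
  expect_equal(sum(st$histogram), st$n_retained)

  st2 <- roi_statistics(rep(150L, 60), 100)
  expect_equal(st2$n_retained, 60L)
  expect_equal(st2$n_total, 100L)
  expect_equal(st2$mean, 150)

  st3 <- roi_statistics(c(0L, 255L), 4)
  expect_equal(st3$mean, 127.5)
  expect_equal(st3$min, 0L)
  expect_equal(st3$max, 255L)

  expect_error(roi_statistics(integer(0), 100), class = "icgquant_empty_roi")
})

test_that("roi_statistics order invariants hold on random samples", {
  set.seed(31)
  for (i in 1:20) {
    vals <- sample(0:255, sample(2:400, 1), TRUE)
    st <- roi_statistics(vals, length(vals))
    expect_true(st$min <= st$q1 && st$q1 <= st$median &&
                  st$median <= st$q3 && st$q3 <= st$max)
    expect_true(st$mean >= 0 && st$mean <= 255)
    expect_equal(sum(st$histogram), st$n_retained)
  }
})

test_that("segment pooling is pixel-weighted, not a mean of ROI means", {
  img <- uniform_image(10, 30, 0, 140, 0)
  img$G[, 11:20] <- 160L
  q <- quantify_segment(img, list(roi(0, 0, 10, 10), roi(0, 10, 10, 10)))
  expect_equal(q$pooled_mean, 150)

  # 100 retained pixels at 100 plus a half-masked ROI of 50 pixels at 200:
  # the pooled mean is (100*100 + 50*200) / 150, not (100 + 200) / 2
  img2 <- uniform_image(10, 20, 0, 100, 0)
  img2$G[, 11:20] <- 200L
  img2$R[1:5, 11:20] <- 255L; img2$G[1:5, 11:20] <- 255L; img2$B[1:5, 11:20] <- 255L
  q2 <- quantify_segment(img2, list(roi(0, 0, 10, 10), roi(0, 10, 10, 10)))
  expect_equal(q2$pooled_mean, (100 * 100 + 50 * 200) / 150)
  expect_equal(q2$n_retained, 150L)

  img3 <- uniform_image(50, 50, 0, 147, 0)
  rois <- lapply(0:9, function(k) roi((k %/% 5) * 10, (k %% 5) * 10, 10, 10))
  expect_equal(quantify_segment(img3, rois)$pooled_mean, 147)
})

test_that("pooled mean equals a naive per-pixel loop on random 8x8 images", {
  set.seed(99)
  for (i in 1:25) {
    img <- random_image(8, 8)
    ref <- naive_pooled_mean(img)
    if (length(ref) == 0) {
      expect_error(quantify_segment(img, list(roi(0, 0, 8, 8))),
                   class = "icgquant_empty_roi")
    } else {
      q <- quantify_segment(img, list(roi(0, 0, 8, 8)))
      expect_identical(sort(q$pooled_values), sort(as.integer(ref)))
      expect_equal(q$pooled_mean, mean(ref))
    }
  }
})

test_that("white reflections only shrink n_retained, never shift remaining values", {
  set.seed(5)
  gen <- generate_synthetic_image(height = 40, width = 40, noise_sd = 6,
                                  reflection_fraction = 0, n_vessels = 0, seed = 21)
  img <- gen$image
  r <- roi(5, 5, 20, 20)
  before <- quantify_segment(img, list(r))

  whitened <- img
  hit <- sample(1600, 300)
  whitened$R[hit] <- 255L; whitened$G[hit] <- 255L; whitened$B[hit] <- 255L
  after <- quantify_segment(whitened, list(r))

  # retained pixels of the whitened image are a subset with unchanged values
  keep <- matrix(TRUE, 40, 40); keep[hit] <- FALSE
  inside <- keep[6:25, 6:25]
  expect_equal(after$n_retained, sum(inside))
  expect_equal(after$pooled_mean, mean(img$G[6:25, 6:25][inside]))
  expect_lte(after$n_retained, before$n_retained)
})

test_that("auto-sampled ROIs are non-overlapping, valid and deterministic", {
  img <- uniform_image(60, 60, 0, 120, 0)
  rois <- auto_sample_rois(img, n = 10, size = 10, seed = 3)
  expect_length(rois, 10)
  for (i in seq_along(rois)) {
    for (j in seq_len(i - 1)) {
      a <- rois[[i]]; b <- rois[[j]]
      disjoint <- a$row0 + a$height <= b$row0 || b$row0 + b$height <= a$row0 ||
        a$col0 + a$width <= b$col0 || b$col0 + b$width <= a$col0
      expect_true(disjoint)
    }
  }
  again <- auto_sample_rois(img, n = 10, size = 10, seed = 3)
  expect_identical(rois, again)
})

test_that("auto-sampling never touches a saturated vessel stripe", {
  img <- uniform_image(50, 50, 0, 120, 0)
  img$G[, 25:26] <- 255L   # green-dominant, near-saturated: a vessel
  rois <- auto_sample_rois(img, n = 6, size = 10, seed = 8)
  for (r in rois) {
    cols <- (r$col0 + 1):(r$col0 + r$width)
    expect_false(any(cols %in% 25:26))
  }
})

test_that("auto-sampling reports a sampling failure when the image is inadmissible", {
  img <- uniform_image(30, 30, 0, 254, 0)  # everything at the saturation cutoff
  expect_error(auto_sample_rois(img, n = 3, size = 10, seed = 1,
                                max_attempts = 200),
               class = "icgquant_sampling_failure")
  expect_error(auto_sample_rois(img, n = 3, size = 10, seed = 1,
                                max_attempts = 200),
               "placed 0 of 3")
})

test_that("pixel export round-trips and coordinates match image positions", {
  img <- uniform_image(10, 10, 0, 90, 0)
  img$G[3, 4] <- 201L          # 0-based (2, 3)
  img$R[1, 1] <- 255L; img$G[1, 1] <- 255L; img$B[1, 1] <- 255L  # discarded
  p <- withr::local_tempfile(fileext = ".csv")
  export_pixels(img, roi(0, 0, 10, 10), p)
  tab <- read_pixel_export(p)
  expect_equal(nrow(tab), 99)
  expect_equal(tab$green[tab$row == 2 & tab$col == 3], 201L)
  expect_false(any(tab$row == 0 & tab$col == 0))
  # every exported coordinate holds the exported value in the source image
  expect_true(all(img$G[cbind(tab$row + 1, tab$col + 1)] == tab$green))

  img3 <- uniform_image(2, 2, 0, 50, 0)
  img3$R[2, ] <- 60L  # bottom row not green-dominant
  p3 <- withr::local_tempfile(fileext = ".csv")
  export_pixels(img3, roi(0, 0, 2, 2), p3)
  expect_equal(nrow(read_pixel_export(p3)), 2)
})

test_that("report bundle is complete and internally consistent", {
  gen <- generate_synthetic_image(height = 48, width = 48, noise_sd = 5,
                                  reflection_fraction = 0.05, n_vessels = 1,
                                  seed = 13)
  img <- gen$image
  rois <- auto_sample_rois(img, n = 3, size = 10, seed = 2)
  out <- withr::local_tempdir()
  q <- quantify_segment(img, rois)
  paths <- render_report(img, rois, out, summary = q)
  expect_length(paths, 4)
  expect_true(all(file.exists(paths)))
  expect_true(all(file.size(paths) > 0))

  js <- jsonlite::read_json(paths[["summary"]])
  expect_equal(js$pooled_mean, q$pooled_mean)

  overlay <- load_image(paths[["overlay"]])
  expect_equal(dim(overlay), dim(img))
})
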