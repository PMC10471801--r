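test_that("an empty scene is all background with no lines", {
  sc <- generate_scene(scene_config(n_plots = 0L, seed = 1))
  expect_true(all(sc$mask == 0L))
  expect_length(sc$lines, 0)
  expect_equal(dim(sc$image), c(256, 256, 3))
})

test_that("scene generation is a deterministic function of its config", {
  a <- generate_scene(scene_config(n_plots = 2L, seed = 7))
  b <- generate_scene(scene_config(n_plots = 2L, seed = 7))
  expect_identical(a$image, b$image)
  expect_identical(a$mask, b$mask)
  expect_identical(a$lines, b$lines)
  d <- generate_scene(scene_config(n_plots = 2L, seed = 8))
  expect_false(identical(a$mask, d$mask))
})

test_that("every true line lies on a mask class transition along its span", {
  for (seed in c(2, 9, 21)) {
    sc <- generate_scene(scene_config(n_plots = 2L, seed = seed))
    H <- nrow(sc$mask); W <- ncol(sc$mask)
    for (ln in sc$lines) {
      lo <- max(ln$span[1] + 1, 1); hi <- min(ln$span[2] - 1, if (ln$orientation == "horizontal") W - 2 else H - 2)
      at <- seq(lo, hi, length.out = 15)
      for (t in at) {
        if (ln$orientation == "horizontal") {
          x <- round(t); y <- ln$coefficients[1] + ln$coefficients[2] * x
          col <- x + 1L
          rows <- (round(y) - 1L):(round(y) + 2L)
          rows <- rows[rows >= 1 & rows <= H]
          vals <- sc$mask[rows, col]
        } else {
          y <- round(t); x <- ln$coefficients[1] + ln$coefficients[2] * y
          row <- y + 1L
          cols <- (round(x) - 1L):(round(x) + 2L)
          cols <- cols[cols >= 1 & cols <= W]
          vals <- sc$mask[row, cols]
        }
        # a class transition within 1 px of the line
        expect_gt(length(unique(vals)), 1)
      }
    }
  }
})

test_that("a single axis-aligned-ish plot yields 4 true lines with the stated slopes", {
  sc <- generate_scene(scene_config(n_plots = 1L, max_edge_slope = 0.2, seed = 5))
  expect_length(sc$lines, 4)
  orient <- vapply(sc$lines, function(l) l$orientation, "")
  expect_equal(sum(orient == "horizontal"), 2)
  expect_equal(sum(orient == "vertical"), 2)
  slopes <- vapply(sc$lines, function(l) abs(l$coefficients[2]), 1)
  expect_true(all(slopes <= 0.2))
})

test_that("zero noise is the identity and flips hit their rate", {
  sc <- generate_scene(scene_config(n_plots = 1L, seed = 3))
  expect_identical(perturb_mask(sc$mask, noise_config()), sc$mask)

  n <- noise_config(flip_rate = 0.05, seed = 1)
  m <- matrix(0L, 256, 256)
  out <- perturb_mask(m, n)
  frac <- mean(out != m)
  sd3 <- 3 * sqrt(0.05 * 0.95 / length(m))
  expect_lt(abs(frac - 0.05), sd3)
  expect_error(noise_config(flip_rate = 0.6), "flip_rate")
})

test_that("boundary jitter roughly preserves region area", {
  sc <- generate_scene(scene_config(n_plots = 1L, seed = 12))
  area0 <- sum(sc$mask != 0)
  rel <- vapply(1:50, function(s) {
    out <- perturb_mask(sc$mask, noise_config(jitter_sigma = 2, seed = s))
    abs(sum(out != 0) - area0) / area0
  }, 1)
  expect_lt(max(rel), 0.10)
})

test_that("noise substreams leave geometry untouched", {
  a <- generate_scene(scene_config(n_plots = 2L, seed = 4,
                                   texture = list(noise_sd = 5, stripe_amp = 0)))
  b <- generate_scene(scene_config(n_plots = 2L, seed = 4,
                                   texture = list(noise_sd = 25, stripe_amp = 10)))
  expect_identical(a$mask, b$mask)
  expect_identical(a$lines, b$lines)
})

test_that("fixture sets round-trip through the dataset layout", {
  out <- file.path(tempdir(), "fixtures-test")
  on.exit(unlink(out, recursive = TRUE))
  cfgs <- lapply(1:4, function(i) scene_config(size = c(128, 128),
                                               n_plots = (i %% 2) + 1L, seed = i))
  nms <- write_fixture_set(cfgs, out)
  expect_length(nms, 4)
  expect_true(all(file.exists(file.path(out, "images", paste0(nms, ".png")))))
  expect_true(all(file.exists(file.path(out, "truth", paste0(nms, ".lines.json")))))

  # re-run: byte-identical files
  sums1 <- tools::md5sum(list.files(out, recursive = TRUE, full.names = TRUE))
  write_fixture_set(cfgs, out)
  expect_identical(tools::md5sum(list.files(out, recursive = TRUE, full.names = TRUE)), sums1)

  # masks read back re-derive the configured number of plots
  for (i in seq_along(nms)) {
    m <- read_mask(file.path(out, "masks", paste0(nms[i], ".png")))
    rm_ <- label_regions(m != 0, min_area = 10)
    expect_equal(nrow(rm_$regions), cfgs[[i]]$n_plots)
    tr <- jsonlite::read_json(file.path(out, "truth", paste0(nms[i], ".lines.json")))
    expect_length(tr, 4 * cfgs[[i]]$n_plots)
  }
})
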