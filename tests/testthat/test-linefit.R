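test_that("an axis-aligned rectangle splits into 2 horizontal and 2 vertical sets", {
  m <- rect_mask(160, 160, 30, 129, 20, 119, 1L)  # 100 x 100 plot
  rm_ <- label_regions(binarize_and_clean(m, 1L, 1L), min_area = 10)
  bp <- trace_boundary(rm_, 1L)
  sets <- split_orientation(bp, orientation_rule(delta_threshold = 20,
                                                 gap_threshold = 20))
  expect_length(sets$horizontal, 2)
  expect_length(sets$vertical, 2)
  # each horizontal set hugs one y level
  ys <- sort(vapply(sets$horizontal, function(s) mean(s[, 2]), 1))
  expect_equal(ys, c(29, 128), tolerance = 1e-6)
  expect_error(split_orientation(matrix(0, 3, 2)), "at least 4")
})

test_that("least-squares fits are exact on noiseless lines", {
  x <- 0:9
  fit <- fit_line_ls(cbind(x, 2 * x + 1), order = 1)
  expect_equal(fit$line$coefficients, c(1, 2), tolerance = 1e-10)
  expect_equal(fit$diagnostics$S, 0, tolerance = 1e-18)

  flat <- fit_line_ls(cbind(x, rep(5, 10)), order = 1)
  expect_equal(flat$line$coefficients, c(5, 0), tolerance = 1e-10)

  # vertical orientation swaps the axes
  v <- fit_line_ls(cbind(3 + 0.5 * (0:9), 0:9), order = 1,
                   orientation = "vertical")
  expect_equal(v$line$coefficients, c(3, 0.5), tolerance = 1e-10)

  expect_error(fit_line_ls(cbind(rep(2, 6), 1:6), order = 1),
               "degenerate orientation")
  expect_error(fit_line_ls(cbind(1:2, 1:2), order = 1), "at least")
})

test_that("noisy-slope recovery is within the OLS sampling bound", {
  errs <- vapply(1:20, function(s) {
    set.seed(s)
    x <- seq(0, 199)
    y <- 30 + 0.2 * x + rnorm(200, 0, 1)
    abs(fit_line_ls(cbind(x, y))$line$coefficients[2] - 0.2)
  }, 1)
  expect_true(all(errs < 0.02))
})

test_that("fit_line_ls minimizes the residual sum of squares", {
  set.seed(2)
  pts <- cbind(0:49, 5 + 0.3 * (0:49) + rnorm(50, 0, 2))
  fit <- fit_line_ls(pts)
  S0 <- fit$diagnostics$S
  th <- fit$line$coefficients
  for (d in list(c(1e-3, 0), c(-1e-3, 0), c(0, 1e-3), c(0, -1e-3))) {
    S1 <- sum((pts[, 2] - (th[1] + d[1]) - (th[2] + d[2]) * pts[, 1])^2)
    expect_gte(S1, S0)
  }
  # permutation invariance
  fit2 <- fit_line_ls(pts[sample(nrow(pts)), ])
  expect_equal(fit2$line$coefficients, th, tolerance = 1e-10)
})

test_that("standardized-residual screening removes gross outliers and refits", {
  x <- 0:19
  pts <- rbind(cbind(x, 2 * x + 1), c(5, 100))
  plain <- fit_line_ls(pts)
  expect_gt(max(plain$diagnostics$z), 3)
  rob <- remove_outliers_and_refit(pts, z_max = 3)
  expect_equal(rob$diagnostics$removed, 21L)
  expect_equal(rob$line$coefficients, c(1, 2), tolerance = 1e-8)

  # with no outliers the screen is a fixed point
  clean <- cbind(x, 2 * x + 1)
  expect_equal(remove_outliers_and_refit(clean)$line$coefficients,
               fit_line_ls(clean)$line$coefficients)
  expect_length(remove_outliers_and_refit(clean)$diagnostics$removed, 0)

  # infinite cutoff never removes
  inf <- remove_outliers_and_refit(pts, z_max = Inf)
  expect_length(inf$diagnostics$removed, 0)
  expect_equal(inf$line$coefficients, plain$line$coefficients)

  expect_error(remove_outliers_and_refit(pts, z_max = -1), "z_max")
})

test_that("angular and vertical errors follow their closed forms", {
  mk <- function(c0, c1, orientation = "horizontal") {
    structure(list(orientation = orientation, order = 1L,
                   coefficients = c(c0, c1), support = 10L),
              class = "boundary_line")
  }
  expect_equal(angular_error(mk(0, 1), mk(0, 0)), 45)
  expect_equal(angular_error(mk(3, 0.5), mk(3, 0.5)), 0)
  expect_equal(angular_error(mk(0, 0.1), mk(0, 0.2)),
               abs(atan(0.1) - atan(0.2)) * 180 / pi, tolerance = 1e-9)
  expect_equal(round(angular_error(mk(0, 0.1), mk(0, 0.2)), 3), 5.599)

  expect_equal(vertical_error(mk(100, 0), mk(104, 0), 1024), 4 / 1024)
  expect_equal(vertical_error(mk(100, 0), mk(104, 0), 2048),
               vertical_error(mk(100, 0), mk(104, 0), 1024) / 2)
  expect_equal(vertical_error(mk(7, 0.2), mk(7, 0.3), 512), 0)

  expect_error(angular_error(mk(0, 1), mk(0, 1, "vertical")), "orientation")
  expect_error(vertical_error(mk(0, 1), mk(0, 1), 0), "image_height")
})
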