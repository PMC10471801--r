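#' Orientation rule for splitting boundary points into line sets
#'
#' A boundary point belongs to a horizontal line set when, over a small
#' window of the walk around it, the x-coordinate varies at least as much as
#' the y-coordinate and the y-variation stays within `delta_threshold`
#' pixels (and symmetrically for vertical sets, so corner points may belong
#' to both). Maximal path-contiguous runs of same-orientation points form
#' candidate line sets; two runs are merged into one set when they are
#' fragments of the same boundary, i.e. their along-line extents do not
#' substantially overlap and their across-line separation is at most
#' `gap_threshold` pixels. Runs with fewer than `min_points` points are
#' discarded. The defaults are stated for 1024 x 1024 tiles and scale
#' linearly with image size.
#'
#' @param delta_threshold largest across-line variation (pixels) allowed
#'   within the direction window.
#' @param gap_threshold across-line separation (pixels) below which two
#'   non-overlapping runs are treated as the same boundary line.
#' @param window odd number of walk steps used to estimate the local
#'   direction.
#' @param min_points smallest usable line set.
#' @export
orientation_rule <- function(delta_threshold = 50, gap_threshold = 50,
                             window = 5L, min_points = 4L) {
  if (delta_threshold <= 0 || gap_threshold <= 0) stop("thresholds must be > 0")
  if (window < 3 || window %% 2 == 0) stop("window must be odd and >= 3")
  structure(list(delta_threshold = delta_threshold,
                 gap_threshold = gap_threshold,
                 window = as.integer(window),
                 min_points = as.integer(min_points)),
            class = "orientation_rule")
}

# windowed central difference along a closed path
cyclic_delta <- function(v, half) {
  n <- length(v)
  idx <- function(i) ((i - 1) %% n) + 1
  v[idx(seq_len(n) + half)] - v[idx(seq_len(n) - half)]
}

# split logical candidate flags into maximal cyclic runs of TRUE
cyclic_runs <- function(flag) {
  n <- length(flag)
  if (all(flag)) return(list(seq_len(n)))
  if (!any(flag)) return(list())
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- c(1, head(ends, -1) + 1)
  runs <- Map(function(s, e) s:e, starts[r$values], ends[r$values])
  # join the wrap-around run
  if (flag[1] && flag[n] && length(runs) > 1) {
    runs[[1]] <- c(runs[[length(runs)]], runs[[1]])
    runs[[length(runs)]] <- NULL
  }
  runs
}

# merge runs that are fragments of the same boundary line: along-line
# intervals must not substantially overlap and across-line separation must
# be <= gap
merge_runs <- function(runs, along, across, gap) {
  if (length(runs) <= 1) return(runs)
  repeat {
    merged <- FALSE
    for (i in seq_along(runs)) {
      for (j in seq_along(runs)) {
        if (j <= i) next
        ai <- range(along[runs[[i]]]); aj <- range(along[runs[[j]]])
        overlap <- min(ai[2], aj[2]) - max(ai[1], aj[1])
        min_len <- min(diff(ai), diff(aj))
        if (overlap > 0.5 * min_len + 1) next
        d <- abs(mean(across[runs[[i]]]) - mean(across[runs[[j]]]))
        if (d <= gap) {
          runs[[i]] <- c(runs[[i]], runs[[j]])
          runs[[j]] <- NULL
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) return(runs)
  }
}

#' Split a boundary path into horizontal and vertical line point sets
#'
#' Walks the ordered boundary path and classifies each point by its local
#' direction (see [orientation_rule()]): stretches where x varies much more
#' than y become horizontal boundary candidates, stretches where y dominates
#' become vertical candidates. Contiguous runs are merged across small gaps
#' and returned as point sets ready for line fitting.
#'
#' @param path a [trace_boundary()] result, or an m x 2 matrix of ordered
#'   `(x, y)` points along a closed contour.
#' @param rule an [orientation_rule()].
#' @return list with `horizontal` and `vertical`: each a list of point
#'   matrices (columns `x`, `y`, duplicate pixels removed).
#' @export
split_orientation <- function(path, rule = orientation_rule()) {
  pts <- if (inherits(path, "boundary_path")) path$points else as.matrix(path)
  if (nrow(pts) < 4) stop("path must have at least 4 points")
  x <- pts[, 1]; y <- pts[, 2]
  half <- (rule$window - 1L) %/% 2L
  dx <- abs(cyclic_delta(x, half))
  dy <- abs(cyclic_delta(y, half))
  pool <- function(cand, along, across) {
    runs <- cyclic_runs(cand)
    # trim half a window from each run end: those points straddle corners
    runs <- lapply(runs, function(r) {
      if (length(r) > 2 * half + rule$min_points) {
        r[(half + 1):(length(r) - half)]
      } else {
        r
      }
    })
    runs <- merge_runs(runs, along, across, rule$gap_threshold)
    sets <- lapply(runs, function(r) unique(pts[r, , drop = FALSE]))
    sets[vapply(sets, nrow, 1L) >= rule$min_points]
  }
  list(
    horizontal = pool(dy <= pmin(rule$delta_threshold, dx), x, y),
    vertical = pool(dx <= pmin(rule$delta_threshold, dy), y, x)
  )
}

#' Least-squares polynomial line fit to boundary points
#'
#' Fits `f(t) = theta_0 + theta_1 t + ... + theta_n t^n` by ordinary least
#' squares. For horizontal lines the dependent variable is y as a function
#' of x; for vertical lines the axes are swapped (x as a function of y), so
#' near-vertical boundaries never produce unbounded slopes.
#'
#' @param points m x 2 matrix of `(x, y)` boundary points.
#' @param order polynomial order `n` (default 1, a straight line).
#' @param orientation `"horizontal"` or `"vertical"`.
#' @return list with `line` (class `boundary_line`: `orientation`, `order`,
#'   `coefficients`, `support`) and `diagnostics` (class `fit_diagnostics`:
#'   `residuals`, `S` the residual sum of squares, `S_e` the residual
#'   standard error with `m - (order + 1)` degrees of freedom, `z` the
#'   standardized absolute residuals, `removed` indices).
#' @export
fit_line_ls <- function(points, order = 1L,
                        orientation = c("horizontal", "vertical")) {
  orientation <- match.arg(orientation)
  points <- as.matrix(points)
  m <- nrow(points)
  if (m < order + 2) stop("need at least order + 2 points")
  t <- if (orientation == "horizontal") points[, 1] else points[, 2]
  v <- if (orientation == "horizontal") points[, 2] else points[, 1]
  X <- outer(t, 0:order, "^")
  if (qr(X)$rank < order + 1) {
    stop("degenerate orientation: the independent coordinate does not vary; ",
         "try the other orientation")
  }
  fit <- stats::lm.fit(X, v)
  e <- fit$residuals
  S <- sum(e^2)
  S_e <- sqrt(S / (m - (order + 1)))
  line <- structure(list(orientation = orientation, order = order,
                         coefficients = unname(fit$coefficients),
                         support = m),
                    class = "boundary_line")
  diag <- structure(list(residuals = unname(e), S = S, S_e = S_e,
                         z = if (S_e > 0) abs(e) / S_e else rep(0, m),
                         removed = integer(0)),
                    class = "fit_diagnostics")
  list(line = line, diagnostics = diag)
}

#' Robust line fit with standardized-residual outlier screening
#'
#' Fits by least squares, computes standardized residuals
#' `Z_i = |e_i| / S_e`, removes every point with `Z_i > z_max` (default 3),
#' and refits, iterating until no point is removed or `max_iterations` is
#' reached. `max_iterations = 1` gives the single screening pass.
#'
#' @inheritParams fit_line_ls
#' @param z_max standardized-residual cutoff (`Inf` disables screening).
#' @param max_iterations largest number of screening passes.
#' @return as [fit_line_ls()]; `diagnostics$removed` holds the indices of
#'   the removed points in the original point order.
#' @export
remove_outliers_and_refit <- function(points, order = 1L,
                                      orientation = c("horizontal", "vertical"),
                                      z_max = 3, max_iterations = 5L) {
  orientation <- match.arg(orientation)
  if (z_max <= 0) stop("z_max must be > 0")
  points <- as.matrix(points)
  if (nrow(points) < order + 3) stop("need at least order + 3 points")
  keep <- seq_len(nrow(points))
  removed <- integer(0)
  res <- NULL
  for (it in seq_len(max_iterations)) {
    if (length(keep) < order + 2) {
      stop("over-pruned: fewer than order + 2 points remain after screening")
    }
    res <- fit_line_ls(points[keep, , drop = FALSE], order, orientation)
    out <- which(res$diagnostics$z > z_max)
    if (length(out) == 0) break
    removed <- c(removed, keep[out])
    keep <- keep[-out]
  }
  if (length(keep) < order + 2) {
    stop("over-pruned: fewer than order + 2 points remain after screening")
  }
  res$diagnostics$removed <- sort(removed)
  res
}

check_order1_pair <- function(line_true, line_fit) {
  if (line_true$order != 1 || line_fit$order != 1) {
    stop("error metrics are defined for order-1 lines")
  }
  if (line_true$orientation != line_fit$orientation) {
    stop("lines must share an orientation convention")
  }
}

#' Angular error between two boundary lines, in degrees
#'
#' The absolute angle between the true and fitted lines,
#' `|atan(slope_true) - atan(slope_fit)|`, computed in the lines' common
#' (possibly axis-swapped) frame.
#'
#' @param line_true,line_fit order-1 `boundary_line` objects with the same
#'   orientation.
#' @return angle in degrees, in `[0, 90]`.
#' @export
angular_error <- function(line_true, line_fit) {
  check_order1_pair(line_true, line_fit)
  a <- abs(atan(line_true$coefficients[2]) - atan(line_fit$coefficients[2]))
  min(a, pi - a) * 180 / pi
}

#' Vertical error between two boundary lines
#'
#' The absolute difference of the lines' values at coordinate 0 (their
#' intercepts), divided by the image extent along the dependent axis: the
#' image height for horizontal lines, the image width for vertical
#' (axis-swapped) lines.
#'
#' @inheritParams angular_error
#' @param image_height image extent (pixels) along the dependent axis.
#' @return non-negative dimensionless ratio.
#' @export
vertical_error <- function(line_true, line_fit, image_height) {
  check_order1_pair(line_true, line_fit)
  if (image_height <= 0) stop("image_height must be > 0")
  abs(line_true$coefficients[1] - line_fit$coefficients[1]) / image_height
}

#' @export
print.boundary_line <- function(x, ...) {
  eq <- if (x$orientation == "horizontal") "y =" else "x ="
  terms <- paste0(signif(x$coefficients, 6),
                  c("", paste0(" t^", seq_len(x$order)))[seq_along(x$coefficients)])
  cat(x$orientation, "boundary line:", eq, paste(terms, collapse = " + "),
      sprintf("(support %d)\n", x$support))
  invisible(x)
}
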