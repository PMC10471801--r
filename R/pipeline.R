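#' End-to-end boundary line extraction
#'
#' Runs the full second stage on a label mask (or on an RGB image when a
#' trained network is supplied): binarize and clean, label regions with
#' small-region exclusion, trace each region's boundary, split the boundary
#' points by orientation, and fit each line set by least squares with
#' standardized-residual outlier screening.
#'
#' @param input integer label mask (H x W), or an H x W x 3 RGB image when
#'   `network` is given.
#' @param network optional trained network from [build_model()]; required
#'   when `input` is an RGB image.
#' @param target_classes classes forming the foreground (default: both field
#'   classes, Crop and Soil).
#' @param kernel_size opening kernel for [binarize_and_clean()].
#' @param min_area region exclusion threshold, see [label_regions()].
#' @param rule an [orientation_rule()]; when `NULL`, the 1024-tile defaults
#'   are scaled linearly to the input size.
#' @param order polynomial order of the fitted lines.
#' @param z_max standardized-residual cutoff for outlier removal.
#' @param per_class if `TRUE`, run the extraction once per foreground class
#'   (so Crop and Soil plots get separate regions) and pool the lines.
#' @return object of class `field_lines`: list with `lines` (each element:
#'   `region_id`, `class_index`, `line`, `diagnostics`), `regions` (the
#'   region table), and `image_size`.
#' @export
extract_field_lines <- function(input, network = NULL,
                                target_classes = c(1L, 2L), kernel_size = 3L,
                                min_area = NULL, rule = NULL, order = 1L,
                                z_max = 3, per_class = TRUE) {
  if (length(dim(input)) == 3) {
    if (is.null(network)) stop("an RGB image input requires a trained network")
    mask <- predict_mask(network, input)
  } else {
    mask <- input
  }
  H <- nrow(mask); W <- ncol(mask)
  if (is.null(rule)) {
    s <- min(H, W) / 1024
    rule <- orientation_rule(delta_threshold = max(50 * s, 4),
                             gap_threshold = max(50 * s, 4))
  }
  class_sets <- if (per_class) as.list(target_classes) else list(target_classes)
  all_lines <- list()
  region_tables <- list()
  for (cls in class_sets) {
    bin <- binarize_and_clean(mask, target_classes = cls,
                              kernel_size = kernel_size)
    rm_ <- label_regions(bin, min_area = min_area)
    if (nrow(rm_$regions) == 0) next
    tab <- rm_$regions
    tab$class_index <- cls[1]
    region_tables[[length(region_tables) + 1]] <- tab
    for (rid in rm_$regions$id) {
      path <- trace_boundary(rm_, rid)
      if (nrow(path$points) < 4) next
      sets <- split_orientation(path, rule)
      for (orient in c("horizontal", "vertical")) {
        for (pts in sets[[orient]]) {
          fit <- tryCatch(
            remove_outliers_and_refit(pts, order = order,
                                      orientation = orient, z_max = z_max),
            error = function(e) NULL)
          if (is.null(fit)) next
          all_lines[[length(all_lines) + 1]] <- list(
            region_id = rid, class_index = cls[1],
            line = fit$line, diagnostics = fit$diagnostics)
        }
      }
    }
  }
  if (length(all_lines) == 0) {
    message("no field regions survived cleaning; returning an empty line set")
  }
  structure(list(lines = all_lines,
                 regions = if (length(region_tables) > 0)
                   do.call(rbind, region_tables) else NULL,
                 image_size = c(H, W)),
            class = "field_lines")
}

#' @export
print.field_lines <- function(x, ...) {
  cat("Extracted ", length(x$lines), " boundary line(s) from a ",
      x$image_size[1], "x", x$image_size[2], " mask\n", sep = "")
  for (l in x$lines) {
    cat(sprintf(" region %d (class %d): ", l$region_id, l$class_index))
    print(l$line)
  }
  invisible(x)
}

# match a truth record to the fitted line of the same orientation closest to
# it across-line; "closest" is evaluated at the midpoint of the truth line's
# span (falling back to the intercept when no span is recorded), which keeps
# nearly collinear lines of different plots apart
match_fitted <- function(true_line, fitted, orientation) {
  cand <- Filter(function(l) l$line$orientation == orientation, fitted)
  if (length(cand) == 0) return(NULL)
  at <- if (!is.null(true_line$span)) unlist(true_line$span) else 0
  d <- vapply(cand, function(l) {
    th <- l$line$coefficients
    fit_v <- vapply(at, function(a) sum(th * a^(seq_along(th) - 1)), numeric(1))
    true_v <- true_line$coefficients[1] + true_line$coefficients[2] * at
    mean(abs(fit_v - true_v))
  }, numeric(1))
  cand[[which.min(d)]]
}

#' Score fitted boundary lines against ground truth
#'
#' Matches every ground-truth line to the fitted line with the same
#' orientation and nearest intercept, and reports per-line angular and
#' vertical errors plus per-class and overall means. Vertical lines are
#' scored in the axis-swapped frame with the image width as the normalizer.
#'
#' @param fitted a [extract_field_lines()] result (or a list of fitted line
#'   records).
#' @param truth list of ground-truth line records (`orientation`,
#'   `coefficients`, optionally `class`), e.g. from [generate_scene()].
#' @param image_size `(H, W)` in pixels.
#' @param truth_classes optional per-truth-line class names ("Crop"/"Soil")
#'   used for the per-class means.
#' @return object of class `line_errors`: data.frame with one row per truth
#'   line (`orientation`, `angular_error`, `vertical_error`, `matched`,
#'   `class`), plus a `summary` attribute with per-class and overall means.
#' @export
evaluate_lines <- function(fitted, truth, image_size, truth_classes = NULL) {
  fl <- if (inherits(fitted, "field_lines")) fitted$lines else fitted
  if (length(truth) == 0) stop("no ground-truth lines to score")
  if (length(fl) == 0) stop("no fitted lines to score against the truth")
  H <- image_size[1]; W <- image_size[2]
  rows <- lapply(seq_along(truth), function(i) {
    tl <- truth[[i]]
    tl_line <- structure(list(orientation = tl$orientation, order = 1L,
                              coefficients = tl$coefficients[1:2],
                              support = NA_integer_),
                         class = "boundary_line")
    m <- match_fitted(tl, fl, tl$orientation)
    if (is.null(m)) {
      return(data.frame(truth_id = i, orientation = tl$orientation,
                        angular_error = NA_real_, vertical_error = NA_real_,
                        matched = FALSE,
                        class = truth_classes[i] %||% NA_character_))
    }
    norm <- if (tl$orientation == "horizontal") H else W
    data.frame(truth_id = i, orientation = tl$orientation,
               angular_error = angular_error(tl_line, m$line),
               vertical_error = vertical_error(tl_line, m$line, norm),
               matched = TRUE,
               class = truth_classes[i] %||% NA_character_)
  })
  df <- do.call(rbind, rows)
  if (!any(df$matched)) stop("no truth line found a matching fitted line")
  summ <- function(sel) {
    c(angular = mean(df$angular_error[sel], na.rm = TRUE),
      vertical = mean(df$vertical_error[sel], na.rm = TRUE))
  }
  summary <- list(overall = summ(df$matched))
  for (cl in unique(stats::na.omit(df$class))) {
    summary[[cl]] <- summ(df$matched & !is.na(df$class) & df$class == cl)
  }
  attr(df, "summary") <- summary
  class(df) <- c("line_errors", "data.frame")
  df
}

#' @export
print.line_errors <- function(x, ...) {
  print.data.frame(x)
  s <- attr(x, "summary")
  cat("\nMean errors (vertical ratio, angular degrees):\n")
  for (nm in names(s)) {
    cat(sprintf("  %-10s vertical %.4f  angular %.3f\n",
                nm, s[[nm]]["vertical"], s[[nm]]["angular"]))
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0) b else a
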