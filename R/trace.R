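#' Binarize a label mask and clean it morphologically
#'
#' Selects the pixels whose class is in `target_classes` as foreground, then
#' applies a morphological opening (erosion followed by dilation) with a
#' square structuring element to remove tiny isolated noise specks, and
#' optionally inverts the result. With `kernel_size = 1` the opening is the
#' identity.
#'
#' @param mask integer label mask (values 0/1/2).
#' @param target_classes class indices treated as foreground (subset of 0:2).
#' @param kernel_size odd side length of the square structuring element.
#' @param invert if `TRUE`, swap foreground and background after cleaning.
#' @return binary 0/1 integer matrix.
#' @export
binarize_and_clean <- function(mask, target_classes = c(1L, 2L),
                               kernel_size = 3L, invert = FALSE) {
  if (length(target_classes) == 0) stop("target_classes must be non-empty")
  if (!all(target_classes %in% 0:2)) stop("target_classes must be in {0,1,2}")
  if (kernel_size < 1 || kernel_size %% 2 == 0) {
    stop("kernel_size must be odd and >= 1")
  }
  bin <- matrix(as.integer(mask %in% target_classes), nrow(mask), ncol(mask))
  if (kernel_size > 1) {
    brush <- EBImage::makeBrush(kernel_size, shape = "box")
    bin <- EBImage::dilate(EBImage::erode(bin, brush), brush)
    bin <- matrix(as.integer(bin > 0.5), nrow(mask), ncol(mask))
  }
  if (invert) bin <- 1L - bin
  bin
}

#' Label 8-connected foreground regions
#'
#' Finds the 8-connected components of a binary mask, drops components whose
#' area is below `min_area` (these are likely misidentified specks), and
#' renumbers the survivors 1..R in the order of each region's first pixel in
#' a row-major scan.
#'
#' @param binary 0/1 matrix.
#' @param min_area minimum pixel count for a region to survive; the default
#'   is 0.1% of the image area.
#' @return object of class `region_map`: list with `labels` (integer matrix,
#'   0 = background) and `regions` (data.frame with `id`, `area` and bounding
#'   box columns `row_min`, `row_max`, `col_min`, `col_max`, 0-based).
#' @export
label_regions <- function(binary, min_area = NULL) {
  binary <- matrix(as.integer(binary != 0), nrow(binary), ncol(binary))
  if (is.null(min_area)) min_area <- 0.001 * length(binary)
  if (min_area < 0) stop("min_area must be >= 0")
  lab <- cpp_label8(binary)
  if (max(lab) > 0) {
    areas <- tabulate(lab, nbins = max(lab))
    keep <- which(areas >= min_area)
    remap <- integer(max(lab))
    remap[keep] <- seq_along(keep)
    lab <- matrix(ifelse(lab > 0, remap[pmax(lab, 1L)], 0L), nrow(lab), ncol(lab))
    areas <- areas[keep]
  } else {
    areas <- integer(0)
  }
  regions <- if (length(areas) > 0) {
    do.call(rbind, lapply(seq_along(areas), function(i) {
      w <- which(lab == i, arr.ind = TRUE)
      data.frame(id = i, area = areas[i],
                 row_min = min(w[, 1]) - 1L, row_max = max(w[, 1]) - 1L,
                 col_min = min(w[, 2]) - 1L, col_max = max(w[, 2]) - 1L)
    }))
  } else {
    data.frame(id = integer(0), area = integer(0), row_min = integer(0),
               row_max = integer(0), col_min = integer(0), col_max = integer(0))
  }
  structure(list(labels = lab, regions = regions), class = "region_map")
}

#' @export
print.region_map <- function(x, ...) {
  cat("Region map: ", nrow(x$regions), " region(s) on a ",
      nrow(x$labels), "x", ncol(x$labels), " grid\n", sep = "")
  if (nrow(x$regions) > 0) print(x$regions)
  invisible(x)
}

# clockwise Moore neighbourhood in image coordinates (y down):
# E, SE, S, SW, W, NW, N, NE as (drow, dcol)
moore_offsets <- matrix(c(
  0L, 1L,  1L, 1L,  1L, 0L,  1L, -1L,
  0L, -1L, -1L, -1L, -1L, 0L, -1L, 1L), ncol = 2, byrow = TRUE)

# Moore-neighbour contour following. The walk keeps a backtrack (the
# background neighbour it came from), scans the 8-neighbourhood of the
# current pixel starting at the backtrack, and moves to the first foreground
# pixel found. It stops when it is about to repeat the initial move, i.e.
# when it stands on the start pixel and the next pixel would again be the
# second point of the path (Jacob's stopping criterion).
# fg: logical matrix; start/back: c(row, col).
moore_walk <- function(fg, start, back, clockwise = TRUE) {
  H <- nrow(fg); W <- ncol(fg)
  offs <- if (clockwise) moore_offsets else moore_offsets[c(1, 8:2), ]
  dir_of <- function(p, q) { # index in offs of q relative to p
    d <- q - p
    which(offs[, 1] == d[1] & offs[, 2] == d[2])
  }
  is_fg <- function(r, c) r >= 1 && r <= H && c >= 1 && c <= W && fg[r, c]
  max_pts <- 4L * sum(fg) + 8L
  path <- matrix(NA_integer_, max_pts, 2L)
  path[1, ] <- start
  np <- 1L
  p <- start
  b_dir <- dir_of(start, back)
  repeat {
    d <- NA_integer_
    for (k in 1:8) {
      dd <- ((b_dir - 1L + k - 1L) %% 8L) + 1L
      q <- p + offs[dd, ]
      if (is_fg(q[1], q[2])) { d <- dd; break }
    }
    if (is.na(d)) return(path[1, , drop = FALSE]) # isolated pixel
    if (np > 1L && p[1] == start[1] && p[2] == start[2] &&
        q[1] == path[2, 1] && q[2] == path[2, 2]) break
    prev_d <- ((d - 2L) %% 8L) + 1L
    b <- p + offs[prev_d, ]
    b_dir <- dir_of(q, b)
    p <- q
    np <- np + 1L
    path[np, ] <- p
    if (np >= max_pts) break
  }
  # drop the final duplicate of the start pixel, if any
  if (np > 1L && path[np, 1] == path[1, 1] && path[np, 2] == path[1, 2]) {
    np <- np - 1L
  }
  path[seq_len(np), , drop = FALSE]
}

#' Trace the boundary of a labelled region
#'
#' Follows the outer contour of one region with Moore-neighbour tracing
#' (8-connectivity, clockwise, starting at the region's uppermost-then-
#' leftmost pixel, Jacob's stopping criterion). Coordinates are reported as
#' `(x = column, y = row)` pixel centres with the origin at the centre of the
#' image's top-left pixel and y increasing downward. Pixels outside the
#' image frame count as background, so a region touching the frame is traced
#' along the frame. With `include_holes = TRUE` the inner contours around
#' enclosed background pockets are traced as well (counterclockwise).
#'
#' @param region_map a [label_regions()] result.
#' @param region_id region to trace.
#' @param include_holes trace inner boundaries too.
#' @return object of class `boundary_path`: list with `region_id`, `points`
#'   (m x 2 matrix, columns `x`, `y`), `closed`, and `holes` (list of inner
#'   contour point matrices, empty unless requested).
#' @export
trace_boundary <- function(region_map, region_id, include_holes = FALSE) {
  stopifnot(inherits(region_map, "region_map"))
  lab <- region_map$labels
  if (!(region_id %in% region_map$regions$id)) {
    stop("unknown region_id: ", region_id)
  }
  fg <- lab == region_id
  # uppermost row, then leftmost column
  rows <- which(rowSums(fg) > 0)
  r0 <- rows[1]
  c0 <- which(fg[r0, ])[1]
  pts <- moore_walk(fg, c(r0, c0), c(r0, c0 - 1L), clockwise = TRUE)

  holes <- list()
  if (include_holes) {
    comp <- cpp_label4(matrix(as.integer(!fg), nrow(fg), ncol(fg)))
    frame_ids <- unique(c(comp[1, ], comp[nrow(comp), ], comp[, 1], comp[, ncol(comp)]))
    hole_ids <- setdiff(setdiff(unique(as.vector(comp)), 0L), frame_ids)
    for (h in hole_ids) {
      hm <- comp == h
      # hole must touch this region with a 4-neighbour to contribute border
      if (!touches4(fg, hm)) next
      hrows <- which(rowSums(hm) > 0)
      hr <- hrows[1]
      hc <- which(hm[hr, ])[1]
      # pixel above the hole's topmost-leftmost pixel lies on the region
      start <- c(hr - 1L, hc)
      if (!fg[start[1], start[2]]) next
      holes[[length(holes) + 1]] <-
        to_xy(moore_walk(fg, start, c(hr, hc), clockwise = FALSE))
    }
  }
  structure(list(region_id = region_id, points = to_xy(pts),
                 closed = TRUE, holes = holes),
            class = "boundary_path")
}

# (row, col) 1-based -> (x, y) 0-based pixel centres
to_xy <- function(pts) {
  out <- cbind(x = pts[, 2] - 1L, y = pts[, 1] - 1L)
  out
}

touches4 <- function(a, b) {
  H <- nrow(a); W <- ncol(a)
  any(a[-H, ] & b[-1, ]) || any(a[-1, ] & b[-H, ]) ||
    any(a[, -W] & b[, -1]) || any(a[, -1] & b[, -W])
}

#' @export
print.boundary_path <- function(x, ...) {
  cat("Boundary of region ", x$region_id, ": ", nrow(x$points), " points",
      if (x$closed) " (closed)", if (length(x$holes) > 0)
        paste0(", ", length(x$holes), " hole contour(s)"), "\n", sep = "")
  invisible(x)
}
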