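#' Configuration for a synthetic field scene
#'
#' A scene holds up to four convex quadrilateral plots (class Crop or Soil) on
#' a Background canvas. Each plot is the intersection of four half-planes
#' whose boundary lines have bounded slope (`max_edge_slope`) relative to the
#' image axes, so every plot edge is exactly a known straight line: the
#' generator returns those lines as ground truth. Plots are placed in disjoint
#' layout cells, which keeps them at least `separation` pixels apart.
#'
#' @param size `(H, W)` in pixels (each at least 64).
#' @param n_plots number of plots, 0 to 4.
#' @param plot_classes per-plot class, values in `c("Crop", "Soil")`; `NULL`
#'   draws them at random.
#' @param texture list with `noise_sd` (Gaussian pixel noise, 0-255 scale) and
#'   `stripe_amp` (amplitude of the periodic row stripes drawn on Crop plots).
#' @param max_edge_slope largest |slope| of a plot edge relative to its axis.
#' @param separation minimum gap between plots, pixels.
#' @param seed integer seed; geometry, texture and any later noise use
#'   separate substreams derived from it, so e.g. changing texture noise never
#'   moves the plot geometry.
#' @return object of class `scene_config`.
#' @export
scene_config <- function(size = c(256L, 256L), n_plots = 2L,
                         plot_classes = NULL,
                         texture = list(noise_sd = 12, stripe_amp = 10),
                         max_edge_slope = 0.3, separation = 8, seed = 0L) {
  if (length(size) != 2 || any(size < 64)) stop("size must be (H, W) with both >= 64")
  if (n_plots < 0 || n_plots > 4) stop("n_plots must be between 0 and 4")
  if (!is.null(plot_classes)) {
    if (length(plot_classes) != n_plots || !all(plot_classes %in% c("Crop", "Soil"))) {
      stop("plot_classes must be n_plots values in {Crop, Soil}")
    }
  }
  structure(list(size = as.integer(size), n_plots = as.integer(n_plots),
                 plot_classes = plot_classes, texture = texture,
                 max_edge_slope = max_edge_slope, separation = separation,
                 seed = as.integer(seed)),
            class = "scene_config")
}

# substream seeds: geometry / texture / noise never share a stream
scene_substream <- function(seed, which) {
  offset <- c(geometry = 1L, texture = 2L, noise = 3L)[[which]]
  (as.integer(seed) * 101L + offset * 10007L) %% 2147483587L
}

# One plot inside cell [r0,r1] x [c0,c1]: four boundary lines
#   top/bottom: y = a + b x   (horizontal orientation)
#   left/right: x = c + d y   (vertical orientation)
# sampled so the lines stay inside fixed bands of the cell; the quadrilateral
# is their half-plane intersection, hence convex and non-empty.
sample_plot <- function(rng, r0, r1, c0, c1, max_slope) {
  h <- r1 - r0; w <- c1 - c0
  cx <- (c0 + c1) / 2; cy <- (r0 + r1) / 2
  band <- 0.32
  hline <- function(lo, hi, half_extent) {
    b <- rng$unif(1, -max_slope, max_slope)
    dev <- abs(b) * half_extent
    if (hi - dev <= lo + dev) b <- b * (hi - lo) / (4 * dev + 1e-9)
    dev <- abs(b) * half_extent
    yc <- rng$unif(1, lo + dev, hi - dev)
    c(yc, b) # value at centre, slope
  }
  top <- hline(r0, r0 + band * h, w / 2)
  bot <- hline(r1 - band * h, r1, w / 2)
  lft <- hline(c0, c0 + band * w, h / 2)
  rgt <- hline(c1 - band * w, c1, h / 2)
  list(
    top = c(top[1] - top[2] * cx, top[2]),   # y = a + b x
    bottom = c(bot[1] - bot[2] * cx, bot[2]),
    left = c(lft[1] - lft[2] * cy, lft[2]),  # x = c + d y
    right = c(rgt[1] - rgt[2] * cy, rgt[2])
  )
}

# x-coordinate where horizontal line (a,b) meets vertical line (c,d)
hv_intersect_x <- function(hl, vl) (vl[1] + vl[2] * hl[1]) / (1 - vl[2] * hl[2])

plot_true_lines <- function(plot, region_id) {
  xs <- c(hv_intersect_x(plot$top, plot$left), hv_intersect_x(plot$top, plot$right))
  xb <- c(hv_intersect_x(plot$bottom, plot$left), hv_intersect_x(plot$bottom, plot$right))
  y_at <- function(hl, x) hl[1] + hl[2] * x
  ys_l <- c(y_at(plot$top, hv_intersect_x(plot$top, plot$left)),
            y_at(plot$bottom, hv_intersect_x(plot$bottom, plot$left)))
  ys_r <- c(y_at(plot$top, hv_intersect_x(plot$top, plot$right)),
            y_at(plot$bottom, hv_intersect_x(plot$bottom, plot$right)))
  mkline <- function(orientation, coefficients, span) {
    list(region_id = region_id, orientation = orientation,
         coefficients = as.numeric(coefficients),
         span = as.numeric(sort(span)))
  }
  list(
    mkline("horizontal", plot$top, xs),
    mkline("horizontal", plot$bottom, xb),
    mkline("vertical", plot$left, ys_l),
    mkline("vertical", plot$right, ys_r)
  )
}

# pixel-centre rasterization of the half-plane intersection
rasterize_plot <- function(plot, H, W) {
  x <- matrix(rep(0:(W - 1), each = H), H, W)
  y <- matrix(rep(0:(H - 1), W), H, W)
  (y >= plot$top[1] + plot$top[2] * x) &
    (y <= plot$bottom[1] + plot$bottom[2] * x) &
    (x >= plot$left[1] + plot$left[2] * y) &
    (x <= plot$right[1] + plot$right[2] * y)
}

# split the frame into 1, 2 or 4 layout cells (row0, row1, col0, col1)
layout_cells <- function(rng, H, W, n, sep) {
  m <- 5 + sep / 2
  if (n <= 1) return(list(c(m, H - 1 - m, m, W - 1 - m)))
  if (n == 2) {
    if (rng$unif(1) < 0.5) {
      s <- rng$unif(1, 0.4, 0.6) * H
      list(c(m, s - sep / 2, m, W - 1 - m), c(s + sep / 2, H - 1 - m, m, W - 1 - m))
    } else {
      s <- rng$unif(1, 0.4, 0.6) * W
      list(c(m, H - 1 - m, m, s - sep / 2), c(m, H - 1 - m, s + sep / 2, W - 1 - m))
    }
  } else {
    sr <- rng$unif(1, 0.4, 0.6) * H
    sc <- rng$unif(1, 0.4, 0.6) * W
    cells <- list(
      c(m, sr - sep / 2, m, sc - sep / 2),
      c(m, sr - sep / 2, sc + sep / 2, W - 1 - m),
      c(sr + sep / 2, H - 1 - m, m, sc - sep / 2),
      c(sr + sep / 2, H - 1 - m, sc + sep / 2, W - 1 - m))
    cells[sort(rng$pick(1:4, n))]
  }
}

#' Generate a synthetic field scene
#'
#' Returns a textured RGB image, the exact label mask rasterized from the
#' plot polygons (a pixel centre strictly inside a plot gets the plot class,
#' everything else Background), and the ground-truth boundary lines of every
#' plot edge in image coordinates (x = column, y = row, origin at the centre
#' of the top-left pixel, y increasing downward).
#'
#' @param config a [scene_config()].
#' @return list with `image` (H x W x 3 integer array), `mask` (H x W integer
#'   matrix, values 0/1/2), `lines` (list of true-line records with
#'   `region_id`, `orientation`, `coefficients`, `span`) and `classes`
#'   (per-plot class names).
#' @export
generate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  H <- config$size[1]; W <- config$size[2]
  geom <- local_rng(scene_substream(config$seed, "geometry"))
  tex <- local_rng(scene_substream(config$seed, "texture"))

  n <- config$n_plots
  mask <- matrix(0L, H, W)
  lines <- list()
  classes <- character(0)
  if (n > 0) {
    cells <- layout_cells(geom, H, W, n, config$separation)
    if (length(cells) < n) stop("scene generation failed: could not place plots")
    cls <- config$plot_classes
    if (is.null(cls)) cls <- c("Crop", "Soil")[geom$int(n, 1L, 2L)]
    for (i in seq_len(n)) {
      cell <- cells[[i]]
      if (cell[2] - cell[1] < 20 || cell[4] - cell[3] < 20) {
        stop("scene generation failed: image too small for requested plots")
      }
      plot <- sample_plot(geom, cell[1], cell[2], cell[3], cell[4],
                          config$max_edge_slope)
      inside <- rasterize_plot(plot, H, W)
      mask[inside] <- match(cls[i], field_palette()$names) - 1L
      lines <- c(lines, plot_true_lines(plot, i))
      classes <- c(classes, cls[i])
    }
  }

  # texture: per-class base colour + Gaussian noise; Crop gets row stripes
  pal <- field_palette()$colors
  image <- array(0, c(H, W, 3))
  stripe <- 1 + (config$texture$stripe_amp / 255) *
    sin(2 * pi * (0:(H - 1)) / 8)
  for (ch in 1:3) {
    base <- matrix(pal[mask + 1L, ch], H, W)
    base[mask == 1L] <- (base * stripe)[mask == 1L]
    image[, , ch] <- base + tex$norm(H * W, 0, config$texture$noise_sd)
  }
  image <- round(pmin(pmax(image, 0), 255))
  storage.mode(image) <- "integer"
  list(image = image, mask = mask, lines = lines, classes = classes)
}

#' Mask corruption settings
#'
#' Emulates the typical failure modes of a segmentation network: wobbling
#' region boundaries (`jitter_sigma`, the standard deviation in pixels of a
#' smooth random displacement field applied to the mask), dropout blobs
#' (`blob_count` random disks reassigned to a random class) and isolated
#' per-pixel label flips (`flip_rate`).
#'
#' @param jitter_sigma boundary displacement standard deviation, pixels.
#' @param flip_rate per-pixel label flip probability, in `[0, 0.5)`.
#' @param blob_count number of dropout disks.
#' @param seed RNG seed.
#' @export
noise_config <- function(jitter_sigma = 0, flip_rate = 0, blob_count = 0L,
                         seed = 0L) {
  if (flip_rate < 0 || flip_rate >= 0.5) stop("flip_rate must be in [0, 0.5)")
  if (jitter_sigma < 0) stop("jitter_sigma must be >= 0")
  structure(list(jitter_sigma = jitter_sigma, flip_rate = flip_rate,
                 blob_count = as.integer(blob_count), seed = as.integer(seed)),
            class = "noise_config")
}

# bilinear upsample of a small matrix to H x W (used for smooth noise fields)
upsample_field <- function(m, H, W) {
  gr <- seq(1, nrow(m), length.out = H)
  gc <- seq(1, ncol(m), length.out = W)
  r0 <- pmin(floor(gr), nrow(m) - 1); fr <- gr - r0
  c0 <- pmin(floor(gc), ncol(m) - 1); fc <- gc - c0
  a <- m[r0, c0] * outer(1 - fr, 1 - fc) + m[r0 + 1, c0] * outer(fr, 1 - fc) +
    m[r0, c0 + 1] * outer(1 - fr, fc) + m[r0 + 1, c0 + 1] * outer(fr, fc)
  a
}

#' Corrupt a label mask
#'
#' Applies, in order: smooth boundary jitter, dropout blobs, independent
#' per-pixel label flips (see [noise_config()]). With an all-zero
#' configuration the mask is returned unchanged.
#'
#' @param mask integer label mask.
#' @param noise a [noise_config()].
#' @return corrupted mask, same shape.
#' @export
perturb_mask <- function(mask, noise) {
  stopifnot(inherits(noise, "noise_config"))
  H <- nrow(mask); W <- ncol(mask)
  rng <- local_rng(scene_substream(noise$seed, "noise"))
  out <- mask

  if (noise$jitter_sigma > 0) {
    g <- max(4L, round(min(H, W) / 16))
    dx <- upsample_field(matrix(rng$norm(g * g), g, g), H, W)
    dy <- upsample_field(matrix(rng$norm(g * g), g, g), H, W)
    # normalize the smooth fields to unit sd, then scale to jitter_sigma
    dx <- dx / max(stats::sd(dx), 1e-9) * noise$jitter_sigma
    dy <- dy / max(stats::sd(dy), 1e-9) * noise$jitter_sigma
    rows <- matrix(rep(1:H, W), H, W) + round(dy)
    cols <- matrix(rep(1:W, each = H), H, W) + round(dx)
    rows <- pmin(pmax(rows, 1), H); cols <- pmin(pmax(cols, 1), W)
    out <- matrix(mask[cbind(as.vector(rows), as.vector(cols))], H, W)
  }

  if (noise$blob_count > 0) {
    for (i in seq_len(noise$blob_count)) {
      r <- rng$unif(1, 1, H); cc <- rng$unif(1, 1, W)
      rad <- rng$unif(1, 2, max(3, min(H, W) / 40))
      cls <- rng$int(1, 0L, 2L)
      rr <- pmax(1, floor(r - rad)):pmin(H, ceiling(r + rad))
      ccr <- pmax(1, floor(cc - rad)):pmin(W, ceiling(cc + rad))
      d2 <- outer((rr - r)^2, (ccr - cc)^2, "+")
      sel <- d2 <= rad^2
      out[rr, ccr][sel] <- cls
    }
  }

  if (noise$flip_rate > 0) {
    flip <- rng$unif(H * W) < noise$flip_rate
    delta <- rng$int(sum(flip), 1L, 2L)
    out[flip] <- (out[flip] + delta) %% 3L
  }
  out
}

#' Write a set of synthetic scenes to disk in the dataset layout
#'
#' Emits `images/<name>.png`, `masks/<name>.png`,
#' `truth/<name>.lines.json` (ground-truth line records) and
#' `splits/train.txt` / `splits/val.txt`.
#'
#' @param config_list list of [scene_config()] objects.
#' @param out_dir output directory (created if needed).
#' @param split_ratio,split_seed passed to [split_dataset()].
#' @return invisibly, the vector of scene names.
#' @export
write_fixture_set <- function(config_list, out_dir, split_ratio = 0.9,
                              split_seed = 0L) {
  for (d in c("images", "masks", "truth", "splits")) {
    dir.create(file.path(out_dir, d), recursive = TRUE, showWarnings = FALSE)
  }
  nms <- sprintf("scene_%03d", seq_along(config_list))
  for (i in seq_along(config_list)) {
    sc <- generate_scene(config_list[[i]])
    write_image(sc$image, file.path(out_dir, "images", paste0(nms[i], ".png")))
    write_mask(sc$mask, file.path(out_dir, "masks", paste0(nms[i], ".png")))
    jsonlite::write_json(sc$lines,
                         file.path(out_dir, "truth", paste0(nms[i], ".lines.json")),
                         auto_unbox = TRUE, digits = NA)
  }
  if (length(nms) > 1) {
    sp <- split_dataset(nms, split_ratio, split_seed)
    writeLines(sp$train, file.path(out_dir, "splits", "train.txt"))
    writeLines(sp$val, file.path(out_dir, "splits", "val.txt"))
  } else {
    writeLines(nms, file.path(out_dir, "splits", "train.txt"))
    writeLines(character(0), file.path(out_dir, "splits", "val.txt"))
  }
  invisible(nms)
}
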