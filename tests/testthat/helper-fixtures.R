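# shared fixtures: all data is generated in code, seeded

# random 0/1 mask with a seeded density
random_binary_mask <- function(seed, H = 32L, W = 32L) {
  set.seed(seed)
  matrix(as.integer(runif(H * W) < runif(1, 0.3, 0.7)), H, W)
}

# brute-force border set of one region: foreground pixels with a 4-neighbour
# outside the region, or touching the image frame; returned as x/y keys
border_pixel_set <- function(fg) {
  H <- nrow(fg); W <- ncol(fg)
  pad <- matrix(FALSE, H + 2, W + 2)
  pad[2:(H + 1), 2:(W + 1)] <- fg
  interior <- pad[1:H, 2:(W + 1)] & pad[3:(H + 2), 2:(W + 1)] &
    pad[2:(H + 1), 1:W] & pad[2:(H + 1), 3:(W + 2)]
  w <- which(fg & !interior, arr.ind = TRUE)
  paste(w[, 2] - 1L, w[, 1] - 1L)
}

path_point_set <- function(bp) {
  pts <- rbind(bp$points, do.call(rbind, bp$holes))
  unique(paste(pts[, 1], pts[, 2]))
}

# axis-aligned rectangle mask: rows r0..r1, cols c0..c1 (1-based), class cls
rect_mask <- function(H, W, r0, r1, c0, c1, cls = 2L) {
  m <- matrix(0L, H, W)
  m[r0:r1, c0:c1] <- cls
  m
}
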