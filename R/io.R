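#' Class palette for field scenes
#'
#' The three scene classes are fixed: index 0 is Background, 1 is Crop
#' (farmland covered by a crop) and 2 is Soil (bare farmland). Colors are for
#' display only; the integer index raster is authoritative everywhere.
#'
#' @return list with `names`, `indices` and a 3x3 `colors` matrix (RGB rows in
#'   0-255, one per class index).
#' @export
field_palette <- function() {
  list(
    names = c("Background", "Crop", "Soil"),
    indices = 0:2,
    colors = matrix(c(
      60L, 60L, 60L,     # Background: dark grey
      40L, 160L, 60L,    # Crop: green
      150L, 105L, 60L),  # Soil: brown
      nrow = 3, byrow = TRUE,
      dimnames = list(c("Background", "Crop", "Soil"), c("r", "g", "b")))
  )
}

check_mask_values <- function(mask) {
  bad <- which(!(mask %in% 0:2))
  if (length(bad) > 0) {
    i <- bad[[1]]
    stop("unknown label ", mask[[i]], " at pixel ", i,
         " (expected values in {0, 1, 2})")
  }
  invisible(mask)
}

#' Read or write a label mask as PNG
#'
#' Masks are stored as 8-bit grayscale PNGs whose pixel value is the class
#' index itself (0, 1, 2). On read, grayscale files are decoded by rounding
#' the 8-bit value; RGB files (e.g. palette-rendered masks) are decoded by
#' nearest-palette-color matching. Write-then-read is the identity on the
#' index raster.
#'
#' @param x for `write_mask`, an integer matrix of class indices; for
#'   `read_mask`, a file path.
#' @param path output file path (`.png`).
#' @return `read_mask` returns an integer matrix of class indices;
#'   `write_mask` returns `path` invisibly.
#' @export
write_mask <- function(x, path) {
  x <- as.matrix(x)
  storage.mode(x) <- "integer"
  check_mask_values(x)
  png::writePNG(x / 255, target = path)
  invisible(path)
}

#' @rdname write_mask
#' @export
read_mask <- function(x) {
  if (!file.exists(x)) stop("mask file not found: ", x)
  arr <- png::readPNG(x)
  if (length(dim(arr)) == 2) {
    mask <- round(arr * 255)
  } else {
    # palette-rendered RGB(A): nearest palette color per pixel
    pal <- field_palette()$colors / 255
    rgb <- arr[, , 1:3, drop = FALSE]
    d <- sapply(seq_len(nrow(pal)), function(i) {
      (rgb[, , 1] - pal[i, 1])^2 + (rgb[, , 2] - pal[i, 2])^2 +
        (rgb[, , 3] - pal[i, 3])^2
    })
    mask <- matrix(max.col(-d, ties.method = "first") - 1L,
                   nrow = dim(arr)[1], ncol = dim(arr)[2])
  }
  storage.mode(mask) <- "integer"
  check_mask_values(mask)
  mask
}

#' Read or write an RGB image as PNG
#'
#' Images are H x W x 3 integer arrays with values in 0-255.
#'
#' @param x H x W x 3 array (write) or file path (read).
#' @param path output path.
#' @export
write_image <- function(x, path) {
  x <- x / 255
  x[x < 0] <- 0; x[x > 1] <- 1
  png::writePNG(x, target = path)
  invisible(path)
}

#' @rdname write_image
#' @export
read_image <- function(x) {
  arr <- png::readPNG(x)
  if (length(dim(arr)) == 2) arr <- array(arr, c(dim(arr), 3))
  out <- round(arr[, , 1:3, drop = FALSE] * 255)
  storage.mode(out) <- "integer"
  out
}

#' Randomly crop square tiles from a large image
#'
#' Emulates the construction of a training set from a stitched orthoimage:
#' `count` square tiles of side `tile_size` are cropped at uniformly random
#' positions, each named after the (0-based) pixel coordinates of its
#' top-left pixel as `"<row>_<col>"`.
#'
#' @param image matrix (mask) or H x W x C array.
#' @param tile_size tile side length in pixels.
#' @param count number of tiles to draw.
#' @param seed RNG seed driving the tile positions.
#' @return named list of tiles (same array type as the input).
#' @export
tile_image <- function(image, tile_size, count, seed = 0L) {
  d <- dim(image)
  H <- d[1]; W <- d[2]
  if (tile_size > H || tile_size > W) stop("tile larger than image")
  if (count < 1) stop("count must be >= 1")
  rng <- local_rng(seed)
  rows <- rng$int(count, 0L, H - tile_size)
  cols <- rng$int(count, 0L, W - tile_size)
  tiles <- lapply(seq_len(count), function(i) {
    r <- rows[i]; cc <- cols[i]
    if (length(d) == 2) {
      image[(r + 1):(r + tile_size), (cc + 1):(cc + tile_size)]
    } else {
      image[(r + 1):(r + tile_size), (cc + 1):(cc + tile_size), , drop = FALSE]
    }
  })
  names(tiles) <- paste0(rows, "_", cols)
  tiles
}

#' Split sample names into training and validation sets
#'
#' Shuffles `names` with the given seed and assigns the first
#' `floor(length(names) * ratio)` to the training set, the remainder to the
#' validation set (a 9:1 split by default, matching common practice for
#' orthoimage tile datasets).
#'
#' @param names character vector of sample names.
#' @param ratio training fraction in (0, 1).
#' @param seed RNG seed.
#' @return list with `train`, `val`, `ratio`, `seed`.
#' @export
split_dataset <- function(names, ratio = 0.9, seed = 0L) {
  if (length(names) == 0) stop("empty dataset")
  if (ratio <= 0 || ratio >= 1) stop("ratio must be in (0, 1)")
  rng <- local_rng(seed)
  perm <- rng$perm(length(names))
  n_train <- floor(length(names) * ratio)
  list(train = names[perm[seq_len(n_train)]],
       val = names[perm[-seq_len(n_train)]],
       ratio = ratio, seed = seed)
}

# Seeded RNG helper: evaluates `expr`-style draws under a private RNG state so
# library code never disturbs the caller's .Random.seed.
local_rng <- function(seed) {
  env <- new.env()
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  set.seed(as.integer(seed))
  env$state <- get(".Random.seed", globalenv())
  if (is.null(old)) {
    rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  with_state <- function(f) {
    function(...) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      assign(".Random.seed", env$state, envir = globalenv())
      on.exit({
        env$state <- get(".Random.seed", globalenv())
        if (is.null(old)) rm(".Random.seed", envir = globalenv())
        else assign(".Random.seed", old, envir = globalenv())
      })
      f(...)
    }
  }
  list(
    int = with_state(function(n, lo, hi) lo + floor(runif(n) * (hi - lo + 1L))),
    unif = with_state(function(n, lo = 0, hi = 1) runif(n, lo, hi)),
    norm = with_state(function(n, mean = 0, sd = 1) rnorm(n, mean, sd)),
    perm = with_state(function(n) sample.int(n)),
    pick = with_state(function(x, n = 1) x[sample.int(length(x), n)])
  )
}
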