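test_that("binarize_and_clean selects classes, opens, and inverts", {
  m <- rect_mask(16, 16, 4, 10, 5, 12, cls = 2L)
  m[2, 2] <- 1L                      # isolated speck of the other class
  b <- binarize_and_clean(m, target_classes = 2L, kernel_size = 1L)
  expect_equal(sum(b), 7 * 8)
  expect_equal(b[2, 2], 0L)

  # kernel 1 is the identity on the class selection
  b2 <- binarize_and_clean(m, target_classes = c(1L, 2L), kernel_size = 1L)
  expect_equal(b2, matrix(as.integer(m %in% 1:2), 16, 16))

  # a single isolated pixel is removed by a 3x3 opening
  s <- matrix(0L, 16, 16); s[8, 8] <- 1L
  expect_true(all(binarize_and_clean(s, 1L, kernel_size = 3L) == 0))
  # but a large block survives opening with its area intact
  blk <- rect_mask(16, 16, 4, 12, 4, 12, 1L)
  expect_equal(binarize_and_clean(blk, 1L, kernel_size = 3L),
               matrix(as.integer(blk == 1L), 16, 16))

  # inversion is an involution
  inv <- binarize_and_clean(m, 2L, 1L, invert = TRUE)
  expect_equal(1L - inv, binarize_and_clean(m, 2L, 1L))
  expect_error(binarize_and_clean(m, integer(0)), "non-empty")
  expect_error(binarize_and_clean(m, 2L, kernel_size = 4L), "odd")
})

test_that("opening never increases the foreground area", {
  for (s in 1:25) {
    m <- random_binary_mask(s)
    b <- binarize_and_clean(m, 1L, kernel_size = 3L)
    expect_lte(sum(b), sum(m))
  }
})

test_that("region labelling is 8-connected with small-region exclusion", {
  m <- matrix(0L, 32, 32)
  m[3:12, 3:12] <- 1L
  m[20:29, 18:27] <- 1L
  rm_ <- label_regions(m, min_area = 10)
  expect_equal(nrow(rm_$regions), 2)
  expect_equal(rm_$regions$area, c(100L, 100L))

  m[16, 16] <- 1L; m[17, 17] <- 1L; m[15, 15] <- 1L  # 3-pixel diagonal speck
  rm2 <- label_regions(m, min_area = 10)
  expect_equal(nrow(rm2$regions), 2)
  rm3 <- label_regions(m, min_area = 0)
  expect_equal(nrow(rm3$regions), 3)   # diagonal chain is one 8-connected blob

  # labels equal a brute-force flood fill on random masks
  flood <- function(bin) {
    lab <- matrix(0L, nrow(bin), ncol(bin)); nx <- 0L
    for (j in seq_len(ncol(bin))) for (i in seq_len(nrow(bin))) {
      if (bin[i, j] == 1L && lab[i, j] == 0L) {
        nx <- nx + 1L
        stack <- list(c(i, j)); lab[i, j] <- nx
        while (length(stack) > 0) {
          p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
          for (dr in -1:1) for (dc in -1:1) {
            r <- p[1] + dr; c <- p[2] + dc
            if (r >= 1 && r <= nrow(bin) && c >= 1 && c <= ncol(bin) &&
                bin[r, c] == 1L && lab[r, c] == 0L) {
              lab[r, c] <- nx
              stack[[length(stack) + 1]] <- c(r, c)
            }
          }
        }
      }
    }
    lab
  }
  for (s in c(5, 6, 7)) {
    m <- random_binary_mask(s, 20, 20)
    got <- label_regions(m, min_area = 0)$labels
    want <- flood(m)
    # same partition (label ids may differ only by order; both scan row-major)
    expect_true(all((got == 0) == (want == 0)))
    for (k in unique(want[want > 0])) {
      expect_equal(length(unique(got[want == k])), 1)
    }
  }
})

test_that("Moore tracing handles degenerate and simple shapes", {
  m <- matrix(0L, 10, 10); m[6, 8] <- 1L
  rm_ <- label_regions(m, min_area = 0)
  bp <- trace_boundary(rm_, 1L)
  expect_equal(nrow(bp$points), 1)
  expect_equal(unname(bp$points[1, ]), c(7, 5))  # (x, y) 0-based
  expect_true(bp$closed)

  # filled 3x3 square: 8 perimeter points
  sq <- rect_mask(8, 8, 2, 4, 2, 4, 1L)
  rs <- label_regions(sq != 0, min_area = 0)
  bps <- trace_boundary(rs, 1L)
  expect_equal(nrow(unique(bps$points)), 8)
  expect_setequal(path_point_set(bps), border_pixel_set(rs$labels == 1))

  # full-frame rectangle: path length 2(w+h) - 4 along the frame
  fr <- matrix(1L, 12, 17)
  rf <- label_regions(fr, min_area = 0)
  bpf <- trace_boundary(rf, 1L)
  expect_equal(nrow(bpf$points), 2 * (12 + 17) - 4)

  expect_error(trace_boundary(rs, 99L), "unknown region_id")
})

test_that("consecutive traced points are 8-adjacent and lie on the border", {
  for (s in c(3, 14, 15)) {
    m <- random_binary_mask(s)
    rm_ <- label_regions(m, min_area = 0)
    for (rid in rm_$regions$id) {
      bp <- trace_boundary(rm_, rid)
      p <- bp$points
      if (nrow(p) > 1) {
        d <- abs(diff(p))
        expect_true(all(pmax(d[, 1], d[, 2]) == 1))
        wrap <- abs(p[1, ] - p[nrow(p), ])
        expect_lte(max(wrap), 1)
      }
      expect_true(all(path_point_set(bp) %in%
                        border_pixel_set(rm_$labels == rid)))
    }
  }
})

test_that("tracing is consistent under 180-degree rotation", {
  for (s in c(8, 9)) {
    m <- random_binary_mask(s, 24, 24)
    rm1 <- label_regions(m, min_area = 0)
    rot <- m[nrow(m):1, ncol(m):1]
    rm2 <- label_regions(rot, min_area = 0)
    sets1 <- lapply(rm1$regions$id, function(r)
      path_point_set(trace_boundary(rm1, r, include_holes = TRUE)))
    sets2 <- lapply(rm2$regions$id, function(r) {
      pts <- trace_boundary(rm2, r, include_holes = TRUE)
      p <- rbind(pts$points, do.call(rbind, pts$holes))
      # map back through the rotation
      unique(paste(ncol(m) - 1 - p[, 1], nrow(m) - 1 - p[, 2]))
    })
    for (s1 in sets1) {
      expect_true(any(vapply(sets2, function(s2) setequal(s1, s2), TRUE)))
    }
  }
})
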