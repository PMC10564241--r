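test_that("channel dominance masks a pure-green disk as insulin only", {
  n <- 64
  rr <- matrix(seq_len(n), n, n); cc <- t(rr)
  disk <- sqrt((rr - 32)^2 + (cc - 32)^2) <= 20
  rgb <- array(0, c(n, n, 3))
  rgb[, , 2][disk] <- 1
  cm <- channel_masks(rgb = rgb)
  expect_equal(sum(cm$insulin), sum(disk))
  expect_equal(sum(cm$glucagon), 0)
  hull <- islet_hull(cm$insulin)
  expect_error(glucagon_distances(cm$glucagon, hull), "glucagon pixels")
})

test_that("R = G ties are assigned to neither channel", {
  rgb <- array(0.5, c(4, 4, 3))  # R == G everywhere
  expect_error(channel_masks(rgb = rgb), "empty insulin")
})

test_that("synthetic masks pass through the masks mode unchanged", {
  m <- simulate_islet_masks(20, 0.5, n_glucagon = 200, seed = 1)
  cm <- channel_masks(insulin = m$insulin, glucagon = m$glucagon)
  expect_identical(cm$insulin, m$insulin)
  expect_identical(cm$glucagon, m$glucagon)
  expect_error(channel_masks(insulin = m$insulin,
                             glucagon = m$glucagon[1:10, 1:10]),
               "same shape")
})

test_that("hull of a filled square is the square, invariant to interior pixels", {
  mask <- matrix(0L, 30, 30)
  mask[10:20, 10:20] <- 1L
  h <- islet_hull(mask)
  expect_equal(attr(h, "area"), 100)  # (20-10)^2 in pixel-center coordinates
  expect_setequal(paste(h[, 1], h[, 2]),
                  paste(c(10, 20, 20, 10), c(10, 10, 20, 20)))
  # removing interior insulin pixels leaves the hull unchanged
  mask2 <- mask; mask2[12:18, 12:18] <- 0L
  h2 <- islet_hull(mask2)
  expect_setequal(paste(h[, 1], h[, 2]), paste(h2[, 1], h2[, 2]))
  # collinear pixels are degenerate
  line <- matrix(0L, 10, 10); line[5, 2:9] <- 1L
  expect_error(islet_hull(line), "collinear")
})

test_that("hull area of a pixel disk approaches pi R^2", {
  m <- simulate_islet_masks(60, 0, n_glucagon = 50, seed = 2)
  h <- islet_hull(m$insulin)
  expect_lt(abs(attr(h, "area") - pi * 60^2) / (pi * 60^2), 0.02)
})

test_that("signed distances follow the inside-positive convention", {
  m <- simulate_islet_masks(50, 0, n_glucagon = 100, seed = 3)
  h <- islet_hull(m$insulin)
  cx <- m$center[1L]
  # pixel at the centroid: distance ~ +R
  d_center <- dualeigen:::signed_polygon_distance(cx, cx, h)
  expect_equal(d_center, 50, tolerance = 0.5)
  # pixel outside at gap d: distance ~ -d
  d_out <- dualeigen:::signed_polygon_distance(cx + 50 + 4, cx, h)
  expect_equal(d_out, -4, tolerance = 0.5)
})

test_that("pure-mantle glucagon lies within the 2 px rim band", {
  m <- simulate_islet_masks(40, 0, n_glucagon = 800, seed = 4)
  h <- islet_hull(m$insulin)
  d <- glucagon_distances(m$glucagon, h)$distances
  # band is defined on pixel radii; hull-vs-circle discretization < 0.3 px
  expect_lte(max(d), 2 + 0.3)
  expect_gte(min(d), -1)
})

test_that("fully infiltrated glucagon reproduces the uniform-disk R/3 distance", {
  R <- 100
  m <- simulate_islet_masks(R, 1, n_glucagon = 20000, seed = 5)
  h <- islet_hull(m$insulin)
  gd <- glucagon_distances(m$glucagon, h)
  # pixel-enumeration oracle: distance to the true circle, same pixels
  pts <- which(m$glucagon > 0, arr.ind = TRUE)
  r_pix <- sqrt((pts[, 2] - m$center[1])^2 + (pts[, 1] - m$center[2])^2)
  expect_equal(mean(gd$distances), mean(R - r_pix), tolerance = 0.02)
  expect_lt(abs(mean(gd$distances) - R / 3) / (R / 3), 0.02)
})

test_that("irregularity index arithmetic is the symmetric trimmed mean", {
  expect_equal(irregularity_index(rep(0, 50)), 0)
  expect_equal(irregularity_index(1:100, trim_fraction = 0.05), 50.5)
  expect_error(irregularity_index(1:4), "fewer than")
  sens <- irregularity_sensitivity(1:100)
  expect_equal(sens$index[sens$trim == 0], 50.5)
  expect_equal(nrow(sens), 4L)
})

test_that("the index is monotone in infiltration depth", {
  idx <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    m <- simulate_islet_masks(60, f, n_glucagon = 3000, seed = 8)
    h <- islet_hull(m$insulin)
    irregularity_index(glucagon_distances(m$glucagon, h))
  }, numeric(1L))
  expect_true(all(diff(idx) > 0))
  # core-mantle ~ rim-level index; fully mixed ~ R/3
  expect_lt(idx[1L], 3)
  expect_equal(idx[5L], 60 / 3, tolerance = 0.1 * 20)
})

test_that("the index is rigid-motion invariant and scale equivariant", {
  m <- simulate_islet_masks(40, 0.6, n_glucagon = 2000, seed = 9)
  h <- islet_hull(m$insulin)
  gd <- glucagon_distances(m$glucagon, h)
  base <- irregularity_index(gd)
  # translation: pad both masks by the same margin
  pad <- function(mask, k) {
    out <- matrix(0L, nrow(mask) + k, ncol(mask) + k)
    out[k + seq_len(nrow(mask)), k + seq_len(ncol(mask))] <- mask
    out
  }
  h_t <- islet_hull(pad(m$insulin, 7))
  gd_t <- glucagon_distances(pad(m$glucagon, 7), h_t)
  expect_equal(irregularity_index(gd_t), base, tolerance = 1e-8)
  # 90-degree rotation (transpose + flip preserves the pixel lattice)
  rot <- function(mask) t(mask[nrow(mask):1, ])
  h_r <- islet_hull(rot(m$insulin))
  gd_r <- glucagon_distances(rot(m$glucagon), h_r)
  expect_equal(irregularity_index(gd_r), base, tolerance = 1e-8)
  # doubling pixel_size doubles the index
  gd2 <- glucagon_distances(m$glucagon, h, pixel_size = 2)
  expect_equal(irregularity_index(gd2), 2 * base, tolerance = 1e-10)
})

test_that("exact signed-rank p-values match the enumeration oracles", {
  # five concordant pairs, one-sided: p = 1/32
  res <- paired_signed_rank(c(5, 9, 14, 30, 37.5), c(2, 3, 4, 4.5, 5))
  expect_equal(res$p.value, 1 / 32)
  expect_true(res$exact)
  # differences (+1, -1): 4 sign patterns, W >= observed in 3
  expect_equal(paired_signed_rank(c(1, 0), c(0, 1), min_pairs = 2)$p.value,
               0.75)
  # negating all differences swaps the one-sided p-values
  a <- c(3, 1, 4, 1, 5); b <- c(2, 2, 2, 2, 2)
  pg <- paired_signed_rank(a, b, alternative = "greater")$p.value
  pl <- paired_signed_rank(b, a, alternative = "less")$p.value
  expect_equal(pg, pl)
  # zero differences are dropped with a warning
  expect_warning(
    res0 <- paired_signed_rank(c(2, 3, 4, 5, 6, 6), c(1, 1, 1, 1, 1, 6)),
    "zero difference")
  expect_equal(res0$n_used, 5L)
})

test_that("exact signed-rank null agrees with wilcox.test on untied data", {
  set.seed(10)
  for (i in 1:5) {
    d <- rnorm(8)
    ours <- paired_signed_rank(d, rep(0, 8), alternative = "two.sided")
    ref <- wilcox.test(d, alternative = "two.sided", exact = TRUE)
    expect_equal(ours$p.value, ref$p.value, tolerance = 1e-12)
  }
})
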