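#' Derive insulin/glucagon channel masks
#'
#' Two input modes. Masks mode: pass two binary masks through (validated:
#' same shape, non-empty insulin). RGB mode: a simplified channel-dominance
#' rule assigns a pixel to insulin when its green channel dominates
#' (G > R and G > threshold) and to glucagon when red dominates (R > G and
#' R > threshold); R = G ties go to neither.
#'
#' @param insulin,glucagon binary matrices (masks mode).
#' @param rgb an H x W x 3 array in [0, 1] (RGB mode).
#' @param threshold channel-dominance intensity threshold (default 0.2).
#' @return list with `insulin` and `glucagon` 0/1 matrices.
#' @export
channel_masks <- function(insulin = NULL, glucagon = NULL, rgb = NULL,
                          threshold = 0.2) {
  if (!is.null(rgb)) {
    if (length(dim(rgb)) != 3L || dim(rgb)[3L] < 3L) {
      stop("`rgb` must be an H x W x 3 array")
    }
    R <- rgb[, , 1L]; G <- rgb[, , 2L]
    insulin <- (G > R & G > threshold) * 1L
    glucagon <- (R > G & R > threshold) * 1L
  } else {
    if (is.null(insulin) || is.null(glucagon)) {
      stop("supply either `rgb` or both `insulin` and `glucagon`")
    }
    if (!identical(dim(insulin), dim(glucagon))) {
      stop("masks must share the same shape")
    }
    insulin <- (insulin > 0) * 1L
    glucagon <- (glucagon > 0) * 1L
  }
  if (!any(insulin == 1L)) stop("empty insulin mask: no hull possible")
  list(insulin = insulin, glucagon = glucagon)
}

# pixel centers of a mask as (x, y) = (column, row) coordinates
mask_points <- function(mask) {
  idx <- which(mask > 0, arr.ind = TRUE)
  cbind(x = idx[, 2L], y = idx[, 1L])
}

#' Convex hull of the insulin region
#'
#' The islet rim is sketched as the convex hull of the insulin pixel
#' centers; glucagon distances are later measured to this polygon's
#' boundary.
#'
#' @param insulin binary matrix (insulin mask).
#' @return matrix of hull vertices (columns x, y, pixel coordinates, in
#'   [grDevices::chull()] order) with attribute `area` (shoelace).
#' @export
islet_hull <- function(insulin) {
  pts <- mask_points(insulin)
  if (nrow(pts) < 3L) stop("need at least 3 insulin pixels for a hull")
  h <- grDevices::chull(pts)
  if (length(h) < 3L) stop("insulin pixels are collinear; hull is degenerate")
  poly <- pts[h, , drop = FALSE]
  nx <- nrow(poly)
  xs <- poly[, 1L]; ys <- poly[, 2L]
  area <- abs(sum(xs * ys[c(2:nx, 1L)] - xs[c(2:nx, 1L)] * ys)) / 2
  attr(poly, "area") <- area
  poly
}

# signed distance of points to a convex polygon boundary:
# positive inside, negative outside
signed_polygon_distance <- function(px, py, poly) {
  nv <- nrow(poly)
  x1 <- poly[, 1L]; y1 <- poly[, 2L]
  x2 <- poly[c(2:nv, 1L), 1L]; y2 <- poly[c(2:nv, 1L), 2L]
  ex <- x2 - x1; ey <- y2 - y1
  len2 <- ex^2 + ey^2
  n <- length(px)
  dmin <- rep(Inf, n)
  inside <- rep(TRUE, n)
  # orientation of the polygon (sign of twice the signed area)
  orient <- sign(sum(x1 * y2 - x2 * y1))
  for (e in seq_len(nv)) {
    t <- ((px - x1[e]) * ex[e] + (py - y1[e]) * ey[e]) / len2[e]
    t <- pmin(1, pmax(0, t))
    dx <- px - (x1[e] + t * ex[e])
    dy <- py - (y1[e] + t * ey[e])
    dmin <- pmin(dmin, sqrt(dx^2 + dy^2))
    # convexity: inside iff on the interior side of every edge
    cross <- ex[e] * (py - y1[e]) - ey[e] * (px - x1[e])
    inside <- inside & (orient * cross >= 0)
  }
  ifelse(inside, dmin, -dmin)
}

#' Signed distances of glucagon pixels to the islet rim
#'
#' For every glucagon pixel center, the Euclidean distance to the nearest
#' point on the hull boundary, signed positive inside the rim and negative
#' outside, scaled by the pixel size. A Gaussian kernel density estimate of
#' the distances (Silverman's bandwidth) describes the alpha/beta-cell
#' spatial distribution; near-zero mass means mantle alpha-cells, positive
#' mass means infiltration into the core.
#'
#' @param glucagon binary matrix (glucagon mask).
#' @param hull an [islet_hull()] polygon.
#' @param pixel_size physical size of one pixel (default 1, i.e. distances
#'   in px).
#' @param min_pixels minimum number of glucagon pixels (default 10).
#' @return list with `distances` (signed, in `pixel_size` units), `kde`
#'   (a [stats::density()] object), `n`.
#' @export
glucagon_distances <- function(glucagon, hull, pixel_size = 1,
                               min_pixels = 10L) {
  pts <- mask_points(glucagon)
  if (nrow(pts) < min_pixels) {
    stop("fewer than ", min_pixels, " glucagon pixels")
  }
  d <- signed_polygon_distance(pts[, 1L], pts[, 2L], hull) * pixel_size
  list(distances = d, kde = stats::density(d, bw = "nrd0"), n = length(d))
}

#' Islet irregularity index
#'
#' The single-valued morphometric index: the symmetric trimmed mean of the
#' signed glucagon-to-rim distances. Near zero for core-mantle islets
#' (alpha-cells on the rim), large and positive when alpha-cells infiltrate
#' the core. The KDE is descriptive only; the index depends on the raw
#' distances alone.
#'
#' @param distances numeric vector of signed distances, or a
#'   [glucagon_distances()] result.
#' @param trim_fraction fraction trimmed from each tail (default 0.05).
#' @param min_retained minimum sample size after trimming (default 5).
#' @return the index (same units as the distances).
#' @export
irregularity_index <- function(distances, trim_fraction = 0.05,
                               min_retained = 5L) {
  if (is.list(distances)) distances <- distances$distances
  n <- length(distances)
  n_kept <- n - 2L * floor(n * trim_fraction)
  if (n_kept < min_retained) {
    stop("fewer than ", min_retained, " distances retained after trimming")
  }
  mean(distances, trim = trim_fraction)
}

#' Trim-fraction sensitivity of the irregularity index
#'
#' @param distances as in [irregularity_index()].
#' @param trims trim fractions to report (default 0, 0.025, 0.05, 0.10).
#' @return data.frame with `trim` and `index`.
#' @export
irregularity_sensitivity <- function(distances,
                                     trims = c(0, 0.025, 0.05, 0.10)) {
  if (is.list(distances)) distances <- distances$distances
  data.frame(trim = trims,
             index = vapply(trims, function(tf) {
               irregularity_index(distances, trim_fraction = tf)
             }, numeric(1L)))
}

# exact signed-rank null by convolution over doubled (integer) average
# ranks; exact under ties too, since the sign-flip null conditions on the
# observed |d|
signed_rank_exact_p <- function(d, alternative) {
  r2 <- as.integer(round(2 * rank(abs(d))))  # doubled ranks are integers
  W2 <- sum(r2[d > 0])
  total <- sum(r2)
  # probability vector over the doubled statistic 0..total
  pr <- c(1, rep(0, total))
  for (w in r2) {
    shifted <- c(rep(0, w), pr[seq_len(total + 1L - w)])
    pr <- (pr + shifted) / 2
  }
  p_ge <- sum(pr[(W2 + 1L):(total + 1L)])
  p_le <- sum(pr[1L:(W2 + 1L)])
  switch(alternative,
         greater = p_ge,
         less = p_le,
         two.sided = min(1, 2 * min(p_ge, p_le)))
}

#' Paired exact Wilcoxon signed-rank comparison of irregularity indices
#'
#' Compares paired cohorts of islet indices (e.g. diabetic vs control
#' animals matched by timepoint) by the Wilcoxon signed-rank test. For up
#' to 25 non-zero pairs the exact sign-flip null distribution is used
#' (computed by convolution, so tied magnitudes are handled exactly);
#' larger samples use the normal approximation with continuity correction.
#' Zero differences are dropped with a warning.
#'
#' @param indices_a,indices_b equal-length paired numeric vectors; the test
#'   concerns the differences `indices_a - indices_b`.
#' @param alternative "greater" (default: A exceeds B), "less" or
#'   "two.sided".
#' @param min_pairs minimum usable pairs (default 5).
#' @return list with `p.value`, `statistic` (V, the positive rank sum),
#'   `n_used`, `alternative`, `exact`.
#' @export
paired_signed_rank <- function(indices_a, indices_b,
                               alternative = c("greater", "less", "two.sided"),
                               min_pairs = 5L) {
  alternative <- match.arg(alternative)
  if (length(indices_a) != length(indices_b)) {
    stop("paired vectors must have equal length")
  }
  d <- indices_a - indices_b
  if (any(d == 0)) {
    warning("dropping ", sum(d == 0), " zero difference(s)")
    d <- d[d != 0]
  }
  n <- length(d)
  if (n < min_pairs) stop("fewer than ", min_pairs, " non-zero pairs")
  V <- sum(rank(abs(d))[d > 0])
  if (n <= 25L) {
    p <- signed_rank_exact_p(d, alternative)
    exact_used <- TRUE
  } else {
    ht <- suppressWarnings(
      stats::wilcox.test(d, mu = 0, alternative = alternative,
                         exact = FALSE, correct = TRUE)
    )
    p <- unname(ht$p.value)
    exact_used <- FALSE
  }
  list(p.value = p, statistic = V, n_used = n,
       alternative = alternative, exact = exact_used)
}
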