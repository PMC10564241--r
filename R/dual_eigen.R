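#' Singular value decomposition of an expression profile
#'
#' Decomposes the log-scale profile \eqn{E} (samples x genes) as
#' \eqn{E = \sum_k \lambda_k u_k v_k^T} with positive, decreasing singular
#' values. Components are indexed from zero: the index-0 component captures
#' the per-gene / per-sample expression baselines, and after good
#' normalization its sample loadings are nearly constant, so every
#' subsequent sample-eigenvector is an empirical contrast (its loadings sum
#' to approximately zero by orthogonality). Each retained component pairs a
#' sample-eigenvector `u[, k]` (macro level: groups, covariates) with its
#' dual gene-eigenvector `v[, k]` (micro level: gene programs).
#'
#' Exact zero singular values (rank deficiency) are dropped.
#'
#' @param profile an [expression_profile()] or a bare numeric matrix
#'   (samples x genes).
#' @return An object of class `eigen_decomposition`: list with `lambda`
#'   (singular values), `u` (samples x r), `v` (genes x r), `k` (0-based
#'   component indices), `sample_ids`, `gene_ids`, `species`, `metadata`.
#' @export
decompose_profile <- function(profile) {
  if (inherits(profile, "expression_profile")) {
    E <- profile$matrix
    species <- profile$species
    metadata <- profile$metadata
  } else {
    E <- as.matrix(profile)
    species <- "unspecified"
    metadata <- NULL
  }
  if (!all(is.finite(E))) stop("non-finite values in expression matrix")
  s <- nrow(E); g <- ncol(E)
  if (s < 2L) stop("at least 2 samples required")
  if (g < s) stop("expected genes >= samples (got ", g, " genes, ", s, " samples)")
  sv <- svd(E)
  tol <- max(sv$d) * max(dim(E)) * .Machine$double.eps
  keep <- sv$d > tol
  structure(
    list(lambda = sv$d[keep],
         u = sv$u[, keep, drop = FALSE],
         v = sv$v[, keep, drop = FALSE],
         k = seq_len(sum(keep)) - 1L,
         sample_ids = rownames(E),
         gene_ids = colnames(E),
         species = species,
         metadata = metadata),
    class = "eigen_decomposition"
  )
}

#' @export
print.eigen_decomposition <- function(x, ...) {
  cat(sprintf("eigen_decomposition: %d samples, %d genes, %d components (k = 0..%d)\n",
              nrow(x$u), nrow(x$v), length(x$lambda), max(x$k)))
  cat("lambda:", format(utils::head(x$lambda, 5), digits = 4),
      if (length(x$lambda) > 5) "...", "\n")
  invisible(x)
}

# reconstruct sum_{k} lambda_k u_k v_k' for components in `k` (0-based)
reconstruct <- function(decomp, k = decomp$k) {
  idx <- match(k, decomp$k)
  if (anyNA(idx)) stop("unknown component index")
  decomp$u[, idx, drop = FALSE] %*%
    (decomp$lambda[idx] * t(decomp$v[, idx, drop = FALSE]))
}

#' Coefficient of variation of the baseline sample loadings
#'
#' After good between-sample normalization the index-0 (baseline)
#' sample-eigenvector is nearly constant, \eqn{u_{0,i} \approx 1/\sqrt{s}}.
#' The coefficient of variation of its loadings quantifies how far the data
#' are from that ideal; a small value licenses the empirical-contrast
#' reading of the higher components.
#'
#' @param decomp an [decompose_profile()] result.
#' @param flag_threshold CV (percent) below which the baseline is flagged as
#'   near-constant. Default 2.
#' @return list with `cv` (percent), `near_constant` (logical), and the
#'   baseline loadings `u0` (re-signed so their mean is positive).
#' @export
baseline_cv <- function(decomp, flag_threshold = 2) {
  stopifnot(inherits(decomp, "eigen_decomposition"))
  u0 <- decomp$u[, 1L]
  if (mean(u0) < 0) u0 <- -u0
  m <- mean(u0)
  if (abs(m) < 1e-12 * stats::sd(u0)) {
    stop("baseline loadings have mean ~ 0; not a baseline component")
  }
  cv <- 100 * stats::sd(u0) / m
  list(cv = cv, near_constant = cv < flag_threshold, u0 = u0)
}

#' Empirical contrast gap of a sample-eigenvector
#'
#' For components `k >= 1`, orthogonality to the near-constant baseline
#' forces the sample loadings to sum to approximately zero; the absolute
#' loading sum measures how far `u_k` is from an exact contrast.
#'
#' @param decomp an [decompose_profile()] result.
#' @param k component index (1-based among contrasts, i.e. `k >= 1`).
#' @return the scalar gap `|sum_i u_{k,i}|`.
#' @export
empirical_contrast_gap <- function(decomp, k) {
  stopifnot(inherits(decomp, "eigen_decomposition"))
  if (k == 0L) stop("k = 0 is the baseline, not a contrast")
  idx <- match(k, decomp$k)
  if (is.na(idx)) stop("no component with index ", k)
  abs(sum(decomp$u[, idx]))
}

#' Polarize an eigen-component
#'
#' Polarization sorts an eigenvector's loadings and fixes the joint sign of
#' the (u, v) pair so that a designated reference group of samples sits at
#' the positive pole. Because the signs of `u_k` and `v_k` may be reversed
#' simultaneously without changing the product `u_k v_k'`, polarization is a
#' pure presentation convention; it never alters the decomposition.
#'
#' @param decomp an [decompose_profile()] result.
#' @param k component index.
#' @param reference sample ids (or logical/integer index) of the reference
#'   group whose mean loading is made positive.
#' @return An object of class `polarized_component`: `k`, `lambda`,
#'   `loadings` (named, original sample order), `sorted` (data.frame sorted
#'   by loading, descending), `gene_loadings` (named), `gene_table`
#'   (data.frame sorted by gene loading, descending), `sign_flipped`.
#' @export
polarize <- function(decomp, k, reference) {
  stopifnot(inherits(decomp, "eigen_decomposition"))
  idx <- match(k, decomp$k)
  if (is.na(idx)) stop("no component with index ", k)
  u <- decomp$u[, idx]
  v <- decomp$v[, idx]
  sid <- decomp$sample_ids
  if (is.null(sid)) sid <- paste0("s", seq_along(u))
  gid <- decomp$gene_ids
  if (is.null(gid)) gid <- paste0("g", seq_along(v))
  ref <- if (is.character(reference)) {
    match(reference, sid)
  } else if (is.logical(reference)) {
    which(reference)
  } else {
    as.integer(reference)
  }
  if (anyNA(ref)) stop("unknown reference sample id")
  if (length(ref) == 0L) stop("reference group is empty")
  m <- mean(u[ref])
  flipped <- FALSE
  if (m < 0) {
    u <- -u; v <- -v; flipped <- TRUE
  } else if (m == 0) {
    warning("reference group mean loading is exactly 0; keeping decomposition sign")
  }
  names(u) <- sid
  names(v) <- gid
  ord <- order(u, decreasing = TRUE)
  sorted <- data.frame(sample_id = sid[ord], loading = u[ord],
                       row.names = NULL, stringsAsFactors = FALSE)
  gord <- order(v, decreasing = TRUE)
  gene_table <- data.frame(gene_id = gid[gord], loading = v[gord],
                           rank = seq_along(v),
                           row.names = NULL, stringsAsFactors = FALSE)
  structure(
    list(k = k, lambda = decomp$lambda[idx], loadings = u, sorted = sorted,
         gene_loadings = v, gene_table = gene_table, sign_flipped = flipped,
         reference = sid[ref]),
    class = "polarized_component"
  )
}

#' @export
print.polarized_component <- function(x, ...) {
  cat(sprintf("polarized_component k = %d (lambda = %.4g, sign %s)\n",
              x$k, x$lambda, if (x$sign_flipped) "flipped" else "kept"))
  cat("top samples:", paste(utils::head(x$sorted$sample_id, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Wilcoxon rank-sum contrast test on sample loadings
#'
#' Tests whether the loadings of one group of samples are shifted relative
#' to the rest, the inferential reading of an empirical contrast. Small
#' samples (total n <= 50, no ties) use the exact rank-sum distribution;
#' otherwise the normal approximation with continuity correction is used,
#' with average ranks on ties.
#'
#' @param loadings numeric vector of sample loadings.
#' @param labels vector with exactly two distinct values (group labels).
#' @param positive the label treated as the first sample (the group whose
#'   shift is tested); defaults to the first level encountered.
#' @param alternative "two.sided" (default), "greater" (positive group
#'   shifted up) or "less".
#' @return list with `p.value`, `statistic` (rank-sum W of the positive
#'   group minus its minimum), `alternative`, `n` per group, `exact`.
#' @export
contrast_test <- function(loadings, labels,
                          positive = NULL,
                          alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2L) stop("labels must contain exactly two groups")
  if (is.null(positive)) positive <- lev[1L]
  if (!positive %in% lev) stop("`positive` is not one of the labels")
  x <- loadings[labels == positive]
  y <- loadings[labels != positive]
  if (length(x) == 0L || length(y) == 0L) stop("one group is empty")
  n <- length(x) + length(y)
  wants_exact <- n <= 50L
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = alternative,
                       exact = wants_exact, correct = TRUE)
  )
  exact_used <- wants_exact && !any(duplicated(c(x, y)))
  list(p.value = unname(ht$p.value), statistic = unname(ht$statistic),
       alternative = alternative, positive = positive,
       n = c(length(x), length(y)), exact = exact_used)
}

#' Sum-of-squares accounting after baseline removal
#'
#' With the baseline extracted, \eqn{E^{(1)} = E - \lambda_0 u_0 v_0^T}, the
#' squared singular values partition the total sum of squares:
#' \eqn{\sum_{k\ge 1}\lambda_k^2 = \|E^{(1)}\|_F^2}. The contrast `u_1`
#' induces per-gene squares \eqn{SS_j = (\sum_i u_{1,i} E^{(1)}_{ij})^2}
#' summing to \eqn{\lambda_1^2} — `u_1` is the unit contrast explaining the
#' largest portion of the sum of squares.
#'
#' @param decomp an [decompose_profile()] result for the full profile.
#' @param E1 optional pre-computed baseline-removed matrix; reconstructed
#'   from `decomp` when missing.
#' @return list with `table` (data.frame: k, lambda, lambda_sq, proportion
#'   over k >= 1, cumulative), `ss_gene` (named per-gene squares for u_1),
#'   `frobenius_sq` of `E1`, `ss_contrast` (= lambda_1^2).
#' @export
sum_of_squares <- function(decomp, E1 = NULL) {
  stopifnot(inherits(decomp, "eigen_decomposition"))
  if (length(decomp$lambda) < 2L) stop("no contrast components (k >= 1) present")
  if (is.null(E1)) E1 <- reconstruct(decomp, k = decomp$k[-1L])
  lam <- decomp$lambda[-1L]
  lam_sq <- lam^2
  prop <- lam_sq / sum(lam_sq)
  u1 <- decomp$u[, 2L]
  ss_gene <- as.vector(crossprod(E1, u1))^2
  names(ss_gene) <- decomp$gene_ids
  list(
    table = data.frame(k = decomp$k[-1L], lambda = lam, lambda_sq = lam_sq,
                       proportion = prop, cumulative = cumsum(prop)),
    ss_gene = ss_gene,
    frobenius_sq = sum(E1^2),
    ss_contrast = lam_sq[1L]
  )
}

#' Per-timepoint differential expression between two groups
#'
#' For a designed two-group time course, averages the replicates of each
#' group at each timepoint and returns the per-gene log difference
#' (group1 - group2), one vector per timepoint. These direct two-sample
#' differences are the oracle against which the dual eigen-analysis can be
#' cross-checked on treatment/control designs.
#'
#' @param profile an [expression_profile()] whose metadata contains the
#'   design columns.
#' @param group_col,time_col metadata column names for group and timepoint.
#' @param groups length-2 character: `c(group1, group2)`; the difference is
#'   group1 minus group2.
#' @return matrix genes x timepoints of mean log differences, columns named
#'   by timepoint (in sorted unique order).
#' @export
timecourse_differential <- function(profile, group_col = "group",
                                    time_col = "week", groups = NULL) {
  stopifnot(inherits(profile, "expression_profile"))
  md <- profile$metadata
  if (is.null(md) || !all(c(group_col, time_col) %in% names(md))) {
    stop("metadata must contain columns '", group_col, "' and '", time_col, "'")
  }
  grp <- as.character(md[[group_col]])
  if (is.null(groups)) groups <- unique(grp)
  if (length(groups) != 2L) stop("exactly two groups required")
  tps <- sort(unique(md[[time_col]]))
  out <- matrix(NA_real_, nrow = ncol(profile$matrix), ncol = length(tps),
                dimnames = list(profile$gene_ids, as.character(tps)))
  for (ti in seq_along(tps)) {
    i1 <- which(grp == groups[1L] & md[[time_col]] == tps[ti])
    i2 <- which(grp == groups[2L] & md[[time_col]] == tps[ti])
    if (length(i1) == 0L || length(i2) == 0L) {
      stop("design cell missing: timepoint ", tps[ti], ", group ",
           if (length(i1) == 0L) groups[1L] else groups[2L])
    }
    out[, ti] <- colMeans(profile$matrix[i1, , drop = FALSE]) -
      colMeans(profile$matrix[i2, , drop = FALSE])
  }
  out
}

#' Stratify samples on the loading plane
#'
#' Divides the plane spanned by two sample-loading vectors into four
#' regions by an x-threshold and a y-threshold: I (x > tx, y > ty),
#' II (x <= tx, y > ty), III (x > tx, y <= ty), IV (x <= tx, y <= ty).
#' Samples in I, II or III exceed at least one threshold; region IV is the
#' doubly-low corner. The "outside IV" union statistic for flagged samples
#' does not depend on the numbering of II and III.
#'
#' @param loadings_x,loadings_y equal-length numeric loading vectors.
#' @param threshold_x,threshold_y region boundaries (defaults -0.01 and
#'   0.025).
#' @param flags optional logical vector marking samples of interest (e.g.
#'   abnormal-HbA1c donors).
#' @param covariate optional numeric covariate summarized per region.
#' @return list with `samples` (per-sample region assignment), `regions`
#'   (per-region counts, flagged counts/proportions, covariate means),
#'   `flagged_outside_iv` (proportion of flagged samples in I, II or III),
#'   `thresholds`.
#' @export
stratify_samples <- function(loadings_x, loadings_y,
                             threshold_x = -0.01, threshold_y = 0.025,
                             flags = NULL, covariate = NULL) {
  n <- length(loadings_x)
  if (length(loadings_y) != n) stop("loading vectors must have equal length")
  hi_x <- loadings_x > threshold_x
  hi_y <- loadings_y > threshold_y
  region <- ifelse(hi_x & hi_y, "I",
            ifelse(!hi_x & hi_y, "II",
            ifelse(hi_x & !hi_y, "III", "IV")))
  region <- factor(region, levels = c("I", "II", "III", "IV"))
  samples <- data.frame(x = loadings_x, y = loadings_y, region = region)
  if (!is.null(flags)) samples$flagged <- flags
  if (!is.null(covariate)) samples$covariate <- covariate
  regions <- data.frame(region = levels(region),
                        n = as.integer(table(region)))
  if (!is.null(flags)) {
    regions$n_flagged <- as.integer(tapply(flags, region, sum, default = 0L))
    regions$prop_flagged <- ifelse(regions$n > 0,
                                   regions$n_flagged / regions$n, NA_real_)
  }
  if (!is.null(covariate)) {
    regions$covariate_mean <- as.numeric(tapply(covariate, region, mean))
  }
  flagged_outside_iv <- if (!is.null(flags) && any(flags)) {
    mean(region[flags] != "IV")
  } else NA_real_
  list(samples = samples, regions = regions,
       flagged_outside_iv = flagged_outside_iv,
       thresholds = c(x = threshold_x, y = threshold_y))
}
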