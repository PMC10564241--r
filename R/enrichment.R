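#' Wilcoxon-scoring enrichment of one gene set
#'
#' Rank-based enrichment of a gene set in any per-gene score vector (a gene
#' eigenvector, an aggregated list, or a per-week log difference). Genes are
#' ranked by their values (average ranks on ties); the statistic is the rank
#' sum W of the set members. The standardized score is
#' \deqn{z = \frac{W - m(N+1)/2}{\sqrt{m(N-m)(N+1)/12}},}
#' positive when the set concentrates at the positive pole (high values).
#' For small problems (set size <= 10, universe <= 30, no ties) the exact
#' rank-sum null distribution is used; otherwise the normal approximation.
#'
#' @param values named numeric vector of per-gene scores (the universe).
#' @param gene_set character vector of member gene ids.
#' @param universe optional universe of gene ids (default: names of
#'   `values`); the set is intersected with it.
#' @param min_size minimum usable intersection size (default 3).
#' @param alternative "two.sided" (default), "greater" (set concentrated at
#'   the positive pole) or "less".
#' @return list: `m` (set size used), `N`, `W`, `z`, `p.value`,
#'   `direction` ("positive" if z > 0 else "negative"), `exact`.
#' @export
wilcoxon_score <- function(values, gene_set, universe = NULL, min_size = 3,
                           alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (is.null(names(values))) stop("`values` must be named by gene id")
  if (!is.null(universe)) values <- values[names(values) %in% universe]
  N <- length(values)
  members <- names(values) %in% gene_set
  m <- sum(members)
  if (m < min_size) {
    stop("gene set intersects the universe in fewer than ", min_size, " genes")
  }
  r <- rank(values)  # average ranks on ties
  W <- sum(r[members])
  if (m == N) {
    return(list(m = m, N = N, W = W, z = 0, p.value = 1,
                direction = "positive", exact = TRUE))
  }
  mu <- m * (N + 1) / 2
  sigma <- sqrt(m * (N - m) * (N + 1) / 12)
  z <- (W - mu) / sigma
  has_ties <- anyDuplicated(values) > 0L
  exact <- !has_ties && m <= 10L && N <= 30L
  if (exact) {
    # U = W - m(m+1)/2 follows the Mann-Whitney null distribution
    U <- W - m * (m + 1) / 2
    lo <- stats::pwilcox(U, m, N - m)
    hi <- 1 - stats::pwilcox(U - 1, m, N - m)
    p <- switch(alternative,
                two.sided = min(1, 2 * min(lo, hi)),
                greater = hi,
                less = lo)
  } else {
    p <- switch(alternative,
                two.sided = 2 * stats::pnorm(-abs(z)),
                greater = stats::pnorm(-z),
                less = stats::pnorm(z))
  }
  list(m = m, N = N, W = W, z = z, p.value = p,
       direction = if (z > 0) "positive" else "negative", exact = exact)
}

#' Enrich a whole gene-set catalog against a score vector
#'
#' Applies [wilcoxon_score()] to every usable set of the catalog and
#' returns one row per set, sorted by p-value, with multiplicity adjustment
#' across the catalog (Benjamini-Hochberg by default).
#'
#' @param values named numeric per-gene score vector.
#' @param catalog a [gene_set_catalog()] or a named list of character
#'   vectors.
#' @param adjust_method method for [stats::p.adjust()] (default "BH").
#' @param min_size,max_size usable set-size bounds after intersection with
#'   the universe (defaults 5 and 2000). Sets outside the bounds are
#'   dropped with a message.
#' @return data.frame: set, size, W, z, p.value, direction, p.adjust —
#'   sorted by p.value.
#' @export
enrich_catalog <- function(values, catalog, adjust_method = "BH",
                           min_size = 5, max_size = 2000) {
  sets <- if (inherits(catalog, "gene_set_catalog")) catalog$sets else catalog
  if (length(sets) == 0L) stop("empty catalog")
  rows <- vector("list", length(sets))
  used <- logical(length(sets))
  for (i in seq_along(sets)) {
    m <- sum(names(values) %in% sets[[i]])
    if (m < min_size || m > max_size) next
    sc <- wilcoxon_score(values, sets[[i]], min_size = min_size)
    rows[[i]] <- data.frame(set = names(sets)[i], size = sc$m, W = sc$W,
                            z = sc$z, p.value = sc$p.value,
                            direction = sc$direction,
                            stringsAsFactors = FALSE)
    used[i] <- TRUE
  }
  if (!any(used)) stop("no usable sets within the size bounds")
  if (any(!used)) {
    message(sum(!used), " set(s) dropped (size outside [",
            min_size, ", ", max_size, "])")
  }
  out <- do.call(rbind, rows[used])
  out$p.adjust <- stats::p.adjust(out$p.value, method = adjust_method)
  out <- out[order(out$p.value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
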