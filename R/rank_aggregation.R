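#' Robust Rank Aggregation rho score
#'
#' For one gene with normalized ranks \eqn{r_1, ..., r_m} across m lists
#' (rank divided by list length, so uniform on (0,1] under the null), sort
#' the ranks ascending and score
#' \deqn{\rho = \min_j P(\beta_{(j)} \le r_{(j)}) = \min_j
#'   \mathrm{BetaCDF}(r_{(j)}; j, m - j + 1),}
#' the smallest tail probability over the order statistics of m independent
#' uniforms. Small rho means the gene is ranked better than chance in at
#' least some lists, robustly to outlier lists.
#'
#' @param r numeric vector of normalized ranks in (0, 1].
#' @param m number of lists (default `length(r)`).
#' @return the rho score in (0, 1].
#' @export
rra_rho <- function(r, m = length(r)) {
  if (length(r) != m) stop("rank vector length must equal m")
  if (any(r <= 0 | r > 1)) stop("normalized ranks must lie in (0, 1]")
  rs <- sort(r)
  j <- seq_len(m)
  min(stats::pbeta(rs, j, m - j + 1))
}

#' Bonferroni p-value for a rho score
#'
#' The rho score is a minimum over m order-statistic probabilities; the
#' Bonferroni bound \eqn{p = \min(1, m \rho)} is a valid (conservative)
#' p-value for how much better a gene is ranked than expected by chance.
#'
#' @param rho rho score(s) in (0, 1].
#' @param m number of lists.
#' @return p-value(s) in (0, 1].
#' @export
rra_pvalue <- function(rho, m) {
  if (any(rho <= 0 | rho > 1)) stop("rho must lie in (0, 1]")
  if (m < 1) stop("m must be >= 1")
  pmin(1, m * rho)
}

# ranks descending by value, ties broken by the stable id order
rank_descending <- function(v, ids) {
  o <- order(-v, ids)
  r <- integer(length(v))
  r[o] <- seq_along(v)
  r
}

#' Aggregate two polarized gene-eigenvectors across a homolog map
#'
#' Restricts both gene-eigenvectors to the one-to-one homolog pairs, ranks
#' each list by loading (descending for the "up" pole — the genes most
#' up-regulated at the positive pole come first — ascending for "down"),
#' normalizes ranks by the number of homologs, and scores each homolog by
#' Robust Rank Aggregation ([rra_rho()]) with the Bonferroni p
#' ([rra_pvalue()]). Both input vectors must already be polarized so their
#' positive poles agree biologically.
#'
#' @param vA,vB named numeric gene-eigenvectors (names = species gene ids).
#' @param map a [homology_map()] or two-column data.frame
#'   `(gene_a, gene_b)`; must be one-to-one.
#' @param pole "up", "down" or "both". With "both", each gene's canonical p
#'   is taken from its better pole and the pole is recorded.
#' @return data.frame sorted by (canonical) rho: gene_a, gene_b, rank_a,
#'   rank_b, norm_rank_a, norm_rank_b, rho, p.value, agg_rank, pole. With
#'   `pole = "both"`, additionally rho_up/p_up/rho_down/p_down.
#' @export
aggregate_eigenvectors <- function(vA, vB, map, pole = c("both", "up", "down")) {
  pole <- match.arg(pole)
  if (inherits(map, "homology_map")) map <- map$pairs
  map <- as.data.frame(map)
  keep <- map[[1L]] %in% names(vA) & map[[2L]] %in% names(vB)
  map <- map[keep, , drop = FALSE]
  n <- nrow(map)
  if (n == 0L) stop("empty homolog intersection")
  a <- unname(vA[map[[1L]]])
  b <- unname(vB[map[[2L]]])

  one_pole <- function(up) {
    sgn <- if (up) 1 else -1
    ra <- rank_descending(sgn * a, map[[1L]])
    rb <- rank_descending(sgn * b, map[[2L]])
    na_ <- ra / n
    nb_ <- rb / n
    # m = 2 closed form: min(1 - (1 - rmin)^2, rmax^2)
    rmin <- pmin(na_, nb_)
    rmax <- pmax(na_, nb_)
    rho <- pmin(1 - (1 - rmin)^2, rmax^2)
    list(rank_a = ra, rank_b = rb, norm_a = na_, norm_b = nb_,
         rho = rho, p = rra_pvalue(rho, 2L))
  }

  if (pole != "both") {
    res <- one_pole(pole == "up")
    out <- data.frame(gene_a = map[[1L]], gene_b = map[[2L]],
                      rank_a = res$rank_a, rank_b = res$rank_b,
                      norm_rank_a = res$norm_a, norm_rank_b = res$norm_b,
                      rho = res$rho, p.value = res$p, pole = pole,
                      stringsAsFactors = FALSE)
  } else {
    up <- one_pole(TRUE)
    dn <- one_pole(FALSE)
    better_up <- up$rho <= dn$rho
    out <- data.frame(gene_a = map[[1L]], gene_b = map[[2L]],
                      rank_a = ifelse(better_up, up$rank_a, dn$rank_a),
                      rank_b = ifelse(better_up, up$rank_b, dn$rank_b),
                      norm_rank_a = ifelse(better_up, up$norm_a, dn$norm_a),
                      norm_rank_b = ifelse(better_up, up$norm_b, dn$norm_b),
                      rho = pmin(up$rho, dn$rho),
                      p.value = pmin(up$p, dn$p),
                      pole = ifelse(better_up, "up", "down"),
                      rho_up = up$rho, p_up = up$p,
                      rho_down = dn$rho, p_down = dn$p,
                      stringsAsFactors = FALSE)
  }
  out <- out[order(out$rho, out$gene_a), , drop = FALSE]
  out$agg_rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
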