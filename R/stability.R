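#' Gene-eigenvector stability by re-sampling samples
#'
#' Repeatedly draws a random subset of the samples (without replacement),
#' decomposes the sub-profile, and correlates each subsample
#' gene-eigenvector with the full-data gene-eigenvector at the same
#' component index, after sign alignment (eigenvector signs are arbitrary;
#' the correlation is made non-negative by flipping, and flips are
#' recorded). The distribution of correlations over replicates measures the
#' stability of each component. Optionally, tracked gene sets are re-scored
#' on every replicate eigenvector and the fraction of replicates in which a
#' set is significantly enriched (raw p < alpha) with its full-data
#' direction is reported.
#'
#' @param profile an [expression_profile()].
#' @param components 0-based component indices to track (default 1).
#' @param fraction subsample fraction of the samples (default 0.9);
#'   `fraction = 1` is the degenerate identity check.
#' @param B number of re-sampling replicates (default 100).
#' @param tracked_sets optional [gene_set_catalog()] or named list of gene
#'   id vectors scored on each replicate.
#' @param alpha raw significance threshold for tracked-set enrichment
#'   (default 0.05).
#' @param seed integer seed; all randomness flows through it.
#' @param match "index" (default: compare component k with component k, as
#'   in comparing each pair of principal eigenvectors) or "best" (diagnostic
#'   mode: compare with the best-correlated subsample component, flagged in
#'   `matched_k` when it differs).
#' @param method correlation type: "pearson" (default) or "spearman".
#' @return object of class `stability_result`: `correlations` (B x
#'   n_components matrix), `flips`, `matched_k`, `set_fractions` (per
#'   tracked set and component), `summary` (per-component median and
#'   quantiles), plus the call parameters.
#' @export
resample_stability <- function(profile, components = 1L, fraction = 0.9,
                               B = 100L, tracked_sets = NULL, alpha = 0.05,
                               seed = 1L, match = c("index", "best"),
                               method = c("pearson", "spearman")) {
  stopifnot(inherits(profile, "expression_profile"))
  match <- match.arg(match)
  method <- match.arg(method)
  s <- nrow(profile$matrix)
  t_size <- round(fraction * s)
  if (t_size < max(components) + 2L) {
    stop("subsample size t = ", t_size, " too small for component ",
         max(components))
  }
  if (fraction > 1) stop("fraction must be <= 1")
  full <- decompose_profile(profile)
  vfull <- full$v[, match(components, full$k), drop = FALSE]

  sets <- if (inherits(tracked_sets, "gene_set_catalog")) tracked_sets$sets else tracked_sets
  full_dir <- NULL
  if (!is.null(sets)) {
    full_dir <- matrix("", nrow = length(sets), ncol = length(components),
                       dimnames = list(names(sets), paste0("k", components)))
    for (ci in seq_along(components)) {
      vals <- stats::setNames(vfull[, ci], profile$gene_ids)
      for (si in seq_along(sets)) {
        full_dir[si, ci] <- wilcoxon_score(vals, sets[[si]])$direction
      }
    }
  }

  cors <- matrix(NA_real_, nrow = B, ncol = length(components),
                 dimnames = list(NULL, paste0("k", components)))
  flips <- matrix(FALSE, nrow = B, ncol = length(components))
  matched_k <- matrix(rep(components, each = B), nrow = B)
  hits <- if (!is.null(sets)) {
    array(FALSE, dim = c(B, length(sets), length(components)))
  } else NULL

  with_seed(seed, {
    for (b in seq_len(B)) {
      rows <- if (t_size == s) seq_len(s) else sample.int(s, t_size)
      sub <- decompose_profile(profile$matrix[rows, , drop = FALSE])
      for (ci in seq_along(components)) {
        k <- components[ci]
        if (match == "index") {
          idx <- match(k, sub$k)
        } else {
          cc <- abs(stats::cor(vfull[, ci], sub$v, method = method))
          idx <- which.max(cc)
          matched_k[b, ci] <- sub$k[idx]
        }
        if (is.na(idx)) next
        vb <- sub$v[, idx]
        r <- stats::cor(vfull[, ci], vb, method = method)
        if (r < 0) {
          vb <- -vb
          r <- -r
          flips[b, ci] <- TRUE
        }
        cors[b, ci] <- r
        if (!is.null(sets)) {
          vals <- stats::setNames(vb, profile$gene_ids)
          for (si in seq_along(sets)) {
            sc <- wilcoxon_score(vals, sets[[si]])
            hits[b, si, ci] <- sc$p.value < alpha &&
              sc$direction == full_dir[si, ci]
          }
        }
      }
    }
  })

  set_fractions <- NULL
  if (!is.null(sets)) {
    set_fractions <- apply(hits, c(2L, 3L), mean)
    dimnames(set_fractions) <- list(names(sets), paste0("k", components))
  }
  summ <- data.frame(
    k = components,
    median = apply(cors, 2L, stats::median, na.rm = TRUE),
    q05 = apply(cors, 2L, stats::quantile, probs = 0.05, na.rm = TRUE),
    q95 = apply(cors, 2L, stats::quantile, probs = 0.95, na.rm = TRUE),
    frac_above_0.9 = colMeans(cors > 0.9, na.rm = TRUE)
  )
  structure(
    list(correlations = cors, flips = flips, matched_k = matched_k,
         set_fractions = set_fractions, summary = summ,
         B = B, t = t_size, fraction = fraction, alpha = alpha,
         match = match, method = method, seed = seed),
    class = "stability_result"
  )
}

#' @export
print.stability_result <- function(x, ...) {
  cat(sprintf("stability_result: B = %d subsamples of size t = %d (fraction %.2f)\n",
              x$B, x$t, x$fraction))
  print(x$summary, row.names = FALSE)
  if (!is.null(x$set_fractions)) {
    cat("tracked-set significant-with-direction fractions:\n")
    print(round(x$set_fractions, 3))
  }
  invisible(x)
}
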