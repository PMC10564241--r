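#' Remove the baseline component of a profile
#'
#' Subtracts the index-0 (baseline) eigen-component:
#' \eqn{E^{(1)} = E - \lambda_0 u_0 v_0^T}. The result is orthogonal to the
#' baseline and carries all the contrast structure; its squared Frobenius
#' norm equals \eqn{\sum_{k \ge 1} \lambda_k^2}.
#'
#' @param profile an [expression_profile()] or numeric matrix
#'   (samples x genes); any shape with at least one positive singular value
#'   is accepted.
#' @param decomp optional pre-computed [decompose_profile()] result.
#' @return the baseline-removed matrix with attributes `lambda0`, `u0`,
#'   `v0`.
#' @export
remove_baseline <- function(profile, decomp = NULL) {
  E <- if (inherits(profile, "expression_profile")) profile$matrix else as.matrix(profile)
  if (is.null(decomp)) {
    sv <- svd(E, nu = 1L, nv = 1L)
    lambda0 <- sv$d[1L]
    u0 <- sv$u[, 1L]
    v0 <- sv$v[, 1L]
  } else {
    lambda0 <- decomp$lambda[1L]
    u0 <- decomp$u[, 1L]
    v0 <- decomp$v[, 1L]
  }
  E1 <- E - lambda0 * tcrossprod(u0, v0)
  attr(E1, "lambda0") <- lambda0
  attr(E1, "u0") <- u0
  attr(E1, "v0") <- v0
  E1
}

#' Concatenate two baseline-removed species profiles over homologs
#'
#' Restricts both profiles to their one-to-one homolog pairs (columns
#' ordered by the map), removes each species' baseline component, optionally
#' divides each block by its Frobenius norm so both species contribute equal
#' variation, and stacks the blocks over the sample dimension.
#'
#' Baselines are recomputed on the homolog-restricted matrices before
#' removal (the restriction changes the gene universe, hence the baseline);
#' set `restrict_first = FALSE` to remove genome-wide baselines first and
#' restrict afterwards.
#'
#' @param profile_a,profile_b [expression_profile()]s for the two species.
#' @param map a [homology_map()]; pairs absent from either profile are
#'   dropped with a message.
#' @param equalize divide each block by its Frobenius norm (default TRUE).
#' @param restrict_first recompute baselines on the homolog-restricted
#'   matrices (default TRUE).
#' @return object of class `concatenated_profile`: `matrix`
#'   ((s_a + s_b) x g_hom), `block` (factor "A"/"B" per row), `map` (pairs
#'   used), `equalized`, `frobenius` (the two pre-division norms),
#'   `species`, `metadata_a`, `metadata_b`.
#' @export
concatenate_profiles <- function(profile_a, profile_b, map, equalize = TRUE,
                                 restrict_first = TRUE) {
  stopifnot(inherits(profile_a, "expression_profile"),
            inherits(profile_b, "expression_profile"))
  pairs <- if (inherits(map, "homology_map")) map$pairs else as.data.frame(map)
  keep <- pairs[[1L]] %in% profile_a$gene_ids & pairs[[2L]] %in% profile_b$gene_ids
  if (!all(keep)) {
    message("concatenate_profiles: dropped ", sum(!keep),
            " homolog pair(s) absent from a profile")
  }
  pairs <- pairs[keep, , drop = FALSE]
  if (nrow(pairs) == 0L) stop("empty homolog intersection")
  if (restrict_first) {
    A <- remove_baseline(subset_profile(profile_a, genes = pairs[[1L]]))
    B <- remove_baseline(subset_profile(profile_b, genes = pairs[[2L]]))
  } else {
    A <- remove_baseline(profile_a)[, pairs[[1L]], drop = FALSE]
    B <- remove_baseline(profile_b)[, pairs[[2L]], drop = FALSE]
  }
  fa <- sqrt(sum(A^2)); fb <- sqrt(sum(B^2))
  if (equalize) {
    A <- A / fa
    B <- B / fb
  }
  colnames(A) <- colnames(B) <- paste(pairs[[1L]], pairs[[2L]], sep = "|")
  mat <- rbind(A, B)
  structure(
    list(matrix = mat,
         block = factor(rep(c("A", "B"), c(nrow(A), nrow(B)))),
         map = pairs, equalized = equalize,
         frobenius = c(A = fa, B = fb),
         species = c(A = profile_a$species, B = profile_b$species),
         sample_ids_a = profile_a$sample_ids,
         sample_ids_b = profile_b$sample_ids,
         metadata_a = profile_a$metadata,
         metadata_b = profile_b$metadata),
    class = "concatenated_profile"
  )
}

#' @export
print.concatenated_profile <- function(x, ...) {
  cat(sprintf("concatenated_profile: (%d + %d) samples x %d homologs (%s)\n",
              sum(x$block == "A"), sum(x$block == "B"), ncol(x$matrix),
              if (x$equalized) "equalized" else "raw"))
  invisible(x)
}

#' Unified dual eigen-analysis of a concatenated two-species profile
#'
#' SVD of the concatenated, baseline-removed matrix. No baseline remains,
#' so components are indexed from 1. Each sample-eigenvector `u_k` is
#' partitioned into its species blocks; each block is contrast-tested
#' against that species' own group labels, and the whole component is
#' polarized so that the species-A reference group's mean loading is
#' positive (u and v flipped together — per-block sign freedom does not
#' exist).
#'
#' @param concat a [concatenate_profiles()] result.
#' @param groups_a,groups_b group label vectors for the species-A and -B
#'   samples (two levels each).
#' @param positive_a,positive_b the label of the reference (positive-pole)
#'   group in each species; defaults to the first label encountered.
#' @param n_components number of components to test (default 2).
#' @param alternative sidedness for the contrast tests (default
#'   "two.sided").
#' @return object of class `unified_decomposition`: `lambda`, `u`, `v`
#'   (indexed from k = 1), `block`, `loadings_a`, `loadings_b` (per
#'   component), `contrasts` (data.frame k, species, p.value),
#'   `sign_flipped`, plus the inputs' ids.
#' @export
unified_dual_eigen <- function(concat, groups_a, groups_b,
                               positive_a = NULL, positive_b = NULL,
                               n_components = 2L,
                               alternative = "two.sided") {
  stopifnot(inherits(concat, "concatenated_profile"))
  ia <- which(concat$block == "A")
  ib <- which(concat$block == "B")
  if (length(ia) < 2L || length(ib) < 2L) {
    stop("each species block needs at least 2 samples")
  }
  if (length(groups_a) != length(ia) || length(groups_b) != length(ib)) {
    stop("group labels must cover each species block")
  }
  if (is.null(positive_a)) positive_a <- as.character(groups_a)[1L]
  if (is.null(positive_b)) positive_b <- as.character(groups_b)[1L]
  sv <- svd(concat$matrix)
  tol <- max(sv$d) * max(dim(concat$matrix)) * .Machine$double.eps
  keep <- sv$d > tol
  lambda <- sv$d[keep]
  u <- sv$u[, keep, drop = FALSE]
  v <- sv$v[, keep, drop = FALSE]
  n_components <- min(n_components, length(lambda))
  flips <- logical(n_components)
  contrasts <- NULL
  for (k in seq_len(n_components)) {
    # polarize: species-A reference group mean positive
    if (mean(u[ia, k][groups_a == positive_a]) < 0) {
      u[, k] <- -u[, k]
      v[, k] <- -v[, k]
      flips[k] <- TRUE
    }
    pa <- contrast_test(u[ia, k], groups_a, positive = positive_a,
                        alternative = alternative)
    pb <- contrast_test(u[ib, k], groups_b, positive = positive_b,
                        alternative = alternative)
    contrasts <- rbind(contrasts,
                       data.frame(k = k, species = c("A", "B"),
                                  p.value = c(pa$p.value, pb$p.value)))
  }
  structure(
    list(lambda = lambda, u = u, v = v, k = seq_along(lambda),
         block = concat$block,
         loadings_a = u[ia, seq_len(n_components), drop = FALSE],
         loadings_b = u[ib, seq_len(n_components), drop = FALSE],
         contrasts = contrasts, sign_flipped = flips,
         gene_pairs = concat$map,
         sample_ids_a = concat$sample_ids_a,
         sample_ids_b = concat$sample_ids_b),
    class = "unified_decomposition"
  )
}

#' @export
print.unified_decomposition <- function(x, ...) {
  cat(sprintf("unified_decomposition: %d components (indexed from k = 1)\n",
              length(x$lambda)))
  print(x$contrasts, row.names = FALSE)
  invisible(x)
}
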