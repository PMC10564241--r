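#' Construct an expression profile
#'
#' The central container of the package: a complete log-scale expression
#' matrix with unique sample and gene identifiers, a species tag and an
#' optional per-sample metadata table. Samples index the rows and genes the
#' columns, so that the singular value decomposition yields
#' sample-eigenvectors on the left and gene-eigenvectors on the right.
#'
#' @param mat numeric matrix, samples x genes, finite, with dimnames. If
#'   `gene_ids`/`sample_ids` are supplied they override the dimnames.
#' @param species character tag identifying the organism/platform.
#' @param metadata optional data.frame with one row per sample (matched by
#'   `sample_id` column or by row order).
#' @param sample_ids,gene_ids optional identifier vectors.
#' @return An object of class `expression_profile` with elements `matrix`,
#'   `sample_ids`, `gene_ids`, `species`, `metadata`.
#' @export
expression_profile <- function(mat, species = "unspecified", metadata = NULL,
                               sample_ids = NULL, gene_ids = NULL) {
  if (!is.matrix(mat) || !is.numeric(mat)) {
    stop("`mat` must be a numeric matrix (samples x genes)")
  }
  if (is.null(sample_ids)) sample_ids <- rownames(mat)
  if (is.null(gene_ids)) gene_ids <- colnames(mat)
  if (is.null(sample_ids) || is.null(gene_ids)) {
    stop("sample and gene identifiers are required (dimnames or arguments)")
  }
  if (length(sample_ids) != nrow(mat) || length(gene_ids) != ncol(mat)) {
    stop("identifier lengths do not match matrix dimensions")
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicated sample id: ", sample_ids[duplicated(sample_ids)][1L])
  }
  if (anyDuplicated(gene_ids)) {
    stop("duplicated gene id: ", gene_ids[duplicated(gene_ids)][1L])
  }
  if (!all(is.finite(mat))) {
    bad <- which(!is.finite(mat), arr.ind = TRUE)[1L, ]
    stop("non-finite value at sample '", sample_ids[bad[1L]],
         "', gene '", gene_ids[bad[2L]],
         "': complete matrices are required")
  }
  dimnames(mat) <- list(sample_ids, gene_ids)
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (nrow(metadata) != nrow(mat)) {
      stop("metadata must have one row per sample")
    }
    if ("sample_id" %in% names(metadata)) {
      if (!setequal(metadata$sample_id, sample_ids)) {
        stop("metadata sample_id column does not match the profile samples")
      }
      metadata <- metadata[match(sample_ids, metadata$sample_id), , drop = FALSE]
      rownames(metadata) <- NULL
    }
  }
  structure(
    list(matrix = mat,
         sample_ids = as.character(sample_ids),
         gene_ids = as.character(gene_ids),
         species = species,
         metadata = metadata),
    class = "expression_profile"
  )
}

#' @export
print.expression_profile <- function(x, ...) {
  cat(sprintf("expression_profile: %d samples x %d genes (species: %s)\n",
              nrow(x$matrix), ncol(x$matrix), x$species))
  if (!is.null(x$metadata)) {
    cat("metadata columns:", paste(names(x$metadata), collapse = ", "), "\n")
  }
  invisible(x)
}

#' @export
dim.expression_profile <- function(x) dim(x$matrix)

#' Restrict a profile to a subset of genes and/or samples
#'
#' @param profile an `expression_profile`.
#' @param genes,samples identifier vectors (or indices) to keep, in the
#'   requested order.
#' @return a new `expression_profile`.
#' @export
subset_profile <- function(profile, genes = NULL, samples = NULL) {
  stopifnot(inherits(profile, "expression_profile"))
  mat <- profile$matrix
  md <- profile$metadata
  if (!is.null(samples)) {
    idx <- if (is.character(samples)) match(samples, profile$sample_ids) else samples
    if (anyNA(idx)) stop("unknown sample id: ", samples[which(is.na(idx))[1L]])
    mat <- mat[idx, , drop = FALSE]
    if (!is.null(md)) md <- md[idx, , drop = FALSE]
  }
  if (!is.null(genes)) {
    jdx <- if (is.character(genes)) match(genes, profile$gene_ids) else genes
    if (anyNA(jdx)) stop("unknown gene id: ", genes[which(is.na(jdx))[1L]])
    mat <- mat[, jdx, drop = FALSE]
  }
  expression_profile(mat, species = profile$species, metadata = md)
}

# run code under a local RNG state seeded by `seed`; the caller's
# .Random.seed is untouched
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  force(code)
}
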