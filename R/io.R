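#' Read an expression table
#'
#' Reads a tab-delimited expression table with identifiers in the first
#' column. On disk the common transcriptomics dialect is genes-as-rows;
#' internally the package keeps samples as rows (the orientation the
#' decomposition operates on), so the default policy transposes on load.
#'
#' @param path file path.
#' @param orientation "genes_as_rows" (default; file rows are genes and the
#'   matrix is transposed on load) or "samples_as_rows".
#' @param species species tag for the resulting profile.
#' @param metadata optional per-sample metadata data.frame or TSV path.
#' @return an [expression_profile()].
#' @export
read_expression <- function(path, orientation = c("genes_as_rows", "samples_as_rows"),
                            species = "unspecified", metadata = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  ids <- as.character(tab[[1L]])
  if (anyDuplicated(ids)) {
    stop("duplicated id in first column: ", ids[duplicated(ids)][1L])
  }
  num <- tab[, -1L, drop = FALSE]
  for (j in seq_along(num)) {
    if (!is.numeric(num[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(num[[j]]))))[1L]
      stop("non-numeric cell at row '", ids[bad], "', column '",
           names(num)[j], "'")
    }
  }
  mat <- as.matrix(num)
  rownames(mat) <- ids
  if (orientation == "genes_as_rows") mat <- t(mat)
  if (is.character(metadata)) {
    metadata <- utils::read.delim(metadata, header = TRUE,
                                  stringsAsFactors = FALSE)
  }
  message(sprintf("read_expression: %d samples x %d genes from %s",
                  nrow(mat), ncol(mat), path))
  expression_profile(mat, species = species, metadata = metadata)
}

# full-precision numeric formatting for lossless TSV round trips
fmt_full <- function(x) sprintf("%.17g", x)

#' Write an expression profile as a genes-as-rows TSV
#'
#' Values are written at full double precision so that
#' `read_expression(write_expression(...))` is a bit-identical round trip.
#'
#' @param profile an [expression_profile()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(profile, path) {
  stopifnot(inherits(profile, "expression_profile"))
  mat <- t(profile$matrix)  # genes as rows on disk
  out <- cbind(gene_id = rownames(mat),
               as.data.frame(apply(mat, 2L, fmt_full), check.names = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Construct a gene-set catalog
#'
#' @param sets named list of character vectors (gene ids).
#' @param universe character vector of all gene ids considered; sets are
#'   intersected with it when supplied.
#' @return object of class `gene_set_catalog` with `sets` and `universe`.
#' @export
gene_set_catalog <- function(sets, universe = NULL) {
  if (is.null(names(sets)) || any(names(sets) == "")) {
    stop("all sets must be named")
  }
  if (!is.null(universe)) {
    sets <- lapply(sets, function(s) intersect(s, universe))
  }
  empty <- lengths(sets) == 0L
  if (any(empty)) {
    warning("dropping ", sum(empty), " empty set(s): ",
            paste(utils::head(names(sets)[empty], 3), collapse = ", "))
    sets <- sets[!empty]
  }
  if (length(sets) == 0L) stop("no non-empty sets")
  structure(list(sets = sets, universe = universe), class = "gene_set_catalog")
}

#' @export
print.gene_set_catalog <- function(x, ...) {
  cat(sprintf("gene_set_catalog: %d sets (sizes %d..%d)\n",
              length(x$sets), min(lengths(x$sets)), max(lengths(x$sets))))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' then member gene ids. Empty sets are dropped with a warning.
#'
#' @param path GMT file path.
#' @param universe optional universe to intersect with.
#' @return a [gene_set_catalog()].
#' @export
read_gmt <- function(path, universe = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)][nzchar(p[-(1:2)])]))
  names(sets) <- vapply(parts, `[[`, "", 1L)
  gene_set_catalog(sets, universe = universe)
}

#' Write a gene-set catalog in GMT format
#'
#' @param catalog a [gene_set_catalog()] or named list.
#' @param path output path.
#' @param descriptions optional per-set description column (defaults to the
#'   set name).
#' @return `path`, invisibly.
#' @export
write_gmt <- function(catalog, path, descriptions = NULL) {
  sets <- if (inherits(catalog, "gene_set_catalog")) catalog$sets else catalog
  if (is.null(descriptions)) descriptions <- names(sets)
  lines <- mapply(function(nm, ds, s) paste(c(nm, ds, s), collapse = "\t"),
                  names(sets), descriptions, sets)
  writeLines(lines, path)
  invisible(path)
}

#' Construct a homology map
#'
#' A one-to-one pairing of gene ids between two species. Rows re-using an
#' already-seen id on either side are dropped (first occurrence kept) with
#' a message, so the retained map is one-to-one.
#'
#' @param gene_a,gene_b equal-length character vectors, or a two-column
#'   data.frame passed as `gene_a`.
#' @return object of class `homology_map` with `pairs` (data.frame
#'   `gene_a`, `gene_b`) and `n_dropped`.
#' @export
homology_map <- function(gene_a, gene_b = NULL) {
  if (is.null(gene_b)) {
    df <- as.data.frame(gene_a)
    gene_a <- as.character(df[[1L]])
    gene_b <- as.character(df[[2L]])
  }
  if (length(gene_a) != length(gene_b)) stop("sides must have equal length")
  dup <- duplicated(gene_a) | duplicated(gene_b)
  if (any(dup)) {
    message("homology_map: dropped ", sum(dup),
            " many-to-many row(s); first occurrences kept")
  }
  structure(
    list(pairs = data.frame(gene_a = gene_a[!dup], gene_b = gene_b[!dup],
                            stringsAsFactors = FALSE),
         n_dropped = sum(dup)),
    class = "homology_map"
  )
}

#' @export
print.homology_map <- function(x, ...) {
  cat(sprintf("homology_map: %d one-to-one pairs (%d dropped on load)\n",
              nrow(x$pairs), x$n_dropped))
  invisible(x)
}

#' Read a two-column homolog table
#'
#' @param path TSV with two columns (species-A id, species-B id); a header
#'   line is detected and kept as column names.
#' @return a [homology_map()].
#' @export
read_homology <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2L) stop("homolog table must have two columns")
  homology_map(tab[[1L]], tab[[2L]])
}

#' Write a homology map as TSV
#' @param map a [homology_map()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_homology <- function(map, path) {
  stopifnot(inherits(map, "homology_map"))
  utils::write.table(map$pairs, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a binary mask image
#'
#' Reads a single-channel (or first-channel) PNG and binarizes at > 0.
#'
#' @param path PNG path.
#' @return integer 0/1 matrix.
#' @export
read_mask <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  img <- png::readPNG(path)
  if (length(dim(img)) == 3L) img <- img[, , 1L]
  mask <- (img > 0) * 1L
  if (!any(mask == 1L)) stop("empty mask: ", path)
  mask
}

#' Write a binary mask as PNG
#' @param mask 0/1 matrix (anything > 0 is foreground).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask > 0) * 1, path)
  invisible(path)
}
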