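#' Gene-by-sample count matrix with sample metadata
#'
#' The central container of the package: a genes x samples matrix of
#' non-negative integer counts plus a per-sample metadata table. Genes are
#' always rows and samples always columns; this orientation is enforced at
#' construction and assumed by every downstream stage.
#'
#' @param counts Numeric matrix of non-negative integers with unique rownames
#'   (gene identifiers) and unique colnames (sample or cell identifiers).
#' @param meta Optional `data.frame` with one row per sample, in the same
#'   order as `colnames(counts)`. Typical columns: `condition`, `donor`,
#'   `disease`, `cluster`, `trajectory_id`, `pseudotime`. Fields are only
#'   checked by the stages that need them.
#'
#' @return An object of class `count_matrix`: a list with elements `counts`
#'   (integer matrix) and `meta` (data.frame keyed by sample id).
#' @examples
#' m <- matrix(0:5, nrow = 3, dimnames = list(paste0("g", 1:3), c("s1", "s2")))
#' cm <- count_matrix(m)
#' dim(cm)
#' @export
count_matrix <- function(counts, meta = NULL) {
  counts <- as.matrix(counts)
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]),
               collapse = ", "))
  }
  if (is.null(meta)) {
    meta <- data.frame(row.names = colnames(counts))
  }
  x <- structure(list(counts = counts, meta = meta), class = "count_matrix")
  validate_count_matrix(x)
  storage.mode(x$counts) <- "double"  # counts can exceed .Machine$integer.max after pseudobulk sums
  x
}

#' Validate a count_matrix
#'
#' Checks the container invariants: non-negative integral counts, unique gene
#' and sample identifiers, and 1:1 correspondence between metadata rows and
#' samples. All analysis stages call this on entry, so corrupted objects are
#' rejected at the door rather than deep inside a computation.
#'
#' @param x A `count_matrix`.
#' @return `x`, invisibly, if valid; otherwise an error is thrown.
#' @export
validate_count_matrix <- function(x) {
  if (!inherits(x, "count_matrix")) {
    stop("not a count_matrix object")
  }
  counts <- x$counts
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stop("counts must be a numeric matrix")
  }
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop("counts must have gene rownames and sample colnames")
  }
  if (anyDuplicated(rownames(counts))) {
    stop("duplicate gene identifiers: ",
         paste(unique(rownames(counts)[duplicated(rownames(counts))]), collapse = ", "))
  }
  if (anyDuplicated(colnames(counts))) {
    stop("duplicate sample identifiers: ",
         paste(unique(colnames(counts)[duplicated(colnames(counts))]), collapse = ", "))
  }
  if (anyNA(counts)) stop("counts contain NA")
  if (any(counts < 0)) stop("counts must be non-negative")
  if (any(counts != round(counts))) stop("counts must be integral")
  if (!is.data.frame(x$meta)) stop("meta must be a data.frame")
  if (nrow(x$meta) != ncol(counts)) {
    stop("meta must have one row per sample (", ncol(counts), " samples, ",
         nrow(x$meta), " meta rows)")
  }
  if (nrow(x$meta) > 0 && !identical(rownames(x$meta), colnames(counts))) {
    stop("meta rownames must equal sample identifiers, in order")
  }
  invisible(x)
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$counts)

#' Subset a count_matrix by genes and/or samples
#'
#' @param x A `count_matrix`.
#' @param i Gene index (names, logical or integer).
#' @param j Sample index; metadata rows are subset in step.
#' @param ... Ignored.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  counts <- x$counts[i, j, drop = FALSE]
  meta <- x$meta[j, , drop = FALSE]
  rownames(meta) <- colnames(counts)
  count_matrix(counts, meta)
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix: ", nrow(x$counts), " genes x ", ncol(x$counts),
      " samples\n", sep = "")
  if (ncol(x$meta) > 0) {
    cat("meta fields: ", paste(colnames(x$meta), collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

#' Attach a sample metadata table to a count_matrix
#'
#' Joins an external annotation table onto the samples of a count matrix.
#' Every sample must be present in the table; extra table rows are ignored
#' with a warning. Sample order is unchanged.
#'
#' @param x A `count_matrix`.
#' @param table A `data.frame` keyed by sample identifier, either through its
#'   rownames or a `sample_id` column.
#' @return `x` with `meta` populated from `table`.
#' @export
attach_metadata <- function(x, table) {
  validate_count_matrix(x)
  if (!is.data.frame(table)) stop("table must be a data.frame")
  if ("sample_id" %in% colnames(table)) {
    ids <- as.character(table$sample_id)
    table <- table[, setdiff(colnames(table), "sample_id"), drop = FALSE]
  } else {
    ids <- rownames(table)
  }
  if (anyDuplicated(ids)) stop("duplicate sample identifiers in metadata table")
  samples <- colnames(x$counts)
  missing <- setdiff(samples, ids)
  if (length(missing) > 0) {
    stop("metadata table is missing samples: ", paste(missing, collapse = ", "))
  }
  extra <- setdiff(ids, samples)
  if (length(extra) > 0) {
    warning("ignoring ", length(extra), " metadata rows for unknown samples: ",
            paste(utils::head(extra, 5), collapse = ", "))
  }
  meta <- table[match(samples, ids), , drop = FALSE]
  rownames(meta) <- samples
  x$meta <- meta
  validate_count_matrix(x)
}
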