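#' Read a count matrix from TSV, CSV or MatrixMarket files
#'
#' TSV/CSV layout: header row of sample identifiers, first column of gene
#' identifiers. MatrixMarket layout: a coordinate-format integer `.mtx` file
#' (1-based indices per the MatrixMarket standard) accompanied by two sidecar
#' text files holding the row (gene) and column (sample) names, one per line.
#'
#' @param path Path to the matrix file.
#' @param format One of `"tsv"`, `"csv"`, `"mtx"`. Defaults to the file
#'   extension.
#' @param row_file,col_file Sidecar name files for `format = "mtx"`; default
#'   `<path>.rows` and `<path>.cols`.
#' @return A [count_matrix] with empty metadata (see [attach_metadata]).
#' @seealso [write_counts] for the inverse operation.
#' @export
read_counts <- function(path, format = c("tsv", "csv", "mtx"),
                        row_file = paste0(path, ".rows"),
                        col_file = paste0(path, ".cols")) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tsv", "csv", "mtx")) ext else "tsv"
  }
  format <- match.arg(format)
  if (format == "mtx") {
    for (f in c(row_file, col_file)) {
      if (!file.exists(f)) stop("companion name file not found: ", f)
    }
    m <- tryCatch(as.matrix(Matrix::readMM(path)),
                  error = function(e) stop("malformed MatrixMarket file ", path,
                                           ": ", conditionMessage(e)))
    rownames(m) <- readLines(row_file)
    colnames(m) <- readLines(col_file)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- tryCatch(
      utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                        colClasses = "character", quote = "\""),
      error = function(e) stop("malformed ", format, " file ", path, ": ",
                               conditionMessage(e)))
    if (ncol(df) < 2) stop("malformed ", format, " file ", path,
                           ": need a gene column plus at least one sample")
    genes <- df[[1]]
    m <- as.matrix(df[, -1, drop = FALSE])
    vals <- suppressWarnings(as.numeric(m))
    bad <- which(is.na(vals))
    if (length(bad) > 0) {
      stop("non-numeric entry at data line ", ((bad[1] - 1) %% nrow(m)) + 1,
           " of ", path)
    }
    m <- matrix(vals, nrow = nrow(m),
                dimnames = list(genes, colnames(df)[-1]))
  }
  if (any(m < 0)) stop("negative count in ", path)
  if (any(m != round(m))) stop("non-integer count in ", path)
  count_matrix(m)
}

#' Write a count matrix to TSV, CSV or MatrixMarket files
#'
#' @param x A [count_matrix].
#' @param path Output path.
#' @inheritParams read_counts
#' @return `path`, invisibly.
#' @export
write_counts <- function(x, path, format = c("tsv", "csv", "mtx"),
                         row_file = paste0(path, ".rows"),
                         col_file = paste0(path, ".cols")) {
  validate_count_matrix(x)
  if (missing(format)) {
    ext <- tolower(tools::file_ext(path))
    format <- if (ext %in% c("tsv", "csv", "mtx")) ext else "tsv"
  }
  format <- match.arg(format)
  if (format == "mtx") {
    Matrix::writeMM(methods::as(Matrix::Matrix(x$counts, sparse = TRUE),
                                "generalMatrix"), path)
    writeLines(rownames(x$counts), row_file)
    writeLines(colnames(x$counts), col_file)
  } else {
    sep <- if (format == "csv") "," else "\t"
    df <- data.frame(gene = rownames(x$counts), x$counts, check.names = FALSE)
    utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' Named collection of gene sets
#'
#' @param sets Named list of character vectors of gene identifiers. Names must
#'   be unique and every set non-empty.
#' @param descriptions Optional character vector of per-set descriptions
#'   (recycled `""` by default).
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!is.list(sets)) stop("sets must be a named list")
  if (length(sets) > 0 && (is.null(names(sets)) || any(names(sets) == ""))) {
    stop("sets must be a fully named list")
  }
  if (anyDuplicated(names(sets))) stop("duplicate set names")
  if (any(lengths(sets) == 0)) {
    stop("empty gene set: ", paste(names(sets)[lengths(sets) == 0], collapse = ", "))
  }
  sets <- lapply(sets, as.character)
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- names(sets)
  structure(list(sets = sets, descriptions = descriptions),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("gene_set_collection with ", length(x$sets), " sets (",
      paste0(utils::head(names(x$sets), 6), collapse = ", "),
      if (length(x$sets) > 6) ", ..." else "", ")\n", sep = "")
  invisible(x)
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' Read gene sets in GMT format
#'
#' One set per line: `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to a GMT file.
#' @return A [gene_set_collection].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3)
  if (length(short) > 0) {
    stop("GMT line ", short[1], " has fewer than 3 fields (name, description, genes)")
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1)
  gene_set_collection(sets, vapply(fields, `[[`, "", 2))
}

#' Write gene sets in GMT format
#'
#' @param x A [gene_set_collection].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "gene_set_collection"))
  lines <- vapply(names(x$sets), function(nm) {
    paste(c(nm, x$descriptions[[nm]], x$sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
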