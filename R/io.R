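# TSV interchange dialect: '#'-prefixed header comments, tab separation,
# first column = row identifiers, floats at 10 significant digits so that
# load -> write round-trips are byte-stable.

format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) "NA" else formatC(v, digits = 10, format = "g")
  }, character(1))
  out
}

#' Write a numeric matrix as commented TSV
#'
#' @param mat Numeric matrix with row and column names.
#' @param path Output file path.
#' @param comments Character vector written as `# `-prefixed header lines.
#' @param id_name Name of the identifier column (first column).
#' @return `path`, invisibly.
#' @export
write_matrix_tsv <- function(mat, path, comments = character(), id_name = "id") {
  stopifnot(is.matrix(mat), !is.null(rownames(mat)), !is.null(colnames(mat)))
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  writeLines(paste(c(id_name, colnames(mat)), collapse = "\t"), con)
  body <- vapply(seq_len(nrow(mat)), function(i) {
    paste(c(rownames(mat)[i], format_num(mat[i, ])), collapse = "\t")
  }, character(1))
  writeLines(body, con)
  invisible(path)
}

#' Read a numeric matrix from commented TSV
#'
#' Rejects ragged rows with the offending (1-based, comment-inclusive) line
#' number.
#'
#' @param path File written by [write_matrix_tsv()] or any TSV with an id
#'   column, optional `#` comments, and a header row.
#' @return Numeric matrix with dimnames.
#' @export
read_matrix_tsv <- function(path) {
  check_rectangular(path)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("matrix TSV needs an id column plus data: ", path)
  rn <- as.character(df[[1L]])
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- rn
  m
}

#' Read a data frame from commented TSV
#'
#' @param path TSV path with a header row; `#` comment lines are skipped.
#' @return A `data.frame` (no row names).
#' @export
read_table_tsv <- function(path) {
  check_rectangular(path)
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write a data frame as commented TSV
#'
#' @param df Data frame.
#' @param path Output path.
#' @param comments Character vector of `#` header lines.
#' @return `path`, invisibly.
#' @export
write_table_tsv <- function(df, path, comments = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  if (length(comments)) writeLines(paste0("# ", comments), con)
  cols <- lapply(df, function(col) if (is.double(col)) format_num(col) else as.character(col))
  writeLines(paste(names(df), collapse = "\t"), con)
  if (nrow(df)) writeLines(do.call(paste, c(cols, sep = "\t")), con)
  invisible(path)
}

check_rectangular <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = "\t", comment.char = "#", quote = "")
  nf <- nf[!is.na(nf)]
  if (length(nf) > 1L && length(unique(nf)) != 1L) {
    lines <- readLines(path)
    keep <- !grepl("^\\s*#", lines) & nzchar(lines)
    widths <- vapply(strsplit(lines[keep], "\t", fixed = TRUE), length, integer(1))
    bad <- which(widths != widths[1L])[1L]
    bad_line <- which(keep)[bad]
    stop(sprintf("ragged TSV '%s': row at line %d has %d fields, expected %d",
                 path, bad_line, widths[bad], widths[1L]))
  }
  invisible(TRUE)
}

#' Read genesets from a GMT file
#'
#' Standard GMT: one set per line, `name<TAB>description<TAB>member...`.
#'
#' @param path GMT file path.
#' @return Named list of character vectors of member gene ids.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(vapply(fields, length, integer(1)) < 3L)
  if (length(bad)) stop("GMT line ", bad[1L], " has fewer than 3 fields")
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- vapply(fields, `[[`, character(1), 1L)
  sets
}

#' Write genesets to a GMT file
#'
#' @param sets Named list of character vectors.
#' @param path Output path.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  stopifnot(is.list(sets), !is.null(names(sets)))
  descriptions <- descriptions %||% rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}
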