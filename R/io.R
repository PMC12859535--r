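# Readers and writers for the plain-text interchange formats: GMT feature
# sets, 2-column p-value TSV, p-value matrix CSV, bound tables.

#' Read a GMT feature-set file
#'
#' Each line: set name, description, then tab-separated member ids. Duplicate
#' members within a line are dropped with a warning; duplicate set names or
#' empty member lists are errors.
#'
#' @param path file path.
#' @return Named list of character member vectors, with the descriptions in
#'   attribute `"description"`; file order preserved.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty GMT file: ", path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nm <- vapply(parts, `[`, "", 1L)
  if (anyDuplicated(nm))
    stop("duplicate set names in ", path, ": ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  desc <- vapply(parts, function(x) if (length(x) >= 2L) x[2L] else "", "")
  sets <- lapply(seq_along(parts), function(i) {
    mem <- parts[[i]][-(1:2)]
    mem <- mem[nzchar(mem)]
    if (length(mem) == 0L)
      stop("set '", nm[i], "' has no members (line ", i, ")")
    if (anyDuplicated(mem)) {
      warning("set '", nm[i], "': duplicate members dropped")
      mem <- unique(mem)
    }
    mem
  })
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(desc, nm)
  sets
}

#' Write a GMT feature-set file
#'
#' @param sets named list of member-id vectors.
#' @param path file path.
#' @param description optional per-set descriptions (defaults to `"na"`).
#' @export
write_gmt <- function(sets, path, description = NULL) {
  nm <- names(sets)
  if (is.null(nm)) stop("'sets' must be named")
  if (is.null(description)) description <- attr(sets, "description")
  if (is.null(description)) description <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(nm[i], description[[i]], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read per-feature p-values from a 2-column TSV
#'
#' Expects a header line and columns (feature id, p-value). Out-of-range
#' p-values are reported with their line number.
#'
#' @param path file path.
#' @return Named numeric p-value vector in file order.
#' @export
read_pvalues <- function(path) {
  df <- utils::read.delim(path, header = TRUE, colClasses = c("character", "numeric"))
  if (ncol(df) < 2L) stop("expected 2 columns (id, p) in ", path)
  p <- df[[2L]]
  bad <- which(is.na(p) | p < 0 | p > 1)
  if (length(bad))
    stop("p-value out of [0,1] on line ", bad[1L] + 1L, " of ", path)
  if (anyDuplicated(df[[1L]])) stop("duplicate feature ids in ", path)
  stats::setNames(p, df[[1L]])
}

#' Write per-feature p-values as a 2-column TSV (full precision)
#'
#' @param p named p-value vector.
#' @param path file path.
#' @export
write_pvalues <- function(p, path) {
  if (is.null(names(p))) names(p) <- as.character(seq_along(p))
  lines <- c("feature_id\tp",
             paste(names(p), sprintf("%.17g", p), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a replicability p-value matrix from CSV
#'
#' First column feature ids, header row of study names.
#'
#' @param path file path.
#' @return Numeric matrix with feature row names and study column names.
#' @export
read_pvalue_matrix <- function(path) {
  df <- utils::read.csv(path, header = TRUE, check.names = FALSE)
  ids <- as.character(df[[1L]])
  mat <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(mat) <- "double"
  bad <- which(is.na(mat) | mat < 0 | mat > 1, arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop("p-value out of [0,1] at row ", bad[1L, 1L], ", column ",
         colnames(mat)[bad[1L, 2L]], " of ", path)
  rownames(mat) <- ids
  mat
}

#' Write a replicability p-value matrix as CSV (full precision)
#'
#' @param pmat numeric matrix, features x studies.
#' @param path file path.
#' @export
write_pvalue_matrix <- function(pmat, path) {
  ids <- rownames(pmat) %||% as.character(seq_len(nrow(pmat)))
  studies <- colnames(pmat) %||% paste0("study", seq_len(ncol(pmat)))
  body <- apply(pmat, 1L, function(r) paste(sprintf("%.17g", r), collapse = ","))
  writeLines(c(paste(c("feature_id", studies), collapse = ","),
               paste(ids, body, sep = ",")), path)
  invisible(path)
}

#' Write a bound table as TSV
#'
#' Emits both the count bound and the TDP (`bound/size`) per set.
#'
#' @param bounds a `bound_table` data.frame (from [predict.focusct()] or
#'   [coherent_bounds()]).
#' @param path file path.
#' @export
write_bounds <- function(bounds, path) {
  df <- as.data.frame(bounds)
  names(df)[names(df) == "set"] <- "set_name"
  names(df)[names(df) == "tdp"] <- "bound_tdp"
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
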