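#' Construct an LC/MS feature table
#'
#' A feature table holds one row per m/z feature (an ion characterized by its
#' mass-to-charge ratio and chromatographic retention time) and one intensity
#' column per sample. It is the central container of the package: every scan,
#' filter and network operation consumes one.
#'
#' @param mz numeric vector of mass-to-charge ratios (Th), one per feature;
#'   all strictly positive.
#' @param rt numeric vector of retention times (seconds), non-negative, same
#'   length as `mz`.
#' @param intensities numeric matrix, features x samples; non-negative or
#'   `NA` (missing). Zeros are allowed and treated as measured.
#' @param sample_ids character vector of unique sample labels; defaults to
#'   the column names of `intensities`.
#'
#' @return An object of class `feature_table` with components `mz`, `rt`,
#'   `intensities`, `sample_ids` and `feature_ids`. Feature identifiers are
#'   the display string `"<mz to 4 dp>_<rt to 0 dp>"`, disambiguated with an
#'   ordinal suffix when two features round to the same label. Internally
#'   features are addressed by row index; the string is for display/export.
#' @seealso [read_feature_table()], [simulate_feature_table()]
#' @export
feature_table <- function(mz, rt, intensities, sample_ids = colnames(intensities)) {
  mz <- as.numeric(mz)
  rt <- as.numeric(rt)
  if (!is.matrix(intensities)) intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  p <- length(mz)
  if (length(rt) != p || nrow(intensities) != p)
    stop("mz, rt and intensity rows must have equal length", call. = FALSE)
  if (anyNA(mz) || any(mz <= 0)) stop("all m/z values must be positive", call. = FALSE)
  if (anyNA(rt) || any(rt < 0)) stop("all retention times must be non-negative", call. = FALSE)
  if (is.null(sample_ids)) sample_ids <- paste0("S", seq_len(ncol(intensities)))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != ncol(intensities))
    stop("sample_ids must match the number of intensity columns", call. = FALSE)
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids: ", paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  if (any(intensities < 0, na.rm = TRUE))
    stop("negative intensities are not allowed", call. = FALSE)
  dimnames(intensities) <- NULL
  structure(list(
    mz = mz, rt = rt, intensities = intensities,
    sample_ids = sample_ids, feature_ids = make_feature_ids(mz, rt)
  ), class = "feature_table")
}

# "mz_rt" display label, 4 / 0 decimals; ties broken with an ordinal suffix
make_feature_ids <- function(mz, rt) {
  base <- sprintf("%.4f_%.0f", mz, rt)
  dup <- ave(seq_along(base), base, FUN = seq_along)
  ifelse(dup > 1L, paste0(base, "_", dup), base)
}

#' @export
print.feature_table <- function(x, ...) {
  cat("LC/MS feature table: ", n_features(x), " features x ", n_samples(x), " samples\n", sep = "")
  cat("  m/z range: ", sprintf("%.4f", min(x$mz)), " - ", sprintf("%.4f", max(x$mz)), " Th\n", sep = "")
  cat("  rt  range: ", sprintf("%.0f", min(x$rt)), " - ", sprintf("%.0f", max(x$rt)), " s\n", sep = "")
  miss <- mean(is.na(x$intensities)) * 100
  cat("  missing intensities: ", sprintf("%.1f", miss), "%\n", sep = "")
  invisible(x)
}

#' Number of features / samples in a feature table
#' @param x a `feature_table`.
#' @return integer count.
#' @export
n_features <- function(x) length(x$mz)

#' @rdname n_features
#' @export
n_samples <- function(x) ncol(x$intensities)

#' Subset a feature table
#'
#' @param x a `feature_table`.
#' @param i feature (row) indices.
#' @param j sample (column) indices.
#' @param ... ignored.
#' @return a `feature_table` restricted to the selected features/samples.
#' @export
`[.feature_table` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(n_features(x))
  if (missing(j)) j <- seq_len(n_samples(x))
  feature_table(x$mz[i], x$rt[i], x$intensities[i, j, drop = FALSE], x$sample_ids[j])
}

#' Read a tab-delimited feature table
#'
#' Parses the standard interchange format: a header row, the first two
#' columns holding m/z and retention time, and one intensity column per
#' sample thereafter. Empty cells and `NA` are read as missing; any other
#' non-numeric intensity cell also becomes missing. A row whose m/z or
#' retention time cannot be parsed (or carries a negative intensity) is a
#' format error naming the offending file line, unless `lenient = TRUE`, in
#' which case such rows are dropped with a warning. Rows are never silently
#' discarded.
#'
#' @param path path to a tab-delimited text file.
#' @param lenient drop malformed rows with a warning instead of erroring.
#' @return a [feature_table()].
#' @export
read_feature_table <- function(path, lenient = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", colClasses = "character",
                           check.names = FALSE, na.strings = character(), quote = "",
                           comment.char = "", blank.lines.skip = FALSE)
  if (ncol(raw) < 3L)
    stop("feature table must have >= 3 columns (m/z, time, >=1 sample): ", path, call. = FALSE)
  if (nrow(raw) < 1L) stop("feature table has no data rows: ", path, call. = FALSE)
  sample_ids <- colnames(raw)[-(1:2)]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample headers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "), call. = FALSE)

  num <- function(v) suppressWarnings(as.numeric(ifelse(trimws(v) %in% c("", "NA"), NA, v)))
  mz <- num(raw[[1]])
  rt <- num(raw[[2]])
  ints <- vapply(raw[-(1:2)], num, numeric(nrow(raw)))
  if (!is.matrix(ints)) ints <- matrix(ints, nrow = nrow(raw))

  bad_key <- is.na(mz) | mz <= 0 | is.na(rt) | rt < 0
  bad_neg <- apply(ints < 0, 1L, any) %in% TRUE
  bad <- bad_key | bad_neg
  if (any(bad)) {
    lines <- which(bad) + 1L  # +1 for the header row
    msg <- paste0("malformed feature row(s) at file line(s) ",
                  paste(lines, collapse = ", "),
                  " (unparseable m/z or time, or negative intensity)")
    if (!lenient) stop(msg, call. = FALSE)
    warning(msg, "; dropped because lenient = TRUE", call. = FALSE)
    mz <- mz[!bad]; rt <- rt[!bad]; ints <- ints[!bad, , drop = FALSE]
    if (length(mz) == 0L) stop("no valid feature rows remain: ", path, call. = FALSE)
  }
  feature_table(mz, rt, ints, sample_ids)
}

#' Write a feature table in the tab-delimited interchange format
#'
#' Inverse of [read_feature_table()]: columns `mz`, `time`, then one column
#' per sample. Missing intensities are written as empty cells.
#'
#' @param table a `feature_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(table, path) {
  stopifnot(inherits(table, "feature_table"))
  df <- data.frame(mz = table$mz, time = table$rt,
                   as.data.frame(table$intensities), check.names = FALSE)
  colnames(df)[-(1:2)] <- table$sample_ids
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a target-metabolite list
#'
#' Each row names one query: the first column is the m/z of the targeted
#' feature, an optional second column its retention time in seconds (used to
#' restrict matching to a chromatographic window), and an optional third
#' column a free-text name. No header row is expected.
#'
#' @param path path to a tab-delimited text file.
#' @return a data frame with columns `mz`, `rt` (`NA` when absent) and
#'   `name` (`NA` when absent), one row per query.
#' @export
read_target_list <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("target list is empty: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  mz <- rt <- numeric(length(lines))
  name <- rep(NA_character_, length(lines))
  for (i in seq_along(parts)) {
    f <- trimws(parts[[i]])
    v <- suppressWarnings(as.numeric(f[1]))
    if (is.na(v) || v <= 0)
      stop("target list: non-numeric or non-positive m/z at row ", i, call. = FALSE)
    mz[i] <- v
    rt[i] <- if (length(f) >= 2L && nzchar(f[2])) suppressWarnings(as.numeric(f[2])) else NA_real_
    if (!is.na(rt[i]) && rt[i] < 0)
      stop("target list: negative retention time at row ", i, call. = FALSE)
    if (length(f) >= 3L && nzchar(f[3])) name[i] <- f[3]
  }
  data.frame(mz = mz, rt = rt, name = name, stringsAsFactors = FALSE)
}

#' Read a class-labels file
#'
#' One label per sample, in the same order as the feature-table columns.
#' Accepts either a single column of labels or two columns
#' (`sample_id<TAB>label`).
#'
#' @param path path to a tab-delimited text file without header.
#' @param n_expected optional expected number of samples; mismatch is an
#'   error.
#' @return character vector of labels (named by sample id when given).
#' @export
read_class_labels <- function(path, n_expected = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.delim(path, header = FALSE, sep = "\t", colClasses = "character",
                           quote = "", blank.lines.skip = TRUE)
  labels <- if (ncol(raw) >= 2L) stats::setNames(raw[[2]], raw[[1]]) else raw[[1]]
  if (!is.null(n_expected) && length(labels) != n_expected)
    stop("class labels file has ", length(labels), " entries; expected ",
         n_expected, call. = FALSE)
  labels
}
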