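## Technical-quality filtering of features, following the usual LC/MS
## triplicate-injection workflow: a feature is kept when its median
## coefficient of variation across technical replicates is below cv_max,
## its replicate-profile Pearson correlation exceeds rep_cor_min, and its
## missing-value fraction is below missing_max. All three comparisons are
## strict.

normalize_replicate_map <- function(table, replicate_map) {
  if (is.null(replicate_map)) replicate_map <- table$sample_ids  # identity grouping
  if (length(replicate_map) != n_samples(table))
    stop("replicate_map must have one entry per sample column", call. = FALSE)
  as.factor(replicate_map)
}

#' Quality-control filter for LC/MS features
#'
#' Computes per-feature technical-quality metrics over groups of technical
#' replicate injections and retains features passing all criteria: median
#' coefficient of variation (CV, percent) below `cv_max`, median Pearson
#' correlation of replicate intensity profiles above `rep_cor_min`, and
#' missing-value percentage below `missing_max` (strict inequalities).
#'
#' The replicate correlation compares, across biological samples, the
#' feature's intensities in the first, second, ... replicate injection of
#' each sample (replicates paired by their order within each group). When
#' every group has a single column (the identity grouping) this criterion
#' cannot be evaluated and is skipped, flagged in the report; the same
#' happens per feature when fewer than three samples provide a complete
#' replicate pair or the feature is constant (correlation undefined).
#'
#' @param table a [feature_table()].
#' @param replicate_map vector (length = number of samples) grouping columns
#'   into technical replicates of the same biological sample; `NULL` means
#'   every column is its own sample.
#' @param cv_max maximum median CV, percent; default 50.
#' @param rep_cor_min minimum median replicate correlation; default 0.7.
#' @param missing_max maximum missing-value percentage; default 30.
#' @return list with `table` (the filtered `feature_table`) and `report`
#'   (data frame of per-feature metrics and pass/fail flags; `cor_skipped`
#'   marks features whose correlation criterion could not be evaluated).
#' @export
qc_filter <- function(table, replicate_map = NULL, cv_max = 50,
                      rep_cor_min = 0.7, missing_max = 30) {
  stopifnot(inherits(table, "feature_table"))
  grp <- normalize_replicate_map(table, replicate_map)
  X <- table$intensities
  p <- n_features(table)
  groups <- split(seq_len(n_samples(table)), grp)

  ## median CV across replicate groups (groups of size 1 give no CV)
  cv_by_group <- lapply(groups, function(cols) {
    if (length(cols) < 2L) return(rep(NA_real_, p))
    sub <- X[, cols, drop = FALSE]
    m <- rowMeans(sub, na.rm = TRUE)
    s <- apply(sub, 1L, stats::sd, na.rm = TRUE)
    cv <- 100 * s / m
    cv[!is.finite(cv)] <- NA_real_
    cv
  })
  cv_mat <- do.call(cbind, cv_by_group)
  median_cv <- apply(cv_mat, 1L, function(v) {
    if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE)
  })

  ## replicate-profile correlation: pair replicate positions within groups
  sizes <- lengths(groups)
  max_rep <- max(sizes)
  cor_skipped_all <- max_rep < 2L
  median_cor <- rep(NA_real_, p)
  if (!cor_skipped_all) {
    rep_cols <- lapply(seq_len(max_rep), function(k)
      vapply(groups, function(cols) if (length(cols) >= k) cols[k] else NA_integer_,
             integer(1)))
    pairs <- utils::combn(max_rep, 2L, simplify = FALSE)
    cors <- sapply(pairs, function(pr) {
      c1 <- rep_cols[[pr[1]]]; c2 <- rep_cols[[pr[2]]]
      ok <- !is.na(c1) & !is.na(c2)
      if (sum(ok) < 3L) return(rep(NA_real_, p))
      A <- X[, c1[ok], drop = FALSE]; B <- X[, c2[ok], drop = FALSE]
      vapply(seq_len(p), function(f) {
        a <- A[f, ]; b <- B[f, ]
        use <- !is.na(a) & !is.na(b)
        if (sum(use) < 3L || stats::sd(a[use]) == 0 || stats::sd(b[use]) == 0)
          return(NA_real_)
        stats::cor(a[use], b[use])
      }, numeric(1))
    })
    if (is.null(dim(cors))) cors <- matrix(cors, nrow = p)
    median_cor <- apply(cors, 1L, function(v)
      if (all(is.na(v))) NA_real_ else stats::median(v, na.rm = TRUE))
  } else if (!is.null(replicate_map) && !all(sizes == 1L)) {
    warning("some replicate groups have a single column; correlation criterion skipped for them",
            call. = FALSE)
  }
  if (cor_skipped_all && !is.null(replicate_map) && all(sizes == 1L))
    warning("all replicate groups have size 1; replicate-correlation criterion skipped",
            call. = FALSE)

  missing_pct <- 100 * rowMeans(is.na(X))

  pass_cv <- !is.na(median_cv) & median_cv < cv_max
  pass_cv[is.na(median_cv)] <- TRUE              # CV undefined (size-1 groups or constant 0-mean): skip
  cor_skipped <- is.na(median_cor)
  pass_cor <- cor_skipped | (median_cor > rep_cor_min)
  pass_missing <- missing_pct < missing_max
  pass <- pass_cv & pass_cor & pass_missing

  report <- data.frame(
    feature_id = table$feature_ids, mz = table$mz, rt = table$rt,
    median_cv = median_cv, median_rep_cor = median_cor,
    missing_pct = missing_pct,
    pass_cv = pass_cv, pass_cor = pass_cor, cor_skipped = cor_skipped,
    pass_missing = pass_missing, pass = pass,
    stringsAsFactors = FALSE
  )
  list(table = table[which(pass), ], report = report)
}

#' Average technical replicates
#'
#' Collapses technical-replicate columns to one column per biological
#' sample by the per-feature mean of non-missing replicate intensities; a
#' group that is entirely missing for a feature stays missing.
#'
#' @inheritParams qc_filter
#' @return a `feature_table` with one column per replicate group (identity
#'   grouping returns the table unchanged apart from column order).
#' @export
average_replicates <- function(table, replicate_map = NULL) {
  stopifnot(inherits(table, "feature_table"))
  grp <- normalize_replicate_map(table, replicate_map)
  groups <- split(seq_len(n_samples(table)), grp)
  avg <- vapply(groups, function(cols) {
    m <- rowMeans(table$intensities[, cols, drop = FALSE], na.rm = TRUE)
    m[is.nan(m)] <- NA_real_
    m
  }, numeric(n_features(table)))
  if (!is.matrix(avg)) avg <- matrix(avg, nrow = n_features(table))
  feature_table(table$mz, table$rt, avg, names(groups))
}
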