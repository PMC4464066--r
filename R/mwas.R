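#' Correlate two intensity profiles
#'
#' Pairwise-complete Pearson or Spearman correlation between two per-sample
#' intensity vectors. With `log_transform = TRUE` values are log10
#' transformed first (non-positive intensities become missing); ranks use
#' midranks for ties in Spearman mode.
#'
#' @param x,y numeric vectors of equal length (may contain `NA`).
#' @param method `"pearson"` or `"spearman"`.
#' @param log_transform log10-transform before correlating (default `TRUE`;
#'   rank-based Spearman is invariant to it).
#' @param min_pairs minimum number of complete pairs required (default 10);
#'   below it the correlation is undefined.
#' @return list with `r` (`NA_real_` when undefined) and `n_used`, the
#'   number of complete pairs.
#' @export
correlate_profile <- function(x, y, method = c("pearson", "spearman"),
                              log_transform = TRUE, min_pairs = 10) {
  method <- match.arg(method)
  if (length(x) != length(y)) stop("x and y must have equal length", call. = FALSE)
  if (log_transform) { x <- log10_intensity(x); y <- log10_intensity(y) }
  ok <- !is.na(x) & !is.na(y)
  n_used <- sum(ok)
  if (n_used < min_pairs) return(list(r = NA_real_, n_used = n_used))
  if (stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
    return(list(r = NA_real_, n_used = n_used))
  list(r = stats::cor(x[ok], y[ok], method = method), n_used = n_used)
}

log10_intensity <- function(x) {
  x[!is.na(x) & x <= 0] <- NA_real_
  log10(x)
}

#' Two-sided p-value for a correlation coefficient
#'
#' Uses the t transform `t = r * sqrt(n - 2) / sqrt(1 - r^2)` on `n - 2`
#' degrees of freedom; Spearman coefficients use the same approximation.
#' A coefficient of exactly +/-1 is assigned p = 0 by convention.
#'
#' @param r correlation coefficient(s) in `[-1, 1]` (vectorized).
#' @param n_used number(s) of complete pairs; must be >= 3 for a defined
#'   p-value.
#' @param method `"pearson"` or `"spearman"` (same transform; recorded for
#'   provenance).
#' @return two-sided p-value(s); `NA` where `r` is `NA` or `n_used < 3`.
#' @export
correlation_pvalue <- function(r, n_used, method = c("pearson", "spearman")) {
  match.arg(method)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE))
    stop("correlation coefficients must lie in [-1, 1]", call. = FALSE)
  n_used <- rep_len(n_used, length(r))
  p <- rep(NA_real_, length(r))
  exact <- !is.na(r) & abs(r) >= 1
  p[exact] <- 0
  ok <- !is.na(r) & !exact & n_used >= 3
  tt <- r[ok] * sqrt(n_used[ok] - 2) / sqrt(1 - r[ok]^2)
  p[ok] <- 2 * stats::pt(-abs(tt), df = n_used[ok] - 2)
  p
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment: `q_(i) = min_{j >= i}
#' p_(j) * m / j`, capped at 1 and mapped back to input order. Undefined
#' entries (`NA`) are excluded from the adjustment (the effective `m` is
#' the number of defined p-values) and stay `NA`.
#'
#' @param p vector of p-values in `[0, 1]`, `NA` allowed.
#' @return vector of q-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  q <- rep(NA_real_, length(p))
  ok <- !is.na(p)
  q[ok] <- stats::p.adjust(p[ok], method = "BH")
  q
}

## Vectorized scan of one target profile against every feature.
## L is the (possibly log10) samples x features matrix.
scan_profile <- function(x, L, method, min_pairs) {
  r <- suppressWarnings(as.vector(stats::cor(x, L, use = "pairwise.complete.obs",
                                             method = method)))
  n_used <- as.vector(crossprod(!is.na(x), !is.na(L)))
  r[n_used < min_pairs] <- NA_real_
  list(r = r, n_used = n_used)
}

#' Targeted metabolome-wide association scan
#'
#' The central fit of the package: for each target metabolite, the target's
#' per-sample intensity profile is correlated against every m/z feature of
#' the table, p-values are attached via the t transform and adjusted by the
#' Benjamini-Hochberg step-up procedure, and features with `q < alpha` form
#' the significant set. Each target is adjusted separately.
#'
#' A target is resolved to its table feature by m/z (and retention time
#' when supplied) within `ppm_tol`/`rt_tol`, taking the closest-ppm match;
#' alternatively an external assay profile (e.g. an orthogonal targeted
#' measurement of the same samples) can be supplied through
#' `target_vectors`, in which case the target acts as a virtual feature and
#' need not be present in the table.
#'
#' With `exclude_self = TRUE` (default) features attributable to the target
#' itself — any feature within `ppm_tol` of the target mass, of its
#' registered adduct forms, or of their 13C isotopologues — are removed
#' from the scan, so that the result reflects association of the target
#' with *other* chemicals rather than with its own ions.
#'
#' @param table a [feature_table()].
#' @param targets data frame with columns `mz`, optional `rt`, optional
#'   `name` (see [read_target_list()]), or a numeric vector of masses.
#' @param method correlation method, `"pearson"` (default) or
#'   `"spearman"`.
#' @param alpha FDR significance level (default 0.05).
#' @param exclude_self drop the target's own ion forms from the scan.
#' @param sig_features optional data frame/vector of m/z values restricting
#'   the scan to matching features (e.g. a prior discriminatory list).
#' @param target_vectors optional named list of numeric per-sample profiles
#'   (names matching `targets$name`) used instead of table features.
#' @param ppm_tol,rt_tol matching tolerances for target resolution and
#'   self-exclusion.
#' @param log_transform log10-transform intensities before Pearson
#'   correlation (default `TRUE`).
#' @param min_pairs minimum complete pairs per correlation (default 10);
#'   features below it get undefined `r` and are excluded from the FDR
#'   adjustment.
#' @return an object of class `mwas`: a list with `results` (one data frame
#'   per target: `feature_index`, `feature_id`, `mz`, `rt`, `r`, `n_used`,
#'   `p`, `q`, `mean_log_intensity`, `significant`), `excluded` (per-target
#'   self-excluded feature ids), the scan settings, and `n_samples`.
#'   Methods: [print.mwas()], [summary.mwas()], [plot.mwas()],
#'   [coef.mwas()].
#' @examples
#' fix <- choline_casestudy_fixture(seed = 1)
#' fit <- run_targeted_mwas(fix$table, fix$target)
#' summary(fit)
#' @export
run_targeted_mwas <- function(table, targets, method = c("pearson", "spearman"),
                              alpha = 0.05, exclude_self = TRUE,
                              sig_features = NULL, target_vectors = NULL,
                              ppm_tol = 10, rt_tol = 30,
                              log_transform = TRUE, min_pairs = 10) {
  stopifnot(inherits(table, "feature_table"))
  method <- match.arg(method)
  targets <- as_query_df(targets)
  if (!is.numeric(alpha) || alpha < 0 || alpha > 1)
    stop("alpha must lie in [0, 1]", call. = FALSE)
  target_names <- ifelse(is.na(targets$name),
                         sprintf("target_%.4f", targets$mz), targets$name)

  L <- t(table$intensities)                        # samples x features
  mean_log <- colMeans(log10_intensity(L), na.rm = TRUE)
  if (log_transform && method == "pearson") L <- log10_intensity(L)

  scan_idx_all <- seq_len(n_features(table))
  if (!is.null(sig_features)) {
    sig <- as_query_df(sig_features)
    m <- match_features(table, sig, ppm_tol = ppm_tol, rt_tol = rt_tol)
    scan_idx_all <- sort(unique(m$feature_index))
    if (length(scan_idx_all) == 0L)
      stop("no table feature matches the supplied significant-feature list",
           call. = FALSE)
  }

  results <- stats::setNames(vector("list", nrow(targets)), target_names)
  excluded <- stats::setNames(vector("list", nrow(targets)), target_names)
  for (k in seq_len(nrow(targets))) {
    ## resolve the target profile
    anchor_index <- NA_integer_
    if (!is.null(target_vectors) && target_names[k] %in% names(target_vectors)) {
      x <- as.numeric(target_vectors[[target_names[k]]])
      if (length(x) != n_samples(table))
        stop("external profile for target '", target_names[k],
             "' must have one value per sample", call. = FALSE)
      if (log_transform && method == "pearson") x <- log10_intensity(x)
    } else {
      m <- match_features(table, targets[k, , drop = FALSE],
                          ppm_tol = ppm_tol, rt_tol = rt_tol)
      if (nrow(m) == 0L)
        stop("target '", target_names[k],
             "' matches no table feature and no external profile was supplied",
             call. = FALSE)
      anchor_index <- m$feature_index[1L]   # closest by |ppm|
      x <- L[, anchor_index]
    }

    ## self-exclusion: the target's own ion family
    scan_idx <- scan_idx_all
    if (!is.na(anchor_index)) scan_idx <- setdiff(scan_idx, anchor_index)
    if (exclude_self) {
      fam <- self_exclusion_masses(targets$mz[k])
      self_idx <- unique(match_features(table, as.numeric(fam),
                                        ppm_tol = ppm_tol)$feature_index)
      scan_idx <- setdiff(scan_idx, self_idx)
      excluded[[k]] <- table$feature_ids[sort(unique(c(
        self_idx, if (!is.na(anchor_index)) anchor_index)))]
    } else {
      excluded[[k]] <- table$feature_ids[anchor_index[!is.na(anchor_index)]]
    }

    sc <- scan_profile(x, L[, scan_idx, drop = FALSE], method, min_pairs)
    p <- correlation_pvalue(sc$r, sc$n_used, method)
    q <- bh_adjust(p)
    results[[k]] <- data.frame(
      feature_index = scan_idx,
      feature_id = table$feature_ids[scan_idx],
      mz = table$mz[scan_idx], rt = table$rt[scan_idx],
      r = sc$r, n_used = sc$n_used, p = p, q = q,
      mean_log_intensity = mean_log[scan_idx],
      significant = !is.na(q) & q < alpha,
      stringsAsFactors = FALSE
    )
  }

  structure(list(
    results = results, excluded = excluded,
    targets = cbind(targets, name_used = target_names),
    method = method, alpha = alpha, log_transform = log_transform,
    ppm_tol = ppm_tol, rt_tol = rt_tol, min_pairs = min_pairs,
    exclude_self = exclude_self, n_samples = n_samples(table),
    call = match.call()
  ), class = "mwas")
}

#' @export
print.mwas <- function(x, ...) {
  cat("Targeted MWAS (", x$method, " correlation, BH FDR at alpha = ",
      format(x$alpha), ")\n", sep = "")
  for (nm in names(x$results)) {
    res <- x$results[[nm]]
    cat("  ", nm, ": ", nrow(res), " features scanned, ",
        sum(res$significant), " significant (q < ", format(x$alpha), "), ",
        length(x$excluded[[nm]]), " self-excluded\n", sep = "")
  }
  invisible(x)
}

#' Summarize a targeted MWAS fit
#'
#' @param object an `mwas` fit.
#' @param ... ignored.
#' @return data frame with one row per target: features scanned, number
#'   significant, strongest positive and negative correlations, and the
#'   number of self-excluded ion forms.
#' @export
summary.mwas <- function(object, ...) {
  out <- do.call(rbind, lapply(names(object$results), function(nm) {
    res <- object$results[[nm]]
    data.frame(target = nm,
               n_scanned = nrow(res),
               n_significant = sum(res$significant),
               max_r = if (all(is.na(res$r))) NA_real_ else max(res$r, na.rm = TRUE),
               min_r = if (all(is.na(res$r))) NA_real_ else min(res$r, na.rm = TRUE),
               n_self_excluded = length(object$excluded[[nm]]),
               stringsAsFactors = FALSE)
  }))
  class(out) <- c("summary.mwas", class(out))
  out
}

#' @export
print.summary.mwas <- function(x, ...) {
  cat("Targeted MWAS summary\n")
  print.data.frame(x, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Correlation coefficients of a targeted MWAS fit
#'
#' @param object an `mwas` fit.
#' @param target target name or index (default: first target).
#' @param ... ignored.
#' @return named numeric vector of per-feature correlation coefficients.
#' @export
coef.mwas <- function(object, target = 1L, ...) {
  res <- object$results[[target]]
  stats::setNames(res$r, res$feature_id)
}
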