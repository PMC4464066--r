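## Exact monoisotopic mass constants (Th, singly charged assumed).
## Proton and neutral-loss/replacement shifts from CODATA/IUPAC atomic masses.
PROTON_MASS   <- 1.0072765   # H+ (H minus electron)
NA_FOR_H      <- 21.9819442  # Na replaces H
H2O_MASS      <- 18.0105646
C13_SHIFT     <- 1.0033548   # 13C - 12C

#' Electrospray adduct registry
#'
#' Mass offsets of common positive-mode adducts relative to the neutral
#' molecule M, plus the corresponding first 13C isotopologues. All species
#' are singly charged.
#'
#' @return data frame with columns `name` (e.g. `"[M+H]+"`) and `delta`
#'   (exact mass shift in Th added to the neutral monoisotopic mass).
#' @export
adduct_registry <- function() {
  base <- c(
    "[M+H]+"     = PROTON_MASS,
    "[M+Na]+"    = PROTON_MASS + NA_FOR_H,
    "[M-H2O]+"   = PROTON_MASS - H2O_MASS,      # in-source water loss of [M+H]+
    "[M+2Na-H]+" = PROTON_MASS + 2 * NA_FOR_H
  )
  iso <- stats::setNames(base + C13_SHIFT, paste0("13C-", names(base)))
  all <- c(base, iso)
  data.frame(name = names(all), delta = unname(all), stringsAsFactors = FALSE)
}

#' Signed parts-per-million mass difference
#'
#' `1e6 * (observed - reference) / reference`; the quantity used throughout
#' for mass-tolerance decisions (default tolerance 10 ppm).
#'
#' @param observed_mz,reference_mz positive masses (Th); vectorized.
#' @return signed ppm deviation.
#' @export
ppm_difference <- function(observed_mz, reference_mz) {
  if (any(observed_mz <= 0, na.rm = TRUE) || any(reference_mz <= 0, na.rm = TRUE))
    stop("masses must be positive", call. = FALSE)
  1e6 * (observed_mz - reference_mz) / reference_mz
}

adduct_delta <- function(name) {
  reg <- adduct_registry()
  i <- match(name, reg$name)
  if (anyNA(i))
    stop("unknown adduct '", paste(name[is.na(i)], collapse = "', '"),
         "'; registry: ", paste(reg$name, collapse = ", "), call. = FALSE)
  reg$delta[i]
}

#' Predict the m/z of one adduct form from another
#'
#' Exact monoisotopic arithmetic: the neutral mass is recovered by removing
#' the offset of the observed adduct and the offset of the requested adduct
#' is added, i.e. `mz - delta(from) + delta(to)`.
#'
#' @param mz observed m/z (Th).
#' @param from_adduct,to_adduct adduct names present in [adduct_registry()].
#' @return predicted m/z of the `to_adduct` form.
#' @export
adduct_transform <- function(mz, from_adduct, to_adduct) {
  if (any(mz <= 0)) stop("masses must be positive", call. = FALSE)
  mz - adduct_delta(from_adduct) + adduct_delta(to_adduct)
}

#' Predict an isotopologue m/z
#'
#' Shifts a mass by `n` 13C-for-12C substitutions (1.0033548 Th each); the
#' usual companion-ion arithmetic for the +1 isotope peak.
#'
#' @param mz observed m/z (Th).
#' @param n number of 13C substitutions (may be negative to go back to the
#'   monoisotopic form).
#' @return shifted m/z.
#' @export
isotope_transform <- function(mz, n = 1L) {
  if (any(mz <= 0)) stop("masses must be positive", call. = FALSE)
  mz + n * C13_SHIFT
}

#' Match query masses against a feature table
#'
#' Finds every feature whose m/z lies within `ppm_tol` of each query (and,
#' when the query carries a retention time, within `rt_tol` seconds of it).
#' Matches are ordered by increasing absolute ppm error within each query.
#'
#' @param table a [feature_table()].
#' @param queries data frame with columns `mz` and optionally `rt`/`name`
#'   (as returned by [read_target_list()]), or a numeric vector of masses.
#' @param ppm_tol mass tolerance in ppm (> 0); default 10.
#' @param rt_tol retention-time tolerance in seconds, used only for queries
#'   that specify an rt; default 30.
#' @return data frame with one row per (query, feature) match: columns
#'   `query_index`, `feature_index`, `feature_id`, `mz`, `rt`, `ppm_error`
#'   and `rt_delta` (`NA` when the query has no rt). Zero rows when nothing
#'   matches.
#' @export
match_features <- function(table, queries, ppm_tol = 10, rt_tol = 30) {
  stopifnot(inherits(table, "feature_table"))
  queries <- as_query_df(queries)
  if (!is.numeric(ppm_tol) || ppm_tol <= 0) stop("ppm_tol must be > 0", call. = FALSE)
  use_rt <- !is.na(queries$rt)
  if (any(use_rt) && (!is.numeric(rt_tol) || rt_tol <= 0))
    stop("rt_tol must be > 0 when queries carry retention times", call. = FALSE)
  out <- vector("list", nrow(queries))
  for (q in seq_len(nrow(queries))) {
    ppm <- ppm_difference(table$mz, queries$mz[q])
    keep <- abs(ppm) <= ppm_tol
    rt_delta <- rep(NA_real_, n_features(table))
    if (use_rt[q]) {
      rt_delta <- table$rt - queries$rt[q]
      keep <- keep & abs(rt_delta) <= rt_tol
    }
    idx <- which(keep)
    if (length(idx) == 0L) next
    idx <- idx[order(abs(ppm[idx]))]
    out[[q]] <- data.frame(
      query_index = q, feature_index = idx, feature_id = table$feature_ids[idx],
      mz = table$mz[idx], rt = table$rt[idx],
      ppm_error = ppm[idx], rt_delta = rt_delta[idx],
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L)
    return(data.frame(query_index = integer(), feature_index = integer(),
                      feature_id = character(), mz = numeric(), rt = numeric(),
                      ppm_error = numeric(), rt_delta = numeric(),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

as_query_df <- function(queries) {
  if (is.numeric(queries)) queries <- data.frame(mz = queries)
  if (!is.data.frame(queries) || !"mz" %in% names(queries))
    stop("queries must be a numeric vector or a data frame with an 'mz' column",
         call. = FALSE)
  if (is.null(queries$rt)) queries$rt <- NA_real_
  if (is.null(queries$name)) queries$name <- NA_character_
  if (any(is.na(queries$mz)) || any(queries$mz <= 0))
    stop("query m/z must be positive", call. = FALSE)
  queries
}

#' Cross-study feature overlap
#'
#' Pairs the features of two studies by mass (and optionally retention
#' time) with greedy one-to-one nearest-|ppm| matching: candidate pairs
#' within tolerance are accepted in order of increasing absolute ppm error,
#' each feature participating in at most one pair. The counts always
#' satisfy `|a| = common + a_only` and `|b| = common + b_only`.
#'
#' @param a,b data frames with columns `mz` and optionally `rt`, or numeric
#'   mass vectors.
#' @param ppm_tol mass tolerance in ppm (> 0).
#' @param rt_tol optional retention-time tolerance in seconds; when given
#'   (and both sides carry `rt`) pairs must also co-elute within it.
#' @return list with `common` (data frame `a_index`, `b_index`,
#'   `ppm_error`), `a_only` and `b_only` (integer indices).
#' @export
overlap_features <- function(a, b, ppm_tol = 10, rt_tol = NULL) {
  a <- as_query_df(a); b <- as_query_df(b)
  if (ppm_tol <= 0) stop("ppm_tol must be > 0", call. = FALSE)
  use_rt <- !is.null(rt_tol) && !all(is.na(a$rt)) && !all(is.na(b$rt))
  if (use_rt && rt_tol <= 0) stop("rt_tol must be > 0", call. = FALSE)
  ppm <- outer(a$mz, b$mz, function(x, y) 1e6 * (x - y) / y)
  ok <- abs(ppm) <= ppm_tol
  if (use_rt) ok <- ok & abs(outer(a$rt, b$rt, "-")) <= rt_tol
  cand <- which(ok, arr.ind = TRUE)
  common <- data.frame(a_index = integer(), b_index = integer(), ppm_error = numeric())
  if (nrow(cand) > 0L) {
    cand <- cand[order(abs(ppm[cand])), , drop = FALSE]
    used_a <- logical(nrow(a)); used_b <- logical(nrow(b))
    keep <- logical(nrow(cand))
    for (k in seq_len(nrow(cand))) {
      i <- cand[k, 1L]; j <- cand[k, 2L]
      if (!used_a[i] && !used_b[j]) {
        keep[k] <- TRUE; used_a[i] <- TRUE; used_b[j] <- TRUE
      }
    }
    cand <- cand[keep, , drop = FALSE]
    common <- data.frame(a_index = cand[, 1L], b_index = cand[, 2L],
                         ppm_error = ppm[cand])
  }
  list(common = common,
       a_only = setdiff(seq_len(nrow(a)), common$a_index),
       b_only = setdiff(seq_len(nrow(b)), common$b_index))
}

## All masses a target can present as, for self-exclusion: every registered
## adduct form of its neutral (assuming the query is the [M+H]+ ion) plus
## the first 13C isotopologue of each form.
self_exclusion_masses <- function(mz, assume_adduct = "[M+H]+") {
  reg <- adduct_registry()
  vapply(reg$name, function(a) adduct_transform(mz, assume_adduct, a), numeric(1))
}
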