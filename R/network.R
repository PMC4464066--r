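#' Pairwise correlation matrix over a feature subset
#'
#' @param table a [feature_table()].
#' @param features integer indices (or feature ids) of the subset; `NULL`
#'   means all features.
#' @param method `"pearson"` or `"spearman"`.
#' @param log_transform log10-transform intensities first (Pearson only;
#'   ranks are invariant).
#' @param min_pairs minimum complete observations per pair; a pair below it
#'   is an error (subset the samples or impute first).
#' @return object of class `corr_matrix`: list with `ids`, symmetric `mat`
#'   with unit diagonal, `method`, `n` (number of samples) and `lambda`
#'   (`NULL`; set by [shrink_correlation()]).
#' @export
sample_correlation_matrix <- function(table, features = NULL,
                                      method = c("pearson", "spearman"),
                                      log_transform = TRUE, min_pairs = 10) {
  stopifnot(inherits(table, "feature_table"))
  method <- match.arg(method)
  idx <- resolve_feature_subset(table, features)
  if (length(idx) < 2L) stop("correlation matrix needs >= 2 features", call. = FALSE)
  L <- t(table$intensities[idx, , drop = FALSE])
  if (log_transform && method == "pearson") L <- log10_intensity(L)
  npair <- crossprod(!is.na(L))
  if (any(npair < min_pairs))
    stop("some feature pairs have fewer than ", min_pairs,
         " complete observations; filter features or impute first", call. = FALSE)
  R <- suppressWarnings(stats::cor(L, use = "pairwise.complete.obs", method = method))
  diag(R) <- 1
  R[is.na(R)] <- 0   # constant features: undefined, treated as uncorrelated
  dimnames(R) <- NULL
  new_corr_matrix(table$feature_ids[idx], R, method, n = nrow(L))
}

new_corr_matrix <- function(ids, mat, method, n, lambda = NULL) {
  structure(list(ids = ids, mat = mat, method = method, n = n, lambda = lambda),
            class = "corr_matrix")
}

#' @export
print.corr_matrix <- function(x, ...) {
  cat(nrow(x$mat), "x", ncol(x$mat), x$method, "correlation matrix")
  if (!is.null(x$lambda)) cat(" (shrinkage lambda =", format(x$lambda, digits = 4), ")")
  cat("\n")
  invisible(x)
}

resolve_feature_subset <- function(table, features) {
  if (is.null(features)) return(seq_len(n_features(table)))
  if (is.character(features)) {
    idx <- match(features, table$feature_ids)
    if (anyNA(idx)) stop("unknown feature id(s): ",
                         paste(features[is.na(idx)], collapse = ", "), call. = FALSE)
    return(idx)
  }
  as.integer(features)
}

## complete-case (default) or half-minimum imputed data matrix for a subset
complete_data_matrix <- function(table, idx, log_transform = TRUE,
                                 impute = c("complete", "halfmin")) {
  impute <- match.arg(impute)
  L <- t(table$intensities[idx, , drop = FALSE])
  if (impute == "halfmin") {
    for (j in seq_len(ncol(L))) {
      miss <- is.na(L[, j])
      if (any(miss)) {
        obs <- L[!miss, j]
        L[miss, j] <- if (length(obs)) min(obs[obs > 0], Inf) / 2 else 0
      }
    }
  } else {
    L <- L[stats::complete.cases(L), , drop = FALSE]
  }
  if (log_transform) L <- log10_intensity(L)
  L
}

#' Shrinkage estimate of a correlation matrix
#'
#' Linear shrinkage of the sample correlation matrix toward the identity
#' target (Schafer-Strimmer): off-diagonal entries become
#' `(1 - lambda) * r_ij` with the analytic optimal intensity
#' `lambda* = sum Var(r_ij) / sum r_ij^2` over `i != j`, clipped to
#' `[0, 1]`, where `Var(r_ij)` is the unbiased empirical variance of the
#' standardized cross-products. `lambda = 1` when all off-diagonal sample
#' correlations are exactly zero (nothing to shrink). The result is always
#' positive definite for `lambda > 0`, which is what makes the partial-
#' correlation transform [cor_to_pcor()] well posed even when features
#' outnumber samples.
#'
#' @inheritParams sample_correlation_matrix
#' @param impute `"complete"` (complete-case rows, default) or `"halfmin"`
#'   (half-minimum imputation of missing intensities).
#' @param lambda optional fixed shrinkage intensity in `[0, 1]` overriding
#'   the analytic estimate (`lambda = 0` reproduces the sample matrix).
#' @return `corr_matrix` with the `lambda` field set.
#' @export
shrink_correlation <- function(table, features = NULL,
                               method = c("pearson", "spearman"),
                               log_transform = TRUE,
                               impute = c("complete", "halfmin"),
                               lambda = NULL) {
  stopifnot(inherits(table, "feature_table"))
  method <- match.arg(method)
  idx <- resolve_feature_subset(table, features)
  if (length(idx) < 2L) stop("correlation matrix needs >= 2 features", call. = FALSE)
  L <- complete_data_matrix(table, idx, log_transform = log_transform,
                            impute = match.arg(impute))
  n <- nrow(L)
  if (n < 3L) stop("shrinkage needs >= 3 complete observations", call. = FALSE)
  if (method == "spearman") L <- apply(L, 2L, rank)
  sds <- apply(L, 2L, stats::sd)
  if (any(sds == 0)) stop("constant feature(s) in the subset; remove before shrinkage",
                          call. = FALSE)
  Xs <- scale(L)                           # standardized, sd uses n - 1
  R <- crossprod(Xs) / (n - 1)
  diag(R) <- 1
  if (is.null(lambda)) {
    ## unbiased variance of the off-diagonal sample correlations:
    ## var(r_ij) = n / (n-1)^3 * sum_k (w_kij - wbar_ij)^2, w_kij = x_ki x_kj
    p <- ncol(Xs)
    W1 <- crossprod(Xs)            # sum_k w_kij  = (n-1) r_ij
    W2 <- crossprod(Xs^2)          # sum_k w_kij^2
    sumsq <- W2 - W1^2 / n         # sum_k (w - wbar)^2
    var_r <- n / (n - 1)^3 * sumsq
    off <- upper.tri(R)
    denom <- sum(R[off]^2)
    lambda <- if (denom == 0) 1 else min(1, max(0, sum(var_r[off]) / denom))
  } else {
    if (lambda < 0 || lambda > 1) stop("lambda must lie in [0, 1]", call. = FALSE)
  }
  S <- (1 - lambda) * R
  diag(S) <- 1
  new_corr_matrix(table$feature_ids[idx], S, method, n = n, lambda = lambda)
}

#' Partial correlations from a correlation matrix
#'
#' The association between each pair of variables after removing the linear
#' effect of all others: with `Omega = R^-1`,
#' `P_ij = -Omega_ij / sqrt(Omega_ii * Omega_jj)` off the diagonal and 1 on
#' it. Feed it a shrunk matrix ([shrink_correlation()]) so the inverse
#' exists; a singular matrix is an error unless `pseudoinverse = TRUE`, in
#' which case the Moore-Penrose inverse is used.
#'
#' @param R a `corr_matrix` (or plain symmetric matrix with unit diagonal).
#' @param pseudoinverse fall back to the Moore-Penrose inverse when `R` is
#'   (numerically) singular.
#' @return `corr_matrix` of partial correlations; `method` gains a
#'   `"partial-"` prefix.
#' @export
cor_to_pcor <- function(R, pseudoinverse = FALSE) {
  if (inherits(R, "corr_matrix")) {
    ids <- R$ids; method <- R$method; n <- R$n; lambda <- R$lambda; M <- R$mat
  } else {
    M <- as.matrix(R); ids <- as.character(seq_len(nrow(M)))
    method <- "unknown"; n <- NA_integer_; lambda <- NULL
  }
  if (nrow(M) != ncol(M) || max(abs(M - t(M))) > 1e-8)
    stop("R must be a symmetric square matrix", call. = FALSE)
  omega <- tryCatch(solve(M), error = function(e) NULL)
  if (is.null(omega)) {
    if (!pseudoinverse)
      stop("correlation matrix is singular; shrink it first or set pseudoinverse = TRUE",
           call. = FALSE)
    omega <- MASS::ginv(M)
  }
  d <- sqrt(diag(omega))
  P <- -omega / tcrossprod(d)
  diag(P) <- 1
  P <- (P + t(P)) / 2
  new_corr_matrix(ids, P, paste0("partial-", method), n = n, lambda = lambda)
}

#' Seeded association network
#'
#' Breadth-first construction of a metabolic association network around
#' seed metabolites. Wave 1 correlates each seed feature against every
#' other feature; edges passing both thresholds (`|r| > r_min` and BH
#' `q < q_max`, adjusted within the wave) recruit depth-1 nodes. With
#' `depth_max = 2` a second wave correlates each depth-1 node against all
#' not-yet-recruited features, recruiting depth-2 nodes — the secondary
#' network structure. In `method = "partial"` mode the recruited node set
#' is re-estimated jointly: a shrinkage correlation matrix over the nodes
#' is inverted to partial correlations ([shrink_correlation()] +
#' [cor_to_pcor()]) and edges are re-derived from those coefficients at the
#' same thresholds.
#'
#' @param table a [feature_table()].
#' @param seeds target queries (see [read_target_list()]) resolved to table
#'   features by m/z (+ rt) within `ppm_tol`/`rt_tol`.
#' @param r_min minimum absolute correlation for an edge, in `[0, 1)`.
#' @param q_max FDR threshold for an edge, in `(0, 1]`.
#' @param depth_max 1 (primary only) or 2 (include secondary wave).
#' @param method `"full"` (marginal correlations) or `"partial"`.
#' @param corr correlation coefficient, `"spearman"` (default for
#'   networks) or `"pearson"`.
#' @param q_adjust `"wave"` (BH within each expansion wave, default) or
#'   `"pooled"` (one BH over all tests of all waves, applied after
#'   expansion).
#' @param node_cap maximum number of recruited nodes (default 500);
#'   exceeding it aborts with advice to raise `r_min`.
#' @param impute imputation mode passed to [shrink_correlation()] in
#'   partial mode.
#' @inheritParams run_targeted_mwas
#' @return object of class `assoc_network`: list with `nodes` (data frame
#'   `id`, `feature_index`, `mz`, `rt`, `is_seed`, `depth`), `edges` (data
#'   frame `from`, `to`, `r`, `q`, `depth`), `method`, `corr`, `r_min`,
#'   `q_max`.
#' @export
build_association_network <- function(table, seeds, r_min = 0.3, q_max = 0.05,
                                      depth_max = 2, method = c("full", "partial"),
                                      corr = c("spearman", "pearson"),
                                      q_adjust = c("wave", "pooled"),
                                      ppm_tol = 10, rt_tol = 30,
                                      log_transform = TRUE, min_pairs = 10,
                                      node_cap = 500,
                                      impute = c("complete", "halfmin")) {
  stopifnot(inherits(table, "feature_table"))
  method <- match.arg(method); corr <- match.arg(corr)
  q_adjust <- match.arg(q_adjust)
  seeds <- as_query_df(seeds)
  if (!is.numeric(r_min) || r_min < 0 || r_min >= 1)
    stop("r_min must lie in [0, 1)", call. = FALSE)
  if (!is.numeric(q_max) || q_max <= 0 || q_max > 1)
    stop("q_max must lie in (0, 1]", call. = FALSE)
  if (!depth_max %in% c(1L, 2L)) stop("depth_max must be 1 or 2", call. = FALSE)

  ## resolve seeds
  seed_idx <- integer(nrow(seeds))
  for (k in seq_len(nrow(seeds))) {
    m <- match_features(table, seeds[k, , drop = FALSE],
                        ppm_tol = ppm_tol, rt_tol = rt_tol)
    if (nrow(m) == 0L)
      stop("seed ", k, " (m/z ", format(seeds$mz[k]),
           ") matches no table feature", call. = FALSE)
    seed_idx[k] <- m$feature_index[1L]
  }
  seed_idx <- unique(seed_idx)

  L <- t(table$intensities)
  if (log_transform && corr == "pearson") L <- log10_intensity(L)

  depth <- rep(NA_integer_, n_features(table))
  depth[seed_idx] <- 0L
  all_tests <- list()

  run_wave <- function(frontier, wave) {
    recruited <- which(!is.na(depth))
    tests <- list()
    for (s in frontier) {
      cand <- setdiff(seq_len(n_features(table)), c(s, if (wave == 1L) integer() else recruited))
      if (wave == 1L) cand <- setdiff(cand, frontier[frontier < s])  # dedupe seed-seed pairs
      if (length(cand) == 0L) next
      sc <- scan_profile(L[, s], L[, cand, drop = FALSE], corr, min_pairs)
      p <- correlation_pvalue(sc$r, sc$n_used, corr)
      tests[[length(tests) + 1L]] <- data.frame(
        u = s, v = cand, r = sc$r, p = p, depth = wave)
    }
    if (length(tests) == 0L) return(NULL)
    do.call(rbind, tests)
  }

  accept <- function(tests) {
    ok <- !is.na(tests$r) & !is.na(tests$q) &
      abs(tests$r) > r_min & tests$q < q_max
    tests[ok, , drop = FALSE]
  }

  wave1 <- run_wave(seed_idx, 1L)
  if (q_adjust == "wave" && !is.null(wave1)) wave1$q <- bh_adjust(wave1$p)
  edges <- NULL
  if (q_adjust == "wave" && !is.null(wave1)) {
    edges <- accept(wave1)
    new1 <- setdiff(unique(c(edges$u, edges$v)), seed_idx)
    depth[new1] <- 1L
    check_node_cap(sum(!is.na(depth)), node_cap)
    if (depth_max == 2L && length(new1) > 0L) {
      wave2 <- run_wave(new1, 2L)
      if (!is.null(wave2)) {
        wave2$q <- bh_adjust(wave2$p)
        e2 <- accept(wave2)
        new2 <- setdiff(unique(e2$v), which(!is.na(depth)))
        depth[new2] <- 2L
        check_node_cap(sum(!is.na(depth)), node_cap)
        edges <- rbind(edges, e2)
      }
    }
  } else if (!is.null(wave1)) {
    ## pooled adjustment: expand provisionally on p < q_max (superset), then
    ## adjust once over every test performed and re-filter
    wave1$q <- NA_real_
    prov <- wave1[!is.na(wave1$r) & abs(wave1$r) > r_min & wave1$p < q_max, ]
    new1 <- setdiff(unique(c(prov$u, prov$v)), seed_idx)
    depth[new1] <- 1L
    check_node_cap(sum(!is.na(depth)), node_cap)
    all <- wave1
    if (depth_max == 2L && length(new1) > 0L) {
      wave2 <- run_wave(new1, 2L)
      if (!is.null(wave2)) { wave2$q <- NA_real_; all <- rbind(all, wave2) }
    }
    all$q <- bh_adjust(all$p)
    edges <- accept(all)
    keep_nodes <- unique(c(seed_idx, edges$u, edges$v))
    depth[setdiff(which(!is.na(depth)), keep_nodes)] <- NA_integer_
    d2 <- setdiff(unique(edges$v[edges$depth == 2L]), which(depth %in% c(0L, 1L)))
    depth[d2] <- 2L
  }
  if (is.null(edges)) edges <- data.frame(u = integer(), v = integer(),
                                          r = numeric(), p = numeric(),
                                          q = numeric(), depth = integer())

  node_idx <- which(!is.na(depth))
  nodes <- data.frame(
    id = table$feature_ids[node_idx], feature_index = node_idx,
    mz = table$mz[node_idx], rt = table$rt[node_idx],
    is_seed = node_idx %in% seed_idx, depth = depth[node_idx],
    stringsAsFactors = FALSE
  )

  net <- new_assoc_network(nodes, edge_df(table, edges), method = method,
                           corr = corr, r_min = r_min, q_max = q_max)

  if (method == "partial" && nrow(nodes) >= 2L) {
    sh <- shrink_correlation(table, nodes$feature_index, method = corr,
                             log_transform = log_transform,
                             impute = match.arg(impute))
    P <- cor_to_pcor(sh, pseudoinverse = TRUE)
    k <- nrow(nodes)
    ut <- which(upper.tri(P$mat), arr.ind = TRUE)
    r <- P$mat[ut]
    p <- correlation_pvalue(pmin(1, pmax(-1, r)), rep(P$n, length(r)), corr)
    q <- bh_adjust(p)
    ok <- abs(r) > r_min & !is.na(q) & q < q_max
    edges <- data.frame(
      u = nodes$feature_index[ut[ok, 1L]], v = nodes$feature_index[ut[ok, 2L]],
      r = r[ok], p = p[ok], q = q[ok],
      depth = pmin(nodes$depth[ut[ok, 1L]], nodes$depth[ut[ok, 2L]]) + 1L
    )
    net <- new_assoc_network(nodes, edge_df(table, edges), method = "partial",
                             corr = corr, r_min = r_min, q_max = q_max,
                             lambda = sh$lambda)
  }
  net
}

check_node_cap <- function(n, cap) {
  if (n > cap)
    stop("network recruited ", n, " nodes, exceeding the cap of ", cap,
         "; use a stricter r_min/q_max or raise node_cap", call. = FALSE)
}

edge_df <- function(table, edges) {
  if (nrow(edges) == 0L)
    return(data.frame(from = character(), to = character(), r = numeric(),
                      q = numeric(), depth = integer(), stringsAsFactors = FALSE))
  data.frame(from = table$feature_ids[edges$u], to = table$feature_ids[edges$v],
             r = edges$r, q = edges$q, depth = edges$depth,
             stringsAsFactors = FALSE)
}

new_assoc_network <- function(nodes, edges, method, corr, r_min, q_max,
                              lambda = NULL) {
  if (anyDuplicated(nodes$id)) stop("duplicate node ids", call. = FALSE)
  if (nrow(edges) > 0L) {
    if (any(edges$from == edges$to)) stop("self-loop edge", call. = FALSE)
    key <- paste(pmin(edges$from, edges$to), pmax(edges$from, edges$to))
    if (anyDuplicated(key)) {
      keep <- !duplicated(key)
      edges <- edges[keep, , drop = FALSE]
    }
    bad <- !(edges$from %in% nodes$id) | !(edges$to %in% nodes$id)
    if (any(bad)) stop("edge endpoint not among nodes", call. = FALSE)
  }
  structure(list(nodes = nodes, edges = edges, method = method, corr = corr,
                 r_min = r_min, q_max = q_max, lambda = lambda),
            class = "assoc_network")
}

#' @export
print.assoc_network <- function(x, ...) {
  cat("Association network (", x$method, " ", x$corr, "): ",
      nrow(x$nodes), " nodes, ", nrow(x$edges), " edges ",
      "(|r| > ", format(x$r_min), ", q < ", format(x$q_max), ")\n", sep = "")
  cat("  depths: ", sum(x$nodes$depth == 0), " seed / ",
      sum(x$nodes$depth == 1), " primary / ",
      sum(x$nodes$depth == 2), " secondary; ",
      sum(x$edges$r > 0), " positive, ", sum(x$edges$r < 0),
      " negative edges\n", sep = "")
  invisible(x)
}

#' @export
summary.assoc_network <- function(object, ...) {
  data.frame(
    nodes = nrow(object$nodes), edges = nrow(object$edges),
    seeds = sum(object$nodes$is_seed),
    primary = sum(object$nodes$depth == 1),
    secondary = sum(object$nodes$depth == 2),
    positive_edges = sum(object$edges$r > 0),
    negative_edges = sum(object$edges$r < 0),
    r_min = object$r_min, q_max = object$q_max, method = object$method
  )
}

#' Association networks at graded stringency
#'
#' One breadth-first expansion is run at the loosest threshold and the
#' stricter networks are carved out of it by edge filtering (`|r| >`
#' threshold), keeping the seeds plus every node incident to a surviving
#' edge. The edge sets are therefore nested by construction: raising the
#' stringency only removes edges, which is the intended reading of a
#' stringency sweep — one dataset examined at increasing confidence, where
#' secondary clusters may detach from the seed as their link to it drops
#' below threshold.
#'
#' @inheritParams build_association_network
#' @param thresholds strictly increasing vector of `r_min` values (default
#'   `c(0.3, 0.5, 0.7)`).
#' @param ... further arguments to [build_association_network()].
#' @return named list of `assoc_network` objects, one per threshold.
#' @export
stringency_sweep <- function(table, seeds, thresholds = c(0.3, 0.5, 0.7),
                             q_max = 0.05, ...) {
  if (length(thresholds) == 0L) stop("thresholds must be non-empty", call. = FALSE)
  if (is.unsorted(thresholds, strictly = TRUE))
    stop("thresholds must be strictly increasing", call. = FALSE)
  base <- build_association_network(table, seeds, r_min = thresholds[1],
                                    q_max = q_max, ...)
  out <- stats::setNames(vector("list", length(thresholds)),
                         sprintf("r_%g", thresholds))
  out[[1L]] <- base
  for (k in seq_along(thresholds)[-1L])
    out[[k]] <- filter_network(base, thresholds[k])
  out
}

## restrict a network to edges with |r| > r_min; keep seeds and incident nodes
filter_network <- function(network, r_min) {
  stopifnot(inherits(network, "assoc_network"))
  edges <- network$edges[abs(network$edges$r) > r_min, , drop = FALSE]
  keep <- network$nodes$is_seed | network$nodes$id %in% c(edges$from, edges$to)
  new_assoc_network(network$nodes[keep, , drop = FALSE], edges,
                    method = network$method, corr = network$corr,
                    r_min = r_min, q_max = network$q_max,
                    lambda = network$lambda)
}

#' Cross-study correlation-pattern similarity
#'
#' Given correlation matrices of the same matched feature set measured in
#' two studies, tests per feature whether its correlation profile (its
#' off-diagonal row) is reproduced: the two rows are Pearson-correlated
#' over the k - 1 shared partners and the feature is selected when the
#' coefficient is positive and its two-sided p-value is below `alpha`.
#'
#' @param corrA,corrB `corr_matrix` objects (or plain matrices) over the
#'   same feature set, in the same order (k >= 3 features).
#' @param alpha significance level (default 0.05).
#' @return data frame with `id`, `similarity_r`, `p` and `selected`; the
#'   selected ids are the features with conserved correlation patterns.
#' @export
pattern_similarity <- function(corrA, corrB, alpha = 0.05) {
  A <- if (inherits(corrA, "corr_matrix")) corrA$mat else as.matrix(corrA)
  B <- if (inherits(corrB, "corr_matrix")) corrB$mat else as.matrix(corrB)
  idsA <- if (inherits(corrA, "corr_matrix")) corrA$ids else as.character(seq_len(nrow(A)))
  idsB <- if (inherits(corrB, "corr_matrix")) corrB$ids else idsA
  if (nrow(A) != nrow(B) || !identical(idsA, idsB))
    stop("the two matrices must be indexed by the same matched feature set",
         call. = FALSE)
  k <- nrow(A)
  if (k < 3L) stop("pattern similarity needs >= 3 matched features", call. = FALSE)
  r <- p <- numeric(k)
  for (f in seq_len(k)) {
    a <- A[f, -f]; b <- B[f, -f]
    if (stats::sd(a) == 0 || stats::sd(b) == 0) { r[f] <- NA; p[f] <- NA; next }
    ct <- stats::cor.test(a, b, method = "pearson")
    r[f] <- unname(ct$estimate); p[f] <- ct$p.value
  }
  data.frame(id = idsA, similarity_r = r, p = p,
             selected = !is.na(p) & p < alpha & r > 0,
             stringsAsFactors = FALSE)
}
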