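#' Simulation configuration for synthetic feature tables
#'
#' Describes a synthetic LC/MS feature table with planted correlation
#' structure: one anchor feature (the future MWAS target), optional modules
#' of features correlated with the anchor, optional companion ions
#' (adduct/isotope copies of a parent with nearly identical intensity
#' profiles), and independent null features. Correlations are realized on
#' the log10-intensity scale, matching the default transform of the scan.
#'
#' Each module is a list with elements `size`, `r_anchor` (true log-scale
#' correlation of every member with the module's parent feature, in
#' (-1, 1)), optional `r_within` (pairwise correlation among members;
#' default `r_anchor^2`, i.e. members associate only through the parent),
#' optional `parent` (feature index the module hangs off; default 1, the
#' anchor — pointing it at a member of an earlier module plants a
#' *secondary* cluster reachable only through that member), optional
#' `parent_link` (`"direct"`, the default, correlates members with the
#' parent itself; `"residual"` correlates them with the component of the
#' parent orthogonal to the anchor, making the secondary cluster exactly
#' uncorrelated with the anchor), optional
#' `rt_range` (seconds; e.g. `c(360, 480)` for a lipid-like late-eluting
#' cluster) and optional `mz`/`rt` vectors fixing member coordinates
#' exactly.
#'
#' Each companion is a list with elements `parent` (`"anchor"` or a feature
#' index), `shift` (`"13C"` or an adduct name, applied to the parent m/z),
#' `scale` (intensity ratio to the parent, default 0.05) and `noise_frac`
#' (noise s.d. as a fraction of the scaled parent s.d., default 0.05 —
#' giving a parent-companion correlation near 0.99, as observed for
#' 12C/13C ion pairs).
#'
#' @param n_samples number of samples (default 50, a typical cohort size
#'   for this design).
#' @param n_null number of features independent of everything else.
#' @param modules list of module descriptions (see Details).
#' @param companions list of companion-ion descriptions (see Details).
#' @param missing_rate fraction of intensity cells set missing completely
#'   at random, in `[0, 1)`.
#' @param log_mean,log_sd mean and s.d. of per-feature log10 intensity
#'   (feature baselines are drawn around `log_mean`).
#' @param anchor_mz,anchor_rt coordinates of the anchor feature.
#' @param mz_range,rt_range ranges from which unspecified feature
#'   coordinates are drawn uniformly.
#' @return object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_samples = 50, n_null = 1000, modules = list(),
                       companions = list(), missing_rate = 0,
                       log_mean = 5, log_sd = 1,
                       anchor_mz = 104.1062, anchor_rt = 51,
                       mz_range = c(85, 1000), rt_range = c(10, 600)) {
  stopifnot(n_samples >= 3, n_null >= 0,
            missing_rate >= 0, missing_rate < 1, log_sd > 0)
  modules <- lapply(seq_along(modules), function(i) {
    m <- modules[[i]]
    if (is.null(m$size) || m$size < 1) stop("module ", i, ": size must be >= 1", call. = FALSE)
    if (is.null(m$r_anchor) || abs(m$r_anchor) >= 1)
      stop("module ", i, ": r_anchor must lie in (-1, 1)", call. = FALSE)
    if (is.null(m$r_within)) m$r_within <- m$r_anchor^2
    if (abs(m$r_within) >= 1) stop("module ", i, ": r_within must lie in (-1, 1)", call. = FALSE)
    if (is.null(m$parent)) m$parent <- 1L
    if (is.null(m$parent_link)) m$parent_link <- "direct"
    if (!m$parent_link %in% c("direct", "residual"))
      stop("module ", i, ": parent_link must be 'direct' or 'residual'", call. = FALSE)
    if (is.null(m$rt_range)) m$rt_range <- c(360, 480)
    m
  })
  companions <- lapply(companions, function(cp) {
    if (is.null(cp$parent)) cp$parent <- "anchor"
    if (is.null(cp$shift)) cp$shift <- "13C"
    if (is.null(cp$scale)) cp$scale <- 0.05
    if (is.null(cp$noise_frac)) cp$noise_frac <- 0.05
    cp
  })
  structure(list(n_samples = n_samples, n_null = n_null, modules = modules,
                 companions = companions, missing_rate = missing_rate,
                 log_mean = log_mean, log_sd = log_sd,
                 anchor_mz = anchor_mz, anchor_rt = anchor_rt,
                 mz_range = mz_range, rt_range = rt_range),
            class = "sim_config")
}

## draw masses uniformly, rejecting any within `ppm` of a protected mass
draw_mz <- function(n, range, protected, ppm = 20) {
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      m <- stats::runif(1, range[1], range[2])
      if (!length(protected) || all(abs(1e6 * (m - protected) / protected) > ppm)) break
    }
    out[i] <- m
  }
  out
}

#' Simulate a feature table with known ground truth
#'
#' Log10 intensities are drawn from a multivariate normal realizing the
#' configured correlation structure: each module forms a block with the
#' anchor whose Cholesky factor is applied to independent standard normals
#' (reusing the anchor's innovations so every block shares the same anchor
#' realization); null features are independent draws. Log intensities are
#' exponentiated to the intensity scale, companion ions are added as
#' scaled-plus-noise copies of their parent with the exact adduct/isotope
#' mass shift, and missing values are inserted completely at random.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the same seed reproduces the table exactly.
#' @return list with `table` (a [feature_table()]) and `truth`, the
#'   ground-truth ledger: one row per feature with `feature_index`,
#'   `feature_id`, `role` (`"anchor"`, `"module"`, `"companion"`,
#'   `"null"`), `module` (id or `NA`), `true_r` (planted log-scale
#'   correlation with the anchor; `NA` for companions of non-anchor
#'   parents) and `parent` (feature index for companions). The ledger is
#'   sufficient to score precision/recall of any discovery run.
#' @export
simulate_feature_table <- function(config, seed = 1L) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(as.integer(seed))
  n <- config$n_samples

  ## feature 1 is the anchor; module blocks are appended in order, each
  ## generated from the Cholesky factor of its (parent + members) block
  ## with the parent's existing scores as the first innovation column, so
  ## every member has exactly the requested correlation with its parent.
  Z <- matrix(stats::rnorm(n), n, 1L)
  role <- "anchor"; module <- NA_integer_; true_r <- 1
  mz <- config$anchor_mz; rt <- config$anchor_rt

  for (i in seq_along(config$modules)) {
    m <- config$modules[[i]]
    sz <- m$size
    if (m$parent > ncol(Z))
      stop("module ", i, ": parent must be an earlier feature", call. = FALSE)
    B <- matrix(m$r_within, sz + 1L, sz + 1L)
    B[1L, ] <- B[, 1L] <- m$r_anchor
    diag(B) <- 1
    U <- tryCatch(chol(B), error = function(e)
      stop("module ", i, ": requested correlation block is not positive definite",
           call. = FALSE))
    parent_scores <- Z[, m$parent]
    if (m$parent_link == "residual") {
      rp <- true_r[m$parent]
      if (abs(rp) >= 1)
        stop("module ", i, ": residual link needs a parent with |true_r| < 1",
             call. = FALSE)
      parent_scores <- (parent_scores - rp * Z[, 1L]) / sqrt(1 - rp^2)
    }
    Zi <- cbind(parent_scores, matrix(stats::rnorm(n * sz), n, sz))
    X <- Zi %*% U                    # first column equals the parent (U[1,1] = 1)
    Z <- cbind(Z, X[, -1L, drop = FALSE])
    role <- c(role, rep("module", sz))
    module <- c(module, rep(i, sz))
    true_r <- c(true_r, rep(
      if (m$parent_link == "residual") 0 else m$r_anchor * true_r[m$parent], sz))
    mz <- c(mz, if (!is.null(m[["mz"]])) m[["mz"]] else rep(NA_real_, sz))
    rt <- c(rt, if (!is.null(m[["rt"]])) m[["rt"]]
                else stats::runif(sz, m$rt_range[1], m$rt_range[2]))
  }
  if (config$n_null > 0L) {
    Z <- cbind(Z, matrix(stats::rnorm(n * config$n_null), n, config$n_null))
    role <- c(role, rep("null", config$n_null))
    module <- c(module, rep(NA_integer_, config$n_null))
    true_r <- c(true_r, rep(0, config$n_null))
    mz <- c(mz, rep(NA_real_, config$n_null))
    rt <- c(rt, stats::runif(config$n_null, config$rt_range[1], config$rt_range[2]))
  }
  p <- ncol(Z)

  ## masses for unspecified features avoid the anchor's ion family so that
  ## self-exclusion removes only what was planted
  protected <- self_exclusion_masses(config$anchor_mz)
  need <- is.na(mz)
  mz[need] <- draw_mz(sum(need), config$mz_range, protected)

  baseline <- stats::rnorm(p, config$log_mean, 0.5)
  logI <- sweep(Z * config$log_sd, 2L, baseline, "+")
  intens <- t(10^logI)               # features x samples

  parent <- rep(NA_integer_, p)
  for (cp in config$companions) {
    pi <- if (identical(cp$parent, "anchor")) 1L else as.integer(cp$parent)
    par_int <- intens[pi, ]
    scaled <- par_int * cp$scale
    ## noise proportional to the signal (ESI ion counts are roughly
    ## multiplicative-noise limited); keeps the pair tightly correlated on
    ## both the raw and the log scale
    eps <- pmax(pmin(stats::rnorm(n), 3), -3)
    comp <- scaled * (1 + cp$noise_frac * eps)
    cmz <- if (identical(cp$shift, "13C")) isotope_transform(mz[pi])
           else adduct_transform(mz[pi], "[M+H]+", cp$shift)
    intens <- rbind(intens, comp)
    mz <- c(mz, cmz); rt <- c(rt, rt[pi] + stats::runif(1, -2, 2))
    role <- c(role, "companion"); module <- c(module, NA_integer_)
    true_r <- c(true_r, if (pi == 1L) 1 else NA_real_)
    parent <- c(parent, pi)
  }
  p <- nrow(intens)

  if (config$missing_rate > 0) {
    drop <- stats::runif(length(intens)) < config$missing_rate
    intens[drop] <- NA_real_
  }

  tab <- feature_table(mz, rt, intens,
                       sample_ids = sprintf("S%02d", seq_len(n)))
  truth <- data.frame(
    feature_index = seq_len(p), feature_id = tab$feature_ids,
    role = role, module = module, true_r = true_r, parent = parent,
    stringsAsFactors = FALSE
  )
  list(table = tab, truth = truth)
}

#' Ready-made choline-like case-study fixture
#'
#' A synthetic table emulating the qualitative structure of a plasma
#' choline targeted MWAS: an anchor ion at m/z 104.1062 eluting at 51 s
#' with a 13C companion ion, a late-eluting (rt > 350 s)
#' phosphocholine-like module of eight features correlated with the anchor
#' at r = 0.6 (coordinates borrowed from known choline-pathway adduct
#' masses), and independent null features across the full rt range. A
#' targeted scan against the anchor should flag the module, the companion
#' should carry the highest correlation when self-exclusion is off, and
#' self-exclusion should remove exactly the anchor and its companion.
#'
#' @param seed integer seed.
#' @param n_null number of null features (default 200).
#' @param n_samples number of samples (default 50).
#' @param missing_rate missing-value rate (default 0.02).
#' @return list with `table`, `target` (one-row query data frame for the
#'   anchor) and `truth` (see [simulate_feature_table()]).
#' @export
choline_casestudy_fixture <- function(seed = 1L, n_null = 200, n_samples = 50,
                                      missing_rate = 0.02) {
  lipid_mz <- c(184.0719, 258.1083, 494.3207, 476.3099,
                516.3030, 517.3063, 496.3376, 522.3532)
  lipid_rt <- c(417, 426, 378, 380, 379, 377, 442, 460)
  cfg <- sim_config(
    n_samples = n_samples, n_null = n_null,
    modules = list(list(size = length(lipid_mz), r_anchor = 0.6,
                        r_within = 0.5, mz = lipid_mz, rt = lipid_rt)),
    companions = list(list(parent = "anchor", shift = "13C",
                           scale = 0.04, noise_frac = 0.05)),
    missing_rate = missing_rate,
    anchor_mz = 104.1062, anchor_rt = 51
  )
  sim <- simulate_feature_table(cfg, seed = seed)
  list(table = sim$table,
       target = data.frame(mz = 104.1062, rt = 51, name = "choline",
                           stringsAsFactors = FALSE),
       truth = sim$truth)
}

#' Operating characteristics of the targeted scan by simulation
#'
#' Repeatedly simulates a feature table (independent nulls plus one module
#' correlated with the anchor), runs the full targeted MWAS pipeline
#' against the anchor, and scores each replicate against the ground-truth
#' ledger: false-discovery proportion, sensitivity for module features, and
#' the mean estimated correlation of module features.
#'
#' @param n_rep number of replicates.
#' @param seed integer master seed (per-replicate seeds are derived from
#'   it).
#' @param n_samples,n_null samples and null features per table.
#' @param module_size,r size and true anchor correlation of the planted
#'   module.
#' @param alpha BH level of the scan.
#' @param missing_rate missing-value rate of the tables.
#' @return data frame with one row per replicate: `fdp`, `sensitivity`,
#'   `mean_r`, `n_discoveries`.
#' @export
mwas_fdr_power_sim <- function(n_rep, seed = 1L, n_samples = 50,
                               n_null = 1000, module_size = 50, r = 0.6,
                               alpha = 0.05, missing_rate = 0) {
  set.seed(as.integer(seed))
  rep_seeds <- sample.int(.Machine$integer.max - 1L, n_rep)
  cfg <- sim_config(
    n_samples = n_samples, n_null = n_null,
    modules = if (module_size > 0)
      list(list(size = module_size, r_anchor = r)) else list(),
    missing_rate = missing_rate
  )
  target <- data.frame(mz = cfg$anchor_mz, rt = cfg$anchor_rt, name = "anchor")
  out <- data.frame(fdp = numeric(n_rep), sensitivity = numeric(n_rep),
                    mean_r = numeric(n_rep), n_discoveries = integer(n_rep))
  for (b in seq_len(n_rep)) {
    sim <- simulate_feature_table(cfg, seed = rep_seeds[b])
    fit <- run_targeted_mwas(sim$table, target, method = "pearson",
                             alpha = alpha)
    res <- fit$results[[1L]]
    roles <- sim$truth$role[res$feature_index]
    disc <- res$significant
    nd <- sum(disc)
    out$n_discoveries[b] <- nd
    out$fdp[b] <- if (nd == 0) 0 else sum(disc & roles == "null") / nd
    mod <- roles == "module"
    out$sensitivity[b] <- if (any(mod)) sum(disc & mod) / sum(mod) else NA_real_
    out$mean_r[b] <- if (any(mod)) mean(res$r[mod], na.rm = TRUE) else NA_real_
  }
  out
}
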