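# The targeted scan: profile correlation, p-values, BH adjustment and the
# full run_targeted_mwas fit.

test_that("correlate_profile handles identity, sign and missingness", {
  x <- 10^rnorm(30, 5, 1)
  expect_equal(correlate_profile(x, x)$r, 1)
  # anti-correlation on the raw scale (log transform disabled; -x would be
  # negative so use a decreasing linear profile)
  a <- seq_len(30); b <- 30 - a + 1
  expect_equal(correlate_profile(a, b, log_transform = FALSE)$r, -1)
  # pairwise-complete removal and the min_pairs guard
  y <- x; y[1:25] <- NA
  out <- correlate_profile(x, y)
  expect_true(is.na(out$r))
  expect_equal(out$n_used, 5L)
  out2 <- correlate_profile(x, y, min_pairs = 3)
  expect_false(is.na(out2$r))
  # zeros become missing under the log transform
  z <- x; z[3] <- 0
  expect_equal(correlate_profile(x, z)$n_used, 29L)
})

test_that("sample correlation of a planted pair falls in its Fisher interval", {
  rho <- 0.7; n <- 50
  set.seed(101)
  z <- rnorm(n)
  x <- 10^(5 + z)
  y <- 10^(5 + rho * z + sqrt(1 - rho^2) * rnorm(n))
  r <- correlate_profile(x, y)$r
  ci <- tanh(atanh(rho) + c(-1, 1) * qnorm(0.975) / sqrt(n - 3))
  expect_gt(r, ci[1]); expect_lt(r, ci[2])
})

test_that("correlation p-values match the t transform and its oracle", {
  # numerical-integration oracle for the two-sided t tail
  t_tail_p <- function(r, n) {
    tt <- abs(r) * sqrt(n - 2) / sqrt(1 - r^2)
    df <- n - 2
    dens <- function(u) gamma((df + 1) / 2) / (sqrt(df * pi) * gamma(df / 2)) *
      (1 + u^2 / df)^(-(df + 1) / 2)
    2 * stats::integrate(dens, tt, Inf, rel.tol = 1e-12)$value
  }
  # the two printed cross-platform choline correlations at n = 50 both sit
  # below the 1e-7 raw-p bound
  p72 <- correlation_pvalue(0.72, 50)
  p68 <- correlation_pvalue(0.68, 50)
  expect_equal(p72, t_tail_p(0.72, 50), tolerance = 1e-6)
  expect_equal(p68, t_tail_p(0.68, 50), tolerance = 1e-6)
  expect_equal(p72, 3.0e-9, tolerance = 0.05)
  expect_equal(p68, 5.9e-8, tolerance = 0.05)
  expect_lt(p72, 1e-7)
  expect_lt(p68, 1e-7)

  expect_equal(correlation_pvalue(0, 20), 1)
  expect_equal(correlation_pvalue(1, 20), 0)
  expect_true(is.na(correlation_pvalue(0.5, 2)))

  # agreement with cor.test across a grid
  set.seed(6)
  for (i in 1:15) {
    n <- sample(5:60, 1)
    x <- rnorm(n); y <- rnorm(n)
    r <- cor(x, y)
    expect_equal(correlation_pvalue(r, n),
                 cor.test(x, y)$p.value, tolerance = 1e-10)
  }
})

test_that("bh_adjust matches the brute-force step-up oracle", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(rep(0.02, 7)), rep(0.02, 7))
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  set.seed(7)
  for (i in 1:20) {
    p <- runif(sample(1:200, 1))^sample(1:3, 1)
    expect_equal(bh_adjust(p), bh_oracle(p), tolerance = 1e-12)
  }
  # NA entries are excluded from m and stay NA
  p <- c(0.01, NA, 0.04)
  q <- bh_adjust(p)
  expect_true(is.na(q[2]))
  expect_equal(q[c(1, 3)], bh_oracle(p[c(1, 3)]))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("q-values are monotone in p and bounded below by p", {
  set.seed(8)
  p <- runif(500)^2
  q <- bh_adjust(p)
  expect_true(all(q >= p - 1e-12))
  o <- order(p)
  expect_true(all(diff(q[o]) >= -1e-12))
})

test_that("targeted scan excludes the target's own ion family", {
  fix <- choline_casestudy_fixture(seed = 11, n_null = 150)
  fit <- run_targeted_mwas(fix$table, fix$target)
  planted <- fix$truth$feature_id[fix$truth$role %in% c("anchor", "companion")]
  expect_setequal(fit$excluded[[1]], planted)
  expect_false(any(planted %in% fit$results[[1]]$feature_id))
  # record count: scanned = features - self-exclusions
  expect_equal(nrow(fit$results[[1]]),
               n_features(fix$table) - length(planted))
  expect_equal(anyDuplicated(fit$results[[1]]$feature_id), 0L)
  # with exclusion off the 13C companion carries the highest correlation
  fit2 <- run_targeted_mwas(fix$table, fix$target, exclude_self = FALSE)
  res2 <- fit2$results[[1]]
  comp_id <- fix$truth$feature_id[fix$truth$role == "companion"]
  expect_equal(res2$feature_id[which.max(res2$r)], comp_id)
  expect_gt(max(res2$r, na.rm = TRUE), 0.95)
})

test_that("planted module features rank above nulls and alpha = 0 kills discoveries", {
  cfg <- sim_config(n_samples = 50, n_null = 1000,
                    modules = list(list(size = 50, r_anchor = 0.6)))
  sim <- simulate_feature_table(cfg, seed = 21)
  target <- data.frame(mz = cfg$anchor_mz, rt = cfg$anchor_rt, name = "anchor")
  fit <- run_targeted_mwas(sim$table, target)
  res <- fit$results[[1]]
  roles <- sim$truth$role[res$feature_index]
  # module features dominate the |r| ranking: at most a vanishing number of
  # nulls above the weakest module member's rank
  top <- order(-abs(res$r))[1:sum(roles == "module")]
  expect_gte(mean(roles[top] == "module"), 0.9)
  fit0 <- run_targeted_mwas(sim$table, target, alpha = 0)
  expect_equal(sum(fit0$results[[1]]$significant), 0L)
})

test_that("significance set is invariant under feature permutation", {
  fix <- choline_casestudy_fixture(seed = 13, n_null = 100)
  fit <- run_targeted_mwas(fix$table, fix$target)
  set.seed(14)
  perm <- sample(n_features(fix$table))
  tabp <- fix$table[perm, ]
  fitp <- run_targeted_mwas(tabp, fix$target)
  expect_setequal(fit$results[[1]]$feature_id[fit$results[[1]]$significant],
                  fitp$results[[1]]$feature_id[fitp$results[[1]]$significant])
})

test_that("external assay profiles act as virtual features", {
  fix <- choline_casestudy_fixture(seed = 15, n_null = 80)
  anchor_int <- fix$table$intensities[1, ]
  assay <- anchor_int * exp(rnorm(length(anchor_int), 0, 0.05))
  # external vector, target absent from the table: drop the anchor feature
  tab2 <- fix$table[-1, ]
  fit <- run_targeted_mwas(tab2, data.frame(mz = 104.1062, rt = 51, name = "assay"),
                           target_vectors = list(assay = assay))
  res <- fit$results[[1]]
  comp <- grep("^105\\.109", res$feature_id)
  expect_equal(length(comp), 0L)  # companion excluded as a 13C self-form
  expect_gt(sum(res$significant), 0)
  # without any resolvable profile the target errors by name
  expect_error(run_targeted_mwas(tab2, data.frame(mz = 999.9, rt = 51, name = "ghost")),
               "ghost")
})

test_that("restricting to a significant-feature list narrows the scan", {
  fix <- choline_casestudy_fixture(seed = 16, n_null = 120)
  module_mz <- fix$truth$feature_id[fix$truth$role == "module"]
  sig <- data.frame(mz = fix$table$mz[fix$truth$role == "module"])
  fit <- run_targeted_mwas(fix$table, fix$target, sig_features = sig)
  expect_setequal(fit$results[[1]]$feature_id, module_mz)
})

test_that("Pearson on ranks equals Spearman when there are no ties", {
  set.seed(17)
  L <- matrix(rnorm(40 * 6, 5, 1), 40, 6)
  tab <- table_from_log_matrix(L)
  rank_tab <- feature_table(tab$mz, tab$rt,
                            t(apply(tab$intensities, 1, rank)),
                            tab$sample_ids)
  target <- data.frame(mz = tab$mz[1], name = "t")
  f_sp <- run_targeted_mwas(tab, target, method = "spearman", exclude_self = FALSE)
  f_pr <- run_targeted_mwas(rank_tab, target, method = "pearson",
                            log_transform = FALSE, exclude_self = FALSE)
  expect_equal(f_sp$results[[1]]$r, f_pr$results[[1]]$r, tolerance = 1e-12)
})
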