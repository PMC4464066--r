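# Correlation matrices, shrinkage, partial correlations, seeded network
# construction, the stringency sweep and cross-study pattern similarity.

test_that("sample_correlation_matrix is symmetric with unit diagonal", {
  set.seed(31)
  L <- matrix(rnorm(60 * 5, 5, 1), 60, 5)
  L[, 3] <- L[, 2]                      # duplicated feature
  tab <- table_from_log_matrix(L)
  R <- sample_correlation_matrix(tab, 1:5)
  expect_equal(R$mat, t(R$mat))
  expect_equal(diag(R$mat), rep(1, 5))
  expect_true(all(abs(R$mat) <= 1 + 1e-12))
  expect_equal(R$mat[2, 3], 1)
  expect_error(sample_correlation_matrix(tab, 1), ">= 2 features")
  # two independent noise features at n = 1000 correlate near zero
  set.seed(32)
  big <- table_from_log_matrix(matrix(rnorm(2000), 1000, 2))
  expect_lt(abs(sample_correlation_matrix(big)$mat[1, 2]), 0.1)
})

test_that("pairs with too few complete observations are an error", {
  set.seed(33)
  L <- matrix(rnorm(30 * 3, 5, 1), 30, 3)
  tab <- table_from_log_matrix(L)
  tab$intensities[2, 1:25] <- NA
  expect_error(sample_correlation_matrix(tab, min_pairs = 10), "complete observations")
})

test_that("shrinkage intensity behaves per the analytic formula", {
  # uncorrelated-by-construction orthogonal columns -> all off-diagonal
  # sample correlations exactly 0 -> lambda = 1 and identity output
  L <- cbind(rep(c(1, -1), 10), rep(c(1, 1, -1, -1), 5), rep(c(1, -1, -1, 1), 5))
  tab <- table_from_log_matrix(L + 5)
  sh0 <- shrink_correlation(tab)
  expect_equal(sh0$lambda, 1)
  expect_equal(sh0$mat, diag(3))

  # lambda always lands in [0, 1]
  set.seed(34)
  for (i in 1:10) {
    n <- sample(5:40, 1); p <- sample(3:8, 1)
    tabi <- table_from_log_matrix(matrix(rnorm(n * p, 5, 1), n, p))
    lam <- shrink_correlation(tabi)$lambda
    expect_gte(lam, 0); expect_lte(lam, 1)
  }

  # strong planted structure, large n: tiny lambda, shrunk ~ sample
  cfg <- sim_config(n_samples = 500, n_null = 0,
                    modules = list(list(size = 9, r_anchor = 0.7, r_within = 0.6)))
  sim <- simulate_feature_table(cfg, seed = 35)
  sh <- shrink_correlation(sim$table)
  sam <- sample_correlation_matrix(sim$table)
  expect_lt(sh$lambda, 0.1)
  expect_lt(max(abs(sh$mat - sam$mat)), 0.05)

  # lambda forced to 0 reproduces the sample matrix exactly
  sh0 <- shrink_correlation(sim$table, lambda = 0)
  expect_equal(sh0$mat, sam$mat, tolerance = 1e-12)
})

test_that("cor_to_pcor matches closed-form partial correlations", {
  # bivariate: partial equals marginal
  R2 <- matrix(c(1, 0.42, 0.42, 1), 2)
  expect_equal(cor_to_pcor(R2)$mat[1, 2], 0.42, tolerance = 1e-12)
  # worked 3x3 example: P12 = (0.6 - 0.25) / 0.75
  R3 <- matrix(c(1, 0.6, 0.5, 0.6, 1, 0.5, 0.5, 0.5, 1), 3)
  expect_equal(cor_to_pcor(R3)$mat[1, 2], (0.6 - 0.25) / 0.75, tolerance = 1e-10)
  # identity in, identity out
  expect_equal(cor_to_pcor(diag(4))$mat, diag(4))
  # randomized oracle: first-order recursive formula on random PD matrices
  set.seed(36)
  for (i in 1:200) {
    R <- random_pd_cor3()
    P <- cor_to_pcor(R)$mat
    expect_equal(P[1, 2], pcor_first_order(R[1, 2], R[1, 3], R[2, 3]),
                 tolerance = 1e-10)
    expect_equal(P[1, 3], pcor_first_order(R[1, 3], R[1, 2], R[3, 2]),
                 tolerance = 1e-10)
    expect_equal(P[2, 3], pcor_first_order(R[2, 3], R[2, 1], R[3, 1]),
                 tolerance = 1e-10)
  }
  # singular matrix errors unless the pseudoinverse fallback is enabled
  S <- matrix(1, 3, 3)
  expect_error(cor_to_pcor(S), "singular")
  expect_silent(cor_to_pcor(S, pseudoinverse = TRUE))
})

test_that("seeded expansion recovers planted primary and secondary modules", {
  # module 1 hangs off the anchor at r = 0.8; module 2 loads on the
  # anchor-orthogonal residual of a module-1 member (r = 0.9, i.e. ~0.54
  # with the member itself) and is exactly uncorrelated with the anchor
  cfg <- sim_config(
    n_samples = 150, n_null = 60,
    modules = list(
      list(size = 5, r_anchor = 0.8, rt_range = c(360, 400)),
      list(size = 5, r_anchor = 0.9, parent = 2L, parent_link = "residual",
           rt_range = c(450, 500))
    ))
  sim <- simulate_feature_table(cfg, seed = 41)
  seed <- data.frame(mz = cfg$anchor_mz, rt = cfg$anchor_rt)
  mod1 <- sim$truth$feature_id[sim$truth$module %in% 1]
  mod2 <- sim$truth$feature_id[sim$truth$module %in% 2]
  n1 <- build_association_network(sim$table, seed, r_min = 0.4, q_max = 0.05,
                                  depth_max = 1, corr = "pearson")
  n2 <- build_association_network(sim$table, seed, r_min = 0.4, q_max = 0.05,
                                  depth_max = 2, corr = "pearson")
  expect_true(all(mod1 %in% n1$nodes$id))
  expect_false(any(mod2 %in% n1$nodes$id))
  expect_true(all(mod1 %in% n2$nodes$id))
  expect_gte(sum(mod2 %in% n2$nodes$id), 4)
  expect_true(all(n2$nodes$depth[n2$nodes$id %in% mod2] == 2))
  # every edge satisfies the thresholds; edge depth = min(node depth) + 1
  dep <- setNames(n2$nodes$depth, n2$nodes$id)
  expect_true(all(abs(n2$edges$r) > 0.4))
  expect_true(all(n2$edges$q < 0.05))
  expect_equal(n2$edges$depth,
               pmin(dep[n2$edges$from], dep[n2$edges$to]) + 1L,
               ignore_attr = TRUE)
})

test_that("network construction validates its inputs", {
  fix <- choline_casestudy_fixture(seed = 42, n_null = 40)
  expect_error(build_association_network(fix$table, fix$target, depth_max = 3),
               "depth_max")
  expect_error(build_association_network(fix$table, fix$target, r_min = 1),
               "r_min")
  expect_error(build_association_network(fix$table, data.frame(mz = 999.123)),
               "matches no table feature")
  expect_error(build_association_network(fix$table, fix$target, r_min = 0,
                                         q_max = 1, node_cap = 5),
               "cap")
})

test_that("stringency sweep yields nested, shrinking networks", {
  fix <- choline_casestudy_fixture(seed = 43, n_null = 150)
  sw <- stringency_sweep(fix$table, fix$target, thresholds = c(0.3, 0.5, 0.7))
  expect_named(sw, c("r_0.3", "r_0.5", "r_0.7"))
  key <- function(net) paste(pmin(net$edges$from, net$edges$to),
                             pmax(net$edges$from, net$edges$to))
  e3 <- key(sw[[1]]); e5 <- key(sw[[2]]); e7 <- key(sw[[3]])
  expect_true(all(e5 %in% e3))
  expect_true(all(e7 %in% e5))
  expect_true(nrow(sw[[1]]$edges) > nrow(sw[[2]]$edges))
  expect_true(nrow(sw[[2]]$edges) > nrow(sw[[3]]$edges))
  # single threshold reduces to build_association_network
  sw1 <- stringency_sweep(fix$table, fix$target, thresholds = 0.3)
  direct <- build_association_network(fix$table, fix$target, r_min = 0.3)
  expect_equal(sw1[[1]]$edges, direct$edges)
  expect_error(stringency_sweep(fix$table, fix$target, thresholds = numeric()),
               "non-empty")
  expect_error(stringency_sweep(fix$table, fix$target, thresholds = c(0.5, 0.3)),
               "increasing")
})

test_that("partial mode conditions away indirect links", {
  # chain A -> B -> C: strong marginal A-C correlation but near-zero partial
  set.seed(44)
  n <- 300
  a <- rnorm(n); b <- 0.9 * a + sqrt(1 - 0.81) * rnorm(n)
  c_ <- 0.9 * b + sqrt(1 - 0.81) * rnorm(n)
  tab <- table_from_log_matrix(cbind(a, b, c_) + 5,
                               mz = c(104.1062, 200.1, 300.1),
                               rt = c(51, 100, 100))
  seed <- data.frame(mz = 104.1062, rt = 51)
  full <- build_association_network(tab, seed, r_min = 0.3, corr = "pearson")
  part <- build_association_network(tab, seed, r_min = 0.3, corr = "pearson",
                                    method = "partial")
  key <- function(net) paste(pmin(net$edges$from, net$edges$to),
                             pmax(net$edges$from, net$edges$to))
  ac <- paste(tab$feature_ids[1], tab$feature_ids[3])
  expect_true(ac %in% key(full))
  expect_false(ac %in% key(part))       # conditioned away through B
  expect_true(length(key(part)) >= 2)   # direct links survive
  expect_equal(part$method, "partial")
  expect_false(is.null(part$lambda))
})

test_that("pattern similarity selects conserved correlation profiles", {
  set.seed(45)
  k <- 12
  R <- random_pd_cor3()
  # identical non-degenerate matrices: everything selected
  cfg <- sim_config(n_samples = 60, n_null = 0,
                    modules = list(list(size = k - 1, r_anchor = 0.5,
                                        r_within = 0.4)))
  sim <- simulate_feature_table(cfg, seed = 46)
  A <- sample_correlation_matrix(sim$table)
  sel <- pattern_similarity(A, A)
  expect_true(all(sel$selected))
  # mismatched index sets error; too-small sets error
  B <- A; B$ids <- rev(B$ids)
  expect_error(pattern_similarity(A, B), "same matched feature set")
  expect_error(pattern_similarity(diag(2), diag(2)), ">= 3")
})

test_that("null pattern similarity selects about alpha * k / 2 features", {
  set.seed(47)
  k <- 60
  n_sel <- replicate(40, {
    A <- stats::cov2cor(crossprod(matrix(rnorm(80 * k), 80, k)) / 79)
    B <- stats::cov2cor(crossprod(matrix(rnorm(80 * k), 80, k)) / 79)
    sum(pattern_similarity(A, B, alpha = 0.05)$selected)
  })
  # expectation alpha * k / 2 = 1.5; allow generous Monte Carlo slack
  expect_lt(mean(n_sel), 3.5)
  expect_gt(mean(n_sel), 0.3)
})
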