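make_group_matrix <- function(seed, n_per_group = 30, n_met = 50,
                              n_info = 5, effect = 2, sdlog = 0.3) {
  g <- generate_group_study(synthetic_scenario(
    group_n = n_per_group, n_metabolites = n_met,
    n_informative = n_info, effect_size = effect, sdlog = sdlog,
    seed = seed))
  g
}

test_that("well-separated groups fit with high Q2, null labels do not", {
  g <- make_group_matrix(seed = 1)
  m <- fit_oplsda(g$matrix, g$design)
  expect_gt(m$Q2_cum, 0.5)
  expect_true(m$R2X_cum >= 0 && m$R2X_cum <= 1)
  expect_true(m$R2Y_cum >= 0 && m$R2Y_cum <= 1)
  expect_lte(m$Q2_cum, 1)

  # labels independent of the data: no predictive ability
  null <- make_group_matrix(seed = 2, effect = 0)
  m0 <- fit_oplsda(null$matrix, null$design)
  expect_lte(m0$Q2_cum, 0.1)
})

test_that("predictive and orthogonal scores are orthogonal", {
  g <- make_group_matrix(seed = 3)
  for (k in 1:2) {
    m <- fit_oplsda(g$matrix, g$design, n_orth = k)
    for (j in seq_len(ncol(m$t_orth))) {
      expect_lt(abs(sum(m$scores * m$t_orth[, j])) /
                  sqrt(sum(m$scores^2) * sum(m$t_orth[, j]^2)), 1e-8)
    }
  }
})

test_that("a perfectly separating metabolite yields R2Y of 1", {
  x <- matrix(rep(c(1, 3), each = 6), ncol = 1,
              dimnames = list(sprintf("s%d", 1:12), "500"))
  d <- group_design(rownames(x), rep(c("case", "control"), each = 6))
  m <- fit_oplsda(x, d, cv_folds = 3)
  expect_equal(m$R2Y_cum, 1, tolerance = 1e-6)
})

test_that("VIP scores are normalized so mean VIP squared is one", {
  g <- make_group_matrix(seed = 4)
  m <- fit_oplsda(g$matrix, g$design)
  v <- vip_scores(m)
  expect_equal(mean(v^2), 1, tolerance = 1e-6)
  expect_equal(sum(v^2), length(v), tolerance = 1e-4)

  # single metabolite: normalization forces VIP = 1 exactly
  x <- matrix(exp(rnorm(12, rep(c(3, 1), each = 6), 0.1)), ncol = 1,
              dimnames = list(sprintf("s%d", 1:12), "500"))
  d <- group_design(rownames(x), rep(c("case", "control"), each = 6))
  expect_equal(unname(vip_scores(fit_oplsda(x, d, cv_folds = 3))), 1)
  expect_error(vip_scores(list()), "fitted model")
})

test_that("exchangeable metabolites share VIP 1 and are not called", {
  # two identical columns: by symmetry both VIP are exactly 1, and the
  # strict VIP > 1 rule excludes them regardless of the p-value
  set.seed(9)
  base <- exp(rnorm(20, rep(c(2.5, 1.5), each = 10), 0.2))
  x <- cbind(base, base)
  dimnames(x) <- list(sprintf("s%d", 1:20), c("100", "200"))
  d <- group_design(rownames(x), rep(c("case", "control"), each = 10))
  v <- vip_scores(fit_oplsda(x, d, cv_folds = 5))
  expect_equal(unname(v), c(1, 1))
  res <- differential_metabolites(x, d, cv_folds = 5)
  expect_true(all(res$p_value < 0.05))
  expect_false(any(res$significant))  # VIP == 1 does not exceed 1
})

test_that("informative metabolites top the VIP ranking", {
  hits <- vapply(1:20, function(s) {
    g <- make_group_matrix(seed = s)
    m <- fit_oplsda(g$matrix, g$design)
    v <- vip_scores(m)
    all(g$truth$informative_idx %in% order(-v)[1:5])
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("differential calling recovers planted effects with few FPs", {
  g <- make_group_matrix(seed = 7)
  res <- differential_metabolites(g$matrix, g$design)
  called <- res$mz[res$significant]
  expect_true(all(g$truth$informative_mz %in% called))
  expect_lte(length(setdiff(called, g$truth$informative_mz)), 3L)
  # sorted by VIP descending
  expect_true(!is.unsorted(rev(res$VIP)))
})

test_that("identical groups produce level-alpha behaviour and clean nulls", {
  null <- make_group_matrix(seed = 8, effect = 0)
  res <- differential_metabolites(null$matrix, null$design)
  expect_lte(sum(res$significant), 5L)  # well under n_met at alpha 0.05

  # on exchangeable null data the VIP > 1 & p < 0.05 conjunction holds
  # its nominal 5% level up to Monte-Carlo precision of the replicate set
  rates <- vapply(1:50, function(s) {
    g <- make_group_matrix(seed = 500 + s, effect = 0)
    mean(differential_metabolites(g$matrix, g$design)$significant)
  }, numeric(1))
  se <- sd(rates) / sqrt(length(rates))
  expect_lte(mean(rates), 0.05 + 2 * se)
})

test_that("zero-variance metabolites are excluded with a note", {
  g <- make_group_matrix(seed = 10, n_met = 10, n_info = 2)
  X <- g$matrix$intensity
  X[, 4] <- 1
  res <- suppressWarnings(differential_metabolites(X, g$design))
  expect_equal(attr(res, "excluded"), colnames(X)[4])
  expect_equal(nrow(res), 9L)
})

test_that("permutation testing mirrors the negative-Q2 diagnostic", {
  g <- make_group_matrix(seed = 12)
  pt <- permutation_test(g$matrix, g$design, n_perm = 50, seed = 12)
  expect_lt(median(pt$permuted_q2), 0)
  expect_gt(pt$observed_q2, max(pt$permuted_q2))
  expect_equal(pt$p_value, 1 / 51, tolerance = 1e-12)

  expect_error(permutation_test(g$matrix, g$design, n_perm = 0), "n_perm")
  expect_warning(permutation_test(g$matrix, g$design, n_perm = 5,
                                  seed = 1), "coarse")
})

test_that("pure-noise data sits inside its permutation distribution", {
  inside <- vapply(1:10, function(s) {
    null <- make_group_matrix(seed = 100 + s, effect = 0, n_met = 20)
    pt <- permutation_test(null$matrix, null$design, n_perm = 30,
                           seed = s)
    pt$p_value > 0.05
  }, logical(1))
  expect_gte(mean(inside), 0.9)
})

test_that("the pipeline is deterministic given data, config and seed", {
  g <- make_group_matrix(seed = 21)
  r1 <- differential_metabolites(g$matrix, g$design, seed = 4)
  r2 <- differential_metabolites(g$matrix, g$design, seed = 4)
  expect_identical(as.data.frame(r1), as.data.frame(r2))
  m1 <- fit_oplsda(g$matrix, g$design, seed = 4)
  m2 <- fit_oplsda(g$matrix, g$design, seed = 4)
  expect_identical(m1$Q2_cum, m2$Q2_cum)
})

test_that("design validation enforces two adequately sized groups", {
  expect_error(group_design(letters[1:6], rep("a", 6)), "two groups")
  expect_error(group_design(letters[1:5], c("a", "a", "a", "b", "b")),
               ">= 3")
  g <- make_group_matrix(seed = 30, n_per_group = 5)
  expect_error(fit_oplsda(g$matrix, g$design, cv_folds = 20), "folds")
})
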