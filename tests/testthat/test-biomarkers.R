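test_that("selected biomarkers are exactly the features with nonzero coefficient rows", {
  toy <- make_toy_blocks(n_subj = 8L, p = 20L, seed = 6L)
  fit <- smbplsr(toy$blocks, toy$labels, ncomp = 2, sparsity = c(0.8, 0.8))
  rep <- select_biomarkers(fit)
  # independent recomputation of B from the stored factors
  B <- fit$weights %*% solve(crossprod(fit$x_loadings, fit$weights),
                             t(fit$y_loadings))
  nz_ids <- fit$feature_ids[rowSums(B != 0) > 0]
  expect_setequal(rep$feature_id, nz_ids)
  # subset of the union of nonzero weight entries
  w_ids <- fit$feature_ids[rowSums(fit$weights != 0) > 0]
  expect_true(all(rep$feature_id %in% w_ids))
  # sorted by aggregate coefficient magnitude
  expect_true(all(diff(rep$coef_max_abs) <= 0))
  # dense models warn that selection is meaningless
  dense <- smbplsr(toy$blocks, toy$labels, ncomp = 2, sparsity = 0)
  expect_warning(select_biomarkers(dense), "not sparse")
})

test_that("sparsity degree controls the number of retained features", {
  set.seed(12)
  n <- 20
  labels <- rep(c("a", "b"), each = n / 2)
  X <- matrix(rnorm(n * 1000), n, 1000)
  fit <- smbplsr(list(b = X), labels, ncomp = 1, sparsity = 0.99)
  n_sel <- nrow(suppressWarnings(select_biomarkers(fit)))
  expect_lte(n_sel, 10)   # k = round(0.01 * 1000)
  expect_gte(n_sel, 1)
})

test_that("one-way ANOVA on logs matches the closed-form oracle", {
  # groups whose logs are exactly {1,2,3} and {4,5,6}
  vals <- exp(c(1, 2, 3, 4, 5, 6))
  grp <- rep(c("a", "b"), each = 3)
  got <- anova_log(vals, grp)
  f_ref <- oneway_f_closed_form(log(vals), grp)   # 13.5 by hand
  expect_equal(got[["F"]], f_ref, tolerance = 1e-12)
  expect_equal(got[["F"]], 13.5, tolerance = 1e-12)
  expect_equal(got[["p"]], pf(13.5, 1, 4, lower.tail = FALSE), tolerance = 1e-12)

  # identical groups: F = 0, p = 1
  same <- c(exp(0), exp(2), exp(0), exp(2))
  got2 <- anova_log(same, c("a", "a", "b", "b"))
  expect_equal(got2[["F"]], 0)
  expect_equal(got2[["p"]], 1)

  # equal means with zero variance everywhere: indistinguishable, p = 1
  got3 <- anova_log(rep(5, 6), rep(c("a", "b", "c"), each = 2))
  expect_equal(got3[["p"]], 1)

  # three groups, equal means, unequal n: F ~ 0
  v <- exp(c(1, 3, 1, 3, 2, 2, 2))
  got4 <- anova_log(v, c("a", "a", "b", "b", "c", "c", "c"))
  expect_lt(got4[["F"]], 1e-10)
  expect_error(anova_log(1:4, c("a", "a", "a", "a")), "two groups")
})

test_that("F-distribution p agrees with a permutation test within Monte-Carlo error", {
  set.seed(14)
  n_per <- 10
  grp <- rep(c("a", "b"), each = n_per)
  vals <- exp(rnorm(2 * n_per, mean = rep(c(0, 1), each = n_per), sd = 1))
  p_f <- anova_log(vals, grp)[["p"]]
  lv <- log(vals)
  f_obs <- oneway_f_closed_form(lv, grp)
  B <- 10000
  f_perm <- replicate(B, oneway_f_closed_form(lv, sample(grp)))
  p_perm <- (1 + sum(f_perm >= f_obs)) / (B + 1)
  mc_sd <- sqrt(p_perm * (1 - p_perm) / B)
  expect_lt(abs(p_f - p_perm), 4 * mc_sd + 0.01)
})

test_that("correlation loadings locate variables by their score correlations", {
  toy <- make_toy_blocks(n_subj = 10L, seed = 15L)
  fit <- smbplsr(toy$blocks, toy$labels, ncomp = 2)
  t1 <- fit$scores[, 1]; t2 <- fit$scores[, 2]
  # orthonormalize the score plane to build exact constructions
  e1 <- t1 / sqrt(sum(t1^2))
  e2 <- t2 - sum(t2 * e1) * e1; e2 <- e2 / sqrt(sum(e2^2))
  vars <- cbind(self = t1,
                mix = (e1 + e2) / sqrt(2),
                const = rep(1, length(t1)))
  cl <- suppressMessages(correlation_loadings(fit, vars))
  expect_equal(cl$r1[1], 1, tolerance = 1e-10)
  expect_equal(abs(cl$r2[1]), abs(cor(t1, t2)), tolerance = 1e-10)
  expect_equal(cl$r1[2], cor(vars[, 2], t1), tolerance = 1e-12)
  expect_equal(cl$r1[2], 1 / sqrt(2), tolerance = 1e-6)
  expect_equal(cl$r2[2], cor(vars[, 2], t2), tolerance = 1e-12)
  expect_true(cl$missing[3] && is.na(cl$r1[3]))
  expect_equal(attr(cl, "inner_radius"), sqrt(0.5))
  # a variable orthogonal to the score plane sits at the origin
  set.seed(2)
  v <- rnorm(length(t1))
  v <- v - mean(v)
  v <- v - e1 * sum(v * e1) - e2 * sum(v * e2)
  cl2 <- correlation_loadings(fit, cbind(orth = v))
  expect_lt(abs(cl2$r1), 1e-10)
  expect_lt(abs(cl2$r2), 1e-10)
  expect_error(correlation_loadings(smbplsr(toy$blocks, toy$labels, ncomp = 1),
                                    vars), "2 components")
})

test_that("squared correlation loadings never exceed the unit circle", {
  toy <- make_toy_blocks(n_subj = 10L, seed = 16L)
  fit <- smbplsr(toy$blocks, toy$labels, ncomp = 2)
  vars <- do.call(cbind, toy$blocks)
  cl <- correlation_loadings(fit, vars)
  expect_true(all(cl$r1^2 + cl$r2^2 <= 1 + 1e-8))
})

test_that("rank-2 correlations have exact structure and closed-form p-values", {
  set.seed(18)
  n <- 20
  scores <- cbind(rnorm(n), rnorm(n))
  # two variables with identical projections: r = 1, p ~ 0
  base <- rnorm(n)
  T2c <- sweep(scores, 2, colMeans(scores))
  proj_base <- T2c %*% solve(crossprod(T2c), crossprod(T2c, base - mean(base)))
  v1 <- drop(proj_base) + 0          # lies in the plane
  v2 <- 2 * drop(proj_base) + 5      # same direction after centering
  hm <- rank2_correlation_heatmap(cbind(a = v1, b = v2, c = rnorm(n)), scores)
  expect_equal(hm$r["a", "b"], 1, tolerance = 1e-10)
  expect_equal(hm$p["a", "b"], 0)
  expect_identical(unname(diag(hm$r)), rep(1, 3))
  expect_identical(unname(diag(hm$p)), rep(0, 3))
  expect_equal(hm$r, t(hm$r))
  expect_equal(hm$df, n - 2L)

  # orthogonal directions in the plane: r = 0, p = 1
  sv <- svd(T2c)
  u1 <- sv$u[, 1]; u2 <- sv$u[, 2]
  hm2 <- rank2_correlation_heatmap(cbind(x = u1, y = u2), scores)
  expect_lt(abs(hm2$r["x", "y"]), 1e-10)
  expect_equal(hm2$p["x", "y"], 1, tolerance = 1e-8)

  # the p-value follows t = r sqrt((n-2)/(1-r^2)); frozen oracle at r = .8
  r <- 0.8
  p_ref <- 2 * pt(-r * sqrt((n - 2) / (1 - r^2)), n - 2)
  expect_equal(p_ref, 2.292887e-05, tolerance = 1e-6)
  expect_equal(rank2_correlation_heatmap(cbind(a = v1, b = v2), scores,
                                         conservative_df = TRUE)$df, n - 3L)
})

test_that("rank-2 correlations are invariant to reparameterizing the score plane", {
  set.seed(19)
  n <- 15
  scores <- cbind(rnorm(n), rnorm(n))
  vars <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, letters[1:4]))
  hm <- rank2_correlation_heatmap(vars, scores)
  A <- matrix(c(2, 1, -1, 0.5), 2, 2)   # invertible
  hm_re <- rank2_correlation_heatmap(vars, scores %*% A)
  expect_equal(hm$r, hm_re$r, tolerance = 1e-10)
  expect_equal(hm$p, hm_re$p, tolerance = 1e-10)
})

test_that("biomarker reports attach ANOVA confirmation with significance flags", {
  sim <- simulate_study(small_sim_config(n_subj = 6, missing = 0))
  mb <- prep_sim_blocks(sim)
  fit <- smbplsr(mb, "class_label", ncomp = 2, sparsity = 0.9)
  rep <- biomarker_report(fit, mb, alpha = 0.05)
  expect_true(all(c("anova_F", "anova_p", "significant") %in% names(rep)))
  expect_true(all(rep$anova_p >= 0 & rep$anova_p <= 1, na.rm = TRUE))
  expect_identical(rep$significant, !is.na(rep$anova_p) & rep$anova_p <= 0.05)
  # planted markers should dominate the top of the list
  planted <- unlist(lapply(sim$truth$blocks, function(b) b$diet_markers$feature_id))
  expect_gt(mean(head(rep$feature_id, 10) %in% planted), 0.5)
})
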