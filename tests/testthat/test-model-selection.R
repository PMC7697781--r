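test_that("leave-one-subject-out folds partition the samples by subject", {
  subj <- rep(c("s1", "s2", "s3"), each = 2)
  sp <- logo_splits(subj)
  expect_length(sp, 3L)
  expect_true(all(vapply(sp, function(f) length(f$test), integer(1)) == 2L))
  all_test <- sort(unname(unlist(lapply(sp, `[[`, "test"))))
  expect_identical(all_test, seq_along(subj))
  for (f in sp) expect_length(intersect(f$train, f$test), 0L)
  # a subject with a single sample forms a singleton fold
  sp2 <- logo_splits(c("a", "a", "b"))
  expect_identical(sp2$b$test, 3L)
  expect_error(logo_splits(rep("only", 4)), "two subjects")
  # data.frame input uses subject_id
  expect_length(logo_splits(data.frame(subject_id = subj)), 3L)
})

test_that("confusion matrix arithmetic gives SR, MCR and sensitivities", {
  true <- c(rep("a", 6), rep("b", 6))
  pred <- c(rep("a", 5), "b", rep("b", 4), "a", "a")
  cs <- confusion_and_success_rate(true, pred)
  expect_equal(unname(cs$confusion), rbind(c(5, 1), c(2, 4)))
  expect_equal(cs$success_rate, 9 / 12)
  expect_equal(cs$mcr, 1 - 9 / 12)
  expect_equal(unname(cs$sensitivity), c(5 / 6, 4 / 6))
  expect_equal(sum(rowSums(cs$confusion)), length(true))
  # perfect prediction
  expect_equal(confusion_and_success_rate(true, true)$success_rate, 1)
  # everything predicted as one class
  cs3 <- confusion_and_success_rate(true, rep("a", 12))
  expect_equal(unname(cs3$sensitivity), c(1, 0))
  expect_error(confusion_and_success_rate(true, c(pred[-1], "zzz")), "zzz")
})

test_that("one-standard-error rule selects the smallest adequate model", {
  # fold errors at the argmin (A = 3) engineered so SE = sd/sqrt(5) = 0.02,
  # hence err(2) = 0.20 <= 0.19 + 0.02 and A_opt = 2
  spread <- c(-1, -0.5, 0, 0.5, 1)
  fold_err <- matrix(0.19, 5, 4)
  fold_err[, 3] <- 0.19 + spread * (0.02 * sqrt(5) / sd(spread))
  expect_equal(sd(fold_err[, 3]) / sqrt(5), 0.02)
  expect_equal(select_n_components(c(0.40, 0.20, 0.19, 0.25), fold_err), 2L)
  # strictly decreasing error with zero SE: take the largest model
  expect_equal(select_n_components(c(0.4, 0.3, 0.2, 0.1),
                                   matrix(rep(c(0.4, 0.3, 0.2, 0.1), each = 3), 3)),
               4L)
  # flat curve: one component suffices
  expect_equal(select_n_components(rep(0.3, 4)), 1L)
})

test_that("cross-validation is perfect on separable data and reproducible", {
  toy <- make_toy_blocks(n_subj = 8L, sep = 5)
  cv <- cross_validate(toy$blocks, toy$labels, subjects = toy$subjects,
                       grid = c(0, 0.5), ncomp_max = 2)
  expect_equal(cv$success_rate, 1)
  expect_equal(unname(diag(cv$confusion)), unname(rowSums(cv$confusion)))
  expect_equal(sum(cv$confusion), length(toy$labels))
  # deterministic: identical rerun
  cv2 <- cross_validate(toy$blocks, toy$labels, subjects = toy$subjects,
                        grid = c(0, 0.5), ncomp_max = 2)
  expect_identical(cv$predictions, cv2$predictions)
  expect_identical(cv$error_surface, cv2$error_surface)
  # ties in the error surface resolve to the smallest degree of sparsity
  expect_true(all(cv$g_path %in% c(0, 0.5)))
  tied <- cv$error_surface[1, 1] == cv$error_surface[1, 2]
  if (tied) expect_equal(cv$g_path[1], 0)
  # a grid of {0} forces the dense path
  cv0 <- cross_validate(toy$blocks, toy$labels, subjects = toy$subjects,
                        grid = 0, ncomp_max = 2)
  expect_equal(unname(cv0$g_path), c(0, 0))
  expect_error(cross_validate(toy$blocks, toy$labels,
                              subjects = toy$subjects, grid = numeric(0)),
               "empty")
})

test_that("regression mode reports cross-validated RMSE", {
  set.seed(9)
  n <- 24
  subj <- rep(sprintf("s%02d", 1:12), each = 2)
  X <- matrix(rnorm(n * 6), n, 6)
  y <- drop(X %*% c(2, -1, 0, 0, 0, 0)) + rnorm(n, sd = 0.1)
  cv <- cross_validate(list(b = X), y, subjects = subj, grid = c(0, 0.5),
                       ncomp_max = 2)
  expect_equal(cv$mode, "regression")
  expect_true(is.finite(cv$rmse))
  expect_lt(cv$rmse, sd(y))   # far better than the null model
})

test_that("sparsity optimization prefers sparse models when few features carry signal", {
  # strong signal confined to 10 of 500 features
  hits <- 0L
  for (seed in 1:5) {
    set.seed(3000 + seed)
    n_subj <- 16; reps <- 2; n <- n_subj * reps
    subj <- rep(sprintf("s%02d", 1:n_subj), each = reps)
    cls <- rep(c("a", "b"), each = n / 2)
    X <- matrix(rnorm(n * 500), n, 500)
    X[cls == "a", 1:10] <- X[cls == "a", 1:10] + 1.5
    opt <- optimize_sparsity(list(b = X), cls, subjects = subj,
                             ncomp_max = 1)
    if (opt$g_path[1] >= 0.9) hits <- hits + 1L
  }
  expect_gte(hits, 4L)
})

test_that("a three-class problem with an intermediate middle class shows minimal middle sensitivity", {
  sim <- simulate_study(sim_config(
    n_subjects_per_diet = 8,
    blocks = list(plasma = sim_block_config(n_features = 80,
                                            n_diet_markers = 0,
                                            n_time_markers = 20,
                                            effect_size = 2,
                                            missing_rate = 0)),
    seed = 31))
  tab <- suppressMessages(blank_filter(suppressWarnings(
    qc_drift_normalize(sim$blocks$plasma))))
  tab <- tab[tab$sample_meta$role == "sample", ]
  cv <- cross_validate(list(plasma = tab$intensities),
                       tab$sample_meta$time_point,
                       subjects = tab$sample_meta$subject_id,
                       grid = c(0, 0.8), ncomp_max = 2)
  expect_equal(unname(which.min(cv$sensitivity)),
               unname(which(names(cv$sensitivity) == "week12")))
})

test_that("held-out subjects never influence the scaling state (no leakage)", {
  toy <- make_toy_blocks(n_subj = 6L, p = 10L, sep = 3, seed = 8L)
  grid <- c(0, 0.9)
  cv <- cross_validate(toy$blocks, toy$labels, subjects = toy$subjects,
                       grid = grid, ncomp_max = 2)
  A <- cv$ncomp_opt
  gpath <- cv$g_path[seq_len(A)]
  # independent re-run of every fold from scratch, estimating all scaling
  # statistics strictly without the held-out subject
  Y <- encode_classes(toy$labels)
  for (f in logo_splits(toy$subjects)) {
    tr_b <- lapply(toy$blocks, function(m) m[f$train, , drop = FALSE])
    te_b <- lapply(toy$blocks, function(m) m[f$test, , drop = FALSE])
    ps <- lapply(tr_b, pareto_scale)
    tr_s <- lapply(ps, `[[`, "x")
    fn <- frobenius_normalize(tr_s)
    fit <- smbplsr(fn$blocks, toy$labels[f$train], ncomp = A,
                   sparsity = gpath, scale = "none", frobenius = FALSE)
    te_s <- Map(function(m, st) pareto_scale(m, st$state)$x, te_b, ps)
    te_s <- frobenius_normalize(te_s, fn$state)$blocks
    yhat <- sweep(do.call(cbind, te_s) %*% coef(fit), 2, fit$y_center, "+")
    pred <- colnames(Y)[max.col(yhat, ties.method = "first")]
    expect_identical(pred, cv$predictions[f$test])
  }
})
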