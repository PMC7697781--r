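test_that("class encoding is one-hot over sorted labels", {
  y <- encode_classes(c("LR", "HR", "LR"))
  expect_identical(colnames(y), c("HR", "LR"))
  expect_equal(unname(y), rbind(c(0L, 1L), c(1L, 0L), c(0L, 1L)))
  expect_true(all(rowSums(y) == 1))
  y3 <- encode_classes(c("week4", "week12", "week20"))
  expect_equal(ncol(y3), 3L)
  expect_error(encode_classes(c("a", "a")), "two distinct")
  expect_error(encode_classes(c("a", "", "b")), "empty")
})

test_that("soft thresholding matches the hand-computed rule", {
  w <- c(3, -1, 2, 0.5)
  out <- soft_threshold(w, 0.5)           # k = 2, lambda = 1
  expect_equal(out, c(2, 0, 1, 0) / sqrt(5))
  # g = 0 only normalizes
  expect_equal(soft_threshold(w, 0), w / sqrt(sum(w^2)))
  # exact ties at the threshold can wipe everything: first index retained
  expect_message(out_tie <- soft_threshold(c(1, 1), 0.5), "retaining index 1")
  expect_equal(out_tie, c(1, 0))
  expect_error(soft_threshold(c(0, 0), 0.5), "zero")
  expect_error(soft_threshold(c(1, 2), 1), "sparsity")
})

test_that("increasing the degree of sparsity never adds nonzero entries", {
  set.seed(5)
  for (rep in 1:10) {
    w <- rnorm(40)
    nz <- vapply(c(0, 0.2, 0.5, 0.7, 0.9, 0.975),
                 function(g) sum(soft_threshold(w, g) != 0), numeric(1))
    expect_true(all(diff(nz) <= 0))
  }
  # retained count tracks k = max(1, round((1 - g) p))
  w <- seq_len(100)
  expect_equal(sum(soft_threshold(w, 0.9) != 0), 10)
  expect_equal(sum(soft_threshold(w, 0.995) != 0), 1)
})

test_that("dense single-block fit matches the eigen-decomposition PLS2 oracle", {
  set.seed(42)
  X <- matrix(rnorm(20 * 10), 20, 10)
  X <- sweep(X, 2, colMeans(X))
  labels <- rep(c("g1", "g2"), each = 10)
  Y <- encode_classes(labels)

  fit <- smbplsr(list(b = X), labels, ncomp = 3, sparsity = 0,
                 scale = "none", frobenius = FALSE)
  oracle <- pls2_eigen_oracle(X, Y, 3)
  expect_lt(max(abs(match_signs(oracle$scores, fit$scores) - fit$scores)), 1e-8)
  expect_lt(max(abs(match_signs(oracle$W, fit$weights) - fit$weights)), 1e-8)
  # first weight is the dominant left singular vector of X'Yc
  Yc <- sweep(Y, 2, colMeans(Y))
  w1 <- svd(crossprod(X, Yc))$u[, 1]
  if (sum(w1 * fit$weights[, 1]) < 0) w1 <- -w1
  expect_lt(max(abs(w1 - fit$weights[, 1])), 1e-8)
})

test_that("model invariants hold for sparse multi-block fits", {
  toy <- make_toy_blocks(n_subj = 8L, p = 15L, seed = 3L)
  fit <- smbplsr(toy$blocks, toy$labels, ncomp = 3, sparsity = c(0.3, 0.6, 0.8))
  Tm <- fit$scores
  # score orthogonality
  for (i in 1:2) for (j in (i + 1):3) {
    cosine <- abs(sum(Tm[, i] * Tm[, j])) /
      (sqrt(sum(Tm[, i]^2)) * sqrt(sum(Tm[, j]^2)))
    expect_lt(cosine, 1e-8)
  }
  # unit-norm sparse weights and super weights summing to one
  expect_equal(unname(colSums(fit$weights^2)), rep(1, 3), tolerance = 1e-12)
  expect_equal(unname(colSums(fit$super_weights)), rep(1, 3), tolerance = 1e-12)
  # super score decomposes exactly into block scores
  recomposed <- fit$block_scores[[1]] + fit$block_scores[[2]]
  expect_equal(recomposed, Tm, tolerance = 1e-12)
  # explained variances are non-negative and cumulative Y variance non-decreasing
  ev <- fit$explained_variance
  expect_true(all(ev$R2X >= 0) && all(ev$R2Y >= 0))
  expect_true(all(diff(ev$cumR2Y) >= 0))
})

test_that("a block of pure noise takes less super weight than the informative block", {
  set.seed(17)
  wins <- 0L
  omega <- matrix(NA_real_, 100, 2)
  for (r in 1:100) {
    n <- 20
    labels <- rep(c("a", "b"), each = n / 2)
    signal <- matrix(rnorm(n * 10), n, 10)
    signal[labels == "a", 1:3] <- signal[labels == "a", 1:3] + 2
    noise <- matrix(rnorm(n * 10), n, 10)
    fit <- smbplsr(list(sig = signal, noi = noise), labels, ncomp = 1)
    omega[r, ] <- fit$super_weights[, 1]
  }
  expect_gt(mean(omega[, 1]), mean(omega[, 2]))
})

test_that("degenerate responses and mismatched predictions error clearly", {
  X <- matrix(rnorm(40), 10, 4)
  expect_error(smbplsr(list(b = X), rep("same", 10), ncomp = 1),
               "two distinct")
  # numeric constant response: no variance to model
  expect_error(smbplsr(list(b = X), rep(1, 10), ncomp = 1), "degenerate")
  toy <- make_toy_blocks()
  fit <- smbplsr(toy$blocks, toy$labels, ncomp = 2)
  expect_error(predict(fit, list(one = toy$blocks$one[, 1:3],
                                 two = toy$blocks$two)),
               "feature mismatch")
})

test_that("prediction separates a separable toy set and breaks ties deterministically", {
  toy <- make_toy_blocks(n_subj = 8L, sep = 5)
  fit <- smbplsr(toy$blocks, toy$labels, ncomp = 2)
  expect_identical(predict(fit, toy$blocks, type = "class"), toy$labels)
  yhat <- predict(fit, toy$blocks, type = "response")
  expect_equal(dim(yhat), c(length(toy$labels), 2L))
  expect_equal(unname(rowSums(yhat)), rep(1, nrow(yhat)), tolerance = 1e-8)
  # exact tie goes to the first class and is logged
  expect_message(out <- smbplsr:::.argmax_classes(rbind(c(0.5, 0.5)), c("A", "B")),
                 "tie")
  expect_identical(out, "A")
})

test_that("model archive round-trips exactly", {
  toy <- make_toy_blocks()
  fit <- smbplsr(toy$blocks, toy$labels, ncomp = 2, sparsity = 0.5)
  f <- tempfile(fileext = ".rds")
  write_smbplsr(fit, f)
  back <- read_smbplsr(f)
  expect_identical(back$weights, fit$weights)
  expect_identical(back$coefficients, fit$coefficients)
  expect_identical(back$scaling_state, fit$scaling_state)
  expect_identical(predict(back, toy$blocks), predict(fit, toy$blocks))
  saveRDS(1:3, f)
  expect_error(read_smbplsr(f), "smbplsr model")
})

test_that("consensus PCA on one block reproduces the SVD and decomposes blocks", {
  set.seed(23)
  X <- matrix(rnorm(15 * 6), 15, 6)
  res <- cpca(list(b = X), ncomp = 3, scale = "center", frobenius = FALSE)
  Xc <- sweep(X, 2, colMeans(X))
  sv <- svd(Xc)
  scores_ref <- sv$u[, 1:3] %*% diag(sv$d[1:3])
  expect_lt(max(abs(match_signs(scores_ref, res$scores) - res$scores)), 1e-8)
  expect_equal(res$explained_variance,
               sv$d[1:3]^2 / sum(sv$d^2), tolerance = 1e-10)

  # duplicated block: each block carries exactly half the loading mass
  res2 <- cpca(list(a = X, b = X), ncomp = 2, scale = "center")
  expect_equal(unname(res2$super_weights),
               matrix(0.5, 2, 2), tolerance = 1e-8)
  # block scores sum to the global score
  expect_equal(res2$block_scores$a + res2$block_scores$b, res2$scores,
               tolerance = 1e-10)

  # rank-1 data: second component explains ~ nothing, extra components truncate
  r1 <- outer(rnorm(12), rnorm(5))
  res3 <- suppressWarnings(cpca(list(b = r1), ncomp = 2, scale = "center",
                                frobenius = FALSE))
  expect_true(res3$ncomp < 2 || res3$explained_variance[2] < 1e-10)
  expect_warning(cpca(list(b = r1), ncomp = 4, scale = "center",
                      frobenius = FALSE), "truncating")
})
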