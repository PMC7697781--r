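# Independent reference implementations and small fixtures used across tests.

# Dense PLS2 by repeated eigen-decomposition of X'YY'X (power-method view of
# the NIPALS fixed point), with super-score deflation. Independent of the
# package's NIPALS loop.
pls2_eigen_oracle <- function(X, Y, ncomp) {
  Yc <- sweep(Y, 2L, colMeans(Y), "-")
  W <- matrix(0, ncol(X), ncomp); Tm <- matrix(0, nrow(X), ncomp)
  P <- matrix(0, ncol(X), ncomp); Q <- matrix(0, ncol(Yc), ncomp)
  Xd <- X; Yd <- Yc
  for (a in seq_len(ncomp)) {
    M <- crossprod(Xd, Yd)
    w <- eigen(M %*% t(M), symmetric = TRUE)$vectors[, 1L]
    tt <- drop(Xd %*% w)
    q <- drop(crossprod(Yd, tt)) / sum(tt^2)
    p <- drop(crossprod(Xd, tt)) / sum(tt^2)
    W[, a] <- w; Tm[, a] <- tt; P[, a] <- p; Q[, a] <- q
    Xd <- Xd - tcrossprod(tt, p)
    Yd <- Yd - tcrossprod(tt, q)
  }
  list(W = W, scores = Tm, P = P, Q = Q)
}

# Align signs of reference columns to a target matrix before comparison.
match_signs <- function(ref, target) {
  for (a in seq_len(ncol(ref))) {
    if (sum(ref[, a] * target[, a]) < 0) ref[, a] <- -ref[, a]
  }
  ref
}

# Closed-form one-way ANOVA F (textbook between/within decomposition).
oneway_f_closed_form <- function(values, groups) {
  groups <- factor(groups)
  gm <- mean(values)
  means <- tapply(values, groups, mean)
  ns <- tabulate(groups)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((values - means[groups])^2)
  df1 <- nlevels(groups) - 1L
  df2 <- length(values) - nlevels(groups)
  (ssb / df1) / (ssw / df2)
}

# A linearly separable two-class toy multiblock with repeated measures.
make_toy_blocks <- function(n_subj = 6L, reps = 2L, p = 8L, sep = 4,
                            seed = 11L) {
  set.seed(seed)
  n <- n_subj * reps
  subj <- rep(sprintf("T%02d", seq_len(n_subj)), each = reps)
  cls <- rep(c("A", "B"), each = n / 2)
  X1 <- matrix(rnorm(n * p), n, p)
  X2 <- matrix(rnorm(n * p), n, p)
  X1[cls == "A", 1] <- X1[cls == "A", 1] + sep
  X2[cls == "B", 2] <- X2[cls == "B", 2] + sep
  colnames(X1) <- paste0("b1_", seq_len(p))
  colnames(X2) <- paste0("b2_", seq_len(p))
  list(blocks = list(one = X1, two = X2), labels = cls, subjects = subj)
}

# Small simulated study used by several suites.
small_sim_config <- function(n_subj = 5L, n_features = 60L, effect = 1.5,
                             missing = 0.05, n_diet = 8L, n_time = 4L) {
  sim_config(
    n_subjects_per_diet = n_subj,
    blocks = list(
      plasma = sim_block_config(n_features = n_features,
                                n_diet_markers = n_diet,
                                n_time_markers = n_time,
                                effect_size = effect,
                                missing_rate = missing),
      feces = sim_block_config(n_features = n_features,
                               n_diet_markers = n_diet,
                               n_time_markers = n_time,
                               effect_size = effect,
                               missing_rate = missing, mode = "ESI-")),
    seed = 99L)
}

# Preprocess simulated metabolomics blocks the way the pipeline does.
prep_sim_blocks <- function(sim) {
  suppressMessages({
    tabs <- lapply(sim$blocks, function(t)
      blank_filter(suppressWarnings(qc_drift_normalize(t))))
    align_blocks(tabs)
  })
}
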