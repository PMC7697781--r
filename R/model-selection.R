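#' Leave-one-subject-out fold assignments
#'
#' Grouped cross-validation for repeated-measures designs: one fold per
#' subject, with all of that subject's samples (every time point) forming the
#' test set, so a model is never judged on an animal it has already seen.
#'
#' @param subjects character vector of subject ids, one per sample, or a
#'   data.frame carrying a `subject_id` column.
#' @return named list (one element per subject, sorted) of
#'   `list(train, test)` integer index vectors; folds are disjoint and cover
#'   all samples.
#' @export
logo_splits <- function(subjects) {
  if (is.data.frame(subjects)) subjects <- subjects$subject_id
  subjects <- as.character(subjects)
  if (anyNA(subjects)) stop("subject_id missing for some samples")
  ids <- sort(unique(subjects))
  if (length(ids) < 2L) stop("leave-one-subject-out needs at least two subjects")
  out <- lapply(ids, function(s) {
    test <- which(subjects == s)
    list(train = setdiff(seq_along(subjects), test), test = test)
  })
  names(out) <- ids
  out
}

#' Confusion matrix, success rate and per-class sensitivity
#'
#' @param true,predicted equal-length label vectors; `predicted` must only use
#'   labels present in the class set of `true` (or `levels`).
#' @param levels optional explicit class set.
#' @return list with `confusion` (true x predicted counts), `success_rate`
#'   (fraction correct, `SR = trace/total`), `mcr` (`1 - SR`) and
#'   `sensitivity` (per-class fraction of actual members recovered).
#' @export
confusion_and_success_rate <- function(true, predicted, levels = NULL) {
  true <- as.character(true); predicted <- as.character(predicted)
  if (length(true) != length(predicted))
    stop("label vectors must have equal length")
  if (is.null(levels)) levels <- sort(unique(true))
  bad <- setdiff(unique(predicted), levels)
  if (length(bad))
    .stopf("predicted label(s) outside the class set: %s", paste(bad, collapse = ", "))
  cm <- table(factor(true, levels = levels), factor(predicted, levels = levels))
  cm <- unclass(cm)
  names(dimnames(cm)) <- c("true", "predicted")
  sr <- sum(diag(cm)) / sum(cm)
  sens <- ifelse(rowSums(cm) > 0, diag(cm) / rowSums(cm), NA_real_)
  list(confusion = cm, success_rate = sr, mcr = 1 - sr, sensitivity = sens)
}

#' Choose the number of latent variables by the one-standard-error rule
#'
#' The optimal component count is the smallest A whose cross-validated error
#' is not significantly higher than the minimum error: operationally, the
#' smallest A with `err(A) <= min(err) + SE`, where `SE` is the fold-wise
#' standard deviation of the error at the minimizing A divided by the square
#' root of the number of folds.
#'
#' @param err numeric vector of CV error (MCR or RMSE) for A = 1, 2, ...
#' @param fold_err matrix of per-fold errors (folds x A) used for the SE; may
#'   be `NULL`, in which case SE = 0 and the argmin is returned directly.
#' @return the selected component count `A_opt`.
#' @export
select_n_components <- function(err, fold_err = NULL) {
  a_min <- which.min(err)
  se <- 0
  if (!is.null(fold_err)) {
    v <- fold_err[, a_min]
    se <- stats::sd(v) / sqrt(length(v))
    if (!is.finite(se)) se <- 0
  }
  which(err <= err[a_min] + se)[1L]
}

## Evaluate a fold: predict the held-out samples of an a-component model
## whose W/P/Q columns are already accumulated.
.fold_predict <- function(Xte, W, P, Q, y_center) {
  PW <- crossprod(P, W)
  B <- tryCatch(W %*% solve(PW, t(Q)), error = function(e) NULL)
  if (is.null(B)) return(NULL)
  sweep(Xte %*% B, 2L, y_center, "+")
}

## One NIPALS component on an already-deflated (X, Y) pair; returns the
## component vectors without mutating the inputs.
.one_component <- function(Xd, Yd, g, tol = 1e-10, max_iter = 500L) {
  vars <- .col_sds(Yd)^2
  if (all(vars < .Machine$double.eps)) return(NULL)
  u <- Yd[, which.max(vars)]
  t_old <- rep(0, nrow(Xd))
  for (it in seq_len(max_iter)) {
    w <- drop(crossprod(Xd, u))
    nw <- sqrt(sum(w^2))
    if (nw == 0) return(NULL)
    w <- soft_threshold(w / nw, g)
    tt <- drop(Xd %*% w)
    stt <- sum(tt^2)
    if (stt == 0) return(NULL)
    q <- drop(crossprod(Yd, tt)) / stt
    u <- drop(Yd %*% q) / sum(q^2)
    if (sqrt(sum((tt - t_old)^2)) / sqrt(stt) < tol) break
    t_old <- tt
  }
  pp <- drop(crossprod(Xd, tt)) / sum(tt^2)
  list(w = w, p = pp, q = q, t = tt)
}

#' Cross-validated sparsity optimization and model assessment
#'
#' Runs the full model-selection protocol under leave-one-subject-out
#' cross-validation: for each component `a = 1..ncomp_max` a greedy forward
#' search over the degree-of-sparsity `grid` fixes `g_a` at the value
#' minimizing the pooled CV error (ties go to the smallest, i.e. least
#' sparse, degree), holding the earlier components' degrees fixed; the
#' component count is then chosen by the one-standard-error rule
#' ([select_n_components()]). All preprocessing (Pareto means/SDs, Frobenius
#' norms, response centering) is estimated on each fold's training samples
#' only and applied frozen to the held-out subject — the held-out samples
#' never influence any statistic used to transform them.
#'
#' @param x a `multiblock` or named list of matrices (rows = samples).
#' @param y class labels (classification) or numeric response (regression);
#'   for a `multiblock`, a character scalar naming a sample-metadata column.
#' @param subjects subject ids per sample; defaults to the `subject_id`
#'   column of an aligned `multiblock`.
#' @param grid candidate degrees of sparsity in `[0, 1)`.
#' @param ncomp_max largest number of latent variables to consider.
#' @param scale,frobenius preprocessing options, as in [smbplsr()].
#' @return an object of class `smbplsr_cv`: `error_surface`
#'   (ncomp_max x grid pooled CV error), `g_path` (chosen degree per
#'   component), `error_per_ncomp`, `fold_error` (folds x ncomp_max at the
#'   chosen path), `ncomp_opt`, and — in classification mode — pooled
#'   out-of-fold `predictions`, `confusion`, `success_rate` (SR_CV), `mcr`,
#'   `sensitivity`; in regression mode `rmse` and pooled predictions.
#' @export
cross_validate <- function(x, y, subjects = NULL,
                           grid = c(0, 0.5, 0.8, 0.9, 0.95, 0.99),
                           ncomp_max = 2L,
                           scale = c("pareto", "center", "none"),
                           frobenius = TRUE) {
  scale <- match.arg(scale)
  if (!length(grid)) stop("empty sparsity grid")
  if (any(grid < 0 | grid >= 1)) stop("grid values must lie in [0, 1)")
  grid <- sort(grid)
  if (inherits(x, "multiblock")) {
    si <- sample_info(x)
    if (is.null(subjects)) subjects <- si$subject_id
    if (is.character(y) && length(y) == 1L) y <- si[[y]]
  }
  if (is.null(subjects)) stop("subject ids are required for grouped CV")
  mats <- .as_block_matrices(x)
  n <- nrow(mats[[1L]])
  if (length(subjects) != n) stop("subjects length does not match sample count")

  mode <- if (is.numeric(y)) "regression" else "classification"
  if (mode == "classification") {
    labels <- as.character(y)
    Yfull <- encode_classes(labels)
    class_labels <- colnames(Yfull)
  } else {
    Yfull <- as.matrix(y)
    if (is.null(colnames(Yfull))) colnames(Yfull) <- paste0("y", seq_len(ncol(Yfull)))
    labels <- NULL
    class_labels <- NULL
  }

  splits <- logo_splits(subjects)
  nfolds <- length(splits)

  ## Preprocess once per fold (independent of the sparsity path).
  folds <- lapply(splits, function(sp) {
    tr_mats <- lapply(mats, function(m) m[sp$train, , drop = FALSE])
    te_mats <- lapply(mats, function(m) m[sp$test, , drop = FALSE])
    prep <- .preprocess_blocks(tr_mats, scale = scale, frobenius = frobenius)
    Xtr <- do.call(cbind, prep$blocks)
    Xte <- do.call(cbind, .preprocess_blocks(te_mats, state = prep$state)$blocks)
    Ytr <- Yfull[sp$train, , drop = FALSE]
    if (mode == "classification" &&
        any(colSums(Ytr) == 0))
      .warnf("class absent from a training fold (held-out subject %s)",
             subjects[sp$test[1]])
    y_center <- colMeans(Ytr)
    list(test = sp$test,
         Xd = Xtr, Yd = sweep(Ytr, 2L, y_center, "-"),
         Xte = Xte, y_center = y_center,
         W = NULL, P = NULL, Q = NULL)
  })

  p <- ncol(folds[[1L]]$Xd)
  err_surface <- matrix(NA_real_, nrow = ncomp_max, ncol = length(grid),
                        dimnames = list(paste0("A", seq_len(ncomp_max)),
                                        paste0("g", grid)))
  g_path <- numeric(0)
  err_per_A <- rep(NA_real_, ncomp_max)
  fold_err <- matrix(NA_real_, nrow = nfolds, ncol = ncomp_max)
  pred_store <- vector("list", ncomp_max)  # pooled predictions at chosen g per A

  pooled_error <- function(yhat_list) {
    ## yhat_list: per fold, matrix of test predictions (or NULL on failure)
    if (mode == "classification") {
      pred <- rep(NA_character_, n)
      for (f in seq_along(folds)) {
        yh <- yhat_list[[f]]
        if (is.null(yh)) next
        pred[folds[[f]]$test] <- .argmax_classes(yh, class_labels)
      }
      ok <- !is.na(pred)
      list(err = mean(pred[ok] != labels[ok]),
           fold = vapply(seq_along(folds), function(f) {
             idx <- folds[[f]]$test
             mean(pred[idx] != labels[idx])
           }, numeric(1)),
           pred = pred)
    } else {
      pred <- matrix(NA_real_, n, ncol(Yfull))
      for (f in seq_along(folds)) {
        yh <- yhat_list[[f]]
        if (is.null(yh)) next
        pred[folds[[f]]$test, ] <- yh
      }
      ok <- stats::complete.cases(pred)
      list(err = sqrt(mean((pred[ok, ] - Yfull[ok, ])^2)),
           fold = vapply(seq_along(folds), function(f) {
             idx <- folds[[f]]$test
             sqrt(mean((pred[idx, , drop = FALSE] - Yfull[idx, , drop = FALSE])^2))
           }, numeric(1)),
           pred = pred)
    }
  }

  for (a in seq_len(ncomp_max)) {
    cand_comp <- vector("list", length(grid))   # per g: per fold component
    best <- NULL
    for (gi in seq_along(grid)) {
      g <- grid[gi]
      comps <- vector("list", nfolds)
      yhat <- vector("list", nfolds)
      for (f in seq_len(nfolds)) {
        fd <- folds[[f]]
        cp <- tryCatch(.one_component(fd$Xd, fd$Yd, g), error = function(e) NULL)
        comps[[f]] <- cp
        if (is.null(cp)) next
        W <- cbind(fd$W, cp$w); P <- cbind(fd$P, cp$p); Q <- cbind(fd$Q, cp$q)
        yhat[[f]] <- .fold_predict(fd$Xte, W, P, Q, fd$y_center)
      }
      sc <- pooled_error(yhat)
      err_surface[a, gi] <- sc$err
      cand_comp[[gi]] <- list(comps = comps, score = sc)
    }
    gi_best <- which.min(err_surface[a, ])   # ties: first = smallest g
    g_path[a] <- grid[gi_best]
    err_per_A[a] <- err_surface[a, gi_best]
    fold_err[, a] <- cand_comp[[gi_best]]$score$fold
    pred_store[[a]] <- cand_comp[[gi_best]]$score$pred
    ## Commit the chosen component: deflate each fold and grow W/P/Q.
    for (f in seq_len(nfolds)) {
      cp <- cand_comp[[gi_best]]$comps[[f]]
      if (is.null(cp)) next
      fd <- folds[[f]]
      folds[[f]]$W <- cbind(fd$W, cp$w)
      folds[[f]]$P <- cbind(fd$P, cp$p)
      folds[[f]]$Q <- cbind(fd$Q, cp$q)
      folds[[f]]$Xd <- fd$Xd - tcrossprod(cp$t, cp$p)
      folds[[f]]$Yd <- fd$Yd - tcrossprod(cp$t, cp$q)
    }
  }

  ncomp_opt <- select_n_components(err_per_A, fold_err)
  pred <- pred_store[[ncomp_opt]]

  out <- list(grid = grid, ncomp_max = ncomp_max, mode = mode,
              error_surface = err_surface, g_path = g_path,
              error_per_ncomp = err_per_A, fold_error = fold_err,
              ncomp_opt = ncomp_opt, folds = names(splits),
              subjects = as.character(subjects))
  if (mode == "classification") {
    ok <- !is.na(pred)
    cs <- confusion_and_success_rate(labels[ok], pred[ok], levels = class_labels)
    out <- c(out, list(predictions = pred, true_labels = labels,
                       confusion = cs$confusion, success_rate = cs$success_rate,
                       mcr = cs$mcr, sensitivity = cs$sensitivity))
  } else {
    out <- c(out, list(predictions = pred, rmse = err_per_A[ncomp_opt]))
  }
  structure(out, class = "smbplsr_cv")
}

#' @export
print.smbplsr_cv <- function(x, ...) {
  cat(sprintf("Leave-one-subject-out CV (%s): %d folds\n", x$mode,
              length(x$folds)))
  cat(sprintf("  A_opt = %d; degree-of-sparsity path: %s\n", x$ncomp_opt,
              paste(format(x$g_path[seq_len(x$ncomp_opt)]), collapse = ", ")))
  if (x$mode == "classification") {
    cat(sprintf("  SR_CV = %.1f%% (MCR = %.3f)\n", 100 * x$success_rate, x$mcr))
    cat("  confusion matrix (true x predicted):\n")
    print(x$confusion)
  } else {
    cat(sprintf("  RMSE_CV = %.4f\n", x$rmse))
  }
  invisible(x)
}

#' Greedy per-component sparsity optimization
#'
#' Convenience wrapper around [cross_validate()] returning just the chosen
#' degree-of-sparsity path and the pooled CV error surface over
#' (component, degree) combinations.
#'
#' @inheritParams cross_validate
#' @return list with `g_path` and `error_surface`.
#' @export
optimize_sparsity <- function(x, y, subjects = NULL,
                              grid = c(0, 0.5, 0.8, 0.9, 0.95, 0.99),
                              ncomp_max = 2L,
                              scale = c("pareto", "center", "none"),
                              frobenius = TRUE) {
  cv <- cross_validate(x, y, subjects = subjects, grid = grid,
                       ncomp_max = ncomp_max, scale = match.arg(scale),
                       frobenius = frobenius)
  list(g_path = cv$g_path, error_surface = cv$error_surface)
}
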