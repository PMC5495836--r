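# Machine learning on connectivity features: RBF-kernel SVM classification
# of injury status and a two-layer feed-forward network trained with
# Bayesian regularization for lesion-size regression. Features are the
# Fisher-z seed-pair connectivities of both chromophore contrasts
# (8 seeds -> 28 pairs per contrast -> 56 features).

#' Build the canonical connectivity feature vector
#'
#' Concatenates the upper triangles of the per-contrast Fisher-z
#' connectivity matrices in a canonical order: seed names sorted
#' lexicographically, pairs taken column-wise from the upper triangle, one
#' block per contrast. The ordering is invariant to the seed order of the
#' input matrices.
#'
#' @param mats named list of \code{connectivity_matrix} objects, one per
#'   contrast.
#' @param contrasts contrast names, in feature-block order.
#' @return named numeric vector (names like \code{HbO2_C_L_M_R}).
#' @export
build_feature_vector <- function(mats, contrasts = names(mats)) {
  stopifnot(all(contrasts %in% names(mats)))
  seed_sets <- lapply(mats[contrasts], function(m) sort(m$seed_names))
  for (ss in seed_sets)
    if (!identical(ss, seed_sets[[1]]))
      stop("seed-set mismatch between contrasts")
  sn <- seed_sets[[1]]
  out <- c()
  for (ch in contrasts) {
    z <- mats[[ch]]$z[sn, sn]
    ut <- upper.tri(z)
    nm <- outer(sn, sn, function(a, b) paste(ch, a, b, sep = "_"))
    v <- z[ut]
    names(v) <- nm[ut]
    out <- c(out, v)
  }
  out
}

#' Classification metrics from a 2x2 confusion matrix
#'
#' @param confusion 2x2 matrix of counts, rows = truth, columns =
#'   prediction, with the positive (injured) class identified by
#'   \code{positive}.
#' @param positive dimname of the positive class.
#' @return named vector \code{Se}, \code{Sp}, \code{PPV}, \code{NPV},
#'   \code{Acc}.
#' @export
classifier_metrics <- function(confusion, positive = "injured") {
  stopifnot(all(dim(confusion) == c(2, 2)))
  lv <- rownames(confusion)
  stopifnot(positive %in% lv, identical(lv, colnames(confusion)))
  neg <- setdiff(lv, positive)
  TP <- confusion[positive, positive]; FN <- confusion[positive, neg]
  TN <- confusion[neg, neg]; FP <- confusion[neg, positive]
  c(Se = TP / (TP + FN), Sp = TN / (TN + FP),
    PPV = TP / (TP + FP), NPV = TN / (TN + FN),
    Acc = (TP + TN) / sum(confusion))
}

# Stratified fold assignment: every class is spread as evenly as possible
# over the k folds. Uses the current RNG stream.
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (lv in levels(y)) {
    idx <- which(y == lv)
    fold[idx] <- sample(rep_len(sample(k), length(idx)))
  }
  fold
}

#' Train an RBF-kernel SVM with grid-searched hyperparameters
#'
#' Soft-margin support vector classifier with Gaussian kernel
#' \eqn{\exp(-\|u-v\|^2 / (2\sigma^2))}. The box constraint C and kernel
#' sigma are selected by stratified inner cross-validation accuracy over a
#' log2-spaced grid; features are z-scored with the training statistics.
#'
#' @param x feature matrix (subjects x features).
#' @param y two-level factor of class labels.
#' @param cost_grid,sigma_grid hyperparameter grids.
#' @param inner_k inner CV folds for the grid search.
#' @param rng_seed integer seed for the inner folds.
#' @return an object of class \code{oic_svm}.
#' @export
train_svm <- function(x, y, cost_grid = 2^seq(-5, 15, by = 2),
                      sigma_grid = 2^seq(-3, 9, by = 2),
                      inner_k = 5, rng_seed = 1L) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  if (nlevels(y) != 2) stop("exactly 2 classes are required")
  if (min(table(y)) < 2) stop("need at least 2 subjects per class")
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  set.seed(as.integer(rng_seed))
  k <- min(inner_k, min(table(y)))
  fold <- stratified_folds(y, k)
  best <- c(acc = -1, cost = NA, sigma = NA)
  for (cost in cost_grid) {
    for (sig in sigma_grid) {
      correct <- 0L
      for (f in seq_len(k)) {
        tr <- fold != f
        if (nlevels(droplevels(y[tr])) < 2) next
        fit <- e1071::svm(xs[tr, , drop = FALSE], y[tr], kernel = "radial",
                          gamma = 1 / (2 * sig^2), cost = cost,
                          scale = FALSE)
        correct <- correct +
          sum(predict(fit, xs[!tr, , drop = FALSE]) == y[!tr])
      }
      acc <- correct / length(y)
      if (acc > best["acc"]) best <- c(acc = acc, cost = cost, sigma = sig)
    }
  }
  model <- e1071::svm(xs, y, kernel = "radial",
                      gamma = 1 / (2 * best[["sigma"]]^2),
                      cost = best[["cost"]], scale = FALSE)
  structure(list(model = model, center = ctr, scale = scl,
                 cost = best[["cost"]], sigma = best[["sigma"]],
                 cv_accuracy = best[["acc"]], levels = levels(y)),
            class = "oic_svm")
}

#' @export
predict.oic_svm <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  predict(object$model, scale(newdata, object$center, object$scale))
}

#' @export
print.oic_svm <- function(x, ...) {
  cat("<oic_svm> RBF SVM, C = ", x$cost, ", sigma = ", x$sigma,
      " (inner-CV accuracy ", signif(x$cv_accuracy, 3), ")\n", sep = "")
  invisible(x)
}

#' Repeated stratified cross-validation of the SVM classifier
#'
#' Repeated stratified k-fold cross-validation; in each outer fold the
#' hyperparameters are selected on inner validation folds of the training
#' part only, so test subjects never influence standardization, grid
#' selection or training. Metrics are computed per repeat and averaged;
#' the pooled confusion matrix over all repeats is also reported.
#'
#' @param x feature matrix (subjects x features).
#' @param y two-level factor; the positive class is \code{positive}.
#' @param k outer folds (default 10).
#' @param repeats number of cross-validation runs to average (default 10).
#' @param rng_seed integer seed.
#' @param positive positive class label (default \code{"injured"}).
#' @param cost_grid,sigma_grid,inner_k passed to \code{\link{train_svm}}.
#' @return an object of class \code{classifier_report}.
#' @export
cross_validate_svm <- function(x, y, k = 10, repeats = 10, rng_seed = 1L,
                               positive = "injured",
                               cost_grid = 2^seq(-5, 15, by = 2),
                               sigma_grid = 2^seq(-3, 9, by = 2),
                               inner_k = 5) {
  x <- as.matrix(x)
  y <- droplevels(as.factor(y))
  stopifnot(nlevels(y) == 2, positive %in% levels(y))
  n <- length(y)
  per_run <- NULL
  agg <- matrix(0L, 2, 2, dimnames = list(levels(y), levels(y)))
  for (rep_i in seq_len(repeats)) {
    rs <- derive_seed(rng_seed, rep_i)
    conf <- matrix(0L, 2, 2, dimnames = list(levels(y), levels(y)))
    for (attempt in 1:10) {
      set.seed(rs + attempt - 1L)
      fold <- stratified_folds(y, min(k, n))
      ok <- all(vapply(unique(fold), function(f)
        nlevels(droplevels(y[fold != f])) == 2, TRUE))
      if (ok) break
      warning("class missing from a training split; re-randomizing folds")
    }
    for (f in sort(unique(fold))) {
      tr <- fold != f
      fit <- train_svm(x[tr, , drop = FALSE], y[tr],
                       cost_grid = cost_grid, sigma_grid = sigma_grid,
                       inner_k = inner_k,
                       rng_seed = derive_seed(rs, f))
      pred <- predict(fit, x[!tr, , drop = FALSE])
      conf <- conf + table(factor(y[!tr], levels(y)),
                           factor(pred, levels(y)))
    }
    agg <- agg + conf
    per_run <- rbind(per_run,
                     data.frame(run = rep_i,
                                t(classifier_metrics(conf, positive))))
  }
  structure(list(confusion = agg,
                 metrics = colMeans(per_run[, -1, drop = FALSE]),
                 aggregate_metrics = classifier_metrics(agg, positive),
                 per_run = per_run, positive = positive,
                 k = k, repeats = repeats),
            class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat("<classifier_report> ", x$repeats, " x ", x$k,
      "-fold cross-validation; mean metrics:\n", sep = "")
  print(round(x$metrics, 4))
  cat("pooled confusion (rows = truth):\n")
  print(x$confusion)
  invisible(x)
}

# Forward pass of the two-layer network on standardized inputs.
ann_forward <- function(theta, xs, hidden) {
  d <- ncol(xs)
  W1 <- matrix(theta[seq_len(hidden * d)], hidden, d)
  b1 <- theta[hidden * d + seq_len(hidden)]
  w2 <- theta[hidden * d + hidden + seq_len(hidden)]
  b2 <- theta[length(theta)]
  A <- tanh(sweep(xs %*% t(W1), 2, b1, "+"))
  list(yhat = as.numeric(A %*% w2 + b2), A = A, w2 = w2)
}

# Jacobian d yhat / d theta (n x K), same parameter layout as ann_forward.
ann_jacobian <- function(fw, xs, hidden) {
  n <- nrow(xs); d <- ncol(xs)
  G <- (1 - fw$A^2) * matrix(fw$w2, n, hidden, byrow = TRUE)  # n x H
  JW1 <- G[, rep(seq_len(hidden), times = d), drop = FALSE] *
    xs[, rep(seq_len(d), each = hidden), drop = FALSE]        # vec(W1)
  cbind(JW1, G, fw$A, rep(1, n))
}

#' Train a Bayesian-regularized feed-forward network
#'
#' Two-layer network (tanh hidden units, linear output) mapping
#' connectivity features to lesion size, trained by Levenberg-Marquardt
#' minimization of \eqn{\beta E_D + \alpha E_W} with evidence-framework
#' updates of the hyperparameters \eqn{\alpha, \beta} (MacKay): after each
#' accepted step the effective number of parameters
#' \eqn{\gamma = K - \alpha\,\mathrm{tr}(H^{-1})} updates
#' \eqn{\alpha = \gamma / 2E_W} and \eqn{\beta = (n - \gamma) / 2E_D}.
#' The Gauss-Newton curvature \eqn{H = \beta J^\top J + \alpha I} is
#' handled through the eigendecomposition of the small \eqn{J J^\top}, so
#' training cost scales with the number of subjects, not parameters.
#' Inputs are z-scored and targets min-max scaled to [-1, 1] using
#' training statistics.
#'
#' @param x feature matrix (subjects x features), >= 5 rows.
#' @param y numeric targets (e.g. fractional lesion volume).
#' @param hidden hidden-layer width (default 20).
#' @param rng_seed integer seed for weight initialization.
#' @param max_epochs epoch cap (default 1000).
#' @param mse_goal stop when training MSE (scaled targets) falls below
#'   this (default 1e-5).
#' @param warmup number of initial epochs of plain Levenberg-Marquardt
#'   before the evidence updates start; updating the hyperparameters while
#'   the weights are still near their small random initialization
#'   overestimates the prior precision and collapses the network.
#' @return an object of class \code{oic_ann}.
#' @export
train_ann <- function(x, y, hidden = 20, rng_seed = 1L, max_epochs = 1000,
                      mse_goal = 1e-5, warmup = 10) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  if (n < 5) stop("at least 5 training subjects are required")
  stopifnot(length(y) == n)
  ctr <- colMeans(x); scl <- apply(x, 2, sd); scl[scl == 0] <- 1
  xs <- scale(x, ctr, scl)
  yr <- range(y)
  ys <- if (diff(yr) > 0) 2 * (y - yr[1]) / diff(yr) - 1 else y - yr[1]
  d <- ncol(xs)
  K <- hidden * d + 2 * hidden + 1
  set.seed(as.integer(rng_seed))
  theta <- runif(K, -0.5, 0.5) / sqrt(d)
  # standard initialization: no weight penalty until the evidence update
  # has seen the first accepted step
  alpha <- 0; beta <- 1; mu <- 0.005
  fw <- ann_forward(theta, xs, hidden)
  e <- ys - fw$yhat
  ED <- sum(e^2) / 2; EW <- sum(theta^2) / 2
  Fobj <- beta * ED + alpha * EW
  gamma <- K
  epochs <- 0L
  for (epoch in seq_len(max_epochs)) {
    epochs <- epoch
    if (mean(e^2) <= mse_goal) break
    J <- ann_jacobian(fw, xs, hidden)
    g <- beta * drop(crossprod(J, e)) - alpha * theta
    eg <- eigen(tcrossprod(J), symmetric = TRUE)
    lam <- pmax(eg$values, 0)
    keep <- lam > 1e-12 * max(lam, 1)
    V <- crossprod(J, eg$vectors[, keep, drop = FALSE])
    V <- sweep(V, 2, sqrt(lam[keep]), "/")          # K x n' eigenvectors
    accepted <- FALSE
    while (mu <= 1e10) {
      a0 <- alpha + mu
      coef <- 1 / (a0 + beta * lam[keep]) - 1 / a0
      delta <- g / a0 + V %*% (coef * drop(crossprod(V, g)))
      th_new <- theta + drop(delta)
      fw_new <- ann_forward(th_new, xs, hidden)
      e_new <- ys - fw_new$yhat
      if (any(!is.finite(e_new)))
        stop("non-finite network output at epoch ", epoch,
             " (mu = ", mu, ", alpha = ", alpha, ", beta = ", beta, ")")
      ED_new <- sum(e_new^2) / 2; EW_new <- sum(th_new^2) / 2
      F_new <- beta * ED_new + alpha * EW_new
      if (F_new < Fobj) {
        theta <- th_new; fw <- fw_new; e <- e_new
        ED <- ED_new; EW <- EW_new
        mu <- max(mu * 0.1, 1e-20)
        accepted <- TRUE
        break
      }
      mu <- mu * 10
    }
    if (!accepted) break
    if (epoch <= warmup) next
    # evidence update on the accepted point; with alpha = 0 the prior is
    # flat and the effective parameter count is the rank of J
    gamma <- if (alpha > 0) {
      tr_hinv <- (K - sum(keep)) / alpha + sum(1 / (alpha + beta * lam[keep]))
      K - alpha * tr_hinv
    } else sum(keep)
    gamma <- min(max(gamma, 1e-3), K - 1e-3)
    if (EW > 0) alpha <- gamma / (2 * EW)
    if (ED > 0) beta <- max((n - gamma) / (2 * ED), 1e-8)
    Fobj <- beta * ED + alpha * EW
  }
  structure(list(theta = theta, hidden = hidden, center = ctr, scale = scl,
                 y_range = yr, epochs = epochs, mse = mean(e^2),
                 gamma = gamma, alpha = alpha, beta = beta,
                 feature_names = colnames(x)),
            class = "oic_ann")
}

#' @export
predict.oic_ann <- function(object, newdata, ...) {
  xs <- scale(as.matrix(newdata), object$center, object$scale)
  yhat <- ann_forward(object$theta, xs, object$hidden)$yhat
  yr <- object$y_range
  if (diff(yr) > 0) (yhat + 1) / 2 * diff(yr) + yr[1] else yhat + yr[1]
}

#' @export
print.oic_ann <- function(x, ...) {
  cat("<oic_ann> ", length(x$center), "-", x$hidden,
      "-1 network, Bayesian regularization: ", x$epochs,
      " epochs, training MSE ", signif(x$mse, 3),
      ", effective parameters ", signif(x$gamma, 4), "/",
      length(x$theta), "\n", sep = "")
  invisible(x)
}

#' Evaluate regression predictions on held-out subjects
#'
#' @param model an \code{oic_ann} (or any object with a \code{predict}
#'   method returning numeric predictions).
#' @param x_test,y_test held-out features and measured targets.
#' @return an object of class \code{regression_report} with \code{r}
#'   (Pearson correlation of predicted vs measured; NA with a note when
#'   the measured targets have zero variance), \code{rmsep} and the
#'   predictions.
#' @export
evaluate_ann <- function(model, x_test, y_test) {
  if (length(y_test) == 0) stop("test set is empty")
  pred <- predict(model, x_test)
  regression_report(pred, y_test)
}

regression_report <- function(pred, y, per_fold = NULL) {
  r <- if (length(y) >= 3 && sd(y) > 0 && sd(pred) > 0) cor(pred, y)
       else NA_real_
  note <- if (is.na(r)) "correlation undefined (zero-variance targets or predictions)"
          else NULL
  structure(list(r = r, rmsep = sqrt(mean((pred - y)^2)),
                 predictions = pred, targets = y, per_fold = per_fold,
                 note = note),
            class = "regression_report")
}

#' @export
print.regression_report <- function(x, ...) {
  cat("<regression_report> r = ", signif(x$r, 4), ", RMSEP = ",
      signif(x$rmsep, 4), " (n = ", length(x$targets), ")\n", sep = "")
  if (!is.null(x$note)) cat("  note: ", x$note, "\n", sep = "")
  invisible(x)
}

#' Cross-validated lesion-size prediction
#'
#' Rotates test folds over the cohort (each subject held out exactly once
#' per rotation), trains the Bayesian-regularized network on the remaining
#' subjects and pools the held-out predictions; r and RMSEP are computed
#' on the pooled predictions.
#'
#' @param x feature matrix (subjects x features).
#' @param y numeric targets.
#' @param k number of folds (default: one subject per fold when n <= 10).
#' @param rng_seed integer seed (fold shuffling and weight init).
#' @param ... passed to \code{\link{train_ann}}.
#' @return a \code{regression_report} with pooled held-out predictions.
#' @export
cross_validate_ann <- function(x, y, k = NULL, rng_seed = 1L, ...) {
  x <- as.matrix(x); y <- as.numeric(y)
  n <- nrow(x)
  if (is.null(k)) k <- if (n <= 10) n else 10
  set.seed(as.integer(rng_seed))
  fold <- sample(rep_len(seq_len(k), n))
  pred <- numeric(n)
  per_fold <- vector("list", k)
  for (f in seq_len(k)) {
    te <- fold == f
    model <- train_ann(x[!te, , drop = FALSE], y[!te],
                       rng_seed = derive_seed(rng_seed, f), ...)
    pred[te] <- predict(model, x[te, , drop = FALSE])
    per_fold[[f]] <- list(test = which(te), predictions = pred[te])
  }
  regression_report(pred, y, per_fold = per_fold)
}
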