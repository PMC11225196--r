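#' Fit a single-response OPLS(-DA) model
#'
#' Orthogonal projections to latent structures for a single response,
#' computed by the classical NIPALS-style algorithm: the predictive weight
#' vector is `w = X'y_c / ||X'y_c||` (with `y_c` the centered response); each
#' orthogonal component is extracted as `p = X't/(t't)` with `t = Xw`,
#' `w_o` proportional to `p - (w'p) w` (normalized), `t_o = X w_o`,
#' `p_o = X't_o/(t_o't_o)`, followed by deflation `X <- X - t_o p_o'`. After
#' removing `n_ortho` orthogonal components the predictive score is
#' `t1 = X w` and the response is regressed on it with the scalar
#' `b = t1'y_c/(t1't1)`. With `n_ortho = 0` the model coincides with a
#' one-component PLS1 fit.
#'
#' For discriminant use the response is the class coding CN = 0 /
#' disease = 1; the fitted value `y_mean + b * t1` is the continuous
#' severity index.
#'
#' @param x numeric matrix (subjects x features), column-centered and
#'   unit-variance scaled (see [fit_scaler()]).
#' @param y numeric response; for OPLS-DA a 0/1 class coding with both
#'   classes present.
#' @param n_ortho number of orthogonal components (default 1).
#' @return An object of class `opls`: list with `w`, `p1`, `b`, `y_mean`,
#'   `t1`, orthogonal `w_o`/`p_o`/`t_o` (matrices, one column per
#'   component), `fitted`, `R2Y`, `R2X` (share of X sum of squares captured
#'   by the predictive and orthogonal parts), `n_ortho`.
#' @examples
#' set.seed(1)
#' x <- scale(matrix(rnorm(40 * 5), 40, 5))
#' y <- rep(c(0, 1), each = 20)
#' x[, 1] <- x[, 1] + y          # planted class signal
#' fit <- opls(scale(x), y)
#' fit
#' @export
opls <- function(x, y, n_ortho = 1) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) stop("x and y dimensions disagree")
  if (nrow(x) < 4L) stop("need at least 4 observations")
  if (stats::sd(y) == 0) stop("constant y: both classes required")
  if (n_ortho < 0) stop("n_ortho must be >= 0")
  y_mean <- mean(y)
  yc <- y - y_mean
  wraw <- drop(crossprod(x, yc))
  w <- wraw / sqrt(sum(wraw^2))

  p <- ncol(x)
  w_o <- p_o <- matrix(0, p, 0)
  t_o <- matrix(0, nrow(x), 0)
  ss_x <- sum(x^2)
  xd <- x
  for (i in seq_len(n_ortho)) {
    tt <- drop(xd %*% w)
    pp <- drop(crossprod(xd, tt)) / sum(tt^2)
    wo <- pp - sum(w * pp) * w
    nwo <- sqrt(sum(wo^2))
    if (nwo < 1e-12) stop("n_ortho exceeds the orthogonal rank of x")
    wo <- wo / nwo
    to <- drop(xd %*% wo)
    po <- drop(crossprod(xd, to)) / sum(to^2)
    xd <- xd - tcrossprod(to, po)
    w_o <- cbind(w_o, wo)
    p_o <- cbind(p_o, po)
    t_o <- cbind(t_o, to)
  }
  t1 <- drop(xd %*% w)
  p1 <- drop(crossprod(xd, t1)) / sum(t1^2)
  b <- sum(t1 * yc) / sum(t1^2)
  fitted <- y_mean + b * t1
  ss_pred <- sum(t1^2) * sum(p1^2)
  ss_orth <- if (ncol(t_o)) sum(vapply(seq_len(ncol(t_o)), function(i) {
    sum(t_o[, i]^2) * sum(p_o[, i]^2)
  }, numeric(1))) else 0
  structure(list(
    w = stats::setNames(w, colnames(x)),
    p1 = stats::setNames(p1, colnames(x)),
    w_o = w_o, p_o = p_o, t_o = t_o,
    t1 = t1, b = b, y_mean = y_mean, n_ortho = n_ortho,
    fitted = fitted, y = y,
    R2Y = 1 - sum((y - fitted)^2) / sum(yc^2),
    R2X = c(predictive = ss_pred / ss_x, orthogonal = ss_orth / ss_x),
    ss_x = ss_x, ss_x_residual = sum((xd - tcrossprod(t1, p1))^2)
  ), class = "opls")
}

#' Project new subjects onto an OPLS model (severity index)
#'
#' Orthogonal variation is removed sequentially (`t_o = x w_o`; `x <- x -
#' t_o p_o'` for each stored pair), then the predictive score `t = x w`
#' yields the severity index `y_mean + b * t` — an unbounded real value,
#' nominally near [0, 1] for the CN = 0 / disease = 1 coding.
#'
#' @param object an [opls()] fit.
#' @param newdata numeric matrix scaled with the model's training scaler.
#' @param ... unused.
#' @return numeric vector of severity indices.
#' @export
predict.opls <- function(object, newdata, ...) {
  if (missing(newdata)) return(object$fitted)
  x <- as.matrix(newdata)
  if (ncol(x) != length(object$w)) {
    stop("feature-dimension mismatch: model has ", length(object$w),
         " features, newdata has ", ncol(x))
  }
  for (i in seq_len(object$n_ortho)) {
    to <- drop(x %*% object$w_o[, i])
    x <- x - tcrossprod(to, object$p_o[, i])
  }
  drop(object$y_mean + object$b * (x %*% object$w))
}

#' @export
fitted.opls <- function(object, ...) object$fitted

#' @export
residuals.opls <- function(object, ...) object$y - object$fitted

#' @export
coef.opls <- function(object, ...) object$w

#' @export
print.opls <- function(x, ...) {
  cat("OPLS model:", length(x$w), "features, 1 predictive +", x$n_ortho,
      "orthogonal component(s)\n")
  cat(sprintf("R2Y = %.3f | R2X(pred) = %.3f | R2X(orth) = %.3f\n",
              x$R2Y, x$R2X[["predictive"]], x$R2X[["orthogonal"]]))
  invisible(x)
}

#' @export
summary.opls <- function(object, ...) {
  top <- sort(abs(object$w), decreasing = TRUE)
  structure(list(model = object, top_weights = utils::head(top, 6)),
            class = "summary.opls")
}

#' @export
print.summary.opls <- function(x, ...) {
  print(x$model)
  cat("Largest |weights|:\n")
  print(round(x$top_weights, 3))
  invisible(x)
}

#' Score plot of an OPLS fit
#'
#' Plots the predictive score `t1` against the first orthogonal score
#' `to1` (or subject index when `n_ortho = 0`), colored by class.
#'
#' @param x an [opls()] fit.
#' @param ... passed to [graphics::plot()].
#' @export
plot.opls <- function(x, ...) {
  ycol <- ifelse(x$y > mean(range(x$y)), "firebrick", "steelblue")
  if (x$n_ortho >= 1) {
    graphics::plot(x$t1, x$t_o[, 1], col = ycol, pch = 19,
                   xlab = "t1 (predictive score)",
                   ylab = "to1 (orthogonal score)", ...)
  } else {
    graphics::plot(x$t1, col = ycol, pch = 19, xlab = "subject",
                   ylab = "t1 (predictive score)", ...)
  }
  invisible(x)
}

.stratified_folds <- function(y, k) {
  if (k == length(y)) return(seq_along(y))  # leave-one-out
  fold <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    if (length(idx) < 2L) {
      stop("class ", cl, " has fewer than 2 members; use smaller k")
    }
    fold[idx] <- sample(rep_len(sample(seq_len(k)), length(idx)))
  }
  fold
}

#' Cross-validated R2/Q2 for an OPLS model
#'
#' Stratified k-fold cross-validation. Within each fold the unit-variance
#' scaler (optional) and the OPLS model are refitted on the training split
#' only and held-out responses are predicted. `Q2 = 1 - PRESS/SS`, with the
#' total sum of squares taken about the full-sample response mean; `R2` is
#' the goodness of fit of the full-data model. By the usual convention a Q2
#' above 0.05 is regarded as significant and above 0.5 as a good model.
#'
#' @param x numeric feature matrix (unscaled if `scale = TRUE`).
#' @param y 0/1 class coding.
#' @param k folds (default 10); `k = n` gives deterministic leave-one-out
#'   (no stratification needed).
#' @param n_ortho orthogonal components.
#' @param seed integer seed for the fold assignment.
#' @param scale refit unit-variance scaling inside each fold (default TRUE).
#' @return An object of class `opls_cv`: list with `Q2`, `R2`, `k`, `folds`,
#'   `heldout` (cross-validated predictions) and `fit` (the full-data
#'   model).
#' @export
opls_cv <- function(x, y, k = 10, n_ortho = 1, seed = 1L, scale = TRUE) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  n <- length(y)
  if (k > n) stop("k cannot exceed n")
  if (min(table(y)) < 2) {
    stop("each class needs at least 2 members (one class has fewer than 2)")
  }
  set.seed(as.integer(seed))
  folds <- .stratified_folds(y, k)
  heldout <- numeric(n)
  for (f in seq_len(k)) {
    tr <- folds != f
    if (!any(folds == f)) next
    if (stats::sd(y[tr]) == 0) {
      stop("a fold lost a class during stratification; use smaller k")
    }
    xtr <- x[tr, , drop = FALSE]
    xte <- x[!tr, , drop = FALSE]
    if (scale) {
      ctr <- colMeans(xtr)
      sc <- apply(xtr, 2, stats::sd)
      sc[sc == 0] <- 1
      xtr <- sweep(sweep(xtr, 2, ctr), 2, sc, "/")
      xte <- sweep(sweep(xte, 2, ctr), 2, sc, "/")
    }
    fit <- opls(xtr, y[tr], n_ortho = n_ortho)
    heldout[!tr] <- predict(fit, xte)
  }
  xs <- if (scale) base::scale(x) else x
  full <- opls(xs, y, n_ortho = n_ortho)
  ssy <- sum((y - mean(y))^2)
  structure(list(Q2 = 1 - sum((y - heldout)^2) / ssy,
                 R2 = full$R2Y, k = k, folds = folds,
                 heldout = heldout, fit = full, seed = as.integer(seed)),
            class = "opls_cv")
}

#' @export
print.opls_cv <- function(x, ...) {
  cat(sprintf("%d-fold cross-validated OPLS: R2 = %.3f, Q2 = %.3f\n",
              x$k, x$R2, x$Q2))
  invisible(x)
}

#' Permutation comparison of R2/Q2
#'
#' Refits the model (full fit for R2, cross-validation for Q2) under random
#' permutations of the class labels while the feature data stay intact, and
#' reports empirical one-sided p-values `(1 + #\{perm >= observed\}) /
#' (1 + n_perm)` for the observed statistics.
#'
#' @inheritParams opls_cv
#' @param n_perm number of label permutations (>= 10; default 100).
#' @return An object of class `opls_permutation`: list with `observed`
#'   (`R2`, `Q2`), `permuted` (data.frame of permuted `R2`/`Q2`),
#'   `p_R2`, `p_Q2`, `n_perm`, `seed`.
#' @export
opls_permutation <- function(x, y, n_perm = 100, k = 10, n_ortho = 1,
                             seed = 1L, scale = TRUE) {
  if (n_perm < 10) stop("n_perm must be >= 10")
  obs <- opls_cv(x, y, k = k, n_ortho = n_ortho, seed = seed, scale = scale)
  set.seed(as.integer(seed) + 1L)
  perms <- replicate(n_perm, sample(y))
  res <- apply(perms, 2, function(yp) {
    cv <- opls_cv(x, yp, k = k, n_ortho = n_ortho,
                  seed = sample.int(.Machine$integer.max, 1), scale = scale)
    c(R2 = cv$R2, Q2 = cv$Q2)
  })
  permuted <- as.data.frame(t(res))
  structure(list(observed = c(R2 = obs$R2, Q2 = obs$Q2),
                 permuted = permuted,
                 p_R2 = (1 + sum(permuted$R2 >= obs$R2)) / (1 + n_perm),
                 p_Q2 = (1 + sum(permuted$Q2 >= obs$Q2)) / (1 + n_perm),
                 n_perm = n_perm, seed = as.integer(seed)),
            class = "opls_permutation")
}

#' @export
print.opls_permutation <- function(x, ...) {
  cat(sprintf("Permutation comparison (%d permutations):\n", x$n_perm))
  cat(sprintf("  observed R2 = %.3f (p = %.3g), Q2 = %.3f (p = %.3g)\n",
              x$observed["R2"], x$p_R2, x$observed["Q2"], x$p_Q2))
  invisible(x)
}
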