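#' Two-class OPLS-DA by NIPALS
#'
#' Orthogonal partial least squares discriminant analysis for a two-class
#' design, fitted from scratch. The raw intensity matrix is log2
#' transformed and column-mean centered internally (no unit-variance or
#' Pareto scaling by default); the class labels are coded -1/+1 and
#' centered. Y-uncorrelated (orthogonal) X-variation is removed by
#' successive orthogonal components before a single predictive component is
#' fitted, so the predictive scores separate the classes while the
#' orthogonal scores capture within-class structure.
#'
#' With `n_ortho = 0` the model reduces exactly to one-component PLS1.
#' Predictive scores are oriented so the second class level has positive
#' mean score.
#'
#' @param X Numeric matrix, samples in rows, features in columns.
#' @param y Two-level class vector (factor, character, or numeric with two
#'   distinct values), one entry per row of `X`.
#' @param n_ortho Number of orthogonal components to strip (default 1).
#' @param log2_transform Log2-transform `X` before centering (requires
#'   positive values). Set `FALSE` if `X` is already on a log scale.
#' @param scaling `"center"` (default), `"uv"` (unit variance) or
#'   `"pareto"`; applied after the log transform.
#'
#' @return An object of class `opls_model` with elements `weights`
#'   (predictive weight vector, unit norm), `scores`, `loadings`, `c_coef`,
#'   `ortho_weights`, `ortho_scores`, `ortho_loadings`, `R2Y`, `R2X`
#'   (named explained-X fractions per component), `vip`, `levels`,
#'   `features`, `dropped`, plus the preprocessing state needed for
#'   prediction.
#' @examples
#' sim <- simulate_metabolome(study_design(), n_features = 60,
#'   n_flavonoids = 20,
#'   planted = planted_spec(list(MvsN = c(up = 8, down = 4))))
#' sub <- sim$groups$group %in% c("M", "N")
#' m <- fit_opls(t(sim$matrix[, sub]), sim$groups$group[sub])
#' m$R2Y
#' @export
fit_opls <- function(X, y, n_ortho = 1L, log2_transform = TRUE,
                     scaling = c("center", "uv", "pareto")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("feat_", seq_len(ncol(X)))
  y <- as.character(y)
  lev <- unique(y)
  if (length(lev) != 2L) {
    stop("y must contain exactly two classes", call. = FALSE)
  }
  if (length(y) != nrow(X)) stop("length(y) must match nrow(X)", call. = FALSE)
  if (any(table(y) < 2L)) {
    stop("each class needs at least two samples", call. = FALSE)
  }
  y_num <- ifelse(y == lev[2], 1, -1)
  yc <- y_num - mean(y_num)

  if (log2_transform) {
    if (any(X <= 0)) {
      stop("log2 transform requires strictly positive intensities",
           call. = FALSE)
    }
    X <- log2(X)
  }
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  sdv <- apply(Xc, 2, stats::sd)
  const <- sdv == 0
  if (any(const)) {
    warning(sum(const), " constant feature column(s) dropped")
    Xc <- Xc[, !const, drop = FALSE]
    sdv <- sdv[!const]
  }
  if (ncol(Xc) == 0L) stop("no non-constant features left", call. = FALSE)
  scale_div <- switch(scaling, center = rep(1, ncol(Xc)),
                      uv = sdv, pareto = sqrt(sdv))
  Xc <- sweep(Xc, 2, scale_div, "/")
  ssx_total <- sum(Xc^2)

  # orthogonal-component filtering (OSC step of O-PLS)
  p_feat <- ncol(Xc)
  Wo <- matrix(0, p_feat, 0)
  Po <- matrix(0, p_feat, 0)
  To <- matrix(0, nrow(Xc), 0)
  r2x_ortho <- numeric(0)
  Xf <- Xc
  for (a in seq_len(n_ortho)) {
    w <- drop(crossprod(Xf, yc))
    w <- w / sqrt(sum(w^2))
    t_p <- drop(Xf %*% w)
    p <- drop(crossprod(Xf, t_p)) / sum(t_p^2)
    w_o <- p - sum(w * p) * w
    nw <- sqrt(sum(w_o^2))
    if (nw < 1e-12) break  # no y-orthogonal variation left
    w_o <- w_o / nw
    t_o <- drop(Xf %*% w_o)
    p_o <- drop(crossprod(Xf, t_o)) / sum(t_o^2)
    Xf <- Xf - tcrossprod(t_o, p_o)
    Wo <- cbind(Wo, w_o); Po <- cbind(Po, p_o); To <- cbind(To, t_o)
    r2x_ortho <- c(r2x_ortho, sum(tcrossprod(t_o, p_o)^2) / ssx_total)
  }

  # single predictive PLS1 component on the filtered matrix
  w <- drop(crossprod(Xf, yc))
  nw <- sqrt(sum(w^2))
  if (nw < 1e-12) stop("no covariance between X and y", call. = FALSE)
  w <- w / nw
  t_p <- drop(Xf %*% w)
  p <- drop(crossprod(Xf, t_p)) / sum(t_p^2)
  c_coef <- sum(yc * t_p) / sum(t_p^2)
  if (mean(t_p[y == lev[2]]) < 0) {  # sign convention
    w <- -w; t_p <- -t_p; p <- -p; c_coef <- -c_coef
  }
  y_hat <- t_p * c_coef
  r2y <- 1 - sum((yc - y_hat)^2) / sum(yc^2)
  r2x_pred <- sum(tcrossprod(t_p, p)^2) / ssx_total

  vip <- sqrt(p_feat) * abs(w)  # one predictive component: SSY weights cancel
  names(vip) <- colnames(Xc)

  structure(
    list(weights = stats::setNames(w, colnames(Xc)),
         scores = t_p,
         loadings = stats::setNames(p, colnames(Xc)),
         c_coef = c_coef,
         ortho_weights = Wo, ortho_loadings = Po, ortho_scores = To,
         R2Y = r2y,
         R2X = c(predictive = r2x_pred,
                 if (length(r2x_ortho))
                   stats::setNames(r2x_ortho,
                                   paste0("orthogonal",
                                          seq_along(r2x_ortho)))),
         vip = vip,
         levels = lev, y = y, y_num = y_num,
         features = colnames(Xc), dropped = names(const)[const],
         center = mu, scale_div = scale_div,
         log2_transform = log2_transform, scaling = scaling,
         n_ortho = ncol(Wo)),
    class = "opls_model"
  )
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf(
    "OPLS-DA model (%s vs %s): 1 predictive + %d orthogonal component(s)\n",
    x$levels[1], x$levels[2], x$n_ortho))
  cat(sprintf("  R2Y = %.3f; R2X: %s\n", x$R2Y,
              paste(sprintf("%s %.1f%%", names(x$R2X), 100 * x$R2X),
                    collapse = ", ")))
  invisible(x)
}

# predict class scores for new samples with a fitted model's
# preprocessing, orthogonal filter and predictive component
predict_opls <- function(model, Xnew) {
  Xnew <- as.matrix(Xnew)
  if (is.null(colnames(Xnew))) {
    colnames(Xnew) <- paste0("feat_", seq_len(ncol(Xnew)))
  }
  if (model$log2_transform) Xnew <- log2(Xnew)
  Xnew <- Xnew[, names(model$center), drop = FALSE]
  Xc <- sweep(Xnew, 2, model$center)
  Xc <- Xc[, model$features, drop = FALSE]
  Xc <- sweep(Xc, 2, model$scale_div, "/")
  if (model$n_ortho > 0) {
    for (a in seq_len(model$n_ortho)) {
      t_o <- drop(Xc %*% model$ortho_weights[, a])
      Xc <- Xc - tcrossprod(t_o, model$ortho_loadings[, a])
    }
  }
  t_p <- drop(Xc %*% model$weights)
  mean(model$y_num) + t_p * model$c_coef
}

#' Cross-validated Q2 of an OPLS-DA model
#'
#' Q2 = 1 - PRESS/TSS over held-out class predictions, the standard
#' predictive-ability statistic of latent-variable models. Folds are
#' stratified by class; when `folds` exceeds the number of samples the
#' procedure falls back to leave-one-out (the usual situation with n = 3
#' replicates per class). Preprocessing, the orthogonal filter and the
#' predictive component are all re-estimated inside each training fold.
#'
#' @inheritParams fit_opls
#' @param folds Number of cross-validation folds (default 7).
#' @param seed Integer seed for the fold assignment.
#' @return Numeric Q2 (at most 1; negative when the model predicts worse
#'   than the class mean).
#' @export
cross_validated_q2 <- function(X, y, n_ortho = 1L, folds = 7L, seed = 1L,
                               log2_transform = TRUE,
                               scaling = c("center", "uv", "pareto")) {
  scaling <- match.arg(scaling)
  X <- as.matrix(X)
  y <- as.character(y)
  n <- nrow(X)
  if (folds < 2L) stop("folds must be at least 2", call. = FALSE)
  if (folds > n) {
    message("folds > n samples; falling back to leave-one-out")
    folds <- n
  }
  lev <- unique(y)
  if (length(lev) != 2L) stop("y must have two classes", call. = FALSE)
  y_num <- ifelse(y == lev[2], 1, -1)

  set.seed(child_seed(seed, "cv_folds"))
  # stratified dealing: shuffle within class, then deal class blocks
  # consecutively across folds so every fold stays class-balanced and
  # folds = n reduces exactly to leave-one-out
  order_idx <- unlist(lapply(lev, function(cl) sample(which(y == cl))))
  fold_id <- integer(n)
  fold_id[order_idx] <- rep(seq_len(folds), length.out = n)
  press <- 0
  for (k in seq_len(folds)) {
    test <- which(fold_id == k)
    if (length(test) == 0L) next
    train <- setdiff(seq_len(n), test)
    if (length(unique(y[train])) < 2L) {
      stop("training fold with a single class; reduce folds", call. = FALSE)
    }
    m <- fit_opls(X[train, , drop = FALSE], y[train], n_ortho = n_ortho,
                  log2_transform = log2_transform, scaling = scaling)
    # keep the -1/+1 coding aligned with the full-data level order
    pred <- predict_opls(m, X[test, , drop = FALSE])
    if (!identical(m$levels, lev)) pred <- -pred
    press <- press + sum((y_num[test] - pred)^2)
  }
  tss <- sum((y_num - mean(y_num))^2)
  1 - press / tss
}

#' Variable importance in projection (VIP)
#'
#' Per-feature VIP scores over the predictive component of a fitted
#' OPLS-DA model: VIP_j = sqrt(p) * |w_j| with the unit-norm predictive
#' weight vector w, so that the mean squared VIP equals 1
#' (sum(VIP^2) = number of features). Features with VIP > 1 contribute
#' more than average to the class separation.
#'
#' @param model A fitted [fit_opls()] model.
#' @return Named numeric vector of VIP scores.
#' @export
compute_vip <- function(model) {
  if (!inherits(model, "opls_model")) {
    stop("compute_vip requires a fitted opls_model", call. = FALSE)
  }
  model$vip
}

#' Model validity verdict from Q2
#'
#' A latent-variable discriminant model is treated as valid when its
#' cross-validated Q2 strictly exceeds the threshold (default 0.5).
#'
#' @param q2 Cross-validated Q2 statistic.
#' @param threshold Validity threshold (default 0.5, strict inequality).
#' @return A list `valid` (logical), `q2`, `threshold`.
#' @examples
#' validate_model(0.7)$valid    # TRUE
#' validate_model(0.5)$valid    # FALSE (strict)
#' @export
validate_model <- function(q2, threshold = 0.5) {
  if (!is.numeric(q2) || length(q2) != 1L) {
    stop("q2 must be a single number", call. = FALSE)
  }
  list(valid = is.finite(q2) && q2 > threshold, q2 = q2,
       threshold = threshold)
}
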