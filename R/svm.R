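# Gaussian-kernel support vector machine.
#
# No SVM library ships with the offline stack, so a compact sequential
# minimal optimization (SMO) solver is implemented here: soft-margin
# C-SVM, RBF kernel exp(-gamma * ||x - y||^2), with the second working
# variable chosen by maximal error difference. Posterior probabilities are
# obtained by a Platt-style sigmoid fit on the training decision values.

rbf_kernel <- function(x, y = x, gamma) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  d2 <- outer(rowSums(x^2), rowSums(y^2), "+") - 2 * tcrossprod(x, y)
  d2[d2 < 0] <- 0
  exp(-gamma * d2)
}

# median heuristic for the kernel width on (standardized) training data
median_gamma <- function(x, max_n = 500L) {
  x <- as.matrix(x)
  n <- nrow(x)
  idx <- if (n > max_n) round(seq(1, n, length.out = max_n)) else seq_len(n)
  d2 <- stats::dist(x[idx, , drop = FALSE])^2
  md <- stats::median(d2[d2 > 0])
  if (!is.finite(md) || md <= 0) md <- 1
  1 / (2 * md)
}

# Platt (1999) sigmoid fit: P(y=1|f) = 1/(1 + exp(A f + B)), smoothed
# targets, fitted by Newton iterations with backtracking.
fit_platt <- function(f, y) {
  n_pos <- sum(y > 0)
  n_neg <- sum(y <= 0)
  t <- ifelse(y > 0, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  obj <- function(ab) {
    z <- ab[1] * f + ab[2]
    p <- 1 / (1 + exp(z))
    eps <- 1e-12
    -sum(t * log(pmax(p, eps)) + (1 - t) * log(pmax(1 - p, eps)))
  }
  res <- stats::optim(c(A = 0, B = log((n_neg + 1) / (n_pos + 1))), obj,
                      method = "BFGS", control = list(maxit = 200))
  res$par
}

platt_prob <- function(f, ab) 1 / (1 + exp(ab[1] * f + ab[2]))

# SMO solver (Platt-style with error cache and deterministic second-choice
# fallbacks). y in {-1, +1}. Returns alpha and bias b for
# f(x) = sum(alpha_i y_i K(x_i, x)) + b.
smo_solve <- function(K, y, C = 1, tol = 1e-3, max_passes = 500) {
  n <- length(y)
  alpha <- numeric(n)
  b <- 0
  fx <- numeric(n)          # decision values without bias
  err <- fx + b - y         # error cache

  take_step <- function(i, j) {
    if (i == j) return(FALSE)
    Ei <- err[i]; Ej <- err[j]
    ai_old <- alpha[i]; aj_old <- alpha[j]
    if (y[i] != y[j]) {
      L <- max(0, aj_old - ai_old); H <- min(C, C + aj_old - ai_old)
    } else {
      L <- max(0, ai_old + aj_old - C); H <- min(C, ai_old + aj_old)
    }
    if (L >= H) return(FALSE)
    eta <- 2 * K[i, j] - K[i, i] - K[j, j]
    if (eta >= -1e-12) return(FALSE)
    aj <- aj_old - y[j] * (Ei - Ej) / eta
    aj <- min(max(aj, L), H)
    if (abs(aj - aj_old) < 1e-8 * (aj + aj_old + 1e-8)) return(FALSE)
    ai <- ai_old + y[i] * y[j] * (aj_old - aj)
    b1 <- b - Ei - y[i] * (ai - ai_old) * K[i, i] - y[j] * (aj - aj_old) * K[i, j]
    b2 <- b - Ej - y[i] * (ai - ai_old) * K[i, j] - y[j] * (aj - aj_old) * K[j, j]
    b_new <- if (ai > 0 && ai < C) b1
      else if (aj > 0 && aj < C) b2
      else (b1 + b2) / 2
    fx <<- fx + y[i] * (ai - ai_old) * K[, i] + y[j] * (aj - aj_old) * K[, j]
    alpha[i] <<- ai
    alpha[j] <<- aj
    b <<- b_new
    err <<- fx + b_new - y
    TRUE
  }

  examine <- function(i) {
    Ei <- err[i]
    r <- Ei * y[i]
    if (!((r < -tol && alpha[i] < C) || (r > tol && alpha[i] > 0))) return(FALSE)
    # second-choice heuristic, then non-bound sweep, then full sweep
    j <- which.max(abs(err - Ei))
    if (take_step(i, j)) return(TRUE)
    nb <- which(alpha > 0 & alpha < C)
    for (j in nb) if (take_step(i, j)) return(TRUE)
    for (j in seq_len(n)) if (take_step(i, j)) return(TRUE)
    FALSE
  }

  passes <- 0
  examine_all <- TRUE
  repeat {
    changed <- 0L
    idx_set <- if (examine_all) seq_len(n) else which(alpha > 0 & alpha < C)
    for (i in idx_set) changed <- changed + examine(i)
    passes <- passes + 1
    if (passes >= max_passes) break
    if (examine_all) {
      if (changed == 0L) break
      examine_all <- FALSE
    } else if (changed == 0L) {
      examine_all <- TRUE
    }
  }
  list(alpha = alpha, b = b)
}

#' Train the Gaussian-kernel walking classifier
#'
#' Standardizes the selected features (statistics from the training data
#' only), solves the soft-margin SVM by SMO, and calibrates posterior
#' probabilities with a Platt sigmoid on the training decision values.
#'
#' @param x Data frame or matrix of features.
#' @param labels Binary labels; the positive ("walking") class is
#'   identified by `positive`.
#' @param feature_subset Feature names to use (default: all columns).
#' @param positive Positive class label (default `"walk"`).
#' @param C Soft-margin cost (default 1).
#' @param gamma RBF width; default is the median-squared-distance
#'   heuristic on the standardized training data.
#' @param prob_threshold Posterior threshold stored with the model
#'   (default 0.8, the published operating point).
#' @return An object of class `walk_classifier`.
#' @export
train_classifier <- function(x, labels, feature_subset = NULL,
                             positive = "walk", C = 1, gamma = NULL,
                             prob_threshold = 0.8) {
  x <- as.data.frame(x)
  if (is.null(feature_subset)) feature_subset <- names(x)
  stopifnot(all(feature_subset %in% names(x)))
  y <- ifelse(labels == positive, 1, -1)
  if (length(unique(y)) < 2) stop("training error: single-class input", call. = FALSE)
  xm <- as.matrix(x[, feature_subset, drop = FALSE])
  ctr <- colMeans(xm)
  scl <- apply(xm, 2, stats::sd)
  scl[scl == 0] <- 1
  xs <- scale(xm, center = ctr, scale = scl)
  if (is.null(gamma)) gamma <- median_gamma(xs)
  K <- rbf_kernel(xs, gamma = gamma)
  fit <- smo_solve(K, y, C = C)
  sv <- which(fit$alpha > 1e-8)
  f_train <- drop(K %*% (fit$alpha * y)) + fit$b
  platt <- fit_platt(f_train, y)
  structure(
    list(selected_features = feature_subset, positive = positive,
         center = ctr, scale = scl, gamma = gamma, C = C,
         sv_x = xs[sv, , drop = FALSE], sv_coef = (fit$alpha * y)[sv],
         b = fit$b, platt = platt, prob_threshold = prob_threshold,
         version = 1L),
    class = "walk_classifier"
  )
}

#' Predict walking posteriors
#'
#' @param object A `walk_classifier`.
#' @param newdata Data frame containing the model's features.
#' @param ... Unused.
#' @return Data frame with decision `score`, posterior `prob` of the
#'   positive class, and hard `label`.
#' @export
predict.walk_classifier <- function(object, newdata, ...) {
  xm <- as.matrix(as.data.frame(newdata)[, object$selected_features, drop = FALSE])
  xs <- scale(xm, center = object$center, scale = object$scale)
  Kp <- rbf_kernel(xs, object$sv_x, gamma = object$gamma)
  f <- drop(Kp %*% object$sv_coef) + object$b
  prob <- platt_prob(f, object$platt)
  data.frame(score = f, prob = prob,
             label = ifelse(f > 0, object$positive, paste0("not_", object$positive)))
}

#' @export
print.walk_classifier <- function(x, ...) {
  cat(sprintf("<walk_classifier> %d SVs, gamma=%.4g, C=%g, threshold=%.2f\n",
              nrow(x$sv_x), x$gamma, x$C, x$prob_threshold))
  cat("features:", paste(x$selected_features, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize / restore a trained classifier
#'
#' Versioned JSON representation; numeric payloads are written at full
#' precision.
#'
#' @param model A `walk_classifier`.
#' @param path File path.
#' @return `path` (write) or the restored `walk_classifier` (read).
#' @export
write_classifier <- function(model, path) {
  payload <- unclass(model)
  payload$sv_x <- list(dim = dim(model$sv_x), data = as.numeric(model$sv_x))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_classifier
#' @export
read_classifier <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  p$sv_x <- matrix(p$sv_x$data, nrow = p$sv_x$dim[1], ncol = p$sv_x$dim[2])
  colnames(p$sv_x) <- p$selected_features
  p$center <- stats::setNames(as.numeric(p$center), p$selected_features)
  p$scale <- stats::setNames(as.numeric(p$scale), p$selected_features)
  p$platt <- as.numeric(p$platt)
  structure(p, class = "walk_classifier")
}
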