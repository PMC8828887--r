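#' Bayesian ridge regression by evidence maximisation
#'
#' Linear regression with a zero-mean Gaussian prior on the coefficients.
#' The noise precision `alpha` and prior precision `lambda` are estimated by
#' maximising the marginal likelihood (MacKay fixed-point updates) with
#' conjugate Gamma hyperpriors of shape/rate 1e-6, so no penalty needs to be
#' chosen by hand. Predictors and response are centred internally; the
#' intercept is recovered afterwards.
#'
#' @param X numeric predictor matrix (n x p), no missing entries.
#' @param y numeric response vector, no missing entries.
#' @param max_iter maximum fixed-point iterations.
#' @param tol convergence tolerance on the coefficient vector.
#' @param hyper shape/rate of the Gamma hyperpriors on both precisions.
#' @return object of class `bayes_ridge` with elements `coef`, `intercept`,
#'   `alpha`, `lambda`, `n_iter`.
#' @examples
#' x <- matrix(rnorm(200), 100, 2)
#' fit <- bayes_ridge(x, 1 + x %*% c(2, -1) + rnorm(100, sd = 0.1))
#' predict(fit, x[1:3, ])
#' @export
bayes_ridge <- function(X, y, max_iter = 300, tol = 1e-4, hyper = 1e-6) {
  X <- as.matrix(X)
  stopifnot(nrow(X) == length(y), !anyNA(X), !anyNA(y))
  n <- nrow(X); p <- ncol(X)
  xbar <- colMeans(X); ybar <- mean(y)
  Xc <- sweep(X, 2, xbar)
  yc <- y - ybar
  XtX <- crossprod(Xc)
  Xty <- crossprod(Xc, yc)
  eig <- eigen(XtX, symmetric = TRUE, only.values = TRUE)$values
  eig <- pmax(eig, 0)
  vy <- stats::var(yc)
  alpha <- if (is.finite(vy) && vy > 0) 1 / vy else 1
  lambda <- 1
  w <- rep(0, p)
  n_iter <- 0L
  for (it in seq_len(max_iter)) {
    A <- XtX * alpha
    diag(A) <- diag(A) + lambda
    w_new <- drop(solve(A, alpha * Xty))
    gamma <- sum(alpha * eig / (lambda + alpha * eig))
    rss <- sum((yc - Xc %*% w_new)^2)
    lambda <- (gamma + 2 * hyper) / (sum(w_new^2) + 2 * hyper)
    alpha <- (n - gamma + 2 * hyper) / (rss + 2 * hyper)
    n_iter <- it
    if (max(abs(w_new - w)) < tol) { w <- w_new; break }
    w <- w_new
  }
  structure(list(coef = w, intercept = ybar - sum(xbar * w),
                 alpha = alpha, lambda = lambda, n_iter = n_iter),
            class = "bayes_ridge")
}

#' @rdname bayes_ridge
#' @param object a fitted `bayes_ridge` model.
#' @param newdata numeric matrix of predictors.
#' @param ... unused.
#' @export
predict.bayes_ridge <- function(object, newdata, ...) {
  drop(as.matrix(newdata) %*% object$coef) + object$intercept
}
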