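## Detection classifiers: ridge-regularized logistic regression (Newton /
## IRLS, written out so the optimum is verifiable against the penalized
## likelihood gradient) and gradient-boosted trees via the xgboost backend.

#' Fit a ridge-regularized logistic classifier
#'
#' Maximizes the Bernoulli log-likelihood of
#' \eqn{P(y=1|x,\omega) = 1/(1+e^{-\omega^T x})} minus
#' \eqn{\frac{\lambda}{2}\|\omega_{-0}\|^2} (the intercept is not
#' penalized) by Newton iterations. The ridge keeps the optimum finite
#' under complete separation; a warning is emitted when separation is
#' detected.
#'
#' @param X numeric matrix, samples x features.
#' @param y binary labels (0/1 or logical).
#' @param lambda ridge penalty (default 1e-4).
#' @param maxIter,tol Newton iteration controls; convergence is declared
#'   when the gradient norm falls below \code{tol}.
#' @return A \linkS4class{LogisticModel}.
#' @export
fitLogistic <- function(X, y, lambda = 1e-4, maxIter = 100L, tol = 1e-8) {
  X <- as.matrix(X)
  y <- as.numeric(as.logical(y) | y == 1)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  X1 <- cbind(1, X)
  p1 <- ncol(X1)
  R <- c(0, rep(lambda, p1 - 1L))
  w <- numeric(p1)
  converged <- FALSE
  it <- 0L
  for (it in seq_len(maxIter)) {
    eta <- drop(X1 %*% w)
    mu <- 1 / (1 + exp(-eta))
    g <- drop(crossprod(X1, y - mu)) - R * w
    if (sqrt(sum(g^2)) < tol) { converged <- TRUE; break }
    wts <- pmax(mu * (1 - mu), 1e-10)
    H <- crossprod(X1 * wts, X1)
    diag(H) <- diag(H) + R + 1e-12
    step <- solve(H, g)
    # halve the step until the penalized log-likelihood does not decrease
    ll <- function(w) {
      eta <- drop(X1 %*% w)
      sum(y * eta - log1p(exp(eta))) - sum(R * w^2) / 2
    }
    ll0 <- ll(w)
    alpha <- 1
    repeat {
      wNew <- w + alpha * step
      if (ll(wNew) >= ll0 - 1e-12 || alpha < 1e-8) break
      alpha <- alpha / 2
    }
    w <- wNew
  }
  if (max(abs(w[-1])) > 1e3 / max(lambda, 1e-12) * 1e-4)
    warning("very large coefficients; data may be separable")
  new("LogisticModel", coefficients = setNames(w, c("(Intercept)",
      colnames(X1)[-1])), lambda = lambda, converged = converged,
      iterations = it)
}

#' Predicted class-1 probabilities of a logistic model
#'
#' @param model a \linkS4class{LogisticModel}.
#' @param X numeric matrix with the fitted number of features.
#' @return numeric vector in (0, 1).
#' @export
predictProb <- function(model, X) {
  X <- as.matrix(X)
  eta <- drop(cbind(1, X) %*% model@coefficients)
  1 / (1 + exp(-eta))
}

#' Fit gradient-boosted trees
#'
#' Thin seeded wrapper around the xgboost backend with a binary logistic
#' objective and single-threaded, deterministic training.
#'
#' @param X numeric matrix, samples x features.
#' @param y binary labels.
#' @param nrounds boosting rounds.
#' @param maxDepth,eta tree depth and learning rate.
#' @param seed RNG seed.
#' @param ... further xgboost parameters.
#' @return An \code{xgb.Booster}.
#' @export
fitBoostedTrees <- function(X, y, nrounds = 50L, maxDepth = 3L, eta = 0.3,
                            seed = 1L, ...) {
  y <- as.numeric(as.logical(y) | y == 1)
  if (length(unique(y)) < 2L) stop("both classes must be present")
  X <- as.matrix(X)
  dtrain <- xgboost::xgb.DMatrix(X, label = y, nthread = 1)
  withSeed(seed, {
    xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = maxDepth,
                    eta = eta, nthread = 1, ...),
      data = dtrain, nrounds = nrounds, verbose = 0)
  })
}

## internal uniform classifier interface used by WFSS and nested CV

.trainClf <- function(spec, X, y, seed = 1L) {
  X <- as.matrix(X)
  hp <- spec$hyperParams
  if (is.null(hp)) hp <- list()
  if (spec$name == "logistic") {
    mu <- colMeans(X)
    sg <- apply(X, 2, sd)
    sg[sg == 0] <- 1
    Xs <- sweep(sweep(X, 2, mu), 2, sg, "/")
    lambda <- if (!is.null(hp$lambda)) hp$lambda else 1e-4
    list(kind = "logistic", model = fitLogistic(Xs, y, lambda = lambda),
         mu = mu, sg = sg)
  } else if (spec$name == "xgboost") {
    args <- c(list(X = X, y = y, seed = seed), hp)
    list(kind = "xgboost", model = do.call(fitBoostedTrees, args))
  } else stop("unknown classifier: ", spec$name)
}

.predictClf <- function(fit, X) {
  X <- as.matrix(X)
  if (fit$kind == "logistic") {
    Xs <- sweep(sweep(X, 2, fit$mu), 2, fit$sg, "/")
    as.integer(predictProb(fit$model, Xs) > 0.5)
  } else {
    d <- xgboost::xgb.DMatrix(X, nthread = 1)
    as.integer(predict(fit$model, d) > 0.5)
  }
}
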