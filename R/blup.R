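#' Code and impute a dosage matrix for ridge regression
#'
#' Markers with more than \code{max_missing} missing calls (strictly) are
#' removed; remaining dosages 0/1/2 are recoded to -1/0/+1 (0 the
#' heterozygote) and missing entries are replaced by the column mean of the
#' coded values.
#'
#' @param genotypes Samples x markers dosage matrix (NA missing).
#' @param max_missing Maximum tolerated missing fraction per marker.
#' @return List with \code{X} (coded, imputed numeric matrix) and
#'   \code{markers} (retained marker names).
#' @export
prepare_matrix <- function(genotypes, max_missing = 0.5) {
  miss <- colMeans(is.na(genotypes))
  keep <- miss <= max_missing
  if (!any(keep)) stop("all markers exceed the missingness threshold")
  X <- genotypes[, keep, drop = FALSE] - 1
  for (j in which(colSums(is.na(X)) > 0L)) {
    mu <- mean(X[, j], na.rm = TRUE)
    X[is.na(X[, j]), j] <- mu
  }
  storage.mode(X) <- "double"
  list(X = X, markers = colnames(genotypes)[keep])
}

#' Random training/holdout split
#'
#' @param ids Sample identifiers.
#' @param fraction Training fraction; the training size is
#'   \code{round(fraction * n)}.
#' @param seed Integer seed (same seed, same split).
#' @return List with \code{training} and \code{holdout} id vectors.
#' @export
train_split <- function(ids, fraction = 0.6, seed = 1L) {
  n <- length(ids)
  if (n < 5L) stop("at least 5 samples are required")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  set.seed(seed)
  take <- sample.int(n, round(fraction * n))
  list(training = ids[take], holdout = ids[-take])
}

#' Ridge-regression BLUP of marker effects
#'
#' Fits \eqn{y = \mu 1 + X g + e} with \eqn{g \sim N(0, \sigma_g^2 I)} and
#' \eqn{e \sim N(0, \sigma_e^2 I)}. Variance components are estimated by
#' REML through the spectral decomposition of \eqn{K = XX'} (single random
#' effect, so the profiled restricted likelihood is a one-dimensional
#' function of \eqn{\lambda = \sigma_e^2/\sigma_g^2}); \eqn{\mu} is the
#' generalized-least-squares intercept and the effects are the equivalent
#' dual-form ridge solution \eqn{\hat g = X'(K + \lambda I)^{-1}(y - \mu 1)}.
#'
#' The trait should already be standardized (Z-transformed) by the caller.
#'
#' @param X Coded marker matrix from \code{\link{prepare_matrix}}.
#' @param y Trait values (one per row of X).
#' @param lambda Optional fixed ridge parameter; if \code{NULL} (default)
#'   it is estimated by REML.
#' @return Object of class \code{"ridge_blup"}: \code{mu}, \code{effects}
#'   (named), \code{sigma2_g}, \code{sigma2_e}, \code{lambda},
#'   \code{markers}.
#' @export
fit_ridge_blup <- function(X, y, lambda = NULL) {
  n <- nrow(X)
  if (n != length(y)) stop("X rows and y length differ")
  if (n < 3L) stop("at least 3 samples are required")
  if (stats::var(y) == 0) stop("degenerate fit: trait variance is zero")

  K <- tcrossprod(X)
  ed <- eigen(K, symmetric = TRUE)
  U <- ed$vectors
  th <- pmax(ed$values, 0)
  zt <- drop(crossprod(U, y))
  xt <- drop(crossprod(U, rep(1, n)))

  profile <- function(loglam) {
    d <- th + exp(loglam)
    mu <- sum(xt * zt / d) / sum(xt^2 / d)
    rt <- zt - xt * mu
    s2 <- sum(rt^2 / d) / (n - 1)
    0.5 * ((n - 1) * log(s2) + sum(log(d)) + log(sum(xt^2 / d)))
  }
  if (is.null(lambda)) {
    opt <- stats::optimize(profile, c(-14, 14))
    lambda <- exp(opt$minimum)
  }
  d <- th + lambda
  mu <- sum(xt * zt / d) / sum(xt^2 / d)
  rt <- zt - xt * mu
  sigma2_g <- sum(rt^2 / d) / (n - 1)
  effects <- drop(crossprod(X, U %*% (rt / d)))
  names(effects) <- colnames(X)

  structure(list(mu = mu, effects = effects,
                 sigma2_g = sigma2_g, sigma2_e = lambda * sigma2_g,
                 lambda = lambda, markers = colnames(X), n = n),
            class = "ridge_blup")
}

#' @export
print.ridge_blup <- function(x, ...) {
  cat(sprintf(
    "ridge BLUP: %d markers, n = %d, lambda = %.3g (s2_g = %.3g, s2_e = %.3g)\n",
    length(x$effects), x$n, x$lambda, x$sigma2_g, x$sigma2_e))
  invisible(x)
}

#' Predict trait values from a fitted ridge BLUP
#'
#' @param object A \code{"ridge_blup"} fit.
#' @param newdata Coded marker matrix with the fit's markers as columns.
#' @param ... Unused.
#' @export
predict.ridge_blup <- function(object, newdata, ...) {
  drop(object$mu + newdata[, object$markers, drop = FALSE] %*% object$effects)
}

#' Markers with an estimated effect in both replicate models
#'
#' A marker is retained when it survived the missingness filter and carries
#' a finite estimated effect in both replicate fits; markers present in
#' only one replicate's model are discarded. Presence, not the point
#' estimate, is the criterion: a marker that fixed in a replicate (constant
#' genotype column, structural zero effect) is still retained, since
#' fixation is itself the footprint of the strongest selection.
#'
#' @param model_a,model_b \code{"ridge_blup"} fits for the two replicates.
#' @return Character vector of retained marker names (possibly empty, with
#'   a warning).
#' @export
cross_replicate_retain <- function(model_a, model_b) {
  ok <- function(m) m$markers[is.finite(m$effects)]
  out <- intersect(ok(model_a), ok(model_b))
  if (!length(out)) warning("no marker retained in both replicates")
  out
}
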