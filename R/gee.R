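# Gaussian GEE with exchangeable working correlation, written from first
# principles: iterated weighted estimating equations with moment updates of
# the dispersion and the common within-cluster correlation, and the sandwich
# (robust) covariance B^-1 M B^-1. The exchangeable structure admits a
# closed-form inverse, V^-1 = (1/phi) [ I/(1-a) - c 11' ] with
# c = a / ((1-a)(1 + (n-1)a)), so the whole fit is vectorized over clusters.

#' Low-level Gaussian GEE fit on a design matrix
#'
#' Identity-link Gaussian generalized estimating equations with an
#' exchangeable working correlation. Iterates (i) the weighted
#' coefficient solve with the current working covariance, then (ii) moment
#' updates of the dispersion `phi = sum(e^2) / (N - p)` and the common
#' correlation `alpha = sum over clusters of pairwise residual products /
#' (phi * (total pairs - p))`, until the maximum coefficient change falls
#' below `tol`. Returns both the model-based and the sandwich covariance.
#'
#' @param y numeric response vector.
#' @param X numeric design matrix (including any intercept column).
#' @param id cluster identifiers (one per row of `X`).
#' @param tol convergence tolerance on `max(abs(delta beta))`.
#' @param maxit iteration cap.
#' @param alpha if a number, the working correlation is held fixed at this
#'   value instead of being estimated.
#' @param blocks optional named list of column index vectors marking
#'   coefficient blocks for [joint_wald()].
#' @return an object of class `gee_exch`.
#' @seealso [gee_exch()] for the formula interface.
#' @export
gee_fit <- function(y, X, id, tol = 1e-8, maxit = 100L, alpha = NULL,
                    blocks = NULL) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  keep <- stats::complete.cases(y, X, id)
  y <- y[keep]; X <- X[keep, , drop = FALSE]; id <- id[keep]
  n <- length(y); p <- ncol(X)
  if (n == 0L) stop("no complete observations")
  cl <- match(id, unique(id))
  n_cl <- max(cl)
  if (n_cl < 2L) stop("need at least 2 clusters")
  sizes <- tabulate(cl, n_cl)
  if (qr(X)$rank < p) stop("design matrix is rank deficient")
  npairs <- sum(sizes * (sizes - 1)) / 2
  alpha_fixed <- !is.null(alpha)
  a <- if (alpha_fixed) alpha else 0
  a_lower <- if (max(sizes) > 1L) -1 / (max(sizes) - 1) + 1e-6 else 0
  cs <- function(M) rowsum(M, cl, reorder = FALSE)  # cluster sums

  alpha_moment <- function(e, phi) {
    eS <- drop(cs(matrix(e)))
    eSq <- drop(cs(matrix(e^2)))
    cross_sum <- sum((eS^2 - eSq) / 2)
    denom <- phi * (npairs - p)
    a <- if (denom > 0) cross_sum / denom else 0
    min(max(a, a_lower), 1 - 1e-6)
  }
  beta <- qr.solve(X, y)  # OLS start
  e <- drop(y - X %*% beta)
  phi <- sum(e^2) / (n - p)
  if (!alpha_fixed) a <- alpha_moment(e, phi)  # moment start from OLS residuals
  converged <- FALSE
  it <- 0L
  XtX <- crossprod(X)
  Xty <- crossprod(X, y)
  XS <- cs(X)                         # cluster sums of columns, n_cl x p
  yS <- drop(cs(matrix(y)))           # cluster sums of response
  repeat {
    it <- it + 1L
    # (i) coefficient solve with current working correlation (phi cancels)
    cvec <- a / ((1 - a) * (1 + (sizes - 1) * a))
    A <- XtX / (1 - a) - crossprod(XS, XS * cvec)
    b <- Xty / (1 - a) - crossprod(XS, yS * cvec)
    beta_new <- solve(A, b)
    delta <- max(abs(beta_new - beta))
    beta <- beta_new
    # (ii) moment updates from current residuals
    e <- drop(y - X %*% beta)
    phi <- sum(e^2) / (n - p)
    if (!alpha_fixed) a <- alpha_moment(e, phi)
    if (delta < tol) { converged <- TRUE; break }
    if (it >= maxit) break
  }
  if (!converged)
    warning("GEE did not converge in ", maxit, " iterations (max |delta beta| = ",
            signif(delta, 3), ")")

  # covariance: bread B = sum Xi' Vi^-1 Xi, meat M = sum ui ui' with
  # ui = Xi' Vi^-1 ei
  cvec <- a / ((1 - a) * (1 + (sizes - 1) * a))
  XS <- cs(X)
  e <- drop(y - X %*% beta)
  eS <- drop(cs(matrix(e)))
  A <- XtX / (1 - a) - crossprod(XS, XS * cvec)   # = phi * B
  U <- (cs(X * e) / (1 - a) - XS * (cvec * eS)) / phi
  Ainv <- solve(A)
  cov_naive <- phi * Ainv
  cov_robust <- (phi * Ainv) %*% crossprod(U) %*% (phi * Ainv)
  cov_robust <- (cov_robust + t(cov_robust)) / 2
  dimnames(cov_naive) <- dimnames(cov_robust) <- list(colnames(X), colnames(X))

  fitted <- drop(X %*% beta)
  structure(list(
    coefficients = stats::setNames(drop(beta), colnames(X)),
    alpha = a, phi = phi,
    vcov_naive = cov_naive, vcov_robust = cov_robust,
    n_iter = it, converged = converged,
    fitted.values = fitted, residuals = e,
    n_obs = n, n_clusters = n_cl, cluster_sizes = sizes,
    blocks = blocks, X = X, y = y, cluster = cl,
    call = match.call()
  ), class = "gee_exch")
}

#' Gaussian GEE with exchangeable working correlation
#'
#' Formula interface to the GEE engine. The response is modeled with an
#' identity link; clustering (repeated measures on the same participant) is
#' given by `id`. Robust (sandwich) standard errors are reported by default
#' and are valid even when the exchangeable working correlation is
#' misspecified. `bs_basis()` may be used inside the formula; its knots are
#' stored so `predict()` on new data re-evaluates the same basis.
#'
#' @param formula model formula.
#' @param data data frame with the model variables.
#' @param id cluster identifier: a column name (character) or a vector of
#'   length `nrow(data)`.
#' @param tol,maxit,alpha passed to [gee_fit()].
#' @return an object of class `gee_exch` with `print`, `summary`, `coef`,
#'   `vcov`, `predict`, `fitted`, `residuals`, `simulate` and `plot` methods.
#' @examples
#' d <- data.frame(y = rnorm(40), x = rep(1:10, 4), g = rep(1:4, each = 10))
#' f <- gee_exch(y ~ x, d, id = "g")
#' summary(f)
#' @export
gee_exch <- function(formula, data, id, tol = 1e-8, maxit = 100L, alpha = NULL) {
  idvec <- if (is.character(id) && length(id) == 1L) {
    if (!id %in% names(data)) stop("id column '", id, "' not found in data")
    data[[id]]
  } else {
    if (length(id) != nrow(data)) stop("'id' must name a column or match nrow(data)")
    id
  }
  mf <- stats::model.frame(formula, data, na.action = stats::na.pass)
  ok <- stats::complete.cases(mf) & !is.na(idvec)
  mf <- mf[ok, , drop = FALSE]
  idvec <- idvec[ok]
  mt <- attr(mf, "terms")
  X <- stats::model.matrix(mt, mf)
  y <- stats::model.response(mf)
  # coefficient blocks from the term assignment (intercept = block 0)
  asg <- attr(X, "assign")
  labs <- attr(mt, "term.labels")
  blocks <- lapply(seq_along(labs), function(k) which(asg == k))
  names(blocks) <- labs
  if (any(asg == 0L)) blocks <- c(list("(Intercept)" = which(asg == 0L)), blocks)
  fit <- gee_fit(y, X, idvec, tol = tol, maxit = maxit, alpha = alpha,
                 blocks = blocks)
  fit$terms <- mt
  fit$call <- match.call()
  fit
}

#' @export
print.gee_exch <- function(x, ...) {
  cat("Gaussian GEE (exchangeable working correlation)\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat(sprintf("Clusters: %d   Observations: %d   Converged: %s (%d iterations)\n",
              x$n_clusters, x$n_obs, x$converged, x$n_iter))
  cat(sprintf("Working correlation alpha = %.4f   Dispersion phi = %.4f\n",
              x$alpha, x$phi))
  cat("\nCoefficients:\n")
  print(signif(stats::coef(x), 5))
  invisible(x)
}

#' @export
summary.gee_exch <- function(object, ...) {
  se <- sqrt(diag(object$vcov_robust))
  z <- stats::coef(object) / se
  tab <- cbind(Estimate = stats::coef(object), `Robust SE` = se,
               `z value` = z, `Pr(>|z|)` = 2 * stats::pnorm(-abs(z)))
  out <- list(coefficients = tab, alpha = object$alpha, phi = object$phi,
              n_clusters = object$n_clusters, n_obs = object$n_obs,
              converged = object$converged, call = object$call)
  class(out) <- "summary.gee_exch"
  out
}

#' @export
print.summary.gee_exch <- function(x, ...) {
  cat("Gaussian GEE (exchangeable working correlation)\n")
  if (!is.null(x$call)) { cat("Call: "); print(x$call) }
  cat(sprintf("Clusters: %d   Observations: %d\n", x$n_clusters, x$n_obs))
  stats::printCoefmat(x$coefficients, P.values = TRUE, has.Pvalue = TRUE)
  cat(sprintf("\nWorking correlation alpha = %.4f   Dispersion phi = %.4f\n",
              x$alpha, x$phi))
  invisible(x)
}

#' @export
coef.gee_exch <- function(object, ...) object$coefficients

#' @export
vcov.gee_exch <- function(object, type = c("robust", "naive"), ...) {
  switch(match.arg(type), robust = object$vcov_robust, naive = object$vcov_naive)
}

#' @export
residuals.gee_exch <- function(object, ...) object$residuals

#' @export
fitted.gee_exch <- function(object, ...) object$fitted.values

#' Predict from a fitted GEE
#'
#' @param object a `gee_exch` fit.
#' @param newdata new data frame (formula fits) or new design matrix with the
#'   training columns (matrix fits); `NULL` returns in-sample fits.
#' @param se.fit also return robust pointwise standard errors
#'   `sqrt(diag(X V X'))`.
#' @param ... unused.
#' @return fitted values, or a list with elements `fit` and `se.fit`.
#' @export
predict.gee_exch <- function(object, newdata = NULL, se.fit = FALSE, ...) {
  X <- if (is.null(newdata)) {
    object$X
  } else if (is.matrix(newdata) || is.null(object$terms)) {
    m <- as.matrix(newdata)
    if (ncol(m) != length(object$coefficients))
      stop("newdata has ", ncol(m), " columns; fit has ",
           length(object$coefficients), " coefficients")
    m
  } else {
    tt <- stats::delete.response(object$terms)
    mf <- stats::model.frame(tt, newdata, na.action = stats::na.pass)
    stats::model.matrix(tt, mf)
  }
  fit <- drop(X %*% object$coefficients)
  if (!se.fit) return(fit)
  se <- sqrt(rowSums((X %*% object$vcov_robust) * X))
  list(fit = fit, se.fit = se)
}

#' @export
simulate.gee_exch <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  n <- object$n_obs
  a <- max(object$alpha, 0)  # the random-intercept decomposition needs a >= 0
  s_b <- sqrt(object$phi * a)
  s_e <- sqrt(object$phi * (1 - a))
  out <- as.data.frame(replicate(nsim, {
    b <- stats::rnorm(object$n_clusters, 0, s_b)[object$cluster]
    object$fitted.values + b + stats::rnorm(n, 0, s_e)
  }))
  names(out) <- paste0("sim_", seq_len(nsim))
  out
}

#' @export
plot.gee_exch <- function(x, ...) {
  graphics::plot(x$fitted.values, x$residuals, xlab = "Fitted values",
                 ylab = "Residuals", main = "GEE residuals vs fitted", ...)
  graphics::abline(h = 0, lty = 2)
  invisible(x)
}

#' Joint Wald test on a block of GEE coefficients
#'
#' Computes `W = b_S' [V_robust(S,S)]^-1 b_S` with a chi-square reference on
#' `|S|` degrees of freedom. A singular block sub-covariance is an error (it
#' signals a defective design), not silently generalized-inverted.
#'
#' @param fit a `gee_exch` object.
#' @param block coefficient block: integer column indices, coefficient names,
#'   or the name(s) of blocks recorded in the fit (formula term labels, or
#'   the `blocks` argument of [gee_fit()]). Several block names are combined
#'   into one joint test.
#' @return object of class `wald_test`: list with `statistic`, `df`, `p.value`.
#' @export
joint_wald <- function(fit, block) {
  stopifnot(inherits(fit, "gee_exch"))
  idx <- if (is.character(block)) {
    if (!is.null(fit$blocks) && all(block %in% names(fit$blocks))) {
      sort(unique(unlist(fit$blocks[block])))
    } else {
      m <- match(block, names(fit$coefficients))
      if (anyNA(m)) stop("unknown block or coefficient name(s): ",
                         paste(block[is.na(m)], collapse = ", "))
      m
    }
  } else {
    as.integer(block)
  }
  p <- length(fit$coefficients)
  if (length(idx) == 0L || any(idx < 1L) || any(idx > p))
    stop("block indices must be a nonempty subset of 1..", p)
  b <- fit$coefficients[idx]
  V <- fit$vcov_robust[idx, idx, drop = FALSE]
  Vi <- tryCatch(solve(V), error = function(e)
    stop("singular robust covariance for block {",
         paste(names(fit$coefficients)[idx], collapse = ", "), "}"))
  W <- drop(t(b) %*% Vi %*% b)
  structure(list(statistic = W, df = length(idx),
                 p.value = stats::pchisq(W, df = length(idx), lower.tail = FALSE),
                 block = names(fit$coefficients)[idx]),
            class = "wald_test")
}

#' @export
print.wald_test <- function(x, ...) {
  cat(sprintf("Joint Wald test: chi^2 = %.4f, df = %d, p = %.4g\n",
              x$statistic, x$df, x$p.value))
  invisible(x)
}

#' Serialize a GEE fit to a JSON document
#'
#' @param fit a `gee_exch` object.
#' @param path optional file path; when `NULL` the JSON string is returned.
#' @return the JSON string, invisibly when written to a file.
#' @export
gee_to_json <- function(fit, path = NULL) {
  doc <- list(
    coefficients = as.list(fit$coefficients),
    alpha = fit$alpha, phi = fit$phi,
    vcov_naive = fit$vcov_naive, vcov_robust = fit$vcov_robust,
    n_iter = fit$n_iter, converged = fit$converged,
    n_obs = fit$n_obs, n_clusters = fit$n_clusters,
    blocks = fit$blocks
  )
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
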