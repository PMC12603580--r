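# B-spline basis construction (Cox-de Boor recursion) and tensor products.
# These are the building blocks of every design matrix in the package.

#' B-spline basis matrix over a clamped (open) knot vector
#'
#' Evaluates a B-spline basis by the Cox-de Boor recursion. Interior knots
#' are placed at quantiles of the observed values; boundary knots are clamped
#' (repeated `degree + 1` times) at the observed range. By default the first
#' basis column is dropped so the basis can sit next to a model intercept
#' without collinearity: `df` counts the *retained* columns, so the number of
#' interior knots is `df - degree`.
#'
#' @param x numeric vector of evaluation points.
#' @param df number of basis columns returned (after the intercept-column
#'   drop when `drop_first = TRUE`).
#' @param degree polynomial degree (default cubic).
#' @param knots interior knots; computed from quantiles of `x` when `NULL`.
#' @param boundary length-2 boundary knots; `range(x)` when `NULL`.
#' @param drop_first drop the first basis column (default `TRUE`).
#' @return a numeric matrix with one column per retained basis function and
#'   attributes `df`, `degree`, `knots`, `boundary`, `drop_first` so the same
#'   basis can be re-evaluated at new points. Class `gravida_bs` so that
#'   model formulas using `bs_basis()` predict safely on new data.
#' @examples
#' b <- bs_basis(seq(0, 10, by = 0.5), df = 5)
#' colSums(b)
#' @export
bs_basis <- function(x, df, degree = 3L, knots = NULL, boundary = NULL,
                     drop_first = TRUE) {
  stopifnot(is.numeric(x), df >= 1L, degree >= 0L)
  if (anyNA(x)) stop("'x' contains missing values")
  n_interior <- df - degree + if (drop_first) 0L else -1L
  if (is.null(knots)) {
    if (n_interior < 0L)
      stop("df too small for degree ", degree,
           " (need df >= degree", if (!drop_first) " + 1", ")")
    if (length(unique(x)) <= df)
      stop("need more than ", df, " distinct values in 'x'")
    knots <- if (n_interior > 0L)
      as.numeric(stats::quantile(unique(x), probs = seq_len(n_interior) / (n_interior + 1L)))
    else numeric(0)
  }
  if (is.null(boundary)) boundary <- range(x)
  if (any(x < boundary[1L] - 1e-12 | x > boundary[2L] + 1e-12))
    stop("'x' outside the boundary knots [", boundary[1L], ", ", boundary[2L], "]")
  full <- deboor_basis(x, knots, boundary, degree)
  out <- if (drop_first) full[, -1L, drop = FALSE] else full
  if (ncol(out) != df)
    stop("internal error: basis has ", ncol(out), " columns, expected ", df)
  colnames(out) <- paste0("bs", seq_len(ncol(out)))
  structure(out,
            df = df, degree = degree, knots = knots, boundary = boundary,
            drop_first = drop_first,
            class = c("gravida_bs", "matrix"))
}

# Full (undropped) clamped B-spline basis by the Cox-de Boor recursion.
# Returns length(knots) + degree + 1 columns; rows sum to one inside the
# boundary (partition of unity).
deboor_basis <- function(x, knots, boundary, degree) {
  t_full <- c(rep(boundary[1L], degree + 1L), sort(knots), rep(boundary[2L], degree + 1L))
  n_basis <- length(t_full) - degree - 1L
  n <- length(x)
  # degree 0: indicator of half-open knot spans; points at the right
  # boundary are assigned to the last non-empty span
  B <- matrix(0, n, length(t_full) - 1L)
  for (j in seq_len(length(t_full) - 1L)) {
    B[, j] <- as.numeric(x >= t_full[j] & x < t_full[j + 1L])
  }
  at_right <- x >= boundary[2L]
  if (any(at_right)) {
    j_last <- max(which(t_full < boundary[2L]))  # last span with positive width
    B[at_right, ] <- 0
    B[at_right, j_last] <- 1
  }
  for (k in seq_len(degree)) {
    ncol_k <- length(t_full) - k - 1L
    Bk <- matrix(0, n, ncol_k)
    for (j in seq_len(ncol_k)) {
      d1 <- t_full[j + k] - t_full[j]
      d2 <- t_full[j + k + 1L] - t_full[j + 1L]
      left  <- if (d1 > 0) (x - t_full[j]) / d1 * B[, j] else 0
      right <- if (d2 > 0) (t_full[j + k + 1L] - x) / d2 * B[, j + 1L] else 0
      Bk[, j] <- left + right
    }
    B <- Bk
  }
  stopifnot(ncol(B) == n_basis)
  B
}

#' Re-evaluate a fitted basis specification at new points
#'
#' @param x new evaluation points.
#' @param basis a matrix returned by [bs_basis()] (or a list with the same
#'   attributes: `df`, `degree`, `knots`, `boundary`, `drop_first`).
#' @return basis matrix at `x` using the stored knots and boundary.
#' @export
bs_apply <- function(x, basis) {
  bs_basis(x,
           df = attr(basis, "df"), degree = attr(basis, "degree"),
           knots = attr(basis, "knots"), boundary = attr(basis, "boundary"),
           drop_first = attr(basis, "drop_first"))
}

#' @export
makepredictcall.gravida_bs <- function(var, call) {
  if (as.character(call)[1L] == "bs_basis" ||
      (is.call(call) && identical(call[[1L]], quote(gravida::bs_basis)))) {
    at <- attributes(var)[c("df", "degree", "knots", "boundary", "drop_first")]
    call <- call[1:2]
    call[names(at)] <- at
  }
  call
}

#' Tensor-product interaction columns of two bases
#'
#' All pairwise element-wise products of the columns of `A` and `B`,
#' ordered A-major (all `B` columns for `A` column 1, then for column 2, ...).
#' Used to let a nonlinear time trend vary smoothly with a second covariate.
#'
#' @param A,B numeric matrices with equal row counts.
#' @return matrix with `ncol(A) * ncol(B)` columns.
#' @export
tensor_product <- function(A, B) {
  A <- as.matrix(A); B <- as.matrix(B)
  if (nrow(A) != nrow(B)) stop("'A' and 'B' must have the same number of rows")
  out <- matrix(0, nrow(A), ncol(A) * ncol(B))
  cn <- character(ncol(out))
  naml <- colnames(A) %||% paste0("A", seq_len(ncol(A)))
  namr <- colnames(B) %||% paste0("B", seq_len(ncol(B)))
  k <- 0L
  for (i in seq_len(ncol(A))) {
    for (j in seq_len(ncol(B))) {
      k <- k + 1L
      out[, k] <- A[, i] * B[, j]
      cn[k] <- paste0(naml[i], ":", namr[j])
    }
  }
  colnames(out) <- cn
  out
}
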