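# Spline bases and roughness penalties for the baseline predictors.
#
# Three constructions are used: a cyclic cubic regression spline for
# seasonality (periodic on the scaled week w in [0,1)), a low-rank thin
# plate regression spline for the WHO-style long-term trend, and a natural
# cubic spline for the Acosta-Irizarry-style trend.  The penalized bases are
# built with mgcv's smooth constructors; the natural cubic basis with
# splines::ns().  Both penalized smooths carry an
# integrated-squared-second-derivative penalty, so a heavily smoothed trend
# (and any forecast beyond the data) is affine in the covariate.

new_spline_basis <- function(values, kind, penalty, smooth = NULL,
                             ns_spec = NULL, k = NULL) {
  structure(list(values = values, kind = kind, penalty = penalty,
                 smooth = smooth, ns_spec = ns_spec, k = k),
            class = "spline_basis")
}

#' @export
print.spline_basis <- function(x, ...) {
  cat(sprintf("%s spline basis: %d rows x %d columns%s\n", x$kind,
              nrow(x$values), ncol(x$values),
              if (is.null(x$penalty)) " (unpenalized)" else
                sprintf(", penalty null space dim %d",
                        x$penalty$null_space_dim)))
  invisible(x)
}

#' Cyclic cubic regression spline basis
#'
#' Periodic cubic regression spline on `k` uniformly spaced knots over
#' `[0, 1]`, with value, first- and second-derivative continuity at the
#' wrap point, and an integrated-squared-second-derivative penalty.  The
#' periodicity constraint absorbs one basis dimension (`k - 1` columns);
#' with `absorb_centering = TRUE` (the default, as used when the smooth
#' enters a model next to an intercept) a sum-to-zero-over-rows constraint
#' absorbs a second one (`k - 2` columns).
#'
#' @param w numeric vector in `[0, 1)`.
#' @param k basis dimension (number of knots), at least 4.
#' @param absorb_centering absorb the sum-to-zero identifiability
#'   constraint into the basis (reparameterising the penalty accordingly)?
#' @return a `spline_basis` object with elements `values` (the model
#'   matrix) and `penalty` (list with the symmetric positive semidefinite
#'   `values` and its `null_space_dim`; the unconstrained penalty's null
#'   space is the constants).
#' @export
cyclic_cubic_basis <- function(w, k = 10, absorb_centering = TRUE) {
  if (k < 4) stop("cyclic cubic basis needs k >= 4", call. = FALSE)
  if (any(w < 0 | w >= 1)) stop("`w` must lie in [0, 1)", call. = FALSE)
  sm <- mgcv::smoothCon(mgcv::s(w, bs = "cc", k = k),
                        data = data.frame(w = w),
                        knots = list(w = seq(0, 1, length.out = k)),
                        absorb.cons = absorb_centering)[[1]]
  new_spline_basis(sm$X, "cyclic-cubic",
                   penalty = list(values = sm$S[[1]],
                                  null_space_dim = if (absorb_centering) 0L else 1L),
                   smooth = sm, k = k)
}

#' Thin plate regression spline basis
#'
#' One-dimensional thin plate regression spline of order 2 (radial basis
#' `|r|^3` family), rank-reduced to `k` columns by eigen-truncation of the
#' full thin-plate penalty, with unpenalized null space spanning
#' `{1, t}`.  Because the penalty is the integrated squared second
#' derivative, predictions beyond the data range are linear
#' extrapolations.
#'
#' @param t numeric covariate vector with at least `k` distinct values.
#' @param k basis dimension, at least 3.
#' @param absorb_centering absorb the sum-to-zero constraint (used next to
#'   an intercept)?
#' @param scale_penalty rescale the penalty for numerical stability (mgcv's
#'   default behaviour)?  Set `FALSE` to keep the raw
#'   integrated-squared-second-derivative scaling, e.g. to compare against
#'   a smoothing-spline solution at a given smoothing parameter.
#' @return a `spline_basis`; the unconstrained penalty has null space
#'   dimension 2 (affine functions), reduced to 1 when the centering
#'   constraint is absorbed.
#' @export
tprs_basis <- function(t, k, absorb_centering = TRUE, scale_penalty = TRUE) {
  if (k < 3) stop("thin plate basis needs k >= 3", call. = FALSE)
  if (length(unique(t)) < k)
    stop("need at least k distinct covariate values", call. = FALSE)
  sm <- mgcv::smoothCon(mgcv::s(t, bs = "tp", k = k),
                        data = data.frame(t = t),
                        absorb.cons = absorb_centering,
                        scale.penalty = scale_penalty)[[1]]
  new_spline_basis(sm$X, "thin-plate",
                   penalty = list(values = sm$S[[1]],
                                  null_space_dim = if (absorb_centering) 1L else 2L),
                   smooth = sm, k = k)
}

#' Natural cubic spline basis
#'
#' Natural (linear beyond the boundary knots) cubic spline basis with
#' `n_knots` internal knots equally spaced over `range`, built with
#' [splines::ns()].  Extrapolation beyond the boundary is linear by
#' construction.  The basis is unpenalized.
#'
#' @param t numeric covariate vector.
#' @param n_knots number of internal knots, at least 1.
#' @param range length-2 numeric, the boundary knots (must cover `t`).
#' @return a `spline_basis` with `n_knots + 1` columns and `penalty =
#'   NULL`.
#' @export
natural_cubic_basis <- function(t, n_knots, range = base::range(t)) {
  stopifnot(n_knots >= 1, length(range) == 2L, range[1] < range[2])
  knots <- seq(range[1], range[2], length.out = n_knots + 2)[seq_len(n_knots) + 1]
  X <- splines::ns(t, knots = knots, Boundary.knots = range)
  new_spline_basis(unclass(X)[, , drop = FALSE], "natural-cubic",
                   penalty = NULL,
                   ns_spec = list(knots = knots, boundary = range),
                   k = n_knots + 1L)
}

#' Evaluate a spline basis at new covariate values
#'
#' Re-evaluates the basis functions (with any absorbed constraints applied
#' consistently) at new covariate values, including values beyond the
#' construction range.
#'
#' @param basis a `spline_basis`.
#' @param newx numeric vector of new covariate values.
#' @return a matrix with `length(newx)` rows, conformable with
#'   `basis$values`.
#' @export
eval_basis <- function(basis, newx) {
  stopifnot(inherits(basis, "spline_basis"))
  if (!is.null(basis$smooth)) {
    nd <- stats::setNames(data.frame(newx), basis$smooth$term)
    mgcv::PredictMat(basis$smooth, nd)
  } else {
    sp <- basis$ns_spec
    unclass(splines::ns(newx, knots = sp$knots,
                        Boundary.knots = sp$boundary))[, , drop = FALSE]
  }
}
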