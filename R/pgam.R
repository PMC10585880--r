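# Penalized generalized linear models with log link: negative binomial with
# unknown dispersion, or quasi-Poisson.  The design is an intercept plus
# optional parametric columns plus zero or more penalized smooth blocks
# (spline_basis objects carrying their penalties).  Smoothing parameters
# are selected by restricted maximum likelihood (mgcv's penalized IRLS with
# Laplace-approximate REML); for the negative binomial the dispersion is
# estimated alongside, for quasi-Poisson the Pearson statistic is used.

#' Fit a penalized count GLM (log link)
#'
#' @param y nonnegative integer response vector.
#' @param parametric optional numeric matrix of unpenalized columns (an
#'   intercept is always added and must not be included here).
#' @param smooths list of penalized `spline_basis` blocks (built with
#'   `absorb_centering = TRUE` so they are identifiable next to the
#'   intercept), at most one penalty each.
#' @param family `"nb"` (negative binomial, dispersion estimated from the
#'   data) or `"quasipoisson"`.
#' @param sp optional vector of fixed smoothing parameters, one per smooth
#'   block (use 0 for an unpenalized fit and a very large value, e.g.
#'   `1e12`, to shrink a block to its penalty null space).
#' @param criterion smoothness-selection criterion; restricted maximum
#'   likelihood (the default) or GCV, kept for cross-checks.
#' @return an object of class `pgam` with elements `coefficients`,
#'   `theta` (NB dispersion; `NA` for quasi-Poisson),
#'   `pearson_dispersion`, `lambdas` (selected or fixed smoothing
#'   parameters), `edf` (effective degrees of freedom per smooth block),
#'   `converged`, `iterations`, and the underlying `fit`.
#' @export
#' @examples
#' g <- week_grid(2010, 2019)
#' s <- simulate_mortality("constant", grid = g, seed = 1)
#' f <- pgam(s$deaths, smooths = list(cyclic_cubic_basis(s$w, k = 10)))
#' f
pgam <- function(y, parametric = NULL, smooths = list(),
                 family = c("nb", "quasipoisson"), sp = NULL,
                 criterion = c("REML", "GCV")) {
  family <- match.arg(family)
  criterion <- match.arg(criterion)
  if (any(y < 0) || any(y != round(y)))
    stop("`y` must be nonnegative integer counts", call. = FALSE)
  n <- length(y)
  if (!is.null(parametric)) {
    parametric <- as.matrix(parametric)
    stopifnot(nrow(parametric) == n)
  }
  stopifnot(is.list(smooths),
            all(vapply(smooths, inherits, logical(1), "spline_basis")))
  for (b in smooths)
    if (is.null(b$penalty))
      stop("all smooth blocks must carry a penalty", call. = FALSE)

  dat <- list(y = y)
  rhs <- character(0)
  pen <- list()
  if (!is.null(parametric)) {
    dat$P <- parametric
    rhs <- "P"
  }
  if (!is.null(sp) && length(sp) != length(smooths))
    stop("`sp` must have one entry per smooth block", call. = FALSE)
  for (j in seq_along(smooths)) {
    nm <- paste0("Z", j)
    dat[[nm]] <- smooths[[j]]$values
    rhs <- c(rhs, nm)
    pen[[nm]] <- if (is.null(sp)) list(smooths[[j]]$penalty$values)
                 else list(smooths[[j]]$penalty$values, sp = sp[j])
  }
  form <- stats::reformulate(if (length(rhs)) rhs else "1", response = "y")
  fam <- if (family == "nb") mgcv::nb() else stats::quasipoisson()
  method <- if (criterion == "REML") "REML" else "GCV.Cp"

  degenerate <- FALSE
  fit <- tryCatch(
    mgcv::gam(form, family = fam, data = dat,
              paraPen = if (length(pen)) pen else NULL, method = method),
    error = function(e) {
      # dispersion estimation breaks down on (near-)zero-variance data;
      # both families reduce to Poisson in that limit
      degenerate <<- TRUE
      warning("dispersion estimation failed (", conditionMessage(e),
              "); refitting with a Poisson likelihood", call. = FALSE)
      mgcv::gam(form, family = stats::poisson(), data = dat,
                paraPen = if (length(pen)) pen else NULL, method = method)
    })
  if (!fit$converged)
    warning("pgam fit did not converge", call. = FALSE)

  # coefficient block bookkeeping: intercept, parametric, then each smooth
  p_par <- if (is.null(parametric)) 0L else ncol(parametric)
  sizes <- vapply(smooths, function(b) ncol(b$values), integer(1))
  idx <- vector("list", length(smooths))
  off <- 1L + p_par
  for (j in seq_along(smooths)) {
    idx[[j]] <- off + seq_len(sizes[j])
    off <- off + sizes[j]
  }
  stopifnot(off == length(stats::coef(fit)))

  theta <- if (family != "nb") NA_real_ else
    if (degenerate) Inf else fit$family$getTheta(TRUE)
  pearson <- sum(stats::residuals(fit, type = "pearson")^2) /
    stats::df.residual(fit)
  structure(list(
    coefficients = stats::coef(fit),
    family = family,
    theta = theta,
    pearson_dispersion = pearson,
    lambdas = if (length(smooths)) unname(fit$sp) else numeric(0),
    edf = vapply(idx, function(i) sum(fit$edf[i]), numeric(1)),
    converged = isTRUE(fit$converged),
    iterations = fit$iter,
    block_index = idx,
    n_parametric = p_par,
    smooths = smooths,
    criterion = criterion,
    fit = fit), class = "pgam")
}

#' @export
print.pgam <- function(x, ...) {
  cat(sprintf("penalized %s GLM (log link), %s smoothness selection\n",
              if (x$family == "nb") "negative-binomial" else "quasi-Poisson",
              x$criterion))
  cat(sprintf("  coefficients: %d (intercept + %d parametric + %d smooth blocks)\n",
              length(x$coefficients), x$n_parametric, length(x$smooths)))
  if (length(x$smooths))
    cat("  smoothing parameters:", format(x$lambdas, digits = 4),
        " edf:", format(x$edf, digits = 4), "\n")
  if (x$family == "nb") cat(sprintf("  theta: %.4g\n", x$theta))
  else cat(sprintf("  Pearson dispersion: %.4g\n", x$pearson_dispersion))
  cat(sprintf("  converged: %s (%d IRLS iterations)\n", x$converged,
              x$iterations))
  invisible(x)
}

#' @export
coef.pgam <- function(object, ...) object$coefficients

#' Predict expected counts from a penalized count GLM
#'
#' @param object a [pgam()] fit.
#' @param parametric new parametric design rows (matrix, required if the
#'   fit has parametric columns).
#' @param smooth_x list of new covariate vectors, one per smooth block, at
#'   which each block's basis is re-evaluated (extrapolation beyond the
#'   training range is supported and, for second-derivative-penalized
#'   trends, affine).
#' @param type `"response"` (expected counts, the default), `"link"` (the
#'   linear predictor) or `"terms"` (a matrix of per-block contributions to
#'   the linear predictor).
#' @param n number of rows to predict for an intercept-only model (ignored
#'   when `parametric` or `smooth_x` determine it).
#' @param ... unused.
#' @return numeric vector, or a matrix for `type = "terms"`.
#' @export
predict.pgam <- function(object, parametric = NULL, smooth_x = list(),
                         type = c("response", "link", "terms"), n = 1L, ...) {
  type <- match.arg(type)
  if (object$n_parametric > 0) {
    if (is.null(parametric))
      stop("fit has parametric columns; supply `parametric`", call. = FALSE)
    parametric <- as.matrix(parametric)
    if (ncol(parametric) != object$n_parametric)
      stop("`parametric` has ", ncol(parametric), " columns; expected ",
           object$n_parametric, call. = FALSE)
  }
  if (length(smooth_x) != length(object$smooths))
    stop("`smooth_x` must supply one covariate vector per smooth block",
         call. = FALSE)
  nr <- if (!is.null(parametric)) nrow(parametric) else
    if (length(smooth_x)) length(smooth_x[[1]]) else n
  beta <- object$coefficients
  terms <- matrix(0, nr, 1 + (object$n_parametric > 0) + length(smooth_x))
  cn <- "(Intercept)"
  terms[, 1] <- beta[1]
  col <- 2L
  if (object$n_parametric > 0) {
    terms[, col] <- parametric %*% beta[1L + seq_len(object$n_parametric)]
    cn <- c(cn, "parametric")
    col <- col + 1L
  }
  for (j in seq_along(smooth_x)) {
    Znew <- eval_basis(object$smooths[[j]], smooth_x[[j]])
    terms[, col] <- Znew %*% beta[object$block_index[[j]]]
    cn <- c(cn, paste0("smooth", j, ".", object$smooths[[j]]$kind))
    col <- col + 1L
  }
  colnames(terms) <- cn
  switch(type,
         terms = terms,
         link = rowSums(terms),
         response = exp(rowSums(terms)))
}
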