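# Conditional Poisson regression for the time-stratified case-crossover
# design. Conditioning on each stratum's total event count turns the
# Poisson likelihood into a product of multinomials, eliminating one
# intercept per stratum:
#   l(beta) = sum_s [ sum_{i in s} y_i x_i'beta - Y_s log sum_{i in s} exp(x_i'beta) ]
# The estimates are identical to a Poisson GLM with one dummy intercept per
# stratum, but the fit scales with the number of regression coefficients,
# not the number of strata.

cp_loglik_parts <- function(eta, y, si, Ys, grp) {
  if (max(eta) - min(eta) < 30 && max(abs(eta)) < 500) {
    # safe without per-stratum centring (the usual case)
    ee <- exp(eta)
    denom <- drop(rowsum(ee, si))
    p <- ee / denom[si]
    ll <- sum(y * eta) - sum(Ys * log(denom))
  } else {
    M <- vapply(grp, function(ii) max(eta[ii]), numeric(1))
    ee <- exp(eta - M[si])
    denom <- drop(rowsum(ee, si))
    p <- ee / denom[si]
    ll <- sum(y * eta) - sum(Ys * (log(denom) + M))
  }
  list(ll = ll, p = p)
}

# Newton-Raphson core on prevalidated inputs: si integer stratum ids
# (1..S, each stratum informative), Ys stratum totals, grp row-index list.
cp_fit_core <- function(y, X, si, Ys, grp, quasi = FALSE, init = NULL,
                        tol = 1e-10, maxit = 100L, check = TRUE) {
  n <- length(y); k <- ncol(X)
  dropped <- character()
  if (check) {
    Xc <- X - rowsum(X, si)[si, , drop = FALSE] / tabulate(si)[si]
    const <- apply(abs(Xc), 2, max) <= 1e-10 * pmax(1, apply(abs(X), 2, max))
    dropped <- colnames(X)[const]
    if (any(const)) {
      warning("dropping stratum-constant covariate(s): ",
              paste(dropped, collapse = ", "),
              " (coefficient not identifiable under the conditional likelihood)")
      X <- X[, !const, drop = FALSE]
      Xc <- Xc[, !const, drop = FALSE]
      k <- ncol(X)
    }
    if (k == 0) stop("no identifiable covariates")
    if (qr(Xc)$rank < k)
      stop("covariate matrix is rank-deficient within strata")
    if (!is.null(init) && length(init) != k) init <- NULL
  }
  beta <- if (is.null(init)) numeric(k) else as.numeric(init)
  obj <- function(b) cp_loglik_parts(drop(X %*% b), y, si, Ys, grp)
  cur <- obj(beta)
  converged <- FALSE
  for (it in seq_len(maxit)) {
    w <- Ys[si] * cur$p                       # conditional expected counts
    grad <- drop(crossprod(X, y - w))
    S <- rowsum(X * w, si)
    H <- crossprod(X * sqrt(w)) - crossprod(S / sqrt(Ys))
    delta <- tryCatch(solve(H, grad), error = function(e) NULL)
    if (is.null(delta)) {   # ill-conditioned: ridge then quasi-Newton polish
      delta <- tryCatch(solve(H + diag(1e-8 * (1 + diag(H)), k), grad),
                        error = function(e) NULL)
      if (is.null(delta)) {
        qn <- stats::optim(beta, fn = function(b) -obj(b)$ll,
                           gr = function(b) {
                             pp <- obj(b)$p
                             -drop(crossprod(X, y - Ys[si] * pp))
                           }, method = "BFGS",
                           control = list(maxit = 200, reltol = 1e-12))
        beta <- qn$par; cur <- obj(beta)
        break
      }
    }
    step <- 1
    new <- cur
    repeat {
      cand <- beta + step * delta
      new <- obj(cand)
      if (is.finite(new$ll) && new$ll >= cur$ll - 1e-12) break
      step <- step / 2
      if (step < 1e-10) break
    }
    dll <- new$ll - cur$ll
    beta <- beta + step * delta
    cur <- new
    if (abs(dll) < tol) { converged <- TRUE; break }
    if (max(abs(beta)) > 1e6)
      break                                   # diverging: likely separation
  }
  if (!converged)
    warning("conditional Poisson fit did not converge (possible separation ",
            "or unbounded coefficient); estimates reported as-is")

  w <- Ys[si] * cur$p
  S <- rowsum(X * w, si)
  H <- crossprod(X * sqrt(w)) - crossprod(S / sqrt(Ys))
  V <- tryCatch(solve(H), error = function(e) matrix(NA_real_, k, k))
  se <- sqrt(pmax(diag(V), 0))
  nstr <- length(Ys)
  dfres <- n - nstr - k
  phi <- if (dfres > 0) sum((y - w)^2 / w) / dfres else NA_real_
  if (quasi) {
    if (!is.finite(phi)) stop("cannot estimate dispersion: no residual df")
    se <- se * sqrt(phi)
    V <- V * phi
  }
  names(beta) <- names(se) <- colnames(X)
  structure(list(coefficients = beta, se = se, vcov = V,
                 loglik = cur$ll,
                 aic = if (quasi) NA_real_ else 2 * k - 2 * cur$ll,
                 dispersion = phi, quasi = quasi, converged = converged,
                 n = n, n_strata = nstr, k = k, dropped = dropped,
                 fitted = w, iterations = it),
            class = "cpfit")
}

#' Fit a conditional Poisson regression
#'
#' Maximises the stratum-conditioned Poisson log-likelihood by
#' Newton-Raphson with analytic gradient and Hessian and step-halving;
#' on an ill-conditioned Hessian the step falls back to a quasi-Newton
#' (BFGS) refinement. Standard errors come from the observed information.
#' Covariate columns that are constant within every stratum carry no
#' information under the conditional likelihood (their coefficient is not
#' identifiable) and are dropped with a warning.
#'
#' With `quasi = TRUE` an overdispersion scale phi is estimated as the
#' Pearson chi-squared statistic of the equivalent stratum-mean model
#' divided by its residual degrees of freedom, standard errors are
#' multiplied by `sqrt(phi)`, and the AIC is reported as unavailable
#' (`NA`), as the quasi-likelihood has no AIC.
#'
#' @param y non-negative integer response (daily event counts).
#' @param X numeric covariate matrix (no intercept; stratum intercepts are
#'   conditioned out).
#' @param strata stratum labels, one per row.
#' @param quasi logical; apply quasi-Poisson dispersion scaling.
#' @param init optional starting coefficient vector (warm start).
#' @param tol convergence tolerance on the log-likelihood change.
#' @param maxit maximum Newton iterations.
#' @return object of class `cpfit`: `coefficients`, `se`, `vcov`,
#'   `loglik`, `aic` (`2k - 2 loglik`, `NA` under `quasi`), `dispersion`,
#'   `converged`, `n`, `n_strata`, `k`, `dropped` (names of removed
#'   stratum-constant columns), `fitted` (conditional expected counts).
#' @examples
#' # one stratum, two days: the conditional likelihood is a binomial logit
#' f <- fit_conditional_poisson(c(10, 20), cbind(x = c(0, 1)), c(1, 1))
#' coef(f)  # log(20/10)
#' @export
fit_conditional_poisson <- function(y, X, strata, quasi = FALSE, init = NULL,
                                    tol = 1e-10, maxit = 100L) {
  X <- as.matrix(X)
  storage.mode(X) <- "double"
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  y <- as.numeric(y)
  n <- length(y)
  stopifnot(nrow(X) == n, length(strata) == n)
  if (any(y < 0) || anyNA(y)) stop("response must be non-negative and complete")
  if (anyNA(X)) stop("covariate matrix must be complete")

  f <- droplevels(factor(strata))
  si <- as.integer(f)
  Ys <- drop(rowsum(y, si))
  sz <- tabulate(si)
  if (!any(sz >= 2 & Ys > 0))
    stop("no informative stratum: need >=1 stratum with >=2 rows and events")
  keep <- sz[si] >= 2 & Ys[si] > 0
  if (!all(keep)) {
    y <- y[keep]; X <- X[keep, , drop = FALSE]
    f <- droplevels(f[keep]); si <- as.integer(f)
    Ys <- drop(rowsum(y, si)); n <- length(y)
  }
  if (!is.null(init)) stopifnot(length(init) == ncol(X))
  cp_fit_core(y, X, si, Ys, split(seq_len(n), si), quasi = quasi,
              init = init, tol = tol, maxit = maxit, check = TRUE)
}

#' @export
coef.cpfit <- function(object, ...) object$coefficients

#' @export
vcov.cpfit <- function(object, ...) object$vcov

#' @export
logLik.cpfit <- function(object, ...) {
  structure(object$loglik, df = object$k, class = "logLik")
}

#' Akaike information criterion of a conditional Poisson fit
#'
#' `2k - 2 loglik`, where k counts the regression coefficients maximised in
#' the conditional likelihood (transformation parameters found by an outer
#' search are not counted; see [optimize_spec()] for a corrected variant).
#' Under quasi-Poisson scaling there is no likelihood and the AIC is
#' reported as unavailable (`NA`).
#'
#' @param object a `cpfit` or `lag_fit` object.
#' @param ... unused.
#' @param k penalty per parameter (2, the AIC convention).
#' @export
AIC.cpfit <- function(object, ..., k = 2) {
  if (isTRUE(object$quasi)) return(NA_real_)
  k * object$k - 2 * object$loglik
}

#' @export
print.cpfit <- function(x, ...) {
  cat(sprintf("conditional Poisson fit: n=%d rows, %d strata, %d coefficient(s)%s\n",
              x$n, x$n_strata, x$k,
              if (x$converged) "" else " [NOT CONVERGED]"))
  print(data.frame(coef = x$coefficients, se = x$se))
  cat(sprintf("logLik %.4f  AIC %s  dispersion %.3f\n", x$loglik,
              if (is.na(x$aic)) "unavailable (quasi)" else sprintf("%.4f", x$aic),
              x$dispersion))
  invisible(x)
}
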