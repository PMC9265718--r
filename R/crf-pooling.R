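#' Per-lag concentration-response curve with confidence envelope
#'
#' Evaluates the log-relative-risk curve of one lag fit on a concentration
#' grid: central `beta * T(Z)` and the normal-theory envelope
#' `(beta -/+ 1.96 SE) * T(Z)`, so `RR(Z) = exp(beta * T(Z))`.
#'
#' @param fit a [lag_fit()] (converged).
#' @param zgrid non-negative concentration grid (ppb).
#' @return list of class `crf_curve`: `lag`, `z`, `beta` (central log-RR),
#'   `lower`, `upper`, `spec`, `r`.
#' @examples
#' f <- lag_fit(beta = 0.00183, se = 0.00039, spec = transform_spec("identity"),
#'              r = 50, lag = 0)
#' exp(rr_curve(f, 30)$beta)  # 1.0564
#' @export
rr_curve <- function(fit, zgrid) {
  stopifnot(inherits(fit, "lag_fit"))
  if (!isTRUE(fit$converged)) stop("curve requires a converged fit")
  if (any(zgrid < 0)) stop("concentrations must be non-negative")
  Tz <- apply_transform(zgrid, fit$spec, fit$r)
  structure(list(lag = fit$lag, z = zgrid,
                 beta = fit$beta * Tz,
                 lower = (fit$beta - 1.96 * fit$se) * Tz,
                 upper = (fit$beta + 1.96 * fit$se) * Tz,
                 slope = fit$beta, se = fit$se,
                 spec = fit$spec, r = fit$r),
            class = "crf_curve")
}

#' Lag inclusion rule for pooling
#'
#' Keeps the lags whose exposure slope is strictly positive; lags with
#' `beta <= 0` indicate no (or inverse) association at that latency and
#' are excluded from the pooled summary. Order is preserved.
#'
#' @param fits list of [lag_fit()] objects.
#' @return integer indices into `fits` of the retained lags.
#' @export
select_lags <- function(fits) {
  stopifnot(length(fits) >= 1)
  betas <- vapply(fits, function(f) f$beta, numeric(1))
  keep <- which(betas > 0)
  if (length(keep) == 0)
    stop(structure(
      class = c("crflag_no_positive_lags", "error", "condition"),
      list(message = "no lag has a positive exposure slope; nothing to pool",
           call = sys.call(-1L))))
  keep
}

# internal: least-squares fit of theta*log(1+z/A)*LWF(z;mu,tau,r) to a
# matrix B (grid x curves) of log-RR values; theta is profiled out
# (linear given the shape), Nelder-Mead on (log A, logit mu, log tau).
fit_pooled_set <- function(B, z, r, maxit = 4000, reltol = 1e-12) {
  B <- as.matrix(B)
  zmax <- max(z)
  if (zmax <= 0) stop("degenerate concentration grid")
  med <- max(stats::median(z), 0.05 * zmax)
  qs <- stats::quantile(z[z > 0], c(0.25, 0.5), names = FALSE)
  # tau = 1 start: a nearly flat LWF, the basin for (log-)linear input curves
  starts <- expand.grid(A = c(med, 10 * med), mu = qs, tau = c(0.01, 0.1, 1),
                        KEEP.OUT.ATTRS = FALSE)
  shape <- function(A, mu, tau) log1p(z / A) * lwf(z, mu, tau, r)
  objective <- function(p) {
    A <- exp(p[1]); mu <- zmax * stats::plogis(p[2]); tau <- exp(p[3])
    if (!all(is.finite(c(A, mu, tau))) || A <= 0 || tau <= 0) return(1e12)
    g <- shape(A, mu, tau)
    if (!all(is.finite(g))) return(1e12)
    den <- sum(g^2) * ncol(B)
    if (den <= 0 || !is.finite(den)) return(1e12)
    theta <- sum(g * rowSums(B)) / den
    sum((theta * g - B)^2)
  }
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    p0 <- c(log(starts$A[i]),
            stats::qlogis(min(max(starts$mu[i] / zmax, 1e-3), 1 - 1e-3)),
            log(starts$tau[i]))
    opt <- stats::optim(p0, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  # Nelder-Mead restarts from the incumbent: the simplex collapses along
  # the A-theta ridge; re-expanding it recovers further progress
  for (rs in 1:5) {
    opt <- stats::optim(best$par, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    if (opt$value >= best$value - 1e-14 * (1 + abs(best$value))) {
      if (opt$value < best$value) best <- opt
      break
    }
    best <- opt
  }
  if (!is.finite(best$value) || best$value >= 1e12)
    stop("pooled least-squares fit failed at all starts")
  A <- exp(best$par[1]); mu <- zmax * stats::plogis(best$par[2])
  tau <- exp(best$par[3])
  g <- shape(A, mu, tau)
  theta <- sum(g * rowSums(B)) / (sum(g^2) * ncol(B))
  list(theta = theta, A = A, mu = mu, tau = tau, rss = best$value,
       converged = best$convergence == 0)
}

#' Pooled concentration-response function
#'
#' Container for the pooled parametric C-RF
#' `RR(Z) = exp(theta * log(1 + Z/A) * LWF(Z; mu, tau))`, together with the
#' independently fitted lower and upper boundary curves (same parametric
#' form, fitted to the per-lag confidence-envelope curves). Constructed by
#' [pool_crf()], or directly from published parameter values for curve
#' evaluation.
#'
#' @param central named list or vector with elements `theta`, `A`, `mu`,
#'   `tau`.
#' @param lower,upper optional parameter sets of the same form for the
#'   boundary curves.
#' @param r concentration range (ppb) entering the LWF.
#' @param zmax largest concentration of the fitting grid (used as the
#'   default threshold-search bound); defaults to 100.
#' @param lags lags that contributed to the fit (metadata).
#' @return list of class `pooled_crf`.
#' @export
pooled_crf <- function(central, lower = NULL, upper = NULL, r,
                       zmax = 100, lags = NULL) {
  chk <- function(p) {
    p <- as.list(p)
    stopifnot(all(c("theta", "A", "mu", "tau") %in% names(p)))
    if (p$A <= 0 || p$tau <= 0) stop("pooled parameters require A > 0, tau > 0")
    p
  }
  structure(list(central = chk(central),
                 lower = if (!is.null(lower)) chk(lower),
                 upper = if (!is.null(upper)) chk(upper),
                 r = r, zmax = zmax, lags = lags),
            class = "pooled_crf")
}

#' @export
print.pooled_crf <- function(x, ...) {
  cat("pooled C-RF: RR(Z) = exp(theta * log(1 + Z/A) * LWF(Z; mu, tau))\n")
  sets <- Filter(Negate(is.null), x[c("central", "lower", "upper")])
  tab <- do.call(rbind, lapply(sets, function(p)
    data.frame(theta = p$theta, A = p$A, mu = p$mu, tau = p$tau,
               rss = if (is.null(p$rss)) NA_real_ else p$rss)))
  print(tab)
  if (!is.null(x$lags)) cat("pooled over lags:", paste(x$lags, collapse = ", "), "\n")
  invisible(x)
}

#' Pool per-lag C-RF curves by least squares
#'
#' Fits the pooled parametric form
#' `beta(Z) = theta * log(1 + Z/A) * LWF(Z; mu, tau)` to the collection of
#' per-lag central log-RR curves by unweighted least squares over the
#' common concentration grid, minimising
#' `sum_lags sum_grid (beta_pooled(Z) - beta_lag(Z))^2` over
#' (theta, A, mu, tau). The same form is then fitted, independently, to
#' the set of per-lag lower-envelope curves and to the set of upper
#' curves, giving the two boundary curves. No weighting or correlation
#' structure enters the least-squares criterion.
#'
#' `theta` is linear in the criterion given (A, mu, tau) and is profiled
#' out; the remaining three parameters are searched by multi-start
#' Nelder-Mead on an unconstrained reparameterisation (see
#' [optimize_spec()]), which handles the A-theta ridge of the scaled-log
#' form.
#'
#' @param curves list of [rr_curve()] results on a common grid (typically
#'   the lags retained by [select_lags()]).
#' @param r concentration range used in the pooled LWF; defaults to the
#'   mean of the per-curve ranges.
#' @return a [pooled_crf()] with `rss` and `converged` recorded per set.
#' @export
pool_crf <- function(curves, r = NULL) {
  stopifnot(length(curves) >= 1,
            all(vapply(curves, inherits, TRUE, "crf_curve")))
  z <- curves[[1]]$z
  for (cu in curves)
    if (length(cu$z) != length(z) || any(cu$z != z))
      stop("all curves must share a common concentration grid")
  if (is.null(r)) r <- mean(vapply(curves, function(c) c$r, numeric(1)))
  sets <- list(central = vapply(curves, function(c) c$beta, numeric(length(z))),
               lower   = vapply(curves, function(c) c$lower, numeric(length(z))),
               upper   = vapply(curves, function(c) c$upper, numeric(length(z))))
  fits <- lapply(sets, function(B)
    fit_pooled_set(matrix(B, nrow = length(z)), z, r))
  pooled_crf(fits$central, fits$lower, fits$upper, r = r, zmax = max(z),
             lags = vapply(curves, function(c) c$lag, numeric(1)))
}

#' Evaluate the pooled relative risk
#'
#' @param pooled a [pooled_crf()].
#' @param z concentrations (ppb), `z >= 0`.
#' @return data.frame with columns `z`, `rr` and, when boundary fits are
#'   present, `lower` and `upper`.
#' @examples
#' p <- pooled_crf(c(theta = 0.0816, A = 50.99, mu = 13.07, tau = 0.0274), r = 50)
#' evaluate_rr(p, 30)  # ~ 1.0385
#' @export
evaluate_rr <- function(pooled, z) {
  stopifnot(inherits(pooled, "pooled_crf"))
  if (any(z < 0)) stop("concentrations must be non-negative")
  ev <- function(p) exp(p$theta * log1p(z / p$A) * lwf(z, p$mu, p$tau, pooled$r))
  out <- data.frame(z = z, rr = ev(pooled$central))
  if (!is.null(pooled$lower)) out$lower <- ev(pooled$lower)
  if (!is.null(pooled$upper)) out$upper <- ev(pooled$upper)
  out
}

#' Detectable concentration threshold
#'
#' Largest grid concentration `Z*` such that `RR(Z) - 1 < epsilon` for all
#' grid points `Z <= Z*`: below `Z*` the curve is indistinguishable from no
#' effect at resolution `epsilon`. Returns `NA` when even the smallest grid
#' concentration exceeds the tolerance (no threshold). A log-linear
#' (untransformed-exposure) curve with a positive slope exceeds any
#' `epsilon > 0` immediately above zero, so it admits no threshold; the
#' sigmoid-weighted pooled form does.
#'
#' @param object a [pooled_crf()] or [crf_curve()].
#' @param epsilon positive tolerance on the excess relative risk.
#' @param zgrid concentration grid; defaults to steps of 0.5 ppb from 0 to
#'   the object's maximum fitted concentration.
#' @return threshold concentration (ppb) or `NA_real_`.
#' @export
detect_threshold <- function(object, epsilon, zgrid = NULL) {
  if (epsilon <= 0) stop("epsilon must be > 0")
  UseMethod("detect_threshold")
}

#' @export
detect_threshold.pooled_crf <- function(object, epsilon, zgrid = NULL) {
  if (is.null(zgrid)) zgrid <- seq(0, object$zmax, by = 0.5)
  rr <- evaluate_rr(object, zgrid)$rr
  threshold_on_grid(zgrid, rr, epsilon)
}

#' @export
detect_threshold.crf_curve <- function(object, epsilon, zgrid = NULL) {
  if (is.null(zgrid)) {
    z <- object$z; rr <- exp(object$beta)
  } else {
    z <- zgrid
    rr <- exp(object$slope * apply_transform(zgrid, object$spec, object$r))
  }
  threshold_on_grid(z, rr, epsilon)
}

threshold_on_grid <- function(z, rr, epsilon) {
  ok <- cumprod(rr - 1 < epsilon) > 0
  if (!any(ok)) return(NA_real_)
  max(z[ok])
}
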