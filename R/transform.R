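#' Logistic weighting function
#'
#' `LWF(Z) = 1 / (1 + exp((mu - Z) / (r * tau)))`: a sigmoid in
#' concentration that controls where the exposure effect "turns on".
#' `mu` (ppb) locates the half-weight concentration, `tau` (dimensionless)
#' sets the steepness relative to the observed concentration range `r`
#' (ppb, max - min of the analysis sample). The output lies strictly in
#' (0, 1) and is non-decreasing in Z.
#'
#' @param z concentrations (ppb), numeric vector.
#' @param mu location parameter (ppb).
#' @param tau steepness parameter (> 0).
#' @param r concentration range (ppb, > 0).
#' @return weights in (0, 1).
#' @examples
#' lwf(30, mu = 13.07, tau = 0.0274, r = 50)  # ~ 1 at 30 ppb
#' lwf(13.07, mu = 13.07, tau = 0.0274, r = 50)  # exactly 0.5 at Z = mu
#' @export
lwf <- function(z, mu, tau, r) {
  if (!is.finite(tau) || tau <= 0) stop("tau must be > 0")
  if (!is.finite(r) || r <= 0) stop("r must be > 0")
  stats::plogis((z - mu) / (r * tau))
}

#' Exposure transformation specification
#'
#' Describes the transformation `T(Z)` submitted to the model in place of
#' the raw concentration. `T(Z) = f(Z) * LWF(Z)` where `f` is one of:
#' \describe{
#'   \item{identity}{`f(Z) = Z`}
#'   \item{sqrt}{`f(Z) = sqrt(Z)`}
#'   \item{log}{`f(Z) = log(1 + Z)` (shifted by one unit so that
#'     near-zero concentration days remain valid)}
#'   \item{power}{`f(Z) = Z^P`, `P > 0`}
#'   \item{scaled_log}{`f(Z) = log(1 + Z/A)`, `A > 0` a scale in ppb; the
#'     flexible family, also the parametric form of the pooled curve}
#' }
#' When `mu` and `tau` are both `NULL` no weighting is applied
#' (`T(Z) = f(Z)`); the no-transformation model of the classical
#' case-crossover analysis is `transform_spec("identity")`.
#'
#' @param family transformation family, see above.
#' @param A scale of the scaled-log family (ppb, > 0).
#' @param mu,tau logistic weighting parameters; both `NULL` for an
#'   unweighted transformation.
#' @param P exponent of the power family (> 0).
#' @return list of class `transform_spec`.
#' @export
transform_spec <- function(family = c("identity", "sqrt", "log", "power",
                                      "scaled_log"),
                           A = NULL, mu = NULL, tau = NULL, P = NULL) {
  family <- match.arg(family)
  weighted <- !is.null(mu) || !is.null(tau)
  if (weighted && (is.null(mu) || is.null(tau)))
    stop("mu and tau must be given together (or both omitted)")
  if (weighted && (!is.finite(tau) || tau <= 0)) stop("tau must be > 0")
  if (family == "scaled_log") {
    if (is.null(A) || !is.finite(A) || A <= 0)
      stop("scaled_log family requires A > 0")
  }
  if (family == "power") {
    if (is.null(P) || !is.finite(P) || P <= 0)
      stop("power family requires P > 0")
  }
  structure(list(family = family, A = A, mu = mu, tau = tau, P = P,
                 weighted = weighted),
            class = "transform_spec")
}

#' @export
print.transform_spec <- function(x, ...) {
  f <- switch(x$family,
              identity = "Z", sqrt = "sqrt(Z)", log = "log(1+Z)",
              power = sprintf("Z^%g", x$P),
              scaled_log = sprintf("log(1+Z/%g)", x$A))
  if (x$weighted)
    cat(sprintf("T(Z) = %s * LWF(Z; mu=%g, tau=%g)\n", f, x$mu, x$tau))
  else cat(sprintf("T(Z) = %s (no weighting)\n", f))
  invisible(x)
}

#' Apply an exposure transformation
#'
#' Evaluates `T(Z) = f(Z) * LWF(Z)` (or plain `f(Z)` for an unweighted
#' spec) on non-negative concentrations.
#'
#' @param z concentrations (ppb), `z >= 0`.
#' @param spec a [transform_spec()].
#' @param r observed concentration range (ppb), required when the spec is
#'   weighted.
#' @return numeric vector `T(z)`.
#' @examples
#' s <- transform_spec("scaled_log", A = 15.2, mu = 14.0, tau = 0.005)
#' apply_transform(30, s, r = 50)  # ~ log(1 + 30/15.2)
#' @export
apply_transform <- function(z, spec, r = NULL) {
  stopifnot(inherits(spec, "transform_spec"))
  if (any(z < 0, na.rm = TRUE)) stop("concentrations must be non-negative")
  f <- switch(spec$family,
              identity = z,
              sqrt = sqrt(z),
              log = log1p(z),
              power = z^spec$P,
              scaled_log = log1p(z / spec$A))
  if (!spec$weighted) return(f)
  if (is.null(r)) stop("r (concentration range) is required for a weighted spec")
  f * lwf(z, spec$mu, spec$tau, r)
}

# internal: fit one lag under a given transformation; returns a lag_fit.
# Uses the design's cached stratum indexing; identifiability of the spline
# block is established once per design, so only the transform column is
# (cheaply) checked for degeneracy here.
fit_spec <- function(design, spec, quasi = FALSE, init = NULL) {
  Tz <- apply_transform(design$z, spec, design$r)
  if (stats::sd(Tz) < 1e-12 * max(1, abs(mean(Tz))))
    stop("degenerate transform: T(Z) is constant on the analysis sample")
  X <- cbind(Tz = Tz, design$W)
  fit <- withCallingHandlers(
    cp_fit_core(design$y, X, design$si, design$Ys, design$grp,
                quasi = quasi, init = init, check = FALSE),
    warning = function(w) {
      if (grepl("did not converge", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  lag_fit(beta = unname(fit$coefficients[1]), se = unname(fit$se[1]),
          spec = spec, r = design$r, lag = design$lag,
          loglik = fit$loglik, aic = fit$aic, dispersion = fit$dispersion,
          spline_coef = fit$coefficients[-1], converged = fit$converged,
          n = fit$n, n_strata = fit$n_strata, k = fit$k)
}

#' Per-lag fit summary
#'
#' Container for the result of one lagged case-crossover fit: the slope
#' `beta` on the transformed exposure `T(Z)` (so `RR(Z) =
#' exp(beta * T(Z))`), its standard error, the attached transformation
#' spec and the exposure range `r` entering the LWF. Fits can also be
#' constructed directly from published coefficients for curve evaluation.
#'
#' @param beta slope on `T(Z)`.
#' @param se standard error of `beta` (> 0).
#' @param spec a [transform_spec()].
#' @param r observed exposure range (ppb).
#' @param lag lag in days.
#' @param loglik,aic,dispersion,spline_coef,converged,n,n_strata,k
#'   optional fit metadata.
#' @return list of class `lag_fit`.
#' @export
lag_fit <- function(beta, se, spec, r, lag = NA_integer_,
                    loglik = NA_real_, aic = NA_real_,
                    dispersion = NA_real_, spline_coef = NULL,
                    converged = TRUE, n = NA_integer_,
                    n_strata = NA_integer_, k = NA_integer_) {
  stopifnot(inherits(spec, "transform_spec"), is.finite(beta))
  if (!is.na(se) && se <= 0) stop("SE must be positive")
  structure(list(lag = lag, beta = beta, se = se, spec = spec, r = r,
                 loglik = loglik, aic = aic, dispersion = dispersion,
                 spline_coef = spline_coef, converged = converged,
                 n = n, n_strata = n_strata, k = k),
            class = "lag_fit")
}

#' @rdname AIC.cpfit
#' @export
AIC.lag_fit <- function(object, ..., k = 2) object$aic

#' @export
print.lag_fit <- function(x, ...) {
  cat(sprintf("lag %s: Beta = %.5g (SE %.3g), AIC %s\n",
              ifelse(is.na(x$lag), "?", x$lag), x$beta, x$se,
              if (is.na(x$aic)) "unavailable" else sprintf("%.2f", x$aic)))
  print(x$spec)
  invisible(x)
}

#' Tabulated percentile search for the transformation parameters
#'
#' The tabulation strategy for the weighted simple-function variant: one
#' conditional Poisson model is fitted per cell of a grid with `mu` at
#' fixed percentiles of the concentration distribution (default 0, 25, 50,
#' 75) and `tau` in a small fixed set (default 0.1 and 0.2), for each
#' candidate family `f`. The cell with the smallest AIC wins; exact ties
#' break deterministically towards smaller `mu`, then smaller `tau`, then
#' the family order as listed. The winning `mu` is then refined by
#' evaluating five percentile steps (of 5 percentile points) above and
#' below it; when the winner sits at the minimum concentration the search
#' extends below the minimum in increments equal to the 5th
#' percentile-minus-minimum difference for as long as the log-likelihood
#' improves.
#'
#' @param design a [build_lagged_design()] result.
#' @param families candidate `f` families, searched in the given order.
#' @param percentiles `mu` percentiles of the observed concentrations.
#' @param taus candidate steepness values.
#' @param powers exponents used when `families` contains `"power"`.
#' @param quasi logical, quasi-Poisson scaling (selection then uses the
#'   unscaled AIC of the corresponding likelihood fit, which is
#'   unavailable; therefore selection requires `quasi = FALSE`).
#' @param refine logical; run the percentile refinement step.
#' @return list: `fit` (the winning [lag_fit()]), `spec`, `audit` (a
#'   data.frame with one row per evaluated cell: family, P, mu,
#'   percentile, tau, loglik, aic, converged, refined).
#' @export
grid_search_spec <- function(design, families = c("sqrt", "identity", "log"),
                             percentiles = c(0, 25, 50, 75),
                             taus = c(0.1, 0.2), powers = 2,
                             quasi = FALSE, refine = TRUE) {
  stopifnot(inherits(design, "lagged_design"), length(families) >= 1)
  if (quasi) stop("grid selection needs AIC; fit the chosen spec with quasi=TRUE afterwards")
  z <- design$z
  qs <- stats::quantile(z, percentiles / 100, names = FALSE, type = 7)
  cells <- list(); audit <- list()
  fam_exp <- list()
  for (f in families) {
    if (f == "power") for (p in powers) fam_exp <- c(fam_exp, list(c(f, p)))
    else fam_exp <- c(fam_exp, list(c(f, NA)))
  }
  eval_cell <- function(fam, P, mu, tau, pct, refined) {
    spec <- transform_spec(fam, mu = mu, tau = tau,
                           P = if (!is.na(P)) as.numeric(P) else NULL)
    fit <- tryCatch(fit_spec(design, spec, quasi = FALSE),
                    error = function(e) NULL)
    list(spec = spec, fit = fit,
         row = data.frame(family = fam,
                          P = if (is.na(P)) NA_real_ else as.numeric(P),
                          mu = mu, percentile = pct, tau = tau,
                          loglik = if (is.null(fit)) NA_real_ else fit$loglik,
                          aic = if (is.null(fit)) Inf else fit$aic,
                          converged = !is.null(fit) && fit$converged,
                          refined = refined))
  }
  fi <- 0L
  for (fe in fam_exp) {
    fi <- fi + 1L
    for (ti in seq_along(taus)) for (pi in seq_along(percentiles)) {
      cell <- eval_cell(fe[1], fe[2], qs[pi], taus[ti], percentiles[pi], FALSE)
      cell$key <- c(fi, ti, pi)
      cells[[length(cells) + 1L]] <- cell
      audit[[length(audit) + 1L]] <- cell$row
    }
  }
  aics <- vapply(cells, function(c) c$row$aic, numeric(1))
  if (all(!is.finite(aics))) stop("all grid cells failed to converge")
  # AIC-minimal; deterministic tie-break: smaller mu, smaller tau, family order
  ord <- order(aics,
               vapply(cells, function(c) c$row$mu, numeric(1)),
               vapply(cells, function(c) c$row$tau, numeric(1)),
               vapply(cells, function(c) c$key[1], numeric(1)))
  best <- cells[[ord[1]]]

  if (refine) {
    pb <- best$row$percentile
    fam <- best$row$family; P <- best$row$P; tau <- best$row$tau
    cand_p <- setdiff(pmin(pmax(pb + 5 * c(-5:-1, 1:5), 0), 100),
                      best$row$percentile)
    for (p in sort(unique(cand_p))) {
      cell <- eval_cell(fam, P, stats::quantile(z, p / 100, names = FALSE),
                        tau, p, TRUE)
      audit[[length(audit) + 1L]] <- cell$row
      if (is.finite(cell$row$aic) &&
          (cell$row$aic < best$row$aic - 1e-12 ||
           (abs(cell$row$aic - best$row$aic) <= 1e-12 &&
            cell$row$mu < best$row$mu)))
        best <- cell
    }
    if (pb == 0) {        # extend below the observed minimum
      inc <- stats::quantile(z, 0.05, names = FALSE) - min(z)
      if (inc > 0) {
        prev_ll <- best$row$loglik
        for (j in seq_len(10)) {
          mu_j <- min(z) - j * inc
          cell <- eval_cell(fam, P, mu_j, tau, -5 * j, TRUE)
          audit[[length(audit) + 1L]] <- cell$row
          if (!is.finite(cell$row$loglik) || cell$row$loglik <= prev_ll) break
          prev_ll <- cell$row$loglik
          if (cell$row$aic < best$row$aic) best <- cell
        }
      }
    }
  }
  list(fit = best$fit, spec = best$spec, audit = do.call(rbind, audit))
}

#' Iterative AIC minimisation of the flexible transformation
#'
#' Selects the parameters (A, mu, tau) of the scaled-log weighted
#' transformation `T(Z) = log(1 + Z/A) * LWF(Z; mu, tau)` by minimising
#' the AIC of the refitted conditional Poisson model, using Nelder-Mead on
#' the unconstrained scale `(log A, logit((mu - min Z)/r), log tau)` (which
#' enforces `A > 0`, `mu` inside the observed concentration range and
#' `tau > 0`). The search is restarted from a small deterministic set of
#' initial values (`mu` at the 25th/50th percentiles, `tau` in
#' \{0.01, 0.1\}, `A` at the median and 10x the median concentration) and
#' the best of all runs is returned, so the procedure is fully
#' deterministic given the data.
#'
#' Note the A-theta ridge: for `A` much larger than the observed
#' concentrations, `log(1 + Z/A) ~ Z/A`, so (beta, A) are only jointly
#' identified up to near-proportionality. The profile is reported as found
#' and not constrained; the fitted curve `beta * T(Z)` itself is stable.
#'
#' @param design a [build_lagged_design()] result.
#' @param init optional [transform_spec()] (scaled_log) used as an
#'   additional starting point.
#' @param quasi logical; when `TRUE`, selection still uses the likelihood
#'   AIC but the returned fit is refitted with dispersion scaling.
#' @param maxit,reltol Nelder-Mead control.
#' @param k_correction when `TRUE` the reported AIC adds 2 per searched
#'   transformation parameter (3), a sensitivity option; the default
#'   counts only the coefficients maximised in the likelihood, matching
#'   the use of the fitted model's AIC.
#' @return list: `fit` (winning [lag_fit()]), `spec`, `audit` (one row per
#'   start: initial and final parameters, AIC, evaluations, convergence),
#'   `aic_corrected`.
#' @export
optimize_spec <- function(design, init = NULL, quasi = FALSE,
                          maxit = 500, reltol = 1e-10, k_correction = FALSE) {
  stopifnot(inherits(design, "lagged_design"))
  z <- design$z
  zmin <- min(z); r <- design$r
  if (r <= 0) stop("degenerate exposure: zero range")
  med <- max(stats::median(z), 0.1 * r)
  q <- stats::quantile(z, c(0.25, 0.5), names = FALSE)
  q <- pmin(pmax(q, zmin + 1e-3 * r), zmin + r * (1 - 1e-3))
  starts <- expand.grid(A = c(med, 10 * med), mu = q, tau = c(0.01, 0.1),
                        KEEP.OUT.ATTRS = FALSE)
  if (!is.null(init)) {
    stopifnot(inherits(init, "transform_spec"), init$family == "scaled_log",
              init$weighted)
    starts <- rbind(starts,
                    data.frame(A = init$A,
                               mu = min(max(init$mu, zmin + 1e-3 * r),
                                        zmin + r * (1 - 1e-3)),
                               tau = init$tau))
  }
  to_par <- function(A, mu, tau)
    c(log(A), stats::qlogis((mu - zmin) / r), log(tau))
  from_par <- function(p)
    list(A = exp(p[1]), mu = zmin + r * stats::plogis(p[2]), tau = exp(p[3]))
  warm <- NULL
  objective <- function(p) {
    th <- from_par(p)
    if (!all(is.finite(unlist(th))) || th$A <= 0 || th$tau <= 0 ||
        th$mu <= zmin || th$mu >= zmin + r) return(1e12)
    spec <- transform_spec("scaled_log", A = th$A, mu = th$mu, tau = th$tau)
    fit <- tryCatch(fit_spec(design, spec, quasi = FALSE, init = warm),
                    error = function(e) NULL)
    if (is.null(fit) || !is.finite(fit$aic)) return(1e12)
    warm <<- c(fit$beta, fit$spline_coef)
    fit$aic
  }
  best <- NULL; audit <- list()
  for (i in seq_len(nrow(starts))) {
    warm <- NULL
    opt <- stats::optim(to_par(starts$A[i], starts$mu[i], starts$tau[i]),
                        objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    th <- from_par(opt$par)
    audit[[i]] <- data.frame(start_A = starts$A[i], start_mu = starts$mu[i],
                             start_tau = starts$tau[i], A = th$A, mu = th$mu,
                             tau = th$tau, aic = opt$value,
                             evaluations = opt$counts[1],
                             converged = opt$convergence == 0)
    if (is.null(best) || opt$value < best$value) best <- c(opt, th)
  }
  if (best$value >= 1e12) stop("objective non-finite at all starts")
  # restart from the incumbent: re-expanding the collapsed simplex along
  # the A-beta ridge often gains a little more
  for (rs in 1:3) {
    warm <- NULL
    opt <- stats::optim(best$par, objective, method = "Nelder-Mead",
                        control = list(maxit = maxit, reltol = reltol))
    if (opt$value >= best$value - 1e-9 * (1 + abs(best$value))) {
      if (opt$value < best$value) best <- c(opt, from_par(opt$par))
      break
    }
    best <- c(opt, from_par(opt$par))
  }
  spec <- transform_spec("scaled_log", A = best$A, mu = best$mu, tau = best$tau)
  fit <- fit_spec(design, spec, quasi = quasi)
  list(fit = fit, spec = spec, audit = do.call(rbind, audit),
       aic_corrected = if (k_correction) fit$aic + 2 * 3 else fit$aic)
}
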