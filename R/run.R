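#' Run the full lagged concentration-response analysis
#'
#' End-to-end pipeline: for each lag 0..`max_lag`, assemble the
#' time-stratified case-crossover design and fit the conditional Poisson
#' model under the requested exposure treatment:
#' \describe{
#'   \item{a}{no transformation, `T(Z) = Z` (the classical log-linear
#'     analysis);}
#'   \item{b}{`T(Z) = f(Z) * LWF(Z)` with `f` and the weighting parameters
#'     chosen on the percentile grid ([grid_search_spec()]);}
#'   \item{c}{the flexible form `T(Z) = log(1 + Z/A) * LWF(Z)` with
#'     (A, mu, tau) chosen by iterative AIC minimisation
#'     ([optimize_spec()]).}
#' }
#' Lags with a positive slope are pooled ([pool_crf()]) into a single
#' parametric C-RF with boundary curves; the pooled relative risk is
#' evaluated at the requested concentrations and the detectable threshold
#' is located. The whole run is deterministic given the input data.
#'
#' @param input a [daily_series()] or a path to the standard input CSV.
#' @param variant `"a"`, `"b"`, `"c"`, or `"all"`.
#' @param max_lag largest lag in days (default 9).
#' @param df spline degrees of freedom for each weather confounder.
#' @param quasi logical, quasi-Poisson dispersion scaling of the final
#'   per-lag fits (variant b/c selection always uses the likelihood AIC).
#' @param eval_points concentrations (ppb) at which the pooled RR is
#'   reported (default 30).
#' @param epsilon excess-RR tolerance for threshold detection.
#' @param n_grid number of equally spaced pooling-grid points from 0 to
#'   the observed maximum concentration (default 200).
#' @param grid_args,optim_args lists of extra arguments for
#'   [grid_search_spec()] / [optimize_spec()].
#' @return object of class `crf_result`: for each requested variant a
#'   list with `fits` (per-lag [lag_fit()]s), `per_lag` (summary
#'   data.frame), `included` (pooled lag indices or `NULL`), `pooled` (a
#'   [pooled_crf()] or `NULL`), `rr` (RR table at `eval_points`),
#'   `threshold`, and `log` (one line per fitted candidate model with its
#'   AIC). Top level: `zgrid`, `call`.
#' @export
crf_run <- function(input, variant = c("c", "a", "b", "all"), max_lag = 9,
                    df = 3, quasi = FALSE, eval_points = 30,
                    epsilon = 0.005, n_grid = 200,
                    grid_args = list(), optim_args = list()) {
  variant <- match.arg(variant)
  series <- if (inherits(input, "daily_series")) input else
    read_daily_series(input)
  if (max_lag < 0) stop("max_lag must be >= 0")
  if (any(eval_points < 0)) stop("evaluation points must be >= 0")
  variants <- if (variant == "all") c("a", "b", "c") else variant
  zmax <- max(series$exposure, na.rm = TRUE)
  zgrid <- seq(0, zmax, length.out = n_grid)

  designs <- lapply(0:max_lag, function(L) build_lagged_design(series, L, df))
  out <- list()
  for (v in variants) {
    fits <- vector("list", max_lag + 1L)
    log_lines <- character()
    for (L in 0:max_lag) {
      d <- designs[[L + 1L]]
      if (v == "a") {
        fits[[L + 1L]] <- fit_spec(d, transform_spec("identity"), quasi = quasi)
        log_lines <- c(log_lines, sprintf(
          "variant=a lag=%d family=identity AIC=%.6f", L, fits[[L + 1L]]$aic))
      } else if (v == "b") {
        gs <- do.call(grid_search_spec, c(list(design = d), grid_args))
        fits[[L + 1L]] <- if (quasi) fit_spec(d, gs$spec, quasi = TRUE) else gs$fit
        log_lines <- c(log_lines, sprintf(
          "variant=b lag=%d family=%s mu=%.4f tau=%.4f AIC=%.6f%s",
          L, gs$audit$family, gs$audit$mu, gs$audit$tau, gs$audit$aic,
          ifelse(gs$audit$refined, " [refine]", "")))
      } else {
        op <- do.call(optimize_spec,
                      c(list(design = d, quasi = quasi), optim_args))
        fits[[L + 1L]] <- op$fit
        log_lines <- c(log_lines, sprintf(
          "variant=c lag=%d start(A=%.3f,mu=%.3f,tau=%.4f) -> A=%.4f mu=%.4f tau=%.5f AIC=%.6f (%d evals)",
          L, op$audit$start_A, op$audit$start_mu, op$audit$start_tau,
          op$audit$A, op$audit$mu, op$audit$tau, op$audit$aic,
          op$audit$evaluations))
      }
    }
    per_lag <- do.call(rbind, lapply(fits, function(f)
      data.frame(lag = f$lag, beta = f$beta, se = f$se,
                 family = f$spec$family,
                 mu = if (f$spec$weighted) f$spec$mu else NA_real_,
                 tau = if (f$spec$weighted) f$spec$tau else NA_real_,
                 A = if (!is.null(f$spec$A)) f$spec$A else NA_real_,
                 P = if (!is.null(f$spec$P)) f$spec$P else NA_real_,
                 r = f$r, loglik = f$loglik, aic = f$aic,
                 dispersion = f$dispersion, converged = f$converged)))
    included <- tryCatch(select_lags(fits), crflag_no_positive_lags =
                           function(e) NULL)
    per_lag$included <- seq_along(fits) %in% included
    pooled <- NULL; rr <- NULL; thr <- NA_real_
    if (is.null(included)) {
      warning("variant ", v, ": no lag has a positive slope; pooling skipped")
    } else {
      curves <- lapply(fits[included], rr_curve, zgrid = zgrid)
      pooled <- pool_crf(curves)
      rr <- evaluate_rr(pooled, eval_points)
      thr <- detect_threshold(pooled, epsilon)
    }
    out[[v]] <- list(fits = fits, per_lag = per_lag, included = included,
                     pooled = pooled, rr = rr, threshold = thr,
                     log = log_lines)
  }
  structure(list(variants = out, zgrid = zgrid, eval_points = eval_points,
                 epsilon = epsilon, quasi = quasi, call = match.call()),
            class = "crf_result")
}

#' @export
print.crf_result <- function(x, digits = 4, ...) {
  cat("Lagged case-crossover concentration-response analysis\n")
  for (v in names(x$variants)) {
    res <- x$variants[[v]]
    cat(sprintf("\n== variant (%s) ==\n", v))
    pl <- res$per_lag
    pl$beta <- signif(pl$beta, 4); pl$se <- signif(pl$se, 3)
    print(pl[c("lag", "beta", "se", "family", "mu", "tau", "A", "aic",
               "included")], row.names = FALSE)
    if (!is.null(res$pooled)) {
      cat(sprintf("pooled over lags {%s}:\n",
                  paste(res$pooled$lags, collapse = ",")))
      p <- res$pooled$central
      cat(sprintf("  theta=%.4f A=%.4f mu=%.4f tau=%.4f (RSS %.3g)\n",
                  p$theta, p$A, p$mu, p$tau, p$rss))
      rr <- res$rr
      for (i in seq_len(nrow(rr)))
        cat(sprintf("  RR(%g ppb) = %.4f [%.4f, %.4f]\n", rr$z[i],
                    round(rr$rr[i], digits), round(rr$lower[i], digits),
                    round(rr$upper[i], digits)))
      cat(sprintf("  threshold (excess RR < %g): %s ppb\n", x$epsilon,
                  ifelse(is.na(res$threshold), "none", res$threshold)))
    } else cat("  pooling skipped (no positive-slope lag)\n")
  }
  invisible(x)
}

#' Write analysis results to disk
#'
#' Emits machine-readable outputs under `dir`: `per_lag.csv` (one row per
#' variant x lag, full precision), `pooled.csv` (pooled and boundary
#' parameters), `rr_at_points.csv` (RR with boundaries at the evaluation
#' points plus the detected threshold) and `run.log` (one line per fitted
#' candidate model with its AIC).
#'
#' @param x a `crf_result`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_crf_result <- function(x, dir) {
  stopifnot(inherits(x, "crf_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  per_lag <- do.call(rbind, lapply(names(x$variants), function(v)
    cbind(variant = v, x$variants[[v]]$per_lag)))
  utils::write.csv(per_lag, file.path(dir, "per_lag.csv"), row.names = FALSE)
  pooled <- do.call(rbind, lapply(names(x$variants), function(v) {
    p <- x$variants[[v]]$pooled
    if (is.null(p)) return(NULL)
    do.call(rbind, lapply(c("central", "lower", "upper"), function(s)
      data.frame(variant = v, set = s, theta = p[[s]]$theta, A = p[[s]]$A,
                 mu = p[[s]]$mu, tau = p[[s]]$tau, rss = p[[s]]$rss,
                 r = p$r)))
  }))
  if (!is.null(pooled))
    utils::write.csv(pooled, file.path(dir, "pooled.csv"), row.names = FALSE)
  rr <- do.call(rbind, lapply(names(x$variants), function(v) {
    res <- x$variants[[v]]
    if (is.null(res$rr)) return(NULL)
    cbind(variant = v, res$rr, threshold = res$threshold)
  }))
  if (!is.null(rr))
    utils::write.csv(rr, file.path(dir, "rr_at_points.csv"), row.names = FALSE)
  writeLines(unlist(lapply(names(x$variants), function(v)
    c(sprintf("# variant %s", v), x$variants[[v]]$log))),
    file.path(dir, "run.log"))
  invisible(dir)
}

#' Plot per-lag curves and the pooled C-RF
#'
#' Left panel: per-lag relative-risk curves of one variant; right panel:
#' the pooled curve with its boundary curves.
#'
#' @param x a `crf_result`.
#' @param variant which variant to draw (default: first fitted).
#' @param ... unused.
#' @export
plot.crf_result <- function(x, variant = names(x$variants)[1], ...) {
  res <- x$variants[[variant]]
  if (is.null(res)) stop("variant not present in result")
  z <- x$zgrid
  op <- graphics::par(mfrow = c(1, 2)); on.exit(graphics::par(op))
  fits <- res$fits[res$included]
  rrmat <- vapply(fits, function(f)
    exp(f$beta * apply_transform(z, f$spec, f$r)), numeric(length(z)))
  graphics::matplot(z, rrmat, type = "l", lty = 1,
                    xlab = "concentration (ppb)", ylab = "RR",
                    main = sprintf("per-lag C-RFs, variant (%s)", variant))
  if (!is.null(res$pooled)) {
    rr <- evaluate_rr(res$pooled, z)
    graphics::plot(z, rr$rr, type = "l", lwd = 2,
                   ylim = range(rr[-1]), xlab = "concentration (ppb)",
                   ylab = "RR", main = "pooled C-RF")
    graphics::lines(z, rr$lower, lty = 2)
    graphics::lines(z, rr$upper, lty = 2)
  }
  invisible(x)
}
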