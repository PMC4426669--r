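# First-order decay model and its least-squares machinery. optim with
# box constraints is used instead of nls() because the recovery
# contracts include exactly-on-model (zero-residual) data, which nls()
# rejects.

decay_rss <- function(par, t, f, fixed_plateau = NULL) {
  k <- par[1]; A <- par[2]
  c0 <- if (is.null(fixed_plateau)) par[3] else fixed_plateau
  r <- c0 + A * exp(-k * t) - f
  sum(r^2)
}

decay_grad <- function(par, t, f, fixed_plateau = NULL) {
  k <- par[1]; A <- par[2]
  c0 <- if (is.null(fixed_plateau)) par[3] else fixed_plateau
  e <- exp(-k * t)
  r <- c0 + A * e - f
  g <- c(-2 * sum(r * A * t * e), 2 * sum(r * e))
  if (is.null(fixed_plateau)) g <- c(g, 2 * sum(r))
  g
}

# Log-linear initialization on baseline-subtracted data.
decay_init <- function(t, f, three_param) {
  c0 <- if (three_param) max(0, min(f)) * 0.9 else 0
  A0 <- max(max(f) - c0, 0.1)
  y <- f - c0
  ok <- y > 0.02 * A0 & t >= 0
  k0 <- if (sum(ok) >= 2 && sd(t[ok]) > 0) {
    max(1e-4, min(10, -unname(coef(lm(log(y[ok]) ~ t[ok]))[2])))
  } else 1e-3
  c(k0, A0, if (three_param) c0)
}

#' Fit a first-order exponential decay to a release time course
#'
#' Least-squares fit of `F(t) = plateau + amplitude * exp(-k t)`
#' (`model = "three_param"`, the default: a free plateau absorbs
#' incomplete release) or with the plateau fixed at zero
#' (`"two_param"`). Initialization comes from a log-linear regression
#' on baseline-subtracted data; optimization is bounded (`k >= 0`,
#' `plateau` in `[0, 1]`). Data whose best fit pins `k` at zero are
#' flagged `no_decay`.
#'
#' @param data a `decay_dataset` (columns `replicate`, `time_min`,
#'   `bound_fraction`; all replicates are pooled into one fit).
#' @param model `"three_param"` or `"two_param"`.
#' @return an object of class `kinetic_fit` with fields `k` (1/min),
#'   `t_half` (min, `ln 2 / k`), `amplitude`, `plateau`, `rss`,
#'   `model`, `converged`, `no_decay`, `n_obs`, and `data` (retained
#'   for bootstrapping).
#' @export
fit_decay <- function(data, model = c("three_param", "two_param")) {
  model <- match.arg(model)
  req <- c("time_min", "bound_fraction")
  if (!all(req %in% names(data))) {
    stopf("data must have columns: %s", paste(req, collapse = ", "))
  }
  t <- data$time_min; f <- data$bound_fraction
  if (any(t < 0)) stopf("times must be non-negative")
  three <- model == "three_param"
  n_par <- if (three) 3L else 2L
  if (length(unique(t)) < n_par) {
    stopf("need >= %d distinct timepoints for %s", n_par, model)
  }
  init <- decay_init(t, f, three)
  lower <- c(0, 1e-6, if (three) 0)
  upper <- c(100, 1.5, if (three) 1)
  fixed <- if (three) NULL else 0
  opt <- optim(init, function(p) decay_rss(p, t, f, fixed),
               gr = function(p) decay_grad(p, t, f, fixed),
               method = "L-BFGS-B", lower = lower, upper = upper,
               control = list(maxit = 500, factr = 10))
  k <- opt$par[1]
  no_decay <- k <= 1e-6
  fit <- structure(
    list(k = k, t_half = if (no_decay) Inf else log(2) / k,
         amplitude = opt$par[2],
         plateau = if (three) opt$par[3] else 0,
         rss = opt$value, model = model,
         converged = opt$convergence == 0, no_decay = no_decay,
         n_obs = length(f), data = data),
    class = "kinetic_fit")
  fit
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("First-order decay fit (%s)\n", x$model))
  cat(sprintf("  k = %.5f /min   t1/2 = %.3f min\n", x$k, x$t_half))
  cat(sprintf("  amplitude = %.4f   plateau = %.4f   rss = %.3g\n",
              x$amplitude, x$plateau, x$rss))
  if (x$no_decay) cat("  [no-decay flag: k pinned at 0]\n")
  if (!is.null(x$ci_k)) {
    cat(sprintf("  95%% CI k: [%.5f, %.5f]\n", x$ci_k[1], x$ci_k[2]))
  }
  invisible(x)
}

#' Bootstrap confidence intervals for a fitted decay
#'
#' Residual-resampling bootstrap: residuals of the pooled fit are
#' resampled with replacement onto the fitted curve, the model is
#' refitted, and the percentile (2.5, 97.5) interval of `k` and
#' `t_half` is reported. Requires at least 2 replicates (single-series
#' residuals confound replicate scatter with lack of fit).
#'
#' @param fit a `kinetic_fit` (its data are carried along).
#' @param n_boot number of bootstrap refits (>= 100).
#' @param seed integer seed.
#' @return the fit, with added fields `ci_k`, `ci_t_half`, `n_boot`.
#' @export
bootstrap_ci <- function(fit, n_boot = 1000, seed = 0) {
  stopifnot(inherits(fit, "kinetic_fit"))
  if (n_boot < 100) stopf("n_boot must be >= 100")
  data <- fit$data
  if (length(unique(data$replicate)) < 2) {
    stopf("bootstrap requires >= 2 replicates")
  }
  t <- data$time_min
  fitted_f <- fit$plateau + fit$amplitude * exp(-fit$k * t)
  resid <- data$bound_fraction - fitted_f
  ks <- with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      d <- data
      d$bound_fraction <- pmin(pmax(
        fitted_f + sample(resid, length(resid), replace = TRUE), 0), 1.05)
      fb <- fit_decay(d, model = fit$model)
      fb$k
    }, numeric(1))
  })
  fit$ci_k <- unname(quantile(ks, c(0.025, 0.975)))
  fit$ci_t_half <- rev(log(2) / fit$ci_k)
  fit$n_boot <- n_boot
  fit
}

#' Fold-acceleration between two fitted decays
#'
#' Ratio `t_half(a) / t_half(b)`: values above 1 mean condition *b*
#' releases nucleotide faster (e.g. basal GEF vs GEF + drug gives
#' roughly threefold).
#'
#' @param fit_a,fit_b converged `kinetic_fit`s.
#' @return the fold-acceleration (numeric scalar).
#' @export
compare_conditions <- function(fit_a, fit_b) {
  stopifnot(inherits(fit_a, "kinetic_fit"), inherits(fit_b, "kinetic_fit"))
  if (fit_a$no_decay || fit_b$no_decay) {
    stopf("cannot compare: a fit carries the no-decay flag")
  }
  if (!fit_a$converged || !fit_b$converged) {
    stopf("cannot compare: a fit did not converge")
  }
  fit_a$t_half / fit_b$t_half
}
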