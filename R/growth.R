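# Growth analysis: three-parameter logistic growth curves, interval
# growth rates, cultivar ANOVA, and trait-versus-yield regression.

#' Three-parameter logistic growth model
#'
#' `y(t) = x0 * xn / (x0 + (xn - x0) * exp(-tau * (t - T)))`, where `x0`
#' is the trait value on the reference day `T` (the first observation
#' day, in days after planting), `xn` the upper asymptote, and `tau` the
#' rate coefficient (per day).  By construction `y(T) = x0` exactly.
#'
#' @param t days after planting.
#' @param x0,xn,tau model parameters.
#' @param T reference day.
#' @return trait values at `t`.
#' @export
logistic3 <- function(t, x0, xn, tau, T = 45) {
  x0 * xn / (x0 + (xn - x0) * exp(-tau * (t - T)))
}

#' Fit the three-parameter logistic growth model
#'
#' Nonlinear least squares (Levenberg-Marquardt via
#' \code{minpack.lm::nlsLM}) with initial values `x0 =` first
#' observation, `xn =` maximum observation, `tau = 0.1`/day, and
#' positivity bounds on all three parameters.  Approximate 95%
#' confidence intervals come from the Jacobian at the optimum.
#' Non-convergence and unidentifiable fits (e.g. a constant series,
#' where `tau` is arbitrary) are flagged, not silently dropped.
#'
#' @param t observation days (DAP), >= 4 values.
#' @param y positive trait values.
#' @param T reference day (first observation day).
#' @param truncate_at_max drop observations after the series maximum
#'   (e.g. to exclude a defoliation-driven decline) before fitting.
#' @param ci_method `"jacobian"` (linearized intervals, default) or
#'   `"bootstrap"` (percentile intervals over residual-resampled
#'   refits).
#' @param n_boot bootstrap replicates when `ci_method = "bootstrap"`.
#' @param boot_seed seed for the bootstrap resampling.
#' @return object of class `growth_fit`: `par` (x0, xn, tau), `se`,
#'   `ci` (2 x 3 matrix), `T`, `sse`, `converged`, `flags` (character),
#'   and the underlying `nls` fit.
#' @examples
#' t <- c(45, 52, 67, 74, 88, 95, 102, 109)
#' y <- logistic3(t, 0.1, 1.0, 0.12)
#' fit_3plm(t, y)$par
#' @export
fit_3plm <- function(t, y, T = min(t), truncate_at_max = FALSE,
                     ci_method = c("jacobian", "bootstrap"),
                     n_boot = 200, boot_seed = 1L) {
  ci_method <- match.arg(ci_method)
  stopifnot(length(t) == length(y))
  ok <- complete.cases(t, y)
  t <- t[ok]; y <- y[ok]
  if (length(t) < 4) stop("need at least 4 observations", call. = FALSE)
  if (any(y <= 0)) stop("trait values must be positive", call. = FALSE)
  if (truncate_at_max) {
    keep <- seq_len(which.max(y))
    t <- t[keep]; y <- y[keep]
    if (length(t) < 4)
      stop("fewer than 4 observations left after truncation", call. = FALSE)
  }
  start <- list(x0 = max(y[which.min(t)], 1e-6), xn = max(y), tau = 0.1)
  flags <- character()
  fit <- tryCatch(
    minpack.lm::nlsLM(
      y ~ x0 * xn / (x0 + (xn - x0) * exp(-tau * (t - T))),
      start = start,
      lower = c(x0 = 1e-8, xn = 1e-8, tau = 1e-8),
      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) e)
  if (inherits(fit, "error")) {
    flags <- c("no_convergence", conditionMessage(fit))
    par <- unlist(start)
    # a (near-)constant series satisfies the model with x0 = xn and any
    # tau: report the degenerate solution and flag tau
    if (diff(range(y)) <= 1e-8 * max(abs(y))) {
      par[c("x0", "xn")] <- mean(y)
      flags <- c(flags, "tau_unidentifiable")
    }
    return(structure(list(par = par, se = rep(NA_real_, 3),
                          ci = matrix(NA_real_, 2, 3,
                                      dimnames = list(c("lwr", "upr"),
                                                      c("x0", "xn", "tau"))),
                          T = T, sse = NA_real_, converged = FALSE,
                          flags = flags, fit = NULL),
                     class = "growth_fit"))
  }
  par <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  resid <- y - predict(fit)
  dfree <- length(y) - 3
  ci <- rbind(lwr = par - qt(0.975, max(dfree, 1)) * se,
              upr = par + qt(0.975, max(dfree, 1)) * se)
  colnames(ci) <- names(par)
  if (ci_method == "bootstrap") {
    yhat <- predict(fit)
    boot <- with_seed(boot_seed, t(replicate(n_boot, {
      yb <- pmax(yhat + sample(resid, replace = TRUE), 1e-8)
      fb <- tryCatch(
        minpack.lm::nlsLM(
          yb ~ x0 * xn / (x0 + (xn - x0) * exp(-tau * (t - T))),
          start = as.list(par),
          lower = c(x0 = 1e-8, xn = 1e-8, tau = 1e-8)),
        error = function(e) NULL)
      if (is.null(fb)) rep(NA_real_, 3) else coef(fb)
    })))
    ci <- apply(boot, 2, quantile, probs = c(0.025, 0.975), na.rm = TRUE)
    dimnames(ci) <- list(c("lwr", "upr"), names(par))
  }
  if (any(!is.finite(se))) flags <- c(flags, "se_not_estimable")
  # flat series: x0 ~ xn makes tau drop out of the model
  if (abs(par["xn"] - par["x0"]) < 1e-6 * max(par["xn"], 1) ||
      (is.finite(se["tau"]) && se["tau"] > 100 * max(abs(par["tau"]), 1e-8)))
    flags <- c(flags, "tau_unidentifiable")
  structure(list(par = par, se = se, ci = ci, T = T,
                 sse = sum(resid^2), converged = TRUE, flags = flags,
                 fit = fit),
            class = "growth_fit")
}

#' @export
print.growth_fit <- function(x, ...) {
  cat(sprintf("<growth_fit: x0=%.4g, xn=%.4g, tau=%.4g (T=%g)%s>\n",
              x$par["x0"], x$par["xn"], x$par["tau"], x$T,
              if (length(x$flags)) paste0(" [", paste(x$flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Evaluate a fitted growth curve
#'
#' @param fit a [fit_3plm()] result.
#' @param t days after planting.
#' @return predicted trait values.
#' @export
predict_3plm <- function(fit, t) {
  stopifnot(inherits(fit, "growth_fit"))
  logistic3(t, fit$par[["x0"]], fit$par[["xn"]], fit$par[["tau"]], fit$T)
}

# reference monitoring calendar (DAP of consecutive collection dates);
# consecutive pairs delimit the named periods P1..P8
.period_dap <- c(43, 45, 52, 67, 74, 88, 95, 102, 109)

#' Interval growth rates
#'
#' `GR = (P_t - P_{t - dt}) / dt` for each consecutive pair of
#' observations.  Intervals matching the reference monitoring calendar
#' (DAP 43-45-52-67-74-88-95-102-109) are labelled P1..P8; other
#' intervals are auto-labelled I1, I2, ...
#'
#' @param t strictly increasing observation days.
#' @param P trait values.
#' @return data frame `interval, t_start, t_end, gr` (empty for a single
#'   observation).
#' @examples
#' growth_rate(c(45, 55), c(1.0, 1.18))  # 0.018 per day
#' @export
growth_rate <- function(t, P) {
  stopifnot(length(t) == length(P))
  if (anyDuplicated(t)) stop("duplicate observation days", call. = FALSE)
  o <- order(t); t <- t[o]; P <- P[o]
  if (length(t) < 2)
    return(data.frame(interval = character(), t_start = numeric(),
                      t_end = numeric(), gr = numeric()))
  i0 <- head(t, -1); i1 <- tail(t, -1)
  lab <- vapply(seq_along(i0), function(k) {
    m <- which(.period_dap[-length(.period_dap)] == i0[k] &
               .period_dap[-1] == i1[k])
    if (length(m) == 1) paste0("P", m) else paste0("I", k)
  }, character(1))
  data.frame(interval = lab, t_start = i0, t_end = i1,
             gr = diff(P) / diff(t))
}

#' One-way cultivar ANOVA per trait and date
#'
#' Fixed-effects one-way ANOVA (F-test) of each trait against the
#' cultivar factor, separately for every observation date.  P-values are
#' reported uncorrected across dates and traits by default; set
#' `p_adjust = "BH"` for a Benjamini-Hochberg correction.
#'
#' @param traits data frame with columns `plot_id`, `dap`, one column
#'   per trait, and (via `groups` or a `cultivar` column) group labels.
#' @param groups cultivar label per row; defaults to `traits$cultivar`.
#' @param trait_cols trait column names; default: all numeric columns
#'   except `dap`.
#' @param p_adjust multiple-testing correction method (default none).
#' @return data frame `trait, dap, p_value` (plus `p_adj` when
#'   corrected).
#' @export
cultivar_anova <- function(traits, groups = traits$cultivar,
                           trait_cols = NULL, p_adjust = "none") {
  stopifnot(!is.null(groups))
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need at least 2 cultivars", call. = FALSE)
  if (is.null(trait_cols)) {
    num <- vapply(traits, is.numeric, logical(1))
    trait_cols <- setdiff(names(traits)[num], c("dap", "n_points"))
  }
  dap <- if (!is.null(traits$dap)) traits$dap else rep(NA_real_, nrow(traits))
  out <- do.call(rbind, lapply(unique(dap), function(d) {
    sel <- if (is.na(d)) is.na(dap) else !is.na(dap) & dap == d
    do.call(rbind, lapply(trait_cols, function(tc) {
      y <- traits[[tc]][sel]; g <- droplevels(groups[sel])
      cc <- is.finite(y)
      if (nlevels(droplevels(g[cc])) < 2 || any(table(g[cc]) < 2))
        stop(sprintf(
          "trait '%s' at dap %s: need >= 2 groups with >= 2 plots each",
          tc, d), call. = FALSE)
      p <- anova(lm(y[cc] ~ g[cc]))[["Pr(>F)"]][1]
      data.frame(trait = tc, dap = d, p_value = p)
    }))
  }))
  rownames(out) <- NULL
  if (p_adjust != "none") out$p_adj <- stats::p.adjust(out$p_value, p_adjust)
  out
}

#' Trait-versus-yield regression by date
#'
#' Ordinary least-squares simple regression of final yield on each trait
#' at each observation date, either per cultivar or pooled, reporting
#' the coefficient of determination R^2.
#'
#' @param traits trait table with `plot_id`, `dap` and trait columns.
#' @param yields data frame `plot_id, cultivar, yield`.
#' @param trait_cols trait column names (default: numeric columns except
#'   `dap` and `n_points`).
#' @param by `"cultivar"` (one regression per cultivar) or `"pooled"`.
#' @return data frame `trait, dap, cultivar, n, r2, slope`; `r2` is `NA`
#'   with a warning when the trait has zero variance, and fewer than 3
#'   matched plots is an error.
#' @export
trait_yield_regression <- function(traits, yields, trait_cols = NULL,
                                   by = c("cultivar", "pooled")) {
  by <- match.arg(by)
  stopifnot(all(c("plot_id", "yield") %in% names(yields)))
  if (any(yields$yield < 0)) stop("yields must be non-negative", call. = FALSE)
  if (is.null(trait_cols)) {
    num <- vapply(traits, is.numeric, logical(1))
    trait_cols <- setdiff(names(traits)[num], c("dap", "n_points"))
  }
  if ("cultivar" %in% names(traits) && "cultivar" %in% names(yields))
    traits <- traits[, setdiff(names(traits), "cultivar")]
  m <- merge(traits, yields, by = "plot_id")
  if (nrow(m) == 0) stop("no matched plot_ids", call. = FALSE)
  groups <- if (by == "cultivar") {
    stopifnot(!is.null(m$cultivar))
    split(seq_len(nrow(m)), m$cultivar)
  } else list(pooled = seq_len(nrow(m)))
  dap <- if (!is.null(m$dap)) m$dap else rep(NA_real_, nrow(m))
  out <- list()
  for (gname in names(groups)) {
    gi <- groups[[gname]]
    for (d in unique(dap[gi])) {
      sel <- gi[(is.na(d) & is.na(dap[gi])) |
                (!is.na(d) & !is.na(dap[gi]) & dap[gi] == d)]
      for (tc in trait_cols) {
        x <- m[[tc]][sel]; yld <- m$yield[sel]
        cc <- is.finite(x) & is.finite(yld)
        if (sum(cc) < 3)
          stop(sprintf("trait '%s', %s, dap %s: fewer than 3 matched plots",
                       tc, gname, d), call. = FALSE)
        if (stats::var(x[cc]) == 0) {
          warning(sprintf("trait '%s' constant in %s at dap %s; R^2 undefined",
                          tc, gname, d))
          out[[length(out) + 1]] <- data.frame(
            trait = tc, dap = d, cultivar = gname, n = sum(cc),
            r2 = NA_real_, slope = NA_real_)
          next
        }
        f <- lm(yld[cc] ~ x[cc])
        out[[length(out) + 1]] <- data.frame(
          trait = tc, dap = d, cultivar = gname, n = sum(cc),
          r2 = summary(f)$r.squared, slope = coef(f)[2])
      }
    }
  }
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Simulate a multi-date field trait table
#'
#' Generates plot-level trait observations for several cultivars over a
#' monitoring calendar by evaluating cultivar-specific logistic growth
#' curves plus plot effects and measurement noise, together with final
#' yields linearly coupled to the plot-level canopy volume asymptote.
#' Used for testing the growth-analysis stage at desk scale.
#'
#' @param n_cultivars number of cultivars.
#' @param plots_per_cultivar replicate plots per cultivar.
#' @param dap observation days (DAP).
#' @param xn per-cultivar asymptotes (recycled); defaults emulate
#'   maximum canopy heights of distinct cultivars.
#' @param x0 initial trait value at the first day.
#' @param tau rate coefficient (per day).
#' @param plot_sd between-plot sd of the asymptote.
#' @param noise_sd measurement noise sd.
#' @param yield_base,yield_slope,yield_sd yield model: `yield_base +
#'   yield_slope * (plot asymptote deviation) + N(0, yield_sd)`.
#' @param seed RNG seed.
#' @return list with `traits` (plot_id, cultivar, dap, trait) and
#'   `yields` (plot_id, cultivar, yield).
#' @export
simulate_field_traits <- function(n_cultivars = 4, plots_per_cultivar = 32,
                                  dap = c(45, 52, 67, 74, 88, 95, 102, 109),
                                  xn = c(1.08, 1.08, 0.96, 0.88),
                                  x0 = 0.15, tau = 0.11,
                                  plot_sd = 0.06, noise_sd = 0.02,
                                  yield_base = 900, yield_slope = 800,
                                  yield_sd = 80, seed = 1L) {
  xn <- rep_len(xn, n_cultivars)
  with_seed(seed, {
    rows <- list(); yrows <- list()
    for (cv in seq_len(n_cultivars)) {
      for (p in seq_len(plots_per_cultivar)) {
        pid <- sprintf("c%d_p%02d", cv, p)
        xn_p <- max(xn[cv] + rnorm(1, sd = plot_sd), x0 + 0.05)
        y <- logistic3(dap, x0, xn_p, tau, T = min(dap)) +
          rnorm(length(dap), sd = noise_sd)
        rows[[length(rows) + 1]] <- data.frame(
          plot_id = pid, cultivar = paste0("cv", cv), dap = dap,
          trait = pmax(y, 1e-3))
        yrows[[length(yrows) + 1]] <- data.frame(
          plot_id = pid, cultivar = paste0("cv", cv),
          yield = max(yield_base + yield_slope * (xn_p - mean(xn)) +
                        rnorm(1, sd = yield_sd), 0))
      }
    }
    list(traits = do.call(rbind, rows), yields = do.call(rbind, yrows))
  })
}
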