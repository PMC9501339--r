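# Growth-curve and structure-relation model fits, plus rank correlation.

#' Growth series container
#'
#' A time series of one biofilm metric over collection days.
#'
#' @param t Collection times in days, strictly increasing, length >= 4.
#' @param y Metric values, same length as `t`.
#' @param metric Metric name (e.g. `"coverage"`, `"ac"`, `"biovolume"`).
#' @param units Units string (e.g. `""` for fractions, `"um3"`).
#' @return A tibble of class `growth_series` with columns `t`, `y` and
#'   attributes `metric`, `units`.
#' @export
growth_series <- function(t, y, metric = "coverage", units = "") {
  if (length(t) != length(y) || length(t) < 4L)
    abort("`t` and `y` must have equal length >= 4.")
  if (any(diff(t) <= 0)) abort("`t` must be strictly increasing.")
  out <- tibble(t = as.numeric(t), y = as.numeric(y))
  class(out) <- c("growth_series", class(out))
  attr(out, "metric") <- metric
  attr(out, "units") <- units
  out
}

new_biofilm_fit <- function(model, estimates, fit, data, converged,
                            notes = character(0)) {
  obs <- data$y
  pred <- if (converged) predict_biofilm(model, coef_named(estimates), data$x)
          else rep(NA_real_, length(obs))
  r <- if (converged && sd(pred) > 0 && sd(obs) > 0) cor(pred, obs) else NA_real_
  structure(list(model = model, estimates = estimates, fit = fit,
                 data = data, R = r, converged = converged, notes = notes),
            class = "biofilm_fit")
}

coef_named <- function(est) setNames(est$estimate, est$term)

predict_biofilm <- function(model, p, x) {
  switch(model,
    monoexponential = {
      # degenerate flat fit carries Vc = NA with A = 0; the decay term is 0
      ex <- if (is.finite(p[["Vc"]])) exp(-x / p[["Vc"]]) else rep(0, length(x))
      p[["SReq"]] + p[["A"]] * ex
    },
    logistic = p[["f_max"]] / (1 + exp(-p[["k"]] * (x - p[["t0"]]))),
    abort(sprintf("unknown model '%s'.", model)))
}

#' @export
print.biofilm_fit <- function(x, ...) {
  cat(sprintf("<biofilm_fit: %s> converged: %s | fit R = %.4g\n",
              x$model, x$converged, x$R))
  print(x$estimates)
  if (length(x$notes)) cat("notes:", paste(x$notes, collapse = "; "), "\n")
  invisible(x)
}

#' @rdname fit_monoexponential
#' @param x A `biofilm_fit`.
#' @param ... Unused.
#' @method tidy biofilm_fit
#' @export
tidy.biofilm_fit <- function(x, ...) x$estimates

#' @rdname fit_monoexponential
#' @method glance biofilm_fit
#' @export
glance.biofilm_fit <- function(x, ...) {
  tibble(model = x$model, R = x$R, converged = x$converged,
         n = length(x$data$y),
         sigma = if (x$converged) sqrt(mean(resid_biofilm(x)^2)) else NA_real_,
         notes = paste(x$notes, collapse = "; "))
}

resid_biofilm <- function(x) {
  x$data$y - predict_biofilm(x$model, coef_named(x$estimates), x$data$x)
}

#' Fit the monoexponential roughness-biovolume relation
#'
#' Fits `SR(V) = SReq + A * exp(-V / Vc)` by Levenberg-Marquardt least
#' squares, the saturating relation between a biofilm roughness measure and
#' its biovolume: roughness rises (A < 0) toward the equilibrium value
#' `SReq` with characteristic volume `Vc > 0` (enforced as a bound).
#' Initialization uses the asymptotic data themselves (`SReq` from the SR
#' mean over the top V-quartile, `A` from the smallest-V point, `Vc` from a
#' third of the V range), plus `n_starts - 1` jittered restarts to escape
#' local minima; the converged start with the lowest residual sum of squares
#' wins.
#'
#' A constant-SR series is degenerate: the fit reports `A = 0`,
#' `SReq = mean(SR)` and flags `Vc` as unidentifiable instead of failing.
#'
#' @param V Biovolume values, um^3, >= 5 points.
#' @param SR Roughness values (any roughness metric on a consistent scale).
#' @param n_starts Number of initializations (default 3).
#' @param seed RNG seed for the jittered restarts.
#' @return A `biofilm_fit` object; `tidy()` gives term/estimate/std.error,
#'   `glance()` the fit-level summary including the correlation R between
#'   fitted and observed values.
#' @export
fit_monoexponential <- function(V, SR, n_starts = 3L, seed = 1L) {
  if (length(V) != length(SR) || length(V) < 5L)
    abort("need >= 5 (V, SR) pairs of equal length.")
  if (any(V < 0)) abort("biovolume values must be non-negative.")
  dat <- data.frame(x = as.numeric(V), y = as.numeric(SR))
  if (sd(dat$y) == 0) {
    est <- tibble(term = c("SReq", "A", "Vc"),
                  estimate = c(mean(dat$y), 0, NA_real_),
                  std.error = NA_real_)
    return(new_biofilm_fit("monoexponential", est, NULL, dat, TRUE,
                           notes = "Vc unidentifiable: constant SR"))
  }
  top <- dat$y[dat$x >= quantile(dat$x, 0.75)]
  init <- c(SReq = mean(top),
            A = dat$y[which.min(dat$x)] - mean(top),
            Vc = max(diff(range(dat$x)) / 3, .Machine$double.eps))
  fit <- multistart_nls(
    y ~ SReq + A * exp(-x / Vc), dat, init,
    lower = c(SReq = -Inf, A = -Inf, Vc = 1e-12),
    n_starts = n_starts, seed = seed)
  finish_fit("monoexponential", fit, dat, c("SReq", "A", "Vc"))
}

#' Fit a logistic coverage-versus-time curve
#'
#' Fits `f(t) = f_max / (1 + exp(-k (t - t0)))` to a substratum-coverage
#' growth series: a lag phase, an exponential-like rise with rate `k`
#' (1/day) around the midpoint `t0` (day), and a plateau at `f_max`
#' (bounded to (0, 1]). A monotone-decreasing series is model-mismatched;
#' the fit then either fails to converge or reports `k < 0`, which is
#' flagged in `notes`.
#'
#' @param gs A [growth_series()] of coverage fractions in `[0, 1]`, or a
#'   numeric vector `t` when `y` is also given.
#' @param y Coverage values when `gs` is a plain time vector.
#' @inheritParams fit_monoexponential
#' @return A `biofilm_fit` (see [fit_monoexponential()]).
#' @export
fit_sigmoid_coverage <- function(gs, y = NULL, n_starts = 3L, seed = 1L) {
  if (inherits(gs, "growth_series")) { t <- gs$t; y <- gs$y }
  else { t <- gs }
  if (length(t) != length(y) || length(t) < 4L)
    abort("need >= 4 (t, y) pairs of equal length.")
  if (min(y) < 0 || max(y) > 1)
    abort("coverage values must lie in [0, 1].")
  dat <- data.frame(x = as.numeric(t), y = as.numeric(y))
  i_half <- which.min(abs(dat$y - max(dat$y) / 2))
  init <- c(f_max = max(max(dat$y), 1e-3), k = 0.5, t0 = dat$x[i_half])
  fit <- multistart_nls(
    y ~ f_max / (1 + exp(-k * (x - t0))), dat, init,
    lower = c(f_max = 1e-9, k = -Inf, t0 = -Inf),
    upper = c(f_max = 1, k = Inf, t0 = Inf),
    n_starts = n_starts, seed = seed)
  out <- finish_fit("logistic", fit, dat, c("f_max", "k", "t0"))
  if (out$converged && out$estimates$estimate[out$estimates$term == "k"] < 0)
    out$notes <- c(out$notes, "k < 0: series decreases, logistic growth mismatched")
  out
}

# Levenberg-Marquardt with jittered restarts; returns the best converged
# nlsLM object or NULL.
multistart_nls <- function(formula, dat, init, lower, upper = NULL,
                           n_starts, seed) {
  starts <- withr::with_seed(seed, {
    lapply(seq_len(n_starts), function(i) {
      if (i == 1L) return(init)
      jit <- init * runif(length(init), 0.5, 1.5)
      pmax(jit, lower + 1e-12)
    })
  })
  fits <- lapply(starts, function(s) {
    tryCatch(
      minpack.lm::nlsLM(formula, data = dat, start = as.list(s),
                        lower = lower, upper = upper,
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) return(NULL)
  dev <- vapply(fits, stats::deviance, numeric(1))
  fits[[which.min(dev)]]
}

finish_fit <- function(model, fit, dat, terms) {
  if (is.null(fit)) {
    est <- tibble(term = terms, estimate = NA_real_, std.error = NA_real_)
    return(new_biofilm_fit(model, est, NULL, dat, FALSE,
                           notes = "non-convergence"))
  }
  sm <- summary(fit)$coefficients
  est <- tibble(term = terms,
                estimate = unname(sm[terms, "Estimate"]),
                std.error = unname(sm[terms, "Std. Error"]))
  notes <- character(0)
  if (model == "monoexponential") {
    vc <- est$estimate[est$term == "Vc"]
    se_vc <- est$std.error[est$term == "Vc"]
    a <- est$estimate[est$term == "A"]
    if (!is.finite(se_vc) || se_vc > 10 * abs(vc) ||
        abs(a) < 1e-8 * max(1, abs(est$estimate[est$term == "SReq"])))
      notes <- "Vc unidentifiable: flat or uninformative SR series"
  }
  new_biofilm_fit(model, est, fit, dat, TRUE, notes = notes)
}

#' Spearman rank correlation
#'
#' Rank correlation between two metric series, with average ranks assigned
#' to ties — the cross-correlation routine used to relate structural biofilm
#' descriptors to each other and to water trophic-state indexes.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    abort("`x` and `y` must have equal length >= 3.")
  if (sd(x) == 0 || sd(y) == 0)
    abort("Spearman correlation undefined for constant input.")
  cor(x, y, method = "spearman")
}
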