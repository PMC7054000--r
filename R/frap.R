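#' Normalized iFRAP trace
#'
#' A time series of the normalized difference between unbleached and
#' bleached regions. Time is in minutes from the first post-bleach frame
#' (pre-bleach frames carry negative times); after normalization the first
#' post-bleach signal is 1.
#'
#' @param time_min Time in minutes, strictly increasing; the first
#'   post-bleach frame is at 0.
#' @param signal Normalized difference signal.
#' @param n_prebleach Number of pre-bleach frames included at the start.
#' @param metadata Optional named list (condition label, cell id, ...).
#' @return A `frap_trace` data frame with attributes `n_prebleach`,
#'   `metadata`.
#' @export
frap_trace <- function(time_min, signal, n_prebleach = 0L, metadata = list()) {
  if (length(time_min) != length(signal)) stop("time and signal lengths differ")
  if (is.unsorted(time_min, strictly = TRUE)) stop("time must be strictly increasing")
  n_prebleach <- as.integer(n_prebleach)
  if (n_prebleach > 0 && any(time_min[seq_len(n_prebleach)] >= 0))
    stop("pre-bleach frames must carry negative times")
  out <- data.frame(time_min = as.numeric(time_min),
                    signal = as.numeric(signal))
  attr(out, "n_prebleach") <- n_prebleach
  attr(out, "metadata") <- metadata
  class(out) <- c("frap_trace", "data.frame")
  out
}

# post-bleach part of a trace
.postbleach <- function(trace) {
  stopifnot(inherits(trace, "frap_trace"))
  trace[trace$time_min >= 0, , drop = FALSE]
}

#' Normalize raw iFRAP intensity series
#'
#' Each channel is divided by its own pre-bleach mean (correcting for
#' acquisition intensity), the difference (unbleached minus bleached) is
#' taken, and the result is rescaled so the first post-bleach frame equals
#' 1. An optional background series is subtracted from both channels first.
#'
#' @param bleached,unbleached Raw intensity series of equal length, longer
#'   than `n_prebleach`.
#' @param n_prebleach Number of leading pre-bleach frames.
#' @param background Optional background series to subtract.
#' @param time_min Optional time axis (minutes); default frame index with
#'   the first post-bleach frame at 0.
#' @return A [frap_trace].
#' @export
normalize_ifrap <- function(bleached, unbleached, n_prebleach,
                            background = NULL, time_min = NULL) {
  n <- length(bleached)
  if (length(unbleached) != n) stop("bleached and unbleached lengths differ")
  n_prebleach <- as.integer(n_prebleach)
  if (n_prebleach < 1 || n <= n_prebleach)
    stop("need at least one pre-bleach and one post-bleach frame")
  if (!is.null(background)) {
    bleached <- bleached - background
    unbleached <- unbleached - background
  }
  pre <- seq_len(n_prebleach)
  mb <- mean(bleached[pre]); mu <- mean(unbleached[pre])
  if (mb <= 0 || mu <= 0) stop("pre-bleach mean must be positive")
  diff <- unbleached / mu - bleached / mb
  first <- diff[n_prebleach + 1L]
  if (!is.finite(first) || first <= 0)
    stop("degenerate trace: first post-bleach difference is not positive; cannot rescale")
  if (is.null(time_min))
    time_min <- seq_len(n) - n_prebleach - 1L
  frap_trace(time_min, diff / first, n_prebleach = n_prebleach)
}

#' Fit constrained exponential kinetics to an iFRAP trace
#'
#' Nonlinear least squares (Levenberg-Marquardt with box constraints) of the
#' post-bleach signal to `f(t) = exp(-koff1 * t)` (single) or
#' `f(t) = a * exp(-koff1 * t) + (1 - a) * exp(-koff2 * t)` (double).
#' Residence times are `1 / koff`. The double model is constrained to
#' `1/koff1` in \[1, 40\] min and `1/koff2` in \[90, 900\] min (1.5-15 hr)
#' with `a` in \[0, 1\]; the single model to residence in \[0.5, 1000\] min.
#' Five deterministic starting points (constraint-box corners plus center)
#' are tried and the best converged fit returned.
#'
#' @param trace A [frap_trace] with at least 10 post-bleach points; the
#'   double model additionally requires a post-bleach duration of at least
#'   30 min.
#' @param model `"single"` or `"double"`.
#' @return An `exp_fit` list: `model`, `a` (dynamic fraction; 1 for single),
#'   `koff1`, `koff2` (1/min; NA for single), `residence1`, `residence2`
#'   (min), `rss`, `n`, `converged`.
#' @export
fit_exponential <- function(trace, model = c("single", "double")) {
  model <- match.arg(model)
  pb <- .postbleach(trace)
  if (nrow(pb) < 10) stop("need at least 10 post-bleach points")
  t <- pb$time_min; y <- pb$signal
  if (model == "double" && max(t) < 30)
    stop("double model requires a post-bleach duration of at least 30 min")
  if (model == "single") {
    lower <- c(k1 = 1 / 1000); upper <- c(k1 = 1 / 0.5)
    starts <- lapply(c(0.5, 5, 50, 500, 1000), function(r) c(k1 = 1 / r))
    resid <- function(par) y - exp(-par[["k1"]] * t)
  } else {
    lower <- c(a = 0, k1 = 1 / 40, k2 = 1 / 900)
    upper <- c(a = 1, k1 = 1 / 1, k2 = 1 / 90)
    starts <- list(c(a = 0.25, k1 = 1 / 5, k2 = 1 / 120),
                   c(a = 0.75, k1 = 1 / 5, k2 = 1 / 600),
                   c(a = 0.25, k1 = 1 / 30, k2 = 1 / 600),
                   c(a = 0.75, k1 = 1 / 30, k2 = 1 / 120),
                   c(a = 0.5, k1 = 1 / 20.5, k2 = 1 / 495))
    resid <- function(par)
      y - par[["a"]] * exp(-par[["k1"]] * t) -
        (1 - par[["a"]]) * exp(-par[["k2"]] * t)
  }
  ctrl <- minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-14,
                                     ptol = 1e-14)
  fits <- list()
  for (st in starts) {
    f <- tryCatch(
      minpack.lm::nls.lm(par = st, lower = lower, upper = upper, fn = resid,
                         control = ctrl),
      error = function(e) NULL)
    # info codes 1-4 indicate a successful Levenberg-Marquardt stop
    if (!is.null(f) && f$info %in% 1:4) fits[[length(fits) + 1L]] <- f
  }
  if (length(fits) == 0L)
    stop(sprintf("no starting point converged for the %s model (n = %d, duration %.1f min)",
                 model, length(t), max(t)))
  rss <- vapply(fits, function(f) f$deviance, numeric(1))
  best <- fits[[which.min(rss)]]
  cf <- best$par
  out <- if (model == "single") {
    list(model = "single", a = 1, koff1 = unname(cf["k1"]), koff2 = NA_real_,
         residence1 = 1 / unname(cf["k1"]), residence2 = NA_real_)
  } else {
    list(model = "double", a = unname(cf["a"]), koff1 = unname(cf["k1"]),
         koff2 = unname(cf["k2"]), residence1 = 1 / unname(cf["k1"]),
         residence2 = 1 / unname(cf["k2"]))
  }
  out$rss <- min(rss)
  out$n <- length(t)
  out$converged <- TRUE
  class(out) <- "exp_fit"
  out
}

#' @export
print.exp_fit <- function(x, ...) {
  if (x$model == "single")
    cat(sprintf("single-exponential fit: residence %.3g min (koff %.3g/min), RSS %.3g\n",
                x$residence1, x$koff1, x$rss))
  else
    cat(sprintf(
      "bi-exponential fit: dynamic %.1f%% at %.3g min, stable %.1f%% at %.3g min, RSS %.3g\n",
      100 * x$a, x$residence1, 100 * (1 - x$a), x$residence2, x$rss))
  invisible(x)
}

#' Choose between single and double exponential fits
#'
#' Fits both models and selects the double model when the nested F-test on
#' residual sums of squares rejects at `alpha` and both mixing components
#' are at least `min_component`; otherwise the single model. A trace the
#' single model already fits to numerical precision is classified single
#' without the F-test (the ratio is 0/0-degenerate).
#'
#' @param trace A [frap_trace].
#' @param alpha F-test significance level.
#' @param min_component Minimum mixing fraction for both components.
#' @return A list: `model` ("single"/"double"), `single`, `double` (the two
#'   `exp_fit`s), `p_value` of the F-test.
#' @export
select_model <- function(trace, alpha = 0.05, min_component = 0.05) {
  fs <- fit_exponential(trace, "single")
  fd <- fit_exponential(trace, "double")
  n <- fs$n
  scale2 <- mean(.postbleach(trace)$signal^2)
  if (fs$rss <= n * scale2 * 1e-12) {
    p <- 1
  } else {
    f <- ((fs$rss - fd$rss) / 2) / (fd$rss / (n - 3))
    p <- stats::pf(max(f, 0), 2, n - 3, lower.tail = FALSE)
  }
  double_ok <- p < alpha && min(fd$a, 1 - fd$a) >= min_component
  list(model = if (double_ok) "double" else "single",
       single = fs, double = fd, p_value = p)
}

#' Soluble fraction from the unbleached-region signal
#'
#' The reduction of fluorescence in the unbleached area immediately after
#' photobleaching estimates the freely diffusing (soluble) fraction:
#' `1 - first post-bleach value / pre-bleach mean`, clipped to \[0, 1\].
#'
#' @param unbleached Raw unbleached-region series.
#' @param n_prebleach Number of leading pre-bleach frames.
#' @return Fraction in \[0, 1\].
#' @export
soluble_fraction <- function(unbleached, n_prebleach) {
  n_prebleach <- as.integer(n_prebleach)
  if (length(unbleached) <= n_prebleach)
    stop("series must extend past the pre-bleach frames")
  pre <- mean(unbleached[seq_len(n_prebleach)])
  if (pre <= 0) stop("pre-bleach mean must be positive")
  min(max(1 - unbleached[n_prebleach + 1L] / pre, 0), 1)
}

#' Stable pool as a share of all complexes
#'
#' Combines a fitted stable fraction within one complex subtype with that
#' subtype's share of all complexes: e.g. a 37% stable fraction of a
#' variant that makes up 25% of the total gives 9.25%, i.e. about 9% of all
#' complexes.
#'
#' @param stable_fraction Stable fraction within the subtype, in \[0, 1\].
#' @param subtype_share The subtype's share of all complexes, in \[0, 1\].
#' @return Percentage of all complexes (0-100).
#' @export
stable_pool_percent <- function(stable_fraction, subtype_share) {
  stopifnot(stable_fraction >= 0, stable_fraction <= 1,
            subtype_share >= 0, subtype_share <= 1)
  100 * stable_fraction * subtype_share
}
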