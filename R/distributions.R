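#' Fit a log-binned Gaussian (log-normal) model to event metrics
#'
#' Histograms positive values (spindle durations, amplitudes, inter-spindle
#' intervals, ...) on `n_bins` log-spaced bins, normalizes the bin counts to
#' total probability 1, and least-squares fits a 1- or 2-component Gaussian
#' in log10 space to the binned probabilities. When `n_components = 2` is
#' requested, the second component is retained only if it improves the fit
#' R-squared by more than `delta_r2` (0.02); otherwise the 1-component fit
#' is returned.
#'
#' For a log10-Gaussian component with parameters (mu, sigma), the density
#' of the values themselves peaks at `10^(mu - sigma^2 * ln 10)`, which is
#' the `mode` reported (in the original units). The fit is equivariant under
#' unit rescaling: multiplying the values by c multiplies the modes by c.
#'
#' @param values positive numeric vector, n >= 10.
#' @param n_bins number of log bins (the analyses use 50 or 100).
#' @param n_components 1 or 2.
#' @param delta_r2 minimum R-squared improvement to retain 2 components.
#' @return Object of class `lognormal_fit`: `components` (data.frame with
#'   `mu`, `sigma` in log10 space, `weight`, `mode`), `n_components`,
#'   `r2_fit`, `bins`, `probs`, `n`, `degenerate`.
#' @export
fit_log_histogram <- function(values, n_bins = 50, n_components = 1,
                              delta_r2 = 0.02) {
  bad <- sum(!is.finite(values) | values <= 0)
  if (bad > 0) stop("non-positive or non-finite values: ", bad)
  if (length(values) < 10L) stop("need at least 10 values")
  if (diff(range(values)) == 0) {
    # all mass in one point: degenerate single mode at that value
    return(structure(list(
      components = data.frame(mu = log10(values[1L]), sigma = 0, weight = 1,
                              mode = values[1L]),
      n_components = 1L, r2_fit = NA_real_, bins = NULL, probs = NULL,
      n = length(values), degenerate = TRUE), class = "lognormal_fit"))
  }
  stopifnot(n_components %in% c(1L, 2L))
  lx <- log10(values)
  edges <- seq(min(lx), max(lx), length.out = n_bins + 1L)
  edges[1L] <- edges[1L] - 1e-9; edges[n_bins + 1L] <- edges[n_bins + 1L] + 1e-9
  counts <- hist(lx, breaks = edges, plot = FALSE)$counts
  probs <- counts / sum(counts)
  centers <- (edges[-1L] + edges[-(n_bins + 1L)]) / 2
  fit1 <- .fit_gauss_bins(centers, probs, 1L)
  best <- fit1
  if (n_components == 2L) {
    fit2 <- .fit_gauss_bins(centers, probs, 2L)
    if (!is.null(fit2) && !is.null(fit1) && fit2$r2 - fit1$r2 > delta_r2)
      best <- fit2
    else if (is.null(fit1) && !is.null(fit2)) best <- fit2
  }
  if (is.null(best)) stop("log-histogram Gaussian fit failed to converge")
  comp <- best$components
  comp$mode <- 10^(comp$mu - comp$sigma^2 * log(10))
  comp <- comp[order(comp$mode), , drop = FALSE]
  rownames(comp) <- NULL
  structure(list(components = comp, n_components = nrow(comp),
                 r2_fit = best$r2, bins = 10^edges, probs = probs,
                 n = length(values), degenerate = FALSE),
            class = "lognormal_fit")
}

# least-squares Gaussian(s) on binned log10 probabilities
.fit_gauss_bins <- function(u, p, k) {
  w <- sum(p)
  mu0 <- sum(u * p) / w
  s0 <- sqrt(max(sum((u - mu0)^2 * p) / w, (u[2] - u[1])^2))
  df <- data.frame(u = u, p = p)
  res <- NULL
  if (k == 1L) {
    res <- tryCatch(minpack.lm::nlsLM(
      p ~ a * exp(-(u - m)^2 / (2 * s^2)), data = df,
      start = list(a = max(p), m = mu0, s = s0),
      lower = c(0, min(u), (u[2] - u[1]) / 4),
      upper = c(Inf, max(u), diff(range(u))),
      control = nls.control(maxiter = 200, warnOnly = TRUE)),
      error = function(e) NULL)
  } else {
    # seed the two components from the two dominant smoothed local maxima
    sm <- as.numeric(stats::filter(p, rep(1 / 3, 3), sides = 2))
    sm[is.na(sm)] <- 0
    pk <- which(sm >= c(-Inf, sm[-length(sm)]) & sm > c(sm[-1L], -Inf) & sm > 0)
    pk <- pk[order(-sm[pk])]
    m1 <- if (length(pk) >= 1L) u[pk[1L]] else mu0 - s0 / 2
    m2 <- if (length(pk) >= 2L) u[pk[2L]] else mu0 + s0 / 2
    res <- tryCatch(minpack.lm::nlsLM(
      p ~ a1 * exp(-(u - m1p)^2 / (2 * s1^2)) + a2 * exp(-(u - m2p)^2 / (2 * s2^2)),
      data = df,
      start = list(a1 = max(p), m1p = m1, s1 = s0 / 2,
                   a2 = max(p) / 2, m2p = m2, s2 = s0 / 2),
      lower = c(0, min(u), (u[2] - u[1]) / 4, 0, min(u), (u[2] - u[1]) / 4),
      upper = c(Inf, max(u), diff(range(u)), Inf, max(u), diff(range(u))),
      control = nls.control(maxiter = 400, warnOnly = TRUE)),
      error = function(e) NULL)
  }
  if (is.null(res)) return(NULL)
  cf <- coef(res)
  fitted_p <- stats::predict(res)
  ssr <- sum((p - fitted_p)^2); sst <- sum((p - mean(p))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  if (k == 1L) {
    comps <- data.frame(mu = cf[["m"]], sigma = abs(cf[["s"]]), weight = 1)
  } else {
    area <- c(cf[["a1"]] * abs(cf[["s1"]]), cf[["a2"]] * abs(cf[["s2"]]))
    comps <- data.frame(mu = c(cf[["m1p"]], cf[["m2p"]]),
                        sigma = abs(c(cf[["s1"]], cf[["s2"]])),
                        weight = area / sum(area))
  }
  list(components = comps, r2 = r2)
}

#' @export
print.lognormal_fit <- function(x, ...) {
  cat(sprintf("<lognormal_fit> %d component(s), n = %d%s\n",
              x$n_components, x$n, if (x$degenerate) " [degenerate]" else ""))
  for (i in seq_len(nrow(x$components)))
    cat(sprintf("  mode %.4g (mu %.3f, sigma %.3f, weight %.2f)\n",
                x$components$mode[i], x$components$mu[i],
                x$components$sigma[i], x$components$weight[i]))
  if (!is.na(x$r2_fit)) cat(sprintf("  fit R^2 %.3f\n", x$r2_fit))
  invisible(x)
}

#' @export
coef.lognormal_fit <- function(object, ...) object$components

#' @export
plot.lognormal_fit <- function(x, ...) {
  if (x$degenerate || is.null(x$bins)) {
    message("degenerate fit: nothing to plot"); return(invisible(x))
  }
  centers <- sqrt(x$bins[-1L] * x$bins[-length(x$bins)])
  plot(centers, x$probs, log = "x", xlab = "value", ylab = "probability", ...)
  u <- log10(centers)
  tot <- 0
  for (i in seq_len(nrow(x$components))) {
    ci <- x$components[i, ]
    # reconstruct each component's amplitude from its weight and width
    bw <- diff(log10(x$bins))[1L]
    a <- ci$weight * bw / (ci$sigma * sqrt(2 * pi))
    tot <- tot + a * exp(-(u - ci$mu)^2 / (2 * ci$sigma^2))
  }
  lines(centers, tot, col = 2)
  invisible(x)
}

#' Compare an event metric across groups (ANOVA + Tukey HSD)
#'
#' Shared implementation with [correlation_group_compare()], operating on
#' per-event metrics. Durations, amplitudes and inter-spindle intervals are
#' log10-transformed before testing (they are log-normally distributed).
#'
#' @param values numeric vector of per-event metrics.
#' @param groups grouping factor.
#' @param log_transform log10-transform the values first (default TRUE;
#'   requires positive values).
#' @return An `axo_group_compare` object.
#' @export
group_compare <- function(values, groups, log_transform = TRUE) {
  if (log_transform) {
    if (any(values <= 0)) stop("log transform requires positive values")
    values <- log10(values)
  }
  correlation_group_compare(values, groups)
}
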