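#' Lags from slow-oscillation peaks to the spindles they precede
#'
#' For each spindle, the lag is the time from the peak of the slow
#' oscillation that directly precedes the spindle peak to the spindle peak
#' itself. Spindles with no preceding slow oscillation are dropped and
#' counted.
#'
#' @param so slow-oscillation epochs (data.frame with `peak_s`, e.g. from
#'   [detect_so_epochs()]) or a numeric vector of SO peak times.
#' @param sp spindle events (data.frame with `peak_s`, e.g. from
#'   [detect_spindles()]) or a numeric vector of spindle peak times.
#' @return list with `lags_s` (positive), `n_dropped`.
#' @export
nesting_lags <- function(so, sp) {
  so_peaks <- if (is.data.frame(so)) so$peak_s else as.numeric(so)
  sp_peaks <- if (is.data.frame(sp)) sp$peak_s else as.numeric(sp)
  so_peaks <- sort(so_peaks)
  idx <- findInterval(sp_peaks, so_peaks)  # latest SO peak <= spindle peak
  # strict precedence: an SO exactly at the spindle peak does not precede it
  tie <- idx >= 1L & so_peaks[pmax(idx, 1L)] == sp_peaks
  idx[tie] <- idx[tie] - 1L
  drop <- idx < 1L
  list(lags_s = sp_peaks[!drop] - so_peaks[idx[!drop]],
       n_dropped = sum(drop))
}

#' Fit the log-log distribution of nesting lags
#'
#' Histograms the lags on `n_bins` log-spaced bins and fits, by ordinary
#' least squares, log10(count) against log10(lag bin center) over the bins
#' above a short-time boundary. The boundary is grid-searched over the
#' log-bin left edges that fall inside `boundary_range` (default 0.001-0.5 s)
#' and the boundary with the best R-squared is returned. Empty bins are
#' skipped rather than floor-imputed, which would bias the slope.
#'
#' For lags drawn from a power law p(t) ~ t^-alpha, log-spaced bin counts
#' scale as t^(1 - alpha), so the fitted slope estimates -(alpha - 1).
#'
#' @param lags numeric vector of positive lags in seconds (>= 20 required).
#' @param n_bins number of log-spaced bins, default 50.
#' @param boundary_range grid-search range for the short-time boundary, s.
#' @return Object of class `nesting_fit`: `lags_s`, `bins` (edges), `counts`,
#'   `boundary_s`, `slope`, `intercept`, `r2`, `median_lag_s`, `n`,
#'   `grid` (data.frame of candidate boundaries and their R-squared).
#' @export
fit_loglog <- function(lags, n_bins = 50, boundary_range = c(0.001, 0.5)) {
  lags <- lags[is.finite(lags) & lags > 0]
  if (length(lags) < 20L) stop("need at least 20 positive lags")
  if (diff(range(lags)) == 0) stop("degenerate lags: all values equal")
  edges <- 10^seq(log10(min(lags)), log10(max(lags)), length.out = n_bins + 1L)
  edges[1L] <- edges[1L] * (1 - 1e-9); edges[n_bins + 1L] <- edges[n_bins + 1L] * (1 + 1e-9)
  counts <- hist(lags, breaks = edges, plot = FALSE)$counts
  centers <- sqrt(edges[-1L] * edges[-(n_bins + 1L)])
  grid <- edges[-(n_bins + 1L)]
  grid <- grid[grid >= boundary_range[1] & grid <= boundary_range[2]]
  if (!length(grid)) grid <- edges[1L]
  fits <- lapply(grid, function(b) {
    use <- which(edges[-(n_bins + 1L)] >= b - 1e-12 & counts > 0)
    if (length(use) < 3L) return(NULL)
    lx <- log10(centers[use]); ly <- log10(counts[use])
    f <- stats::lm.fit(cbind(1, lx), ly)
    ssr <- sum(f$residuals^2); sst <- sum((ly - mean(ly))^2)
    r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
    list(boundary = b, slope = f$coefficients[2L],
         intercept = f$coefficients[1L], r2 = r2, n_bins_used = length(use))
  })
  fits <- fits[!vapply(fits, is.null, logical(1))]
  if (!length(fits)) stop("no boundary candidate left >= 3 non-empty bins")
  r2s <- vapply(fits, `[[`, numeric(1), "r2")
  best <- fits[[which.max(r2s)]]
  structure(list(lags_s = lags, bins = edges, counts = counts,
                 boundary_s = best$boundary, slope = unname(best$slope),
                 intercept = unname(best$intercept), r2 = best$r2,
                 median_lag_s = median(lags), n = length(lags),
                 grid = data.frame(
                   boundary_s = vapply(fits, `[[`, numeric(1), "boundary"),
                   r2 = r2s)),
            class = "nesting_fit")
}

#' @export
print.nesting_fit <- function(x, ...) {
  cat(sprintf("<nesting_fit> n = %d lags, median %.3g s\n", x$n, x$median_lag_s))
  cat(sprintf("  log-log fit above %.3g s: slope %.3f, R^2 %.3f\n",
              x$boundary_s, x$slope, x$r2))
  invisible(x)
}

#' @export
coef.nesting_fit <- function(object, ...) {
  c(intercept = object$intercept, slope = object$slope)
}

#' @export
plot.nesting_fit <- function(x, ...) {
  centers <- sqrt(x$bins[-1L] * x$bins[-length(x$bins)])
  use <- x$counts > 0
  plot(centers[use], x$counts[use], log = "xy",
       xlab = "lag (s)", ylab = "count",
       main = "slow-oscillation to spindle lag", ...)
  xs <- centers[use & centers >= x$boundary_s]
  lines(xs, 10^(x$intercept + x$slope * log10(xs)), col = 2)
  abline(v = x$boundary_s, lty = 3)
  invisible(x)
}
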