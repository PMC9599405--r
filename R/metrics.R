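#' Quantify a strand gradient profile
#'
#' Summary descriptors of a concentration (or fluorescence) profile along a
#' printed strand. The dominant direction is taken from the sign of the
#' rank correlation between position and value; a monotone envelope is fitted
#' by isotonic regression (pool-adjacent-violators) in that direction, and the
#' 10/50/90% crossings of its span are located by linear interpolation.
#' Measuring on the monotone envelope deliberately excludes a descending
#' inner-filter tail from the transition width; the tail is instead reported
#' through plateau/decline detection.
#'
#' @param profile A [strand_profile] (columns `s_m`, `C_A`), or any data frame
#'   whose first two columns are position and value.
#' @param plateau_tol Plateau tolerance as a fraction of the profile span
#'   (default 0.05): samples within `plateau_tol * span` of the maximum count
#'   as plateau; minimum plateau length is 2 samples.
#' @return A `gradient_metrics` object: `midpoint_m` (position of the 50%
#'   crossing; `NA` with `constant = TRUE` for a flat profile),
#'   `width_10_90_m`, `monotone_fraction`, `direction` (+1 rising, -1
#'   falling), `plateau_detected`, `plateau_interval_m`, `decline_detected`.
#' @examples
#' s <- seq(0, 0.2, by = 0.002)
#' prof <- strand_profile(s, 1 / (1 + exp(-(s - 0.1) / 0.01)))
#' compute_gradient_metrics(prof)   # midpoint ~0.1 m, width ~4.39 * 0.01 m
#' @export
compute_gradient_metrics <- function(profile, plateau_tol = 0.05) {
  stopifnot(is.data.frame(profile), ncol(profile) >= 2L)
  s <- profile[[1]]
  v <- profile[[2]]
  if (length(s) < 4L) stop("need at least 4 samples")
  if (any(diff(s) <= 0)) stop("positions must be strictly increasing")

  span_raw <- diff(range(v))
  if (span_raw == 0) {
    out <- list(midpoint_m = NA_real_, width_10_90_m = 0,
                monotone_fraction = 1, direction = 0L,
                plateau_detected = TRUE, plateau_interval_m = range(s),
                decline_detected = FALSE, constant = TRUE)
    class(out) <- "gradient_metrics"
    return(out)
  }

  rho <- suppressWarnings(stats::cor(s, v, method = "spearman"))
  if (is.na(rho) || rho == 0) rho <- sum(diff(v))
  dir <- if (rho >= 0) 1L else -1L

  iso <- stats::isoreg(s, dir * v)
  env <- dir * iso$yf                       # monotone envelope, original scale
  lo <- min(env); hi <- max(env)
  span <- hi - lo
  if (span == 0) {
    midpoint <- NA_real_; width <- 0; constant <- TRUE
  } else {
    constant <- FALSE
    cross <- function(level) {
      y <- dir * env                        # increasing sequence
      lv <- dir * level
      i <- which(y >= lv - 1e-15)[1]
      if (i == 1L) return(s[1])
      s[i - 1] + (lv - y[i - 1]) / (y[i] - y[i - 1]) * (s[i] - s[i - 1])
    }
    s10 <- cross(lo + 0.1 * span)
    s50 <- cross(lo + 0.5 * span)
    s90 <- cross(lo + 0.9 * span)
    if (dir < 0) { tmp <- s10; s10 <- s90; s90 <- tmp }
    midpoint <- s50
    width <- abs(s90 - s10)
  }

  # pairs consistent with the dominant direction; a span-relative tolerance
  # keeps numerically flat plateaus from counting as reversals
  monotone_fraction <- mean(dir * diff(v) >= -1e-6 * span_raw)

  # plateau: longest run of samples within plateau_tol * span of the maximum
  near_max <- v >= max(v) - plateau_tol * span_raw
  r <- rle(near_max)
  plateau_detected <- any(r$values & r$lengths >= 2L)
  plateau_interval <- c(NA_real_, NA_real_)
  if (plateau_detected) {
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    cand <- which(r$values & r$lengths >= 2L)
    best <- cand[which.max(r$lengths[cand])]
    plateau_interval <- c(s[starts[best]], s[ends[best]])
  }
  i_max <- which.max(v)
  decline_detected <- i_max < length(v) &&
    v[length(v)] < max(v) - plateau_tol * span_raw

  out <- list(midpoint_m = midpoint, width_10_90_m = width,
              monotone_fraction = monotone_fraction, direction = dir,
              plateau_detected = plateau_detected,
              plateau_interval_m = plateau_interval,
              decline_detected = decline_detected, constant = constant)
  class(out) <- "gradient_metrics"
  out
}

#' @export
print.gradient_metrics <- function(x, ...) {
  if (isTRUE(x$constant)) {
    cat("Gradient metrics: constant profile (width 0, midpoint undefined)\n")
    return(invisible(x))
  }
  cat(sprintf(
    paste0("Gradient metrics: midpoint %.4g m, 10-90%% width %.4g m,\n",
           "  monotone fraction %.3f (%s), plateau %s, terminal decline %s\n"),
    x$midpoint_m, x$width_10_90_m, x$monotone_fraction,
    if (x$direction >= 0) "rising" else "falling",
    if (x$plateau_detected)
      sprintf("at [%.4g, %.4g] m", x$plateau_interval_m[1],
              x$plateau_interval_m[2]) else "none",
    if (x$decline_detected) "yes" else "no"))
  invisible(x)
}

#' Core-shell segregation statistic of an outlet cross section
#'
#' Signed difference between the mean A-concentration in the outer half of the
#' flux-weighted annuli and the inner half: positive values indicate an A-rich
#' shell around a B-rich core, as arises late in a no-slip extrusion.
#'
#' @param xs A `cross_section` (columns `r_inner_m`, `r_outer_m`, `C_A`,
#'   optionally `flux_w` per-annulus flux weights; equal weights assumed
#'   otherwise).
#' @return Signed difference in `[-1, 1]`; 0 for a uniform section.
#' @export
core_shell_statistic <- function(xs) {
  stopifnot(is.data.frame(xs), nrow(xs) >= 2L)
  ca <- xs$C_A
  w <- if (!is.null(xs$flux_w)) xs$flux_w else rep(1, nrow(xs))
  ok <- !is.na(ca)
  if (!all(ok)) {
    warning("empty/NA annuli excluded from the core-shell statistic")
    ca <- ca[ok]; w <- w[ok]
    if (length(ca) < 2L) stop("fewer than 2 usable annuli")
  }
  w <- w / sum(w)
  cw <- cumsum(w)
  prev <- c(0, cw[-length(cw)])
  w_in <- pmax(pmin(cw, 0.5) - prev, 0)      # flux overlap with inner half
  w_out <- w - w_in
  sum(w_out * ca) / sum(w_out) - sum(w_in * ca) / sum(w_in)
}

#' Average replicate strand samples per position
#'
#' Collapses a replicated sampling table (as produced by
#' [synth_strand_samples] or read from measured data) to one mean value per
#' position, the form consumed by [compute_gradient_metrics].
#'
#' @param samples Data frame with columns `s_m` and `intensity` (replicate
#'   rows per position).
#' @return A data frame (`s_m`, `C_A`) of per-position means, ordered by
#'   position, of class `strand_profile`.
#' @export
average_replicates <- function(samples) {
  stopifnot(is.data.frame(samples), all(c("s_m", "intensity") %in% names(samples)))
  agg <- stats::aggregate(intensity ~ s_m, data = samples, FUN = mean)
  agg <- agg[order(agg$s_m), ]
  structure(data.frame(s_m = agg$s_m, C_A = agg$intensity),
            class = c("strand_profile", "data.frame"))
}
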