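#' Fix-screening settings
#'
#' Quality screening for GPS fixes: remove two-dimensional fixes (computed
#' from only three satellites) whose PDOP exceeds a threshold, following the
#' standard screening option that drops 2D fixes of questionable accuracy
#' while keeping all 3D fixes.
#'
#' @param pdop_threshold positive PDOP cutoff (default 5).
#' @param drop_2d_above_threshold if FALSE, screening is disabled and the
#'   table passes through unchanged.
#' @return an object of class \code{screen_config}.
#' @export
screen_config <- function(pdop_threshold = 5, drop_2d_above_threshold = TRUE) {
  if (!is.numeric(pdop_threshold) || pdop_threshold <= 0)
    stop("pdop_threshold must be > 0")
  structure(list(pdop_threshold = pdop_threshold,
                 drop_2d_above_threshold = isTRUE(drop_2d_above_threshold)),
            class = "screen_config")
}

#' Screen a fix table
#'
#' Removes records with \code{dim == "2D"} and \code{pdop} above the
#' threshold; all other records are retained in their original order.
#'
#' @param fixes data.frame with columns \code{dim} and \code{pdop} (plus any
#'   others, e.g. a [observe_gps()] fix table).
#' @param cfg a [screen_config()].
#' @return the screened fix table.
#' @export
screen_fixes <- function(fixes, cfg = screen_config()) {
  stopifnot(inherits(cfg, "screen_config"))
  for (col in c("dim", "pdop"))
    if (!col %in% names(fixes))
      stop("fix table lacks required column '", col, "'")
  if (!cfg$drop_2d_above_threshold) return(fixes)
  drop <- fixes$dim == "2D" & fixes$pdop > cfg$pdop_threshold
  fixes[!drop, , drop = FALSE]
}

#' Subsampling specification
#'
#' Describes a coarsening of a regularly scheduled fix series: either a
#' \code{factor} multiplying the base interval (synthetic sweeps use factors
#' 1..12) or an absolute \code{target_interval} (collar-style sweeps use
#' 300..3600 s in 300-s steps).
#'
#' @param base_interval nominal interval of the input series (seconds, or
#'   unit steps for synthetic data).
#' @param factor positive integer multiplier of \code{base_interval}.
#' @param target_interval absolute target interval; must be a positive
#'   multiple of \code{base_interval}. Give exactly one of \code{factor} and
#'   \code{target_interval}.
#' @param tolerance seconds of slack allowed when matching a timestamp to
#'   its grid slot (default 0: exact matching, appropriate for synthetic
#'   data).
#' @return an object of class \code{subsample_spec}.
#' @export
subsample_spec <- function(base_interval, factor = NULL,
                           target_interval = NULL, tolerance = 0) {
  if (base_interval <= 0) stop("base_interval must be > 0")
  if (is.null(factor) == is.null(target_interval))
    stop("give exactly one of 'factor' and 'target_interval'")
  if (is.null(target_interval)) {
    if (factor < 1 || factor != round(factor))
      stop("factor must be a positive integer")
    target_interval <- base_interval * factor
  } else {
    ratio <- target_interval / base_interval
    if (target_interval <= 0 || abs(ratio - round(ratio)) > 1e-9)
      stop("target_interval must be a positive multiple of base_interval")
    factor <- round(ratio)
  }
  if (tolerance < 0) stop("tolerance must be >= 0")
  structure(list(base_interval = base_interval, factor = as.integer(factor),
                 target_interval = target_interval, tolerance = tolerance),
            class = "subsample_spec")
}

#' Subsample a fix series to a coarser regular grid
#'
#' Selects the fixes whose timestamps fall on the grid
#' \code{anchor + k * target_interval} (within \code{tolerance}), where the
#' anchor is the first timestamp. Missing grid slots are simply absent; no
#' interpolation is performed, so the fixes selected at one interval need
#' not be a subset of those selected at another.
#'
#' @param t strictly increasing timestamps.
#' @param spec a [subsample_spec()].
#' @return integer indices of the selected fixes.
#' @export
subsample <- function(t, spec) {
  stopifnot(inherits(spec, "subsample_spec"))
  if (any(diff(t) <= 0)) stop("timestamps must be strictly increasing")
  anchor <- t[1]
  slot <- round((t - anchor) / spec$target_interval)
  on_grid <- abs(t - (anchor + slot * spec$target_interval)) <=
    spec$tolerance + 1e-9
  idx <- which(on_grid)
  # with a nonzero tolerance two fixes can claim the same slot: keep the first
  idx[!duplicated(slot[idx])]
}

#' Convert positions and timestamps to movement rates and turning angles
#'
#' Movement rate \eqn{r_i} is the Euclidean distance between fixes i and
#' i+1 divided by the elapsed time; the turning angle \eqn{\phi_i} is the
#' signed angle (quadrant-aware arctangent, counter-clockwise positive, in
#' (-pi, pi], exact reversals mapped to pi) between the displacement
#' vectors i -> i+1 and i+1 -> i+2. A rate is valid only if its two fixes
#' occupy consecutive grid slots of the stated interval, an angle only if
#' its three fixes do; values spanning gaps are computed but flagged invalid
#' and excluded from analysis.
#'
#' @param x,y planar coordinates of the (already subsampled) fixes.
#' @param t strictly increasing timestamps.
#' @param interval the nominal inter-fix interval of the series.
#' @param tolerance timestamp slack for grid-slot matching (default 0).
#' @return a \code{step_series} data.frame with one row per fix pair:
#'   \code{t} (timestamp of the first fix), \code{r}, \code{phi},
#'   \code{valid_r}, \code{valid_phi}, \code{from} (index of the step's
#'   first fix in the input). Attributes: \code{interval}, \code{n_r},
#'   \code{n_phi}.
#' @export
to_step_series <- function(x, y, t, interval, tolerance = 0) {
  n <- length(t)
  stopifnot(length(x) == n, length(y) == n)
  if (n < 2) stop("need at least 2 fixes to compute a movement rate")
  dt <- diff(t)
  if (any(dt == 0)) stop("duplicate timestamps (zero time difference)")
  if (any(dt < 0)) stop("timestamps must be strictly increasing")
  slot <- round((t - t[1]) / interval)
  if (any(abs(t - (t[1] + slot * interval)) > tolerance + 1e-9))
    stop("timestamps do not lie on the stated interval grid")
  dx <- diff(x); dy <- diff(y)
  r <- sqrt(dx^2 + dy^2) / dt
  valid_r <- diff(slot) == 1L
  m <- n - 1L
  phi <- rep(NA_real_, m)
  valid_phi <- rep(FALSE, m)
  if (n >= 3) {
    i <- seq_len(n - 2L)
    cross <- dx[i] * dy[i + 1] - dy[i] * dx[i + 1]
    dot <- dx[i] * dx[i + 1] + dy[i] * dy[i + 1]
    a <- atan2(cross, dot)
    a[a <= -pi + 1e-15] <- pi       # exact reversals belong to +pi
    phi[i] <- a
    valid_phi[i] <- valid_r[i] & valid_r[i + 1]
    phi[!valid_phi] <- NA_real_
  }
  out <- data.frame(t = t[-n], r = r, phi = phi,
                    valid_r = valid_r, valid_phi = valid_phi,
                    from = seq_len(m))
  class(out) <- c("step_series", "data.frame")
  attr(out, "interval") <- interval
  attr(out, "n_r") <- sum(valid_r)
  attr(out, "n_phi") <- sum(valid_phi)
  out
}

#' @export
print.step_series <- function(x, ...) {
  cat("Step series at interval", attr(x, "interval"), "-",
      attr(x, "n_r"), "valid rates,", attr(x, "n_phi"), "valid angles\n")
  invisible(x)
}

# rows of a step series that enter the mixture likelihood: valid rate,
# with the angle kept only where itself valid
step_data <- function(steps) {
  stopifnot(inherits(steps, "step_series"))
  keep <- steps$valid_r
  phi <- steps$phi[keep]
  phi[!steps$valid_phi[keep]] <- NA_real_
  list(r = steps$r[keep], phi = phi, from = steps$from[keep],
       n = sum(keep))
}
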