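#' Movement-regime parameters
#'
#' A regime is one of the two behavioural modes of the synthetic generator:
#' \code{"straight"} (fast, directionally persistent transiting) or
#' \code{"area_restricted"} (slow, reversal-biased foraging/resting).
#' Turning angles are drawn from a von Mises distribution with mean
#' \code{mu_turn} and concentration \code{kappa_turn}; step lengths follow a
#' positive random walk with Gaussian innovations of SD \code{step_sd},
#' restarted at \code{step_init} at the beginning of each segment.
#'
#' @param label one of \code{"straight"}, \code{"area_restricted"}.
#' @param mu_turn mean turning angle, radians in (-pi, pi].
#' @param kappa_turn von Mises concentration, >= 0.
#' @param step_sd SD of the step-length innovation, > 0 (length units).
#' @param step_init initial step length of a segment of this regime, > 0.
#' @return an object of class \code{regime_params}.
#' @export
regime_params <- function(label, mu_turn, kappa_turn, step_sd, step_init) {
  label <- match.arg(label, c("straight", "area_restricted"))
  for (v in c("mu_turn", "kappa_turn", "step_sd", "step_init")) {
    val <- get(v)
    if (!is.numeric(val) || length(val) != 1 || !is.finite(val))
      stop("regime parameter '", v, "' must be a single finite number")
  }
  if (kappa_turn < 0) stop("kappa_turn must be >= 0")
  if (step_sd <= 0) stop("step_sd must be > 0")
  if (step_init <= 0) stop("step_init must be > 0")
  structure(
    list(label = label, mu_turn = wrap_angle(mu_turn), kappa_turn = kappa_turn,
         step_sd = step_sd, step_init = step_init),
    class = "regime_params"
  )
}

#' Default regime calibration
#'
#' Reads the packaged regime configuration file (straight + area-restricted
#' parameters). The values are data, not code constants; an alternative
#' calibration can be supplied via [read_regimes()].
#'
#' @return named list with elements \code{straight} and
#'   \code{area_restricted}, each a [regime_params()] object.
#' @export
default_regimes <- function() {
  path <- system.file("extdata", "regimes-default.yaml", package = "statewalk")
  if (path == "") stop("packaged regime configuration not found")
  read_regimes(path)
}

#' Read a regime configuration file
#'
#' @param path YAML file with top-level keys \code{straight} and
#'   \code{area_restricted}, each holding \code{mu_turn}, \code{kappa_turn},
#'   \code{step_sd}, \code{step_init}. Missing or non-finite entries are an
#'   error (the generator never falls back to silent defaults).
#' @return named list of two [regime_params()] objects.
#' @export
read_regimes <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list()
  for (lab in c("straight", "area_restricted")) {
    entry <- cfg[[lab]]
    if (is.null(entry)) stop("regime config is missing the '", lab, "' block")
    for (v in c("mu_turn", "kappa_turn", "step_sd", "step_init"))
      if (is.null(entry[[v]]))
        stop("regime '", lab, "' is missing parameter '", v, "'")
    out[[lab]] <- regime_params(lab, entry$mu_turn, entry$kappa_turn,
                                entry$step_sd, entry$step_init)
  }
  out
}

#' Generator configuration
#'
#' Settings for the two-regime trajectory generator: segments of alternating
#' regimes, each containing a uniformly drawn number of points, truncated so
#' the whole track has exactly \code{target_points} points.
#'
#' @param regimes list with a \code{straight} and an \code{area_restricted}
#'   [regime_params()]; defaults to [default_regimes()].
#' @param seg_len_min,seg_len_max segment length bounds in points
#'   (default 20 and 100).
#' @param target_points total number of trajectory points (default 487).
#' @param seed integer RNG seed.
#' @param start_xy starting coordinates (default the origin).
#' @return an object of class \code{generator_config}.
#' @export
generator_config <- function(regimes = default_regimes(),
                             seg_len_min = 20L, seg_len_max = 100L,
                             target_points = 487L, seed = 1L,
                             start_xy = c(0, 0)) {
  stopifnot(inherits(regimes$straight, "regime_params"),
            inherits(regimes$area_restricted, "regime_params"))
  seg_len_min <- as.integer(seg_len_min)
  seg_len_max <- as.integer(seg_len_max)
  target_points <- as.integer(target_points)
  if (seg_len_min < 1 || seg_len_min > seg_len_max)
    stop("need 1 <= seg_len_min <= seg_len_max")
  if (target_points < 2)
    stop("target_points must be >= 2")
  if (regimes$straight$step_init <= regimes$area_restricted$step_init)
    stop("the straight regime must start with longer steps than the ",
         "area-restricted regime (animals move slower while area-restricted)")
  structure(
    list(regimes = regimes, seg_len_min = seg_len_min,
         seg_len_max = seg_len_max, target_points = target_points,
         seed = as.integer(seed), start_xy = as.numeric(start_xy)),
    class = "generator_config"
  )
}

#' Draw alternating segment lengths
#'
#' Segment lengths are uniform integers on \[seg_len_min, seg_len_max\];
#' segments alternate between the two regimes starting from a uniformly
#' chosen one, and the final segment is truncated so the lengths sum to
#' exactly \code{target_points}. Uses the current RNG state.
#'
#' @param cfg a [generator_config()].
#' @return data.frame with columns \code{regime} and \code{length}.
#' @export
draw_segment_lengths <- function(cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  lens <- integer(0)
  total <- 0L
  while (total < cfg$target_points) {
    l <- cfg$seg_len_min +
      sample.int(cfg$seg_len_max - cfg$seg_len_min + 1L, 1L) - 1L
    lens <- c(lens, l)
    total <- total + l
  }
  excess <- total - cfg$target_points
  lens[length(lens)] <- lens[length(lens)] - excess
  if (lens[length(lens)] == 0L) lens <- lens[-length(lens)]
  first <- sample(c("straight", "area_restricted"), 1L)
  regimes <- rep(c("straight", "area_restricted"),
                 length.out = length(lens) + (first == "area_restricted"))
  if (first == "area_restricted") regimes <- regimes[-1]
  data.frame(regime = regimes[seq_along(lens)], length = lens,
             stringsAsFactors = FALSE)
}

#' Simulate a two-regime trajectory
#'
#' Generates a correlated random walk made of alternating straight and
#' area-restricted segments. Within a segment the heading accumulates von
#' Mises turns and the step length follows a positive Gaussian random walk;
#' each segment restarts at the regime's initial step length with a heading
#' drawn uniformly on the circle. Timestamps are 0, 1, 2, ... in arbitrary
#' units.
#'
#' @param cfg a [generator_config()]; \code{cfg$seed} seeds the RNG so the
#'   result is fully reproducible.
#' @return a \code{true_trajectory} data.frame with columns \code{x},
#'   \code{y}, \code{t}, \code{state_true} (regime label per point),
#'   \code{step_len} and \code{heading} (attributes of the step arriving at
#'   each point; NA for the first point).
#' @export
simulate_trajectory <- function(cfg = generator_config()) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  segs <- draw_segment_lengths(cfg)
  n <- cfg$target_points
  state <- rep(segs$regime, segs$length)
  x <- y <- t_ <- numeric(n)
  step_len <- heading <- rep(NA_real_, n)
  x[1] <- cfg$start_xy[1]; y[1] <- cfg$start_xy[2]
  t_ <- as.numeric(seq_len(n) - 1L)
  seg_of <- rep(seq_len(nrow(segs)), segs$length)
  d <- NA_real_; h <- NA_real_
  for (i in 2:n) {
    reg <- cfg$regimes[[state[i]]]
    if (seg_of[i] != seg_of[i - 1] || i == 2L) {
      # first step of a segment: regime's initial step, uniform new heading
      d <- reg$step_init
      h <- runif(1, -pi, pi)
    } else {
      h <- wrap_angle(h + rvonmises(1, reg$mu_turn, reg$kappa_turn))
      repeat {                       # truncate the step walk at zero
        d_new <- stats::rnorm(1, d, reg$step_sd)
        if (d_new > 0) break
      }
      d <- d_new
    }
    x[i] <- x[i - 1] + d * cos(h)
    y[i] <- y[i - 1] + d * sin(h)
    step_len[i] <- d
    heading[i] <- h
  }
  out <- data.frame(x = x, y = y, t = t_, state_true = state,
                    step_len = step_len, heading = heading,
                    stringsAsFactors = FALSE)
  class(out) <- c("true_trajectory", "data.frame")
  attr(out, "segments") <- segs
  attr(out, "config") <- cfg
  out
}

#' GPS-collar observation settings
#'
#' Emulates how a GPS collar records a trajectory: one candidate fix per
#' nominal interval, random dropouts, isotropic position noise, a 2D/3D fix
#' flag and a log-normal PDOP (positional dilution of precision) value.
#'
#' @param fix_interval nominal seconds between fixes (default 300, i.e.
#'   5 min). Trajectory time units are mapped one-to-one onto fix intervals.
#' @param dropout_prob probability a candidate fix is lost, in \[0, 1).
#' @param p_2d probability a retained fix is two-dimensional (three
#'   satellites only), in \[0, 1\].
#' @param pdop_lognormal_mu,pdop_lognormal_sigma log-normal parameters of
#'   the PDOP draw.
#' @param position_noise_sd SD of the isotropic Gaussian position error,
#'   >= 0 (length units).
#' @param seed integer RNG seed.
#' @return an object of class \code{observation_config}.
#' @export
observation_config <- function(fix_interval = 300, dropout_prob = 0.1,
                               p_2d = 0.15, pdop_lognormal_mu = 1.0,
                               pdop_lognormal_sigma = 0.5,
                               position_noise_sd = 0, seed = 1L) {
  if (dropout_prob < 0 || dropout_prob >= 1) stop("dropout_prob must be in [0, 1)")
  if (p_2d < 0 || p_2d > 1) stop("p_2d must be in [0, 1]")
  if (position_noise_sd < 0) stop("position_noise_sd must be >= 0")
  if (fix_interval <= 0) stop("fix_interval must be > 0")
  structure(
    list(fix_interval = fix_interval, dropout_prob = dropout_prob,
         p_2d = p_2d, pdop_lognormal_mu = pdop_lognormal_mu,
         pdop_lognormal_sigma = pdop_lognormal_sigma,
         position_noise_sd = position_noise_sd, seed = as.integer(seed)),
    class = "observation_config"
  )
}

#' Observe a trajectory through an emulated GPS collar
#'
#' Each trajectory point is a candidate fix at \code{fix_interval} seconds
#' after the previous one. Candidates are dropped independently with
#' \code{dropout_prob}; retained fixes receive position noise, a dimension
#' flag and a PDOP draw. The column \code{point} records which trajectory
#' point produced each fix (bookkeeping for synthetic studies only).
#'
#' @param traj a \code{true_trajectory} (or any data.frame with x, y, t).
#' @param ocfg an [observation_config()].
#' @return a \code{fix_table} data.frame with columns \code{x}, \code{y},
#'   \code{t} (seconds), \code{dim} ("2D"/"3D"), \code{pdop}, \code{point}.
#' @export
observe_gps <- function(traj, ocfg = observation_config()) {
  stopifnot(inherits(ocfg, "observation_config"),
            all(c("x", "y", "t") %in% names(traj)))
  set.seed(ocfg$seed)
  n <- nrow(traj)
  keep <- runif(n) >= ocfg$dropout_prob
  idx <- which(keep)
  m <- length(idx)
  out <- data.frame(
    x = traj$x[idx] + stats::rnorm(m, 0, ocfg$position_noise_sd),
    y = traj$y[idx] + stats::rnorm(m, 0, ocfg$position_noise_sd),
    t = traj$t[idx] * ocfg$fix_interval,
    dim = ifelse(runif(m) < ocfg$p_2d, "2D", "3D"),
    pdop = stats::rlnorm(m, ocfg$pdop_lognormal_mu, ocfg$pdop_lognormal_sigma),
    point = idx,
    stringsAsFactors = FALSE
  )
  class(out) <- c("fix_table", "data.frame")
  attr(out, "fix_interval") <- ocfg$fix_interval
  out
}

#' @export
print.true_trajectory <- function(x, ...) {
  segs <- attr(x, "segments")
  cat("Two-regime synthetic trajectory:", nrow(x), "points,",
      if (!is.null(segs)) nrow(segs) else NA, "segments\n")
  tab <- table(x$state_true)
  cat("  points per regime:",
      paste(names(tab), tab, sep = " = ", collapse = ", "), "\n")
  invisible(x)
}
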