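#' Probability-to-colour gradient
#'
#' Linear colour gradient used to paint per-point state probabilities:
#' probability 1 of state 1 maps to the state-1 endpoint (red), probability
#' 0 (i.e. state 2) to the state-2 endpoint (green), with the midpoint
#' (yellow) at 0.5 marking points the model leaves undetermined.
#'
#' @param state1,state2 endpoint colours (defaults "red" and "green").
#' @param midpoint colour at probability 0.5 (default "yellow").
#' @return an object of class \code{color_gradient_spec}.
#' @export
color_gradient_spec <- function(state1 = "red", state2 = "green",
                                midpoint = "yellow") {
  structure(list(state1 = state1, state2 = state2, midpoint = midpoint),
            class = "color_gradient_spec")
}

#' Map state-1 probabilities to colours
#'
#' @param p probabilities of state 1, in \[0, 1\].
#' @param spec a [color_gradient_spec()].
#' @return vector of hex colours.
#' @export
prob_to_color <- function(p, spec = color_gradient_spec()) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("probabilities must be in [0, 1]")
  ramp <- grDevices::colorRamp(c(spec$state2, spec$midpoint, spec$state1))
  out <- rep(NA_character_, length(p))
  ok <- !is.na(p)
  if (any(ok)) {
    rgb <- ramp(p[ok])
    out[ok] <- grDevices::rgb(rgb[, 1], rgb[, 2], rgb[, 3], maxColorValue = 255)
  }
  out
}

band_df <- function(dens, degrees = FALSE) {
  x <- dens$grid
  if (degrees) x <- x * 180 / pi
  data.frame(x = x, mean = dens$mean_curve,
             lo1 = pmax(0, dens$mean_curve - dens$sd_curve),
             hi1 = dens$mean_curve + dens$sd_curve,
             lo2 = pmax(0, dens$mean_curve - 2 * dens$sd_curve),
             hi2 = dens$mean_curve + 2 * dens$sd_curve)
}

#' Panel figure of posterior rate and angle densities
#'
#' One panel per state and metric: the posterior mean density (solid line)
#' with one and two posterior SDs shaded in dark and light grey; angles are
#' shown in degrees. If a \code{step_series} is supplied, data histograms
#' are drawn behind the curves with bars coloured by the mean state-1
#' probability of the observations they contain.
#'
#' @param summary a [posterior_summary()].
#' @param out_path output image file (png or pdf, decided by extension).
#' @param steps optional \code{step_series} for the histograms.
#' @param gradient a [color_gradient_spec()].
#' @param width,height device size in inches.
#' @return \code{out_path}, invisibly.
#' @export
plot_posterior_panels <- function(summary, out_path, steps = NULL,
                                  gradient = color_gradient_spec(),
                                  width = 8, height = 5) {
  stopifnot(inherits(summary, "posterior_summary"))
  curves <- do.call(rbind, lapply(summary$states, function(s) {
    rbind(cbind(band_df(s$rate_density), state = s$state, metric = "rate"),
          cbind(band_df(s$angle_density, degrees = TRUE),
                state = s$state, metric = "angle (deg)"))
  }))
  curves$panel <- paste0("state ", curves$state, ": ", curves$metric)
  g <- ggplot2::ggplot(curves, ggplot2::aes(x = .data$x)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo2, ymax = .data$hi2),
                         fill = "grey85") +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lo1, ymax = .data$hi1),
                         fill = "grey60") +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean)) +
    ggplot2::facet_wrap(~panel, scales = "free") +
    ggplot2::labs(x = NULL, y = "density") +
    ggplot2::theme_bw()
  if (!is.null(steps)) {
    dat <- step_data(steps)
    p1 <- summary$probs[, 1]
    hists <- list()
    for (s in summary$states) {
      assigned <- max.col(summary$probs, ties.method = "first") == s$state
      rr <- dat$r[assigned]
      br <- pretty(dat$r, 24)
      cut_r <- cut(rr, br, include.lowest = TRUE)
      dens_r <- tapply(rr, cut_r, length)
      dens_r[is.na(dens_r)] <- 0
      wbin <- diff(br)
      pbar <- tapply(p1[assigned], cut_r, mean)
      hists[[length(hists) + 1]] <- data.frame(
        xmid = (br[-1] + br[-length(br)]) / 2, w = wbin,
        d = as.numeric(dens_r) / (sum(dens_r) * wbin),
        p = as.numeric(pbar),
        panel = paste0("state ", s$state, ": rate"))
    }
    hh <- do.call(rbind, hists)
    hh$col <- prob_to_color(ifelse(is.na(hh$p), 0.5, hh$p), gradient)
    g <- g + ggplot2::geom_col(
      data = hh,
      ggplot2::aes(x = .data$xmid, y = .data$d),
      width = hh$w, fill = hh$col, alpha = 0.5, inherit.aes = FALSE)
  }
  ggplot2::ggsave(out_path, g, width = width, height = height, dpi = 150)
  invisible(out_path)
}

circle_df <- function(cx, cy, r, n = 90) {
  th <- seq(0, 2 * pi, length.out = n)
  data.frame(x = cx + r * cos(th), y = cy + r * sin(th))
}

#' Mean-vector diagram
#'
#' Unit-circle plot of the posterior mean turn vectors: one arrow per state
#' and sweep point, with a circle of radius equal to the posterior SD of
#' the mean vector drawn around each arrow head. Arrow length measures
#' turning-angle concentration (1 = point distribution, 0 = uniform).
#'
#' @param vectors data.frame with columns \code{interval}, \code{state},
#'   \code{mv_x}, \code{mv_y}, \code{mv_sd} (one row per arrow), e.g. the
#'   trend table of [run_resolution_sweep()].
#' @param out_path output image file.
#' @param reference_length optional dashed reference arrow length along the
#'   positive x axis.
#' @param width,height device size in inches.
#' @return \code{out_path}, invisibly.
#' @export
plot_mean_vectors <- function(vectors, out_path, reference_length = NULL,
                              width = 6, height = 6) {
  need <- c("interval", "state", "mv_x", "mv_y", "mv_sd")
  if (!all(need %in% names(vectors)))
    stop("vectors needs columns ", paste(need, collapse = ", "))
  unit <- circle_df(0, 0, 1, 181)
  circles <- do.call(rbind, lapply(seq_len(nrow(vectors)), function(i)
    cbind(circle_df(vectors$mv_x[i], vectors$mv_y[i], vectors$mv_sd[i]),
          id = i, state = vectors$state[i])))
  vectors$state <- factor(vectors$state)
  g <- ggplot2::ggplot() +
    ggplot2::geom_path(data = unit, ggplot2::aes(.data$x, .data$y),
                       colour = "grey50") +
    ggplot2::geom_path(data = circles,
                       ggplot2::aes(.data$x, .data$y, group = .data$id,
                                    colour = factor(.data$state)),
                       linewidth = 0.3) +
    ggplot2::geom_segment(
      data = vectors,
      ggplot2::aes(x = 0, y = 0, xend = .data$mv_x, yend = .data$mv_y,
                   colour = .data$state),
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::scale_colour_manual(values = c("red", "green3", "blue"),
                                 name = "state") +
    ggplot2::coord_equal(xlim = c(-1.05, 1.05), ylim = c(-1.05, 1.05)) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_bw()
  if (!is.null(reference_length))
    g <- g + ggplot2::geom_segment(
      ggplot2::aes(x = 0, y = 0, xend = reference_length, yend = 0),
      linetype = "dashed",
      arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")))
  ggplot2::ggsave(out_path, g, width = width, height = height, dpi = 150)
  invisible(out_path)
}

#' Trajectory coloured by behavioural-state probability
#'
#' Draws the movement path with each point coloured by its posterior
#' probability of being in state 1 (red = state 1, green = state 2,
#' yellow = undetermined). A step's probability is painted on the middle
#' fix of the triple that produced its turning angle (the step's second
#' fix); fixes with no step probability are grey.
#'
#' @param traj data.frame with columns \code{x}, \code{y} (fix positions,
#'   in the order used to build the step series).
#' @param probs steps x states probability matrix from
#'   [state_probabilities()] (its \code{from} attribute maps steps to fix
#'   indices).
#' @param out_path output image file.
#' @param gradient a [color_gradient_spec()].
#' @param pie draw an inset-style side panel with the mean state
#'   proportions (default TRUE).
#' @param width,height device size in inches.
#' @return \code{out_path}, invisibly.
#' @export
plot_trajectory_states <- function(traj, probs, out_path,
                                   gradient = color_gradient_spec(),
                                   pie = TRUE, width = 7, height = 6) {
  from <- attr(probs, "from") %||% seq_len(nrow(probs))
  p_point <- rep(NA_real_, nrow(traj))
  mid <- from + 1L
  ok <- mid <= nrow(traj)
  p_point[mid[ok]] <- probs[ok, 1]
  cols <- prob_to_color(p_point, gradient)
  cols[is.na(cols)] <- "grey70"
  df <- data.frame(x = traj$x, y = traj$y, col = cols)
  g <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_path(colour = "grey80") +
    ggplot2::geom_point(colour = df$col, size = 1.3) +
    ggplot2::coord_equal() +
    ggplot2::theme_bw() +
    ggplot2::labs(x = "x", y = "y")
  if (pie) {
    props <- colMeans(probs)
    g <- g + ggplot2::labs(
      subtitle = paste0("mean state proportions: ",
                        paste(sprintf("state %d = %.2f", seq_along(props),
                                      props), collapse = ", ")))
  }
  ggplot2::ggsave(out_path, g, width = width, height = height, dpi = 150)
  invisible(out_path)
}
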