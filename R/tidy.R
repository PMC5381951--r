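#' Tidy and summarize result objects
#'
#' `tidy()` returns the tabular content of a result object as a tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x a `sec_pmf`, `sec_assay` or `sec_trajectory`.
#' @param ... unused.
#' @return A tibble.
#' @name tidiers
NULL

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.sec_pmf <- function(x, ...) {
  out <- tibble(z = x$z, F = x$F)
  out$gate <- attr(x, "gate")
  out$g <- attr(x, "bead")$g
  out
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.sec_pmf <- function(x, ...) {
  tibble(
    gate = attr(x, "gate"),
    g = attr(x, "bead")$g,
    lambda = attr(x, "bead")$lambda,
    F_min = min(x$F), F_max = max(x$F),
    z_min = x$z[which.min(x$F)],
    barrier = max(x$F) - min(x$F)
  )
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.sec_assay <- function(x, ...) {
  as_tibble(unclass(x))
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.sec_assay <- function(x, ...) {
  avg <- x[x$frame == "average", ]
  as_tibble(unclass(avg))
}

#' @rdname tidiers
#' @exportS3Method generics::tidy
tidy.sec_trajectory <- function(x, ...) {
  if (is.null(x$frames)) {
    return(tibble(time_s = x$time_s, outcome = x$outcome))
  }
  nt <- dim(x$frames)[3]
  purrr::map_dfr(seq_len(nt), function(k) {
    fr <- x$frames[, , k, drop = FALSE]
    dim(fr) <- dim(fr)[1:2]
    placed <- which(is.finite(fr[, 1]))
    tibble(frame = k, time_s = x$frame_times[k], bead = placed,
           x = fr[placed, 1], y = fr[placed, 2], z = fr[placed, 3])
  })
}

#' @rdname tidiers
#' @exportS3Method generics::glance
glance.sec_trajectory <- function(x, ...) {
  tibble(outcome = x$outcome, finished = x$finished, steps = x$steps,
         time_s = x$time_s, n_flips = x$n_flips,
         open_fraction = x$n_open_steps / x$steps)
}

#' Plot methods for result objects
#'
#' `autoplot()` methods: free-energy profile for `sec_pmf`, outcome
#' probabilities for `sec_assay`, and the z-coordinate of each bead over
#' time for a `sec_trajectory` with saved frames.
#'
#' @param object result object.
#' @param ... unused.
#' @return A ggplot object.
#' @name plots
NULL

#' @rdname plots
#' @exportS3Method ggplot2::autoplot
autoplot.sec_pmf <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$z, y = .data$F)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = expression(z ~ (sigma)),
      y = expression(F ~ (epsilon)),
      title = paste0("Single-bead translocation PMF (gate ",
                     attr(object, "gate"), ")")
    ) +
    ggplot2::theme_minimal()
}

#' @rdname plots
#' @exportS3Method ggplot2::autoplot
autoplot.sec_assay <- function(object, ...) {
  df <- object[object$frame == "average", ]
  if ("p_integration" %in% names(df) && "loop_res" %in% names(df) == FALSE) {
    xvar <- if ("n_leu" %in% names(df)) "n_leu" else "frame"
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data[[xvar]],
                                          y = .data$p_integration)) +
      ggplot2::geom_point() +
      ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$p_integration - .data$se,
                                          ymax = .data$p_integration + .data$se),
                             width = 0.1) +
      ggplot2::labs(y = "p(integration)")
  } else {
    p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$loop_res,
                                          y = .data$p_type2,
                                          colour = factor(.data$t_trans))) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "C-terminal loop length (residues)",
                    y = "p(Type 2)", colour = "t_trans (s)")
  }
  p + ggplot2::theme_minimal()
}

#' @rdname plots
#' @exportS3Method ggplot2::autoplot
autoplot.sec_trajectory <- function(object, ...) {
  df <- tidy(object)
  if (!"bead" %in% names(df)) abort("trajectory has no saved frames to plot")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$z,
                                   group = .data$bead,
                                   colour = factor(.data$bead))) +
    ggplot2::geom_line(show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = c(-2, 2), linetype = 2) +
    ggplot2::labs(x = "time (s)", y = expression(z ~ (sigma))) +
    ggplot2::theme_minimal()
}
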