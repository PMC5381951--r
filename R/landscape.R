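#' Single-bead translocation potential of mean force by quadrature
#'
#' Free-energy profile along the channel axis for one free bead with the
#' gate fixed:
#' \deqn{F(z) = -kT \ln \iint_{x^2+y^2 \le R^2} e^{-\beta U_1(x, y, z)}
#'   \,dx\,dy + C,}
#' where \eqn{U_1} is the single-bead potential (solvation + channel
#' interaction, optionally electrostatics with the fixed charges and the
#' ribosome terms). The cross-section integral runs over a cylinder of
#' radius `radius` (1.5 \eqn{\sigma}, matching the restraint geometry of
#' the reference calculations) on a uniform Cartesian grid. The profile is
#' vertically shifted so its average over the normalization window
#' (4.0-4.5 \eqn{\sigma}) is zero.
#'
#' @param bead a one-row bead tibble or list with `g` (and optionally `q`,
#'   `lambda_open`, `lambda_closed`; \eqn{\lambda} defaults to
#'   [lambda_interp()] of `g`, `q` to 0).
#' @param gate `"open"` or `"closed"`.
#' @param geom a [sec_geometry()].
#' @param radius integration cylinder radius in \eqn{\sigma}.
#' @param z z-grid in \eqn{\sigma}.
#' @param spacing Cartesian grid spacing over the cross-section
#'   (\eqn{\sigma}).
#' @param include_elec,include_ribo include electrostatics with fixed
#'   charges / ribosome repulsion in \eqn{U_1}.
#' @param lambda override the \eqn{\lambda} coefficient directly (used by
#'   the fitting routines).
#' @param window normalization window on z (\eqn{\sigma}); if the grid does
#'   not cover it, the profile mean is used instead.
#' @param constants,table model parameters.
#' @return A tibble of class `sec_pmf` with columns `z` and `F`
#'   (\eqn{\epsilon}), and the settings stored as attributes.
#' @examples
#' geom <- synthetic_channel_fixture()
#' pmf <- pmf_numeric(list(g = -6.1), "open", geom, z = seq(-3, 4.5, 0.25))
#' head(pmf)
#' @export
pmf_numeric <- function(bead, gate = c("closed", "open"), geom,
                        radius = 1.5, z = seq(-5, 4.5, by = 0.1),
                        spacing = 0.025, include_elec = TRUE,
                        include_ribo = FALSE, lambda = NULL,
                        window = c(4, 4.5),
                        constants = sec_constants(),
                        table = softcore_table(constants)) {
  gate <- match.arg(gate)
  g <- bead$g
  q <- if (!is.null(bead$q)) bead$q else 0
  if (is.null(lambda)) {
    lambda <- if (gate == "open") {
      if (!is.null(bead$lambda_open)) bead$lambda_open
      else lambda_interp(g)$lambda_open
    } else {
      if (!is.null(bead$lambda_closed)) bead$lambda_closed
      else lambda_interp(g)$lambda_closed
    }
  }
  disc <- .disc_points(radius, spacing)
  fields <- .bead_fields(disc, z, gate, geom, constants, table)
  FF <- .pmf_from_fields(fields, nrow(disc), g, q, lambda,
                         include_elec, include_ribo)
  FF <- FF - .pmf_shift(FF, z, window)
  out <- tibble(z = z, F = FF)
  class(out) <- c("sec_pmf", class(out))
  attr(out, "gate") <- gate
  attr(out, "bead") <- list(g = g, q = q, lambda = lambda)
  attr(out, "radius") <- radius
  attr(out, "spacing") <- spacing
  out
}

.disc_points <- function(radius, spacing) {
  xs <- seq(-radius, radius, by = spacing)
  gr <- expand.grid(x = xs, y = xs)
  as.matrix(gr[gr$x^2 + gr$y^2 <= radius^2, ])
}

# evaluate the single-bead field components on disc x z
.bead_fields <- function(disc, z, gate, geom, constants, table) {
  npt <- nrow(disc)
  pts <- cbind(disc[rep(seq_len(npt), times = length(z)), , drop = FALSE],
               rep(z, each = npt))
  cg_single_bead_fields(pts, as.integer(gate == "open"),
                        .geom_matrices(geom),
                        .pars_list(constants, table))
}

.pmf_from_fields <- function(fields, npt, g, q, lambda,
                             include_elec, include_ribo) {
  S <- fields[, 1]
  U <- g * S + (1 - S) * (lambda * fields[, 2] + (1 - lambda) * fields[, 3]) +
    S * fields[, 4]
  if (include_elec) U <- U + q * fields[, 5]
  if (include_ribo) U <- U + fields[, 6]
  nz <- length(U) / npt
  vapply(seq_len(nz), function(k) {
    u <- U[((k - 1) * npt + 1):(k * npt)]
    m <- min(u)
    -(log(sum(exp(-(u - m)))) - m) # -log sum exp(-u), stable
  }, numeric(1))
}

.pmf_shift <- function(FF, z, window) {
  sel <- z >= window[1] & z <= window[2]
  if (any(sel)) mean(FF[sel]) else mean(FF)
}

#' Fit the channel-interaction coefficient to a reference PMF
#'
#' Bounded one-dimensional least squares over \eqn{\lambda \in [0, 1]}
#' between the model PMF ([pmf_numeric()] with `lambda` free) and a
#' reference profile, restricted to \eqn{z \ge -2\sigma} (the fitting range
#' used for the channel parameterization). A free vertical offset is
#' profiled out, so the result does not depend on how either curve was
#' normalized.
#'
#' @param reference a data frame with columns `z` (\eqn{\sigma}) and `F`
#'   (\eqn{\epsilon}), e.g. from [read_pmf()].
#' @param g bead transfer free energy in \eqn{\epsilon}.
#' @param gate `"open"` or `"closed"`.
#' @param geom a [sec_geometry()].
#' @param q bead charge.
#' @param z_min lower end of the fitting range (\eqn{\sigma}).
#' @param tol optimizer tolerance on \eqn{\lambda}.
#' @inheritParams pmf_numeric
#' @return A list with `lambda`, `objective` (residual sum of squares) and
#'   `flat` (`TRUE` when the objective does not discriminate, with a
#'   warning).
#' @export
fit_lambda <- function(reference, g, gate = c("closed", "open"), geom,
                       q = 0, z_min = -2, radius = 1.5, spacing = 0.05,
                       include_elec = TRUE, include_ribo = FALSE,
                       tol = 1e-4, constants = sec_constants(),
                       table = softcore_table(constants)) {
  gate <- match.arg(gate)
  ref <- reference[reference$z >= z_min, ]
  if (nrow(ref) < 3) abort("reference PMF must cover the range z >= -2 sigma")
  disc <- .disc_points(radius, spacing)
  fields <- .bead_fields(disc, ref$z, gate, geom, constants, table)
  obj <- function(lambda) {
    FF <- .pmf_from_fields(fields, nrow(disc), g, q, lambda,
                           include_elec, include_ribo)
    r <- FF - ref$F
    sum((r - mean(r))^2)
  }
  fit <- optimize(obj, c(0, 1), tol = tol)
  # boundary refinement: optimize() never quite reaches the interval ends
  cand <- c(fit$minimum, 0, 1)
  vals <- c(fit$objective, obj(0), obj(1))
  best <- which.min(vals)
  flat <- diff(range(vals)) < 1e-8
  if (flat) warning("objective is flat in lambda; reference does not discriminate")
  list(lambda = cand[best], objective = vals[best], flat = flat)
}

#' Fit soft-core channel parameters to a reference PMF
#'
#' Bounded least squares over the three free soft-core parameters
#' (\eqn{\epsilon_{int}}, \eqn{r_{cr}}, \eqn{\sigma_j}) of one bounding
#' potential row, with \eqn{\alpha} tied to \eqn{\epsilon_{int}} through
#' the energy cap ([alpha_from_cap()]) and \eqn{\epsilon_{cr}} through
#' [eps_cr_from_params()]. The bead's \eqn{\lambda} is pinned to 1 (base
#' `"LLL"`) or 0 (base `"DDD"`) so only the fitted bounding potential
#' contributes, mirroring how the bounding potentials are parameterized one
#' at a time.
#'
#' @param reference data frame with columns `z`, `F`.
#' @param gate `"open"` or `"closed"`.
#' @param geom a [sec_geometry()].
#' @param base `"LLL"` (fit with \eqn{\lambda = 1}) or `"DDD"`
#'   (\eqn{\lambda = 0}).
#' @param class_fit `"normal"` or `"confined"`: which channel-bead class row
#'   to fit; the other class keeps its current parameters.
#' @param g bead transfer free energy used for the solvation term.
#' @param start optional named start values `c(eps_int=, r_cr=, sigma_j=)`.
#' @param z_min fitting range lower bound.
#' @inheritParams fit_lambda
#' @return A list with `params` (the fitted row, as in [softcore_table()]),
#'   `residual` and `convergence` (0 = converged; best-found values are
#'   returned with a warning otherwise).
#' @export
fit_softcore_to_pmf <- function(reference, gate = c("closed", "open"), geom,
                                base = c("LLL", "DDD"),
                                class_fit = c("normal", "confined"),
                                g = if (base == "LLL") -6.1 else 23.1,
                                start = NULL, q = 0, z_min = -2,
                                radius = 1.5, spacing = 0.1,
                                constants = sec_constants(),
                                table = softcore_table(constants)) {
  gate <- match.arg(gate)
  base <- match.arg(base)
  class_fit <- match.arg(class_fit)
  force(g)
  ref <- reference[reference$z >= z_min, ]
  row_name <- paste0("U", base, gate,
                     if (class_fit == "confined") "-confined" else "")
  i_row <- which(table$potential == row_name)
  lambda <- if (base == "LLL") 1 else 0
  disc <- .disc_points(radius, spacing)
  if (is.null(start)) {
    start <- c(eps_int = table$eps_int[i_row], r_cr = table$r_cr[i_row],
               sigma_j = table$sigma_j[i_row])
  }
  obj <- function(par) {
    tab <- table
    tab$eps_int[i_row] <- par[1]
    tab$r_cr[i_row] <- par[2]
    tab$sigma_j[i_row] <- par[3]
    tab$alpha[i_row] <- alpha_from_cap(par[1], constants$energy_cap)
    tab$eps_cr[i_row] <- eps_cr_from_params(par[1], tab$alpha[i_row], par[2])
    fields <- .bead_fields(disc, ref$z, gate, geom, constants, tab)
    FF <- .pmf_from_fields(fields, nrow(disc), g, q, lambda, TRUE, FALSE)
    r <- FF - ref$F
    sum((r - mean(r))^2)
  }
  starts <- unique(list(
    start,
    c(eps_int = table$eps_int[i_row], r_cr = table$r_cr[i_row],
      sigma_j = table$sigma_j[i_row]),
    c(eps_int = 1, r_cr = 2.5, sigma_j = 1)
  ))
  fits <- lapply(starts, function(s0) {
    stats::optim(s0, obj, method = "L-BFGS-B",
                 lower = c(0.01, 1.05, 0.5), upper = c(20, 3.5, 2),
                 control = list(parscale = c(0.5, 1, 0.5)))
  })
  fit <- fits[[which.min(vapply(fits, `[[`, numeric(1), "value"))]]
  if (fit$convergence != 0 && fit$value > 1e-6) {
    warning("soft-core fit did not fully converge; returning best found")
  }
  alpha <- alpha_from_cap(fit$par[1], constants$energy_cap)
  params <- tibble(
    potential = row_name, base = base, gate = gate,
    confined = class_fit == "confined",
    eps_int = unname(fit$par[1]),
    eps_cr = eps_cr_from_params(fit$par[1], alpha, fit$par[2]),
    r_cr = unname(fit$par[2]), alpha = alpha,
    sigma_j = unname(fit$par[3])
  )
  list(params = params, residual = fit$value, convergence = fit$convergence)
}

#' Read and write reference PMF profiles
#'
#' Two-column whitespace-delimited text (`z_sigma`, `F_eps`) with `#`
#' comment lines.
#'
#' @param path file path.
#' @param rescale optional multiplicative factor applied to `F` on read
#'   (e.g. 0.25 for raw residue-based reference curves whose energy scale
#'   must be brought onto the model's; packaged curves are already on the
#'   model scale).
#' @return `read_pmf()` returns a tibble with columns `z`, `F`;
#'   `write_pmf()` returns `path` invisibly.
#' @export
read_pmf <- function(path, rescale = 1) {
  tab <- read.table(path, header = FALSE, comment.char = "#",
                    col.names = c("z", "F"))
  tibble(z = tab$z, F = tab$F * rescale)
}

#' @rdname read_pmf
#' @param pmf a data frame with columns `z`, `F`.
#' @export
write_pmf <- function(pmf, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# z_sigma  F_eps", con)
  writeLines(sprintf("%.10g %.10g", pmf$z, pmf$F), con)
  invisible(path)
}
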