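# ggplot2 displays for the package's result types.

#' @describeIn run_trajectory long-format view of a trajectory: one row per
#'   time and tracked quantity.
#' @param x A `uvp_trajectory`.
#' @param ... Unused.
#' @export
tidy.uvp_trajectory <- function(x, ...) {
  base <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(x), "time", "electronic", "elastic",
                  "kinetic", "total"),
    -"time", names_to = "quantity", values_to = "value"
  )
  keep <- !vapply(x$adiabatic, is.null, logical(1))
  if (any(keep)) {
    k <- length(x$adiabatic[keep][[1]])
    pops <- dplyr::bind_rows(lapply(which(keep), function(i) {
      tibble::tibble(
        time = rep(x$time[i], 2 * k),
        quantity = c(paste0("P(S", seq_len(k) - 1, ")"),
                     paste0("P(phi", seq_len(k) - 1, ")")),
        value = c(x$adiabatic[[i]], x$diabatic[[i]])
      )
    }))
    base <- dplyr::bind_rows(base, pops)
  }
  base
}

#' @describeIn run_trajectory energy components and populations vs time.
#' @param object A `uvp_trajectory`.
#' @export
autoplot.uvp_trajectory <- function(object, ...) {
  td <- tidy.uvp_trajectory(object)
  td$panel <- ifelse(grepl("^P\\(", td$quantity), "population", "energy (eV)")
  ggplot(td, aes(x = .data$time, y = .data$value, colour = .data$quantity)) +
    geom_line() +
    facet_wrap(~panel, scales = "free_y", ncol = 1) +
    labs(x = "time (fs)", y = NULL, colour = NULL) +
    theme_minimal()
}

#' @describeIn spectrum_from_chain stick spectrum with optional Lorentzian
#'   envelope at the table's `eta`.
#' @param object A `spectrum_table`.
#' @param broaden Draw the Lorentzian envelope.
#' @param ... Unused.
#' @export
autoplot.spectrum_table <- function(object, broaden = TRUE, ...) {
  p <- ggplot(object, aes(x = .data$energy)) +
    geom_segment(aes(xend = .data$energy, y = 0, yend = .data$intensity)) +
    labs(x = "transition energy (eV)", y = "normalized intensity") +
    theme_minimal()
  eta <- attr(object, "eta")
  if (broaden && !is.null(eta) && is.finite(eta) && eta > 0) {
    grid <- seq(max(0, min(object$energy) - 1), max(object$energy) + 1,
                length.out = 400)
    env <- vapply(grid, function(e) {
      sum(object$intensity * eta^2 / ((e - object$energy)^2 + eta^2))
    }, numeric(1))
    p <- p + geom_line(data = tibble::tibble(energy = grid, env = env),
                       aes(y = .data$env), linetype = 2, colour = "grey40")
  }
  p
}

#' @describeIn lz_scan populations and classical yield against the
#'   symmetry-breaking scale.
#' @param object An `lz_scan` tibble.
#' @param ... Unused.
#' @export
autoplot.lz_scan <- function(object, ...) {
  td <- tidyr::pivot_longer(
    dplyr::select(tibble::as_tibble(object), "zeta", "p_s1", "p_s2",
                  "p_classical"),
    -"zeta", names_to = "quantity", values_to = "probability"
  )
  ggplot(td, aes(x = .data$zeta, y = .data$probability,
                 colour = .data$quantity)) +
    geom_line() + geom_point() +
    labs(x = expression(zeta), y = "probability at probe time",
         colour = NULL) +
    theme_minimal()
}

#' @describeIn projected_gradient_fit fitted vs target densities and the eps
#'   profile.
#' @param object An `epsfit_result`.
#' @export
autoplot.epsfit_result <- function(object, ...) {
  td <- tidy.epsfit_result(object)
  long <- tidyr::pivot_longer(td, c("density", "target"),
                              names_to = "which", values_to = "value")
  ggplot(long, aes(x = .data$site)) +
    geom_line(aes(y = .data$value, colour = .data$which)) +
    geom_point(aes(y = .data$value, colour = .data$which)) +
    geom_segment(data = td, aes(xend = .data$site, y = 1, yend = 1 + .data$eps),
                 colour = "grey50", linetype = 3) +
    labs(x = "site", y = "density (electrons/site); dotted: 1 + eps (eV)",
         colour = NULL) +
    theme_minimal()
}

#' @describeIn dmrg_run per-sweep truncation diagnostics.
#' @param object A `dmrg_result`.
#' @export
autoplot.dmrg_result <- function(object, ...) {
  lg <- object$log
  lg$step <- seq_len(nrow(lg))
  td <- tidyr::pivot_longer(
    dplyr::select(lg, "step", "discarded", "entropy"),
    -"step", names_to = "quantity", values_to = "value"
  )
  ggplot(td, aes(x = .data$step, y = .data$value)) +
    geom_line() +
    facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    labs(x = "truncation step", y = NULL) +
    theme_minimal()
}
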