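# Fit the symmetry-breaking on-site potentials eps to target ground-state
# charge densities by projected gradient descent under the box constraint
# |eps_i| <= eps_max.

#' Charge-density fit target
#'
#' Wraps a vector of per-site target densities, mean-shifting it to 1
#' electron per site (charge neutrality of the half-filled pi-system) and
#' carrying the box bound for the fit.
#'
#' @param densities Numeric vector of target densities (one per conjugated
#'   carbon), e.g. mean-shifted Mulliken densities from an electronic
#'   structure calculation.
#' @param eps_max Box bound on `|eps_i|` (eV).
#' @return Object of class `density_target`.
#' @export
density_target <- function(densities, eps_max = 1.0) {
  d <- as.numeric(densities)
  if (length(d) < 2 || any(!is.finite(d))) stop("invalid target densities")
  d <- d - mean(d) + 1
  structure(list(d_opt = d, eps_max = eps_max, n_sites = length(d)),
            class = "density_target")
}

#' Ground-state site densities for a given eps
#'
#' `<n_n>` per site of the ground state at the supplied geometry, via exact
#' diagonalization or static DMRG. Densities sum to the electron count; for
#' `eps = 0` on a mirror-symmetric half-filled chain they are all 1 by
#' particle-hole symmetry.
#'
#' @param params A [model_params()] (its `eps` is the potential in force).
#' @param chain Geometry (default undistorted).
#' @param engine `"exact"` or `"dmrg"`.
#' @param max_states,cutoff DMRG truncation controls.
#' @return Numeric vector of `N` densities.
#' @export
ground_state_densities <- function(params, chain = chain_state(params),
                                   engine = c("exact", "dmrg"),
                                   max_states = params$max_states,
                                   cutoff = params$trunc_cutoff) {
  engine <- match.arg(engine)
  if (engine == "exact") {
    basis <- sector_basis(params$n_sites, params$n_sites, 0)
    h <- full_hamiltonian(params, chain, basis)
    # iterative ground state: the fit solves many nearby eps vectors
    sol <- davidson(function(x) sp_mult(h, x), Matrix::diag(h), k = 1,
                    guesses = NULL, tol = 1e-10)
    site_densities(sector_state(sol$vectors[, 1], basis))
  } else {
    res <- dmrg_run(params, chain, n_states = 1, max_states = max_states,
                    cutoff = cutoff, n_sweeps = 4)
    mps_site_expectations(res$states[[1]], site_operators()$n_tot)
  }
}

#' Coefficient of determination between target and model densities
#'
#' `r^2 = 1 - sum (d_opt - d)^2 / sum (d_opt - mean(d_opt))^2`: 1 for a
#' perfect match, 0 when the model does no better than the target mean,
#' invariant under a common mean shift of both vectors.
#'
#' @param d_opt,d Density vectors of equal length.
#' @return Scalar `r^2`.
#' @export
r_squared <- function(d_opt, d) {
  if (length(d_opt) != length(d)) stop("density vectors differ in length")
  sst <- sum((d_opt - mean(d_opt))^2)
  if (sst < 1e-14) stop("zero-variance target: r^2 undefined")
  1 - sum((d_opt - d)^2) / sst
}

#' Fit eps to target densities by projected gradient descent
#'
#' Minimizes `E(eps) = || d_opt - d(eps) ||` over the box
#' `|eps_i| <= eps_max`, with the gradient from forward finite differences
#' (one ground-state solve per site), a backtracking line search, and
#' componentwise clipping to the box after every trial step. The box prevents
#' the unphysically large on-site potentials an unconstrained fit drifts
#' into.
#'
#' @param target A [density_target()].
#' @param params A [model_params()]; its `eps` is ignored (the fit starts
#'   from `eps = 0`, the centre of the box).
#' @param chain Geometry (default undistorted).
#' @param engine,max_states,cutoff See [ground_state_densities()].
#' @param grad_step Finite-difference step (eV).
#' @param init_step Initial line-search step (eV).
#' @param shrink Backtracking factor.
#' @param tol Stop when the objective improves by less than this.
#' @param max_iter Iteration cap.
#' @return Object of class `epsfit_result`: `eps` (fitted vector),
#'   `densities`, `r_squared`, `objective`, `iterations`, `converged`, and a
#'   per-iteration `trace` tibble (objective non-increasing on accepted
#'   steps).
#' @export
projected_gradient_fit <- function(target, params, chain = chain_state(params),
                                   engine = c("exact", "dmrg"),
                                   max_states = params$max_states,
                                   cutoff = params$trunc_cutoff,
                                   grad_step = 1e-3, init_step = 0.2,
                                   shrink = 0.5, tol = 1e-6, max_iter = 60) {
  stopifnot(inherits(target, "density_target"))
  engine <- match.arg(engine)
  if (target$n_sites != params$n_sites) {
    stop("target has ", target$n_sites, " sites; model has ", params$n_sites)
  }
  emax <- target$eps_max
  dens <- function(eps) {
    p <- params
    p$eps <- eps
    p$eps_max <- max(p$eps_max, emax, max(abs(eps)))
    ground_state_densities(p, chain, engine, max_states, cutoff)
  }
  objective <- function(eps) sqrt(sum((target$d_opt - dens(eps))^2))
  clip <- function(eps) pmin(pmax(eps, -emax), emax)
  eps <- rep(0, params$n_sites)
  obj <- objective(eps)
  trace <- list(tibble::tibble(iteration = 0L, objective = obj, step = NA_real_))
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    grad <- vapply(seq_len(params$n_sites), function(i) {
      epsi <- eps
      epsi[i] <- epsi[i] + grad_step
      (objective(epsi) - obj) / grad_step
    }, numeric(1))
    gn <- sqrt(sum(grad^2))
    if (gn < 1e-12) { converged <- TRUE; break }
    step <- init_step / gn
    accepted <- FALSE
    for (ls in 1:12) {
      trial <- clip(eps - step * grad)
      otrial <- objective(trial)
      if (otrial < obj - 1e-12) { accepted <- TRUE; break }
      step <- step * shrink
    }
    if (!accepted) { converged <- TRUE; break }   # smallest-step fallback done
    improve <- obj - otrial
    eps <- trial; obj <- otrial
    trace[[length(trace) + 1]] <- tibble::tibble(iteration = it,
                                                 objective = obj, step = step)
    if (improve < tol) { converged <- TRUE; break }
  }
  d <- dens(eps)
  r2 <- tryCatch(r_squared(target$d_opt, d), error = function(e) NA_real_)
  structure(
    list(eps = eps, densities = d, r_squared = r2,
         objective = obj, iterations = it, converged = converged,
         target = target, trace = dplyr::bind_rows(trace)),
    class = "epsfit_result"
  )
}

#' @exportS3Method base::print
print.epsfit_result <- function(x, ...) {
  cat("<epsfit_result>", ifelse(x$converged, "converged", "iteration cap"),
      "after", x$iterations, "iterations\n")
  cat("  r^2 =", signif(x$r_squared, 4), " objective =",
      signif(x$objective, 4), "\n")
  cat("  eps (eV):", paste(signif(x$eps, 4), collapse = " "), "\n")
  invisible(x)
}

#' @describeIn projected_gradient_fit per-site tidy view of the fit.
#' @param x An `epsfit_result`.
#' @param ... Unused.
#' @export
tidy.epsfit_result <- function(x, ...) {
  tibble::tibble(site = seq_along(x$eps), eps = x$eps,
                 density = x$densities, target = x$target$d_opt)
}

#' @describeIn projected_gradient_fit one-row fit summary.
#' @export
glance.epsfit_result <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, objective = x$objective,
                 iterations = x$iterations, converged = x$converged,
                 eps_max = x$target$eps_max,
                 box_saturated = sum(abs(abs(x$eps) - x$target$eps_max) < 1e-9))
}
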