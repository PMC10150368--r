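# Configuration (YAML), fixture registry, tabular text output and RDS
# checkpoints shared by all modules. Physics paths contain no hidden RNG:
# identical configuration gives identical output.

config_keys <- c(
  "n_sites", "u_coulomb", "v_coulomb", "beta0", "alpha", "spring_k", "eps",
  "lambda_spin", "gamma", "nuclear_mass", "dt_trotter", "dt_nuclear",
  "trunc_cutoff", "max_states", "eps_max", "lattice_spacing",
  "mode", "duration", "engine", "record_every", "analyse_every", "n_track",
  "zeta", "probe_time", "at_times", "targets_file", "output", "seed"
)

#' Load a run configuration
#'
#' Reads a YAML file of model and run settings. Omitted physics keys fall
#' back to the printed carotenoid parametrization (see [model_params()]);
#' unknown keys are rejected with a field-level message. An empty file yields
#' the full defaults at `n_sites = 18`.
#'
#' @param path YAML file path.
#' @return Object of class `run_config`: list with `params` (a
#'   [model_params()]) and `run` (remaining run settings).
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  unknown <- setdiff(names(raw), config_keys)
  if (length(unknown)) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "))
  }
  pkeys <- intersect(names(raw), names(formals(model_params)))
  n <- if (!is.null(raw$n_sites)) raw$n_sites else 18L
  pargs <- raw[setdiff(pkeys, "n_sites")]
  params <- do.call(model_params, c(list(n_sites = n), pargs))
  run <- raw[setdiff(names(raw), c(pkeys, "n_sites"))]
  structure(list(params = params, run = run), class = "run_config")
}

#' Save a run configuration
#'
#' Writes a [run_config][load_config()] (or a bare [model_params()]) as YAML;
#' `load_config(save_config(x, f))` round-trips losslessly.
#'
#' @param config A `run_config` or `uvp_params`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  if (inherits(config, "uvp_params")) {
    config <- structure(list(params = config, run = list()),
                        class = "run_config")
  }
  p <- unclass(config$params)
  out <- c(p, config$run)
  yaml::write_yaml(out, path)
  invisible(path)
}

#' @exportS3Method base::print
print.run_config <- function(x, ...) {
  cat("<run_config>\n")
  print(x$params)
  if (length(x$run)) {
    cat("  run:", paste(names(x$run), unlist(lapply(x$run, paste, collapse = ",")),
                        sep = "=", collapse = " "), "\n")
  }
  invisible(x)
}

#' Deterministic test fixtures
#'
#' Small, fully reproducible systems with oracle reference quantities
#' regenerated from scratch at every call:
#' \describe{
#'   \item{hubbard_dimer}{N = 2 dimer whose half-filled spectrum has the
#'     closed form `(U - V)/2 +- sqrt(((U - V)/2)^2 + 4 beta^2)`, 0 and
#'     `U - V`.}
#'   \item{n6_symmetric}{N = 6 symmetric chain (eps = 0), dimerized geometry;
#'     labelled eigenstates and bipartite entropies.}
#'   \item{n6_weak_eps}{N = 6 with a weak symmetry-breaking ramp.}
#'   \item{n8_dmrg}{N = 8 dimerized chain for DMRG-vs-oracle statics.}
#'   \item{lz_mini}{the engineered N = 6 crossing used for the Landau-Zener
#'     scan: V = 3.25 eV, a donor-acceptor potential ramp of amplitude
#'     0.6 eV, damping 0.05 / fs.}
#' }
#'
#' @param name Fixture name.
#' @return List with `params`, `chain`, and fixture-specific references.
#' @export
make_fixture <- function(name = c("hubbard_dimer", "n6_symmetric",
                                  "n6_weak_eps", "n8_dmrg", "lz_mini")) {
  name <- match.arg(name)
  switch(
    name,
    hubbard_dimer = {
      p <- model_params(2, u_coulomb = 4, v_coulomb = 1, beta0 = 1,
                        lambda_spin = 1)
      x <- (p$u_coulomb - p$v_coulomb) / 2
      list(params = p, chain = chain_state(p),
           closed_form = sort(c(x - sqrt(x^2 + 4 * p$beta0^2), 0,
                                p$u_coulomb - p$v_coulomb,
                                x + sqrt(x^2 + 4 * p$beta0^2))))
    },
    n6_symmetric = {
      p <- model_params(6, lambda_spin = 2)
      ch <- chain_state(p, displacements = 0.03 * (-1)^(1:6))
      b <- sector_basis(6, 6, 0)
      ee <- exact_eigenstates(p, ch, b, k = 6)
      list(params = p, chain = ch,
           energies = ee$energy, labels = ee$label,
           entropies = vapply(1:5, function(cut) {
             reduced_density_entropy(ee$vector[[1]], cut, b)
           }, numeric(1)))
    },
    n6_weak_eps = {
      p <- model_params(6, lambda_spin = 2,
                        eps = 0.1 * c(1, 0.6, 0.2, -0.2, -0.6, -1))
      list(params = p, chain = chain_state(p, displacements = 0.03 * (-1)^(1:6)))
    },
    n8_dmrg = {
      p <- model_params(8)
      list(params = p, chain = chain_state(p, displacements = 0.02 * (-1)^(1:8)))
    },
    lz_mini = {
      p <- model_params(6, v_coulomb = 3.25, lambda_spin = 2, gamma = 0.05,
                        eps = 0.6 * c(1, 0.6, 0.2, -0.2, -0.6, -1))
      list(params = p, chain = chain_state(p), probe_time = 10,
           zeta = c(0.1, 0.5, 1, 1.5, 2))
    }
  )
}

schema_header <- function(type, columns) {
  paste0("# polyenedyn ", type, " v1: ", paste(columns, collapse = "\t"))
}

#' Write a trajectory as tabular text
#'
#' One row per record; list-columns are flattened to `u_<i>`, `p_ad_<i>`,
#' `p_di_<i>` columns. A schema header line (`# polyenedyn trajectory v1`)
#' stamps the format. Rows containing non-finite populations are refused.
#'
#' @param records A [run_trajectory()] tibble.
#' @param path Output path (TSV).
#' @return `path`, invisibly.
#' @export
write_trajectory <- function(records, path) {
  if (!nrow(records)) stop("empty trajectory")
  flat <- records
  nu <- length(flat$displacements[[1]])
  for (i in seq_len(nu)) {
    flat[[paste0("u_", i)]] <- vapply(flat$displacements, `[`, numeric(1), i)
  }
  pad <- flat$adiabatic[!vapply(flat$adiabatic, is.null, logical(1))]
  if (length(pad)) {
    k <- length(pad[[1]])
    for (i in seq_len(k)) {
      flat[[paste0("p_ad_", i)]] <- vapply(flat$adiabatic, function(v) {
        if (is.null(v)) NA_real_ else v[i]
      }, numeric(1))
      flat[[paste0("p_di_", i)]] <- vapply(flat$diabatic, function(v) {
        if (is.null(v)) NA_real_ else v[i]
      }, numeric(1))
    }
    vals <- unlist(pad)
    if (any(is.nan(vals)) || any(is.infinite(vals))) {
      stop("non-finite population: refusing to write trajectory")
    }
  }
  flat$displacements <- NULL; flat$adiabatic <- NULL; flat$diabatic <- NULL
  con <- file(path, "w")
  writeLines(schema_header("trajectory", names(flat)), con)
  writeLines(paste(names(flat), collapse = "\t"), con)
  utils::write.table(as.data.frame(flat), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' Read a tabular trajectory written by [write_trajectory()]
#'
#' @param path TSV path.
#' @return A tibble (flattened columns).
#' @export
read_trajectory <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# polyenedyn trajectory")) {
    stop("not a polyenedyn trajectory file: ", path)
  }
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      comment.char = "#"))
}

#' Write / read a spectrum table
#'
#' Tabular text with a schema header; metadata (time stamp, broadening,
#' source energy) stored as header comments.
#'
#' @param table A `spectrum_table`.
#' @param path Output path.
#' @return `path` (write) or a tibble (read).
#' @export
write_spectrum <- function(table, path) {
  if (!nrow(table)) stop("empty spectrum")
  hdr <- c(schema_header("spectrum", names(table)),
           paste0("# time: ", attr(table, "time")),
           paste0("# eta: ", attr(table, "eta")),
           paste0("# source_energy: ", attr(table, "source_energy")))
  con <- file(path, "w")
  writeLines(c(hdr, paste(names(table), collapse = "\t")), con)
  utils::write.table(as.data.frame(table), con, sep = "\t", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  close(con)
  invisible(path)
}

#' @rdname write_spectrum
#' @export
read_spectrum <- function(path) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "# polyenedyn spectrum")) {
    stop("not a polyenedyn spectrum file: ", path)
  }
  tibble::as_tibble(utils::read.table(path, header = TRUE, sep = "\t",
                                      comment.char = "#"))
}

#' Checkpoint a simulation state
#'
#' Serializes a state (MPS or sector state) plus chain geometry to an RDS
#' container for later resumption.
#'
#' @param state Electronic state object.
#' @param chain A [chain_state()].
#' @param path Output path.
#' @param time Trajectory time stamp (fs).
#' @return `path` (write) or the checkpoint list (read).
#' @export
write_checkpoint <- function(state, chain, path, time = NA) {
  saveRDS(list(state = state, chain = chain, time = time,
               version = "polyenedyn-checkpoint-v1"), path)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  x <- readRDS(path)
  if (!identical(x$version, "polyenedyn-checkpoint-v1")) {
    stop("not a polyenedyn checkpoint: ", path)
  }
  x
}

#' Read / write two-column site-value text files
#'
#' The exchange format for target densities and fitted potentials: comment
#' lines start with `#`, then one `site value` pair per line.
#'
#' @param path File path.
#' @param values Numeric vector to write.
#' @return Numeric vector (read) or `path` (write).
#' @export
read_site_values <- function(path) {
  tab <- utils::read.table(path, header = FALSE, comment.char = "#")
  if (ncol(tab) < 2) stop("expected two columns (site, value) in ", path)
  tab[[2]][order(tab[[1]])]
}

#' @rdname read_site_values
#' @export
write_site_values <- function(values, path) {
  writeLines(c("# site\tvalue",
               paste(seq_along(values), signif(values, 10), sep = "\t")), path)
  invisible(path)
}
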