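# Matrix-product representation of the renormalized DMRG state.
#
# Tensors A[[n]] have dimensions (D_left, 4, D_right), site 1 the fastest
# index of the corresponding dense Fock vector. The state is kept in mixed
# canonical form: tensors strictly left of `center` are left-orthonormal,
# strictly right of it right-orthonormal. Truncations are Schmidt (reduced
# density matrix) truncations of the two-site wavefunction, reported as
# discarded weight, retained dimension and von Neumann entropy.

new_mps <- function(tensors, center = 1L) {
  structure(list(tensors = tensors, center = as.integer(center),
                 n_sites = length(tensors)),
            class = "uvp_mps")
}

#' @exportS3Method base::print
print.uvp_mps <- function(x, ...) {
  dims <- vapply(x$tensors, function(a) dim(a)[3], numeric(1))
  cat("<uvp_mps>", x$n_sites, "sites, center", x$center,
      ", bond dims:", paste(dims[-x$n_sites], collapse = " "), "\n")
  invisible(x)
}

mps_bond_dims <- function(mps) {
  vapply(mps$tensors, function(a) dim(a)[3], numeric(1))[-mps$n_sites]
}

#' Product-state MPS
#'
#' @param local_states List of length-4 local state vectors (one per site),
#'   or a vector of local basis indices 1..4.
#' @return A `uvp_mps` of bond dimension 1.
#' @export
mps_product_state <- function(local_states) {
  if (is.numeric(local_states) && !is.list(local_states)) {
    local_states <- lapply(local_states, function(i) {
      v <- rep(0, 4); v[i] <- 1; v
    })
  }
  tensors <- lapply(local_states, function(v) {
    array(as.complex(v / sqrt(sum(Mod(v)^2))), c(1, 4, 1))
  })
  new_mps(tensors, center = 1L)
}

# matrix views of a site tensor
tmat_l <- function(a) matrix(a, dim(a)[1] * 4L, dim(a)[3])        # (Dl*4) x Dr
tmat_r <- function(a) matrix(a, dim(a)[1], 4L * dim(a)[3])        # Dl x (4*Dr)

#' Convert an exact sector state to an MPS
#'
#' Sequential Schmidt decomposition of the dense Fock vector; exact when
#' `max_states` is large enough (bond dimension at most `4^(N/2)`).
#'
#' @param state A [sector_state()] or full Fock amplitude vector.
#' @param basis Basis when `state` is a sector amplitude vector.
#' @param max_states Bond-dimension cap.
#' @param cutoff Discarded-weight target per cut.
#' @return A `uvp_mps` with the orthogonality center on site 1.
#' @export
as_mps <- function(state, basis = NULL, max_states = Inf, cutoff = 0) {
  if (inherits(state, "sector_state") || !is.null(basis)) {
    st <- resolve_state(state, basis)
    v <- dense_from_sector(st$vec, st$basis)
    n <- st$basis$n_sites
  } else {
    v <- as.complex(state)
    n <- as.integer(round(log(length(v), 4)))
    if (4^n != length(v)) stop("length must be a power of 4")
  }
  tensors <- vector("list", n)
  m <- matrix(v, nrow = 4)   # site 1 fastest
  dl <- 1L
  for (k in seq_len(n - 1)) {
    sv <- svd(m)
    keep <- trunc_rank(sv$d, max_states, cutoff)
    tensors[[k]] <- array(sv$u[, seq_len(keep), drop = FALSE], c(dl, 4, keep))
    m <- (sv$d[seq_len(keep)] * Conj(t(sv$v[, seq_len(keep), drop = FALSE])))
    dl <- keep
    if (k < n - 1) m <- matrix(m, nrow = dl * 4L)  # absorb next site
  }
  tensors[[n]] <- array(m, c(dl, 4, 1))
  out <- new_mps(tensors, center = n)
  mps_move_center(out, 1L)
}

# rank kept by a Schmidt truncation: largest M <= max_states with discarded
# weight below cutoff (at least 1 state kept)
trunc_rank <- function(d, max_states, cutoff) {
  if (cutoff <= 0) return(as.integer(min(max_states, length(d))))
  w <- d^2
  tot <- sum(w)
  if (tot == 0) return(1L)
  cum <- rev(cumsum(rev(w))) / tot   # cum[k] = weight of ranks >= k
  keep <- which(c(cum[-1], 0) < cutoff)[1]
  if (is.na(keep)) keep <- length(d)
  min(keep, max_states, length(d))
}

#' Densify an MPS to the full Fock vector
#'
#' Exponential in `N`; intended for cross-checks at small `N`.
#'
#' @param mps A `uvp_mps`.
#' @return Complex vector of length `4^N` (site 1 fastest).
#' @export
mps_dense <- function(mps) {
  t_acc <- matrix(1 + 0i, 1, 1)
  x <- 1L
  for (n in seq_len(mps$n_sites)) {
    a <- mps$tensors[[n]]
    t_acc <- t_acc %*% tmat_r(a)          # (x, 4*Dr)
    x <- x * 4L
    t_acc <- matrix(t_acc, nrow = x)
  }
  as.vector(t_acc)
}

#' @rdname mps_dense
#' @param basis Sector basis to restrict to.
#' @export
mps_sector_state <- function(mps, basis) {
  sector_state(sector_from_dense(mps_dense(mps), basis), basis, normalize = FALSE)
}

mps_norm2 <- function(mps) {
  a <- mps$tensors[[mps$center]]
  Re(sum(Conj(a) * a))
}

mps_scale <- function(mps, s) {
  mps$tensors[[mps$center]] <- mps$tensors[[mps$center]] * s
  mps
}

mps_normalize <- function(mps) mps_scale(mps, 1 / sqrt(mps_norm2(mps)))

# Move the orthogonality center one site (QR-like via SVD for stability).
shift_center_right <- function(mps) {
  c0 <- mps$center
  a <- mps$tensors[[c0]]
  sv <- svd(tmat_l(a))
  r <- length(sv$d)
  mps$tensors[[c0]] <- array(sv$u, c(dim(a)[1], 4, r))
  m <- sv$d * Conj(t(sv$v))
  b <- mps$tensors[[c0 + 1]]
  mps$tensors[[c0 + 1]] <- array(m %*% tmat_r(b), c(r, 4, dim(b)[3]))
  mps$center <- c0 + 1L
  mps
}

shift_center_left <- function(mps) {
  c0 <- mps$center
  a <- mps$tensors[[c0]]
  sv <- svd(tmat_r(a))
  r <- length(sv$d)
  mps$tensors[[c0]] <- array(Conj(t(sv$v)), c(r, 4, dim(a)[3]))
  m <- sv$u %*% diag(sv$d, r)
  b <- mps$tensors[[c0 - 1]]
  mps$tensors[[c0 - 1]] <- array(tmat_l(b) %*% m, c(dim(b)[1], 4, r))
  mps$center <- c0 - 1L
  mps
}

mps_move_center <- function(mps, to) {
  while (mps$center < to) mps <- shift_center_right(mps)
  while (mps$center > to) mps <- shift_center_left(mps)
  mps
}

#' Inner product of two MPS
#'
#' @param a,b `uvp_mps` objects over the same chain.
#' @return Complex scalar `<a|b>`.
#' @export
mps_overlap <- function(a, b) {
  stopifnot(a$n_sites == b$n_sites)
  e <- matrix(1 + 0i, 1, 1)
  for (n in seq_len(a$n_sites)) {
    ta <- a$tensors[[n]]; tb <- b$tensors[[n]]
    # e'(ia', ib') = sum_{ia, ib, s} conj(ta[ia,s,ia']) e[ia,ib] tb[ib,s,ib']
    m <- Conj(t(tmat_l(ta))) %*% rbind_block(e, tb)
    e <- m
  }
  e[1, 1]
}

# helper: (e %*% along the left index of tb) giving ((Dla*4) x Drb) matrix
# arranged so the conjugated tensor can contract both the bond and spin index
rbind_block <- function(e, tb) {
  dlb <- dim(tb)[1]; drb <- dim(tb)[3]
  m <- e %*% matrix(tb, dlb, 4L * drb)        # (Dla, 4*Drb)
  matrix(aperm(array(m, c(nrow(e), 4L, drb)), c(1, 2, 3)), nrow(e) * 4L, drb)
}

# contract neighbouring tensors into the two-site wavefunction
theta_tensor <- function(mps, n) {
  a <- mps$tensors[[n]]; b <- mps$tensors[[n + 1]]
  m <- tmat_l(a) %*% tmat_r(b)                # (Dl*4) x (4*Dr)
  array(m, c(dim(a)[1], 4, 4, dim(b)[3]))
}

# apply a 16x16 two-site operator to theta
apply_gate <- function(theta, gate) {
  d <- dim(theta)
  tm <- matrix(aperm(theta, c(2, 3, 1, 4)), 16L)        # (16, Dl*Dr)
  tm <- gate %*% tm
  aperm(array(tm, c(4, 4, d[1], d[4])), c(3, 1, 2, 4))
}

#' Schmidt truncation of a two-site wavefunction
#'
#' Splits the two-site tensor by SVD, retaining the `max_states` largest
#' Schmidt states or fewer if the discarded weight already falls below
#' `cutoff`. This is the density-matrix truncation of DMRG: the retained
#' columns are the dominant eigenvectors of the block reduced density matrix
#' and the discarded weight equals the quadratic-norm loss.
#'
#' @param theta Array `(Dl, 4, 4, Dr)`.
#' @param max_states Retained-dimension cap `M_S`.
#' @param cutoff Discarded-weight target.
#' @param center `"left"` or `"right"`: which factor keeps the singular values
#'   (the new orthogonality center).
#' @return List with tensors `a`, `b`, the `report` row (discarded weight,
#'   retained dimension, entropy) and the Schmidt values `schmidt`.
#' @export
split_theta <- function(theta, max_states = Inf, cutoff = 0,
                        center = c("right", "left")) {
  center <- match.arg(center)
  sp <- split_theta_fast(theta, max_states, cutoff, center == "right")
  list(a = sp$a, b = sp$b,
       report = tibble::tibble(discarded = sp$discarded, retained = sp$retained,
                               entropy = sp$entropy),
       schmidt = sp$schmidt)
}

# allocation-lean core of split_theta (La.svd, plain-list report fields)
split_theta_fast <- function(theta, max_states, cutoff, center_right) {
  d <- dim(theta)
  sv <- La.svd(matrix(theta, d[1] * 4L, 4L * d[4]))
  w <- sv$d^2
  tot <- sum(w)
  if (tot < 1e-300) stop("zero-norm two-site state in truncation")
  keep <- trunc_rank(sv$d, max_states, cutoff)
  disc <- sum(w[-seq_len(keep)]) / tot
  omega <- w[seq_len(keep)] / tot
  omega <- omega[omega > 1e-16]
  entropy <- -sum(omega * log(omega))
  u <- sv$u[, seq_len(keep), drop = FALSE]
  vh <- sv$vt[seq_len(keep), , drop = FALSE]
  dkeep <- sv$d[seq_len(keep)]
  if (center_right) {
    a <- array(u, c(d[1], 4, keep))
    b <- array(dkeep * vh, c(keep, 4, d[4]))
  } else {
    a <- array(u * rep(dkeep, each = nrow(u)), c(d[1], 4, keep))
    b <- array(vh, c(keep, 4, d[4]))
  }
  list(a = a, b = b, discarded = disc, retained = keep, entropy = entropy,
       schmidt = dkeep / sqrt(tot))
}

# Expectation of a 16x16 bond operator at bond n; center must be at n or n+1.
mps_bond_expectation <- function(mps, n, op) {
  stopifnot(mps$center %in% c(n, n + 1L))
  th <- theta_tensor(mps, n)
  th2 <- apply_gate(th, op)
  Re(sum(Conj(th) * th2))
}

# All bond-order expectations <T_n>, one center sweep.
mps_bond_orders <- function(mps) {
  top <- bond_order_two_site()
  n <- mps$n_sites
  mps <- mps_move_center(mps, 1L)
  out <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    out[k] <- mps_bond_expectation(mps, k, top)
    if (k < n - 1) mps <- shift_center_right(mps)
  }
  out
}

# Single-site expectations of a 4x4 operator for every site.
mps_site_expectations <- function(mps, op4) {
  n <- mps$n_sites
  mps <- mps_move_center(mps, 1L)
  out <- numeric(n)
  for (k in seq_len(n)) {
    a <- mps$tensors[[k]]
    am <- aperm(a, c(2, 1, 3))
    dm <- dim(a)
    tm <- matrix(am, 4L)
    t2 <- op4 %*% tm
    out[k] <- Re(sum(Conj(am) * array(t2, dim(am))))
    if (k < n) mps <- shift_center_right(mps)
  }
  out
}

#' Bipartite entropy profile of an MPS
#'
#' Von Neumann entropy of the Schmidt spectrum at every bond.
#'
#' @param mps A `uvp_mps`.
#' @return Numeric vector of length `N - 1`.
#' @export
mps_entropy_profile <- function(mps) {
  n <- mps$n_sites
  mps <- mps_move_center(mps, 1L)
  out <- numeric(n - 1)
  for (k in seq_len(n - 1)) {
    th <- theta_tensor(mps, k)
    d <- dim(th)
    sv <- svd(matrix(th, d[1] * 4L, 4L * d[4]), nu = 0, nv = 0)
    w <- sv$d^2; w <- w / sum(w); w <- w[w > 1e-16]
    out[k] <- -sum(w * log(w))
    if (k < n - 1) mps <- shift_center_right(mps)
  }
  out
}
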