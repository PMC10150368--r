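# Occupation-number sector basis and fermionic bitstring algebra.
#
# Mode packing: site n contributes two Jordan-Wigner modes at bit positions
# 2(n-1) (spin up) and 2(n-1)+1 (spin down), so a configuration word read in
# base 4 gives the local state of each site in the order
# {0 = empty, 1 = up, 2 = down, 3 = doubly occupied}. Words are ordered by
# increasing mode index when building creation-operator products, which makes
# the doubly occupied site state equal to cdag_up cdag_dn |0>, matching
# site_operators(). Site 1 is the fastest index of the full Fock vector, so a
# sector amplitude maps to full-space index word + 1.

# All N-bit masks with k bits set, as integers.
bit_configs <- function(n, k) {
  if (k < 0 || k > n) return(integer(0))
  if (k == 0) return(0L)
  combs <- utils::combn(n, k)
  as.integer(colSums(matrix(2^(combs - 1), nrow = k)))
}

# Spread an N-bit site mask onto even bit positions (base-4 digits).
spread_bits <- function(mask, n) {
  out <- integer(length(mask))
  for (j in seq_len(n)) {
    out <- out + ((mask %/% 2^(j - 1)) %% 2L) * 4L^(j - 1)
  }
  as.integer(out)
}

#' Sector basis for exact diagonalization
#'
#' Enumerates all electron configurations of an open chain with fixed electron
#' count and spin projection. Usable for chains short enough to enumerate
#' (roughly `N <= 10` at half filling).
#'
#' @inheritParams sector_dimension
#' @return An object of class `sector_basis`: sorted configuration words plus
#'   quantum-number bookkeeping. Its `dim` element equals
#'   [sector_dimension()].
#' @export
sector_basis <- function(n_sites, n_electrons, s_z) {
  dim <- sector_dimension(n_sites, n_electrons, s_z)
  if (dim == 0) stop("infeasible quantum numbers: empty sector")
  if (dim > 5e6) stop("sector dimension ", dim, " too large to enumerate ",
                      "(exact engine capacity ~5e6 configurations)")
  n_up <- (n_electrons + 2 * s_z) / 2
  n_dn <- (n_electrons - 2 * s_z) / 2
  ups <- spread_bits(bit_configs(n_sites, n_up), n_sites)
  dns <- 2L * spread_bits(bit_configs(n_sites, n_dn), n_sites)
  words <- sort(as.integer(outer(ups, dns, "+")))
  structure(
    list(n_sites = as.integer(n_sites), n_electrons = as.integer(n_electrons),
         s_z = s_z, n_up = as.integer(n_up), n_dn = as.integer(n_dn),
         words = words, dim = length(words), cache = new.env(parent = emptyenv())),
    class = "sector_basis"
  )
}

#' @exportS3Method base::print
print.sector_basis <- function(x, ...) {
  cat("<sector_basis> N =", x$n_sites, " N_e =", x$n_electrons,
      " S_z =", x$s_z, " dim =", x$dim, "\n")
  invisible(x)
}

# Exact index of each word in the sorted basis (words must all be present).
word_index <- function(basis, words) findInterval(words, basis$words)

# Per-site local state (0..3) for all words: dim x N integer matrix.
site_codes <- function(basis) {
  get_cached(basis, "site_codes", {
    w <- basis$words
    m <- vapply(seq_len(basis$n_sites),
                function(n) as.integer((w %/% 4L^(n - 1)) %% 4L),
                integer(length(w)))
    matrix(m, nrow = length(w))
  })
}

get_cached <- function(basis, key, expr) {
  if (!is.null(basis$cache[[key]])) return(basis$cache[[key]])
  val <- force(expr)
  basis$cache[[key]] <- val
  val
}

# Site occupation numbers n_n per configuration: dim x N matrix.
site_occupations <- function(basis) {
  get_cached(basis, "site_occ", {
    sc <- site_codes(basis)
    (sc %% 2L) + (sc %/% 2L)
  })
}

# Double-occupancy count per configuration (the ionicity diagonal).
double_occupancy_diag <- function(basis) {
  get_cached(basis, "docc", rowSums(site_codes(basis) == 3L))
}

# Parity (count of set bits) of `words` restricted to bits below `bit`.
occ_below <- function(words, bit) {
  out <- integer(length(words))
  if (bit == 0) return(out)
  for (b in seq_len(bit) - 1L) out <- out + (words %/% 2^b) %% 2L
  out
}

# Sparse one-direction hop c^dag_{n+1,sigma} c_{n,sigma} within the sector.
# Returns a dgCMatrix A; the bond-order operator is A + t(A) summed over spin.
hop_matrix <- function(basis, n, sigma) {
  w <- basis$words
  shift <- if (sigma == "up") 0L else 1L
  b_from <- 2L * (n - 1L) + shift
  b_to <- 2L * n + shift
  occ_from <- (w %/% 2^b_from) %% 2L
  occ_to <- (w %/% 2^b_to) %% 2L
  ok <- occ_from == 1L & occ_to == 0L
  if (!any(ok)) {
    return(Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                                dims = c(basis$dim, basis$dim)))
  }
  src <- which(ok)
  neww <- w[src] - as.integer(2^b_from) + as.integer(2^b_to)
  # JW string: modes strictly between b_from and b_to
  nbet <- integer(length(src))
  for (b in seq.int(b_from + 1L, b_to - 1L)) {
    nbet <- nbet + (w[src] %/% 2^b) %% 2L
  }
  Matrix::sparseMatrix(i = word_index(basis, neww), j = src,
                       x = 1 - 2 * (nbet %% 2L),
                       dims = c(basis$dim, basis$dim))
}

# Bond-order operator T_n as a sparse symmetric matrix (cached per basis).
bond_order_matrix <- function(basis, n) {
  get_cached(basis, paste0("T", n), {
    a <- hop_matrix(basis, n, "up") + hop_matrix(basis, n, "dn")
    a + Matrix::t(a)
  })
}

# Total-spin-squared operator in the sector (cached).
spin_squared_matrix <- function(basis) {
  get_cached(basis, "s2", {
    sc <- site_codes(basis)
    singly <- rowSums(sc == 1L | sc == 2L)
    diagpart <- basis$s_z^2 + singly / 2
    # off-diagonal: S+_i S-_j for i != j (all matrix elements +1)
    ii <- list(); jj <- list(); k <- 0L
    w <- basis$words
    for (j in seq_len(basis$n_sites)) {
      upj <- sc[, j] == 1L                    # singly up at j: S-_j acts
      if (!any(upj)) next
      for (i in seq_len(basis$n_sites)) {
        if (i == j) next
        src <- which(upj & sc[, i] == 2L)     # singly down at i: S+_i acts
        if (!length(src)) next
        neww <- w[src] + as.integer(4^(j - 1)) - as.integer(4^(i - 1))
        k <- k + 1L
        ii[[k]] <- word_index(basis, neww); jj[[k]] <- src
      }
    }
    off <- if (k > 0) {
      Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj),
                           x = rep(1, length(unlist(ii))),
                           dims = c(basis$dim, basis$dim))
    } else {
      Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                           dims = c(basis$dim, basis$dim))
    }
    off + Matrix::Diagonal(basis$dim, diagpart)
  })
}

# Permutation sign of occupied-mode relabelling: parity of inversions.
perm_sign <- function(mapped_modes) {
  k <- length(mapped_modes)
  if (k < 2) return(1)
  inv <- 0L
  for (a in seq_len(k - 1)) {
    inv <- inv + sum(mapped_modes[(a + 1):k] < mapped_modes[a])
  }
  if (inv %% 2L == 0L) 1 else -1
}

# C2 site-reversal operator (signed permutation matrix, cached).
c2_matrix <- function(basis) {
  get_cached(basis, "c2", {
    N <- basis$n_sites
    w <- basis$words
    idx <- integer(length(w)); sgn <- numeric(length(w))
    for (q in seq_along(w)) {
      modes <- which(as.logical(bitwAnd(rep(w[q], 2 * N), 2^(0:(2 * N - 1))))) - 1L
      site <- modes %/% 2L + 1L
      spin <- modes %% 2L
      newm <- 2L * (N - site) + spin
      neww <- sum(2^newm)
      idx[q] <- word_index(basis, as.integer(neww))
      sgn[q] <- perm_sign(newm)
    }
    Matrix::sparseMatrix(i = idx, j = seq_along(w), x = sgn,
                         dims = c(basis$dim, basis$dim))
  })
}

# Particle-hole operator J = prod_m (cdag_m + (-1)^{site} c_m), cached.
# Conjugation sends cdag_{n,sigma} -> (-1)^n c_{n,sigma}; valid at half
# filling where it maps the sector onto itself.
ph_matrix <- function(basis) {
  get_cached(basis, "ph", {
    N <- basis$n_sites
    if (basis$n_electrons != N || basis$s_z != 0) {
      stop("particle-hole map defined on the half-filled S_z = 0 sector")
    }
    w <- basis$words
    idx <- integer(length(w)); sgn <- numeric(length(w))
    full <- sum(4^(seq_len(N) - 1)) * 3  # all-modes-occupied word
    for (q in seq_along(w)) {
      word <- w[q]; s <- 1
      occ <- integer(2 * N)
      for (m in 0:(2 * N - 1)) occ[m + 1] <- (word %/% 2^m) %% 2L
      cur <- occ
      for (m in 0:(2 * N - 1)) {
        below <- if (m == 0) 0L else sum(cur[seq_len(m)])
        if (cur[m + 1] == 0L) {          # cdag_m
          s <- s * (-1)^below
          cur[m + 1] <- 1L
        } else {                         # (-1)^site * c_m
          site <- m %/% 2L + 1L
          s <- s * (-1)^below * (-1)^site
          cur[m + 1] <- 0L
        }
      }
      idx[q] <- word_index(basis, as.integer(full - word))
      sgn[q] <- s
    }
    Matrix::sparseMatrix(i = idx, j = seq_along(w), x = sgn,
                         dims = c(basis$dim, basis$dim))
  })
}

# Embed a sector amplitude vector in the full 4^N Fock vector (site 1 fastest).
dense_from_sector <- function(state, basis) {
  v <- rep(0 + 0i, 4^basis$n_sites)
  v[basis$words + 1] <- state
  v
}

# Restrict a full Fock vector to the sector basis.
sector_from_dense <- function(vec, basis) vec[basis$words + 1]

# Sparse-real times possibly-complex vector (Matrix has no complex methods).
sp_mult <- function(m, v) {
  if (is.complex(v)) {
    as.vector(m %*% Re(v)) + 1i * as.vector(m %*% Im(v))
  } else {
    as.vector(m %*% v)
  }
}
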