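#' @title Symmetric per-molecule descriptor matrices
#' @name descriptors
#' @description The three N x N matrices that fill the image channels —
#'   interatomic distance, Coulomb (full or reduced) and ReaxFF-style
#'   uncorrected bond order — plus the diagonal-only ionization-energy and
#'   atomic-number matrices.
NULL

descriptor_matrix <- function(values, tag) {
  structure(list(values = values, property_tag = tag), class = "descriptor_matrix")
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix %s, %d x %d>\n", x$property_tag,
              nrow(x$values), ncol(x$values)))
  invisible(x)
}

#' Pairwise Euclidean distance matrix
#'
#' R_ij = sqrt((x_i - x_j)^2 + (y_i - y_j)^2 + (z_i - z_j)^2), in
#' Angstrom; the diagonal is exactly zero. Computed from unordered pairs
#' so the matrix is symmetric to the last bit.
#'
#' @param mol a [molecule].
#' @return `descriptor_matrix` with tag `"distance"`.
#' @export
distance_matrix <- function(mol) {
  n <- n_atoms(mol)
  d <- matrix(0, n, n)
  if (n > 1L) {
    idx <- which(upper.tri(d), arr.ind = TRUE)
    diff <- mol$coords[idx[, 1], , drop = FALSE] - mol$coords[idx[, 2], , drop = FALSE]
    r <- sqrt(rowSums(diff * diff))
    d[idx] <- r
    d[idx[, c(2, 1), drop = FALSE]] <- r
  }
  descriptor_matrix(d, "distance")
}

#' Coulomb matrix (full or reduced)
#'
#' Off-diagonal entries are Z_i Z_j / R_ij; the full variant carries
#' 0.5 * Z_i^2.4 on the diagonal while the reduced variant zeroes it.
#' The reduced form exists because the diagonal self-interaction terms
#' are numerically much larger than the pair terms and can dominate a
#' jointly normalized channel.
#'
#' @param mol a [molecule].
#' @param mode `"full"` or `"reduced"`.
#' @param elements element constant table.
#' @return `descriptor_matrix` tagged `"coulomb_full"` or `"coulomb_reduced"`.
#' @export
coulomb_matrix <- function(mol, mode = c("full", "reduced"),
                           elements = element_table()) {
  mode <- match.arg(mode)
  n <- n_atoms(mol)
  z <- elements$Z[match(mol$symbols, elements$symbol)]
  r <- distance_matrix(mol)$values
  if (n > 1L && any(r[upper.tri(r)] == 0)) {
    stop("degenerate geometry: coincident distinct atoms (R_ij = 0 for i != j)")
  }
  m <- matrix(0, n, n)
  if (n > 1L) {
    off <- upper.tri(m)
    zz <- outer(z, z)
    m[off] <- zz[off] / r[off]
    m <- m + t(m)
  }
  if (mode == "full") diag(m) <- 0.5 * z^2.4
  descriptor_matrix(m, paste0("coulomb_", mode))
}

#' Uncorrected ReaxFF bond-order matrix
#'
#' BO'_ij = BO_sigma + BO_pi + BO_pipi, each term
#' exp[pbo_odd * (r_ij / r0)^pbo_even] for the pair's sigma/pi/pi-pi
#' reference radius. A term whose radius carries the -1 sentinel (or any
#' non-positive value) contributes exactly zero; a pair absent from the
#' table yields zero bond order with one warning. No distance cutoff or
#' ReaxFF correction terms are applied: this is the raw descriptor, not a
#' force-field evaluation.
#'
#' @param mol a [molecule].
#' @param params a `pair_param_table` from [load_pair_params()].
#' @return `descriptor_matrix` with tag `"bond_order"`.
#' @export
bond_order_matrix <- function(mol, params = load_pair_params()) {
  n <- n_atoms(mol)
  r <- distance_matrix(mol)$values
  m <- matrix(0, n, n)
  missing_pairs <- character(0)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        p <- lookup_pair(params, mol$symbols[i], mol$symbols[j])
        if (is.null(p)) {
          missing_pairs <- c(missing_pairs, pair_key(mol$symbols[i], mol$symbols[j]))
          next
        }
        bo <- bond_order_terms(r[i, j], p)
        m[i, j] <- bo
        m[j, i] <- bo
      }
    }
  }
  if (length(missing_pairs) > 0L) {
    warning(sprintf("no bond-order parameters for pair(s) %s; contributions set to 0",
                    paste(unique(missing_pairs), collapse = ", ")))
  }
  descriptor_matrix(m, "bond_order")
}

bond_order_terms <- function(r, p) {
  term <- function(r0, pbo_a, pbo_b) {
    if (is.null(r0) || r0 <= 0) return(0)
    exp(pbo_a * (r / r0)^pbo_b)
  }
  term(p$r0_sigma, p$pbo1, p$pbo2) +
    term(p$r0_pi, p$pbo3, p$pbo4) +
    term(p$r0_pipi, p$pbo5, p$pbo6)
}

#' Diagonal-only descriptor matrices
#'
#' Ionization energy (eV) or atomic number placed on the diagonal, zero
#' elsewhere — the per-atom properties of the image channels.
#'
#' @param mol a [molecule].
#' @param property `"ionization"` or `"atomic_number"`.
#' @param elements element constant table.
#' @return `descriptor_matrix` tagged `"ionization_diag"` or
#'   `"atomic_number_diag"`.
#' @export
diagonal_matrix <- function(mol, property = c("ionization", "atomic_number"),
                            elements = element_table()) {
  property <- match.arg(property)
  i <- match(mol$symbols, elements$symbol)
  vals <- switch(property,
                 ionization = elements$ionization_energy[i],
                 atomic_number = elements$Z[i])
  descriptor_matrix(diag(vals, nrow = n_atoms(mol)),
                    paste0(switch(property, ionization = "ionization",
                                  atomic_number = "atomic_number"), "_diag"))
}
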