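# Independent scalar-loop oracles and fixture builders. These
# deliberately avoid the package's vectorized code paths: every formula
# is evaluated entry by entry with plain arithmetic.

fixture_molecule <- function(seed, n_heavy = NULL) {
  set.seed(seed)
  rng <- if (is.null(n_heavy)) c(1L, 9L) else c(n_heavy, n_heavy)
  generate_molecule(synthesis_config(heavy_atom_range = rng),
                    id = sprintf("fix%04d", seed))
}

oracle_distance <- function(mol) {
  n <- length(mol$symbols)
  d <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        d[i, j] <- sqrt((mol$coords[i, 1] - mol$coords[j, 1])^2 +
                        (mol$coords[i, 2] - mol$coords[j, 2])^2 +
                        (mol$coords[i, 3] - mol$coords[j, 3])^2)
      }
    }
  }
  d
}

oracle_coulomb <- function(mol, mode, elements = element_table()) {
  n <- length(mol$symbols)
  z <- numeric(n)
  for (i in seq_len(n)) z[i] <- elements$Z[elements$symbol == mol$symbols[i]]
  r <- oracle_distance(mol)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) {
        if (mode == "full") m[i, j] <- 0.5 * z[i]^2.4
      } else {
        m[i, j] <- z[i] * z[j] / r[i, j]
      }
    }
  }
  m
}

oracle_bond_term <- function(r, r0, pa, pb) {
  if (is.null(r0) || r0 <= 0) 0 else exp(pa * (r / r0)^pb)
}

oracle_bond_order <- function(mol, params) {
  n <- length(mol$symbols)
  r <- oracle_distance(mol)
  m <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j) {
        p <- lookup_pair(params, mol$symbols[i], mol$symbols[j])
        if (!is.null(p)) {
          m[i, j] <- oracle_bond_term(r[i, j], p$r0_sigma, p$pbo1, p$pbo2) +
            oracle_bond_term(r[i, j], p$r0_pi, p$pbo3, p$pbo4) +
            oracle_bond_term(r[i, j], p$r0_pipi, p$pbo5, p$pbo6)
        }
      }
    }
  }
  m
}

# per-pixel reference encoder: gen type A, black margin, fixed offset,
# no quantization — every step a scalar loop
naive_encode_A_black <- function(mol, size, elements = element_table(),
                                 params = load_pair_params()) {
  n <- length(mol$symbols)
  stopifnot(n <= size)
  norm01 <- function(vals) {
    lo <- min(vals); hi <- max(vals)
    if (hi == lo) rep(0, length(vals)) else 255 * (vals - lo) / (hi - lo)
  }
  dist <- oracle_distance(mol)
  redc <- oracle_coulomb(mol, "reduced", elements)
  bond <- oracle_bond_order(mol, params)
  ion <- numeric(n)
  for (i in seq_len(n)) {
    ion[i] <- elements$ionization_energy[elements$symbol == mol$symbols[i]]
  }
  out <- array(0, dim = c(size, size, 3))
  off_vals <- function(m) m[row(m) != col(m)]
  if (n > 1) {
    ndist <- norm01(off_vals(dist)); nred <- norm01(off_vals(redc))
    nbond <- norm01(off_vals(bond))
    k <- 0
    for (j in seq_len(n)) {
      for (i in seq_len(n)) {
        if (i != j) {
          k <- k + 1
          out[i, j, 1] <- ndist[k]
          out[i, j, 2] <- nred[k]
          out[i, j, 3] <- nbond[k]
        }
      }
    }
  }
  nion <- norm01(ion)
  for (i in seq_len(n)) out[i, i, 1] <- nion[i]
  out
}

write_pair_file <- function(text) {
  path <- tempfile(fileext = ".txt")
  writeLines(text, path)
  path
}

stack_images <- function(ds) {
  s <- dim(ds$images[[1]]$pixels)[1]
  x <- array(0, dim = c(s, s, 3, length(ds$images)))
  for (i in seq_along(ds$images)) x[, , , i] <- ds$images[[i]]$pixels
  list(x = x, y = ds$manifest$label)
}
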