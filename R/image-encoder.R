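#' @title Encoding molecules as three-channel images
#' @name image_encoder
#' @description Normalizes descriptor matrices to [0, 255], composes them
#'   into the six fixed red/green/blue layouts (generation types A-F) and
#'   unifies image size with the resize / black-fill / average-fill margin
#'   policies.
NULL

#' Encoding configuration
#'
#' @param gen_type one of `"A"`..`"F"`: which descriptors fill which
#'   channel (see [compose_channels()]).
#' @param canvas_size S, the square output size in pixels (the studied
#'   range is 32-48; S = N + M where M is the margin).
#' @param margin_mode `"resize"` (bilinear upscale of the N x N block),
#'   `"black"` (zero fill) or `"average"` (per-channel mean fill).
#' @param offset_mode `"fixed"` (top-left) or `"random"`; forced to
#'   `"fixed"` under `margin_mode = "resize"`, where positioning does not
#'   apply.
#' @param normalization list: `scheme = "per_image"` (observed min -> 0,
#'   max -> 255, constant matrices -> 0) or `scheme = "fixed"` with
#'   `ranges`, a named list of `c(lo, hi)` per property tag (values
#'   clipped).
#' @param quantize emit integral uint8-style pixels (round half up);
#'   FALSE keeps the float pipeline output.
#' @param combined_joint for channels combining an off-diagonal and a
#'   diagonal property: normalize them jointly instead of independently.
#'   Off by default because diagonal magnitudes (e.g. Coulomb
#'   self-interaction) can dwarf pair terms and flatten the channel.
#' @return object of class `encoding_config`.
#' @export
encoding_config <- function(gen_type = "A", canvas_size = 32L,
                            margin_mode = c("resize", "black", "average"),
                            offset_mode = c("fixed", "random"),
                            normalization = list(scheme = "per_image"),
                            quantize = TRUE, combined_joint = FALSE) {
  margin_mode <- match.arg(margin_mode)
  offset_mode <- match.arg(offset_mode)
  if (!gen_type %in% LETTERS[1:6]) stop("gen_type must be one of A..F")
  canvas_size <- as.integer(canvas_size)
  if (canvas_size < 1L) stop("canvas_size must be >= 1")
  if (margin_mode == "resize") offset_mode <- "fixed"
  if (!normalization$scheme %in% c("per_image", "fixed")) {
    stop("normalization$scheme must be 'per_image' or 'fixed'")
  }
  if (normalization$scheme == "fixed") {
    for (rg in normalization$ranges) {
      if (rg[2] <= rg[1]) stop("fixed normalization range must have hi > lo")
    }
  }
  structure(list(gen_type = gen_type, canvas_size = canvas_size,
                 margin_mode = margin_mode, offset_mode = offset_mode,
                 normalization = normalization, quantize = isTRUE(quantize),
                 combined_joint = isTRUE(combined_joint)),
            class = "encoding_config")
}

#' @export
print.encoding_config <- function(x, ...) {
  cat(sprintf("<encoding_config %s | S=%d | margin=%s/%s | norm=%s%s>\n",
              x$gen_type, x$canvas_size, x$margin_mode, x$offset_mode,
              x$normalization$scheme, if (x$quantize) " | uint8" else ""))
  invisible(x)
}

#' Normalize a matrix onto [0, 255]
#'
#' Per-image scheme: affine map sending the observed minimum (over `mask`,
#' default all cells) to 0 and the maximum to 255; constant matrices map
#' to all zeros. Fixed scheme: affine map of the configured `[lo, hi]`
#' with clipping.
#'
#' @param values numeric matrix.
#' @param scheme `list(scheme = "per_image")` or
#'   `list(scheme = "fixed", lo =, hi =)`.
#' @param mask optional logical matrix: cells over which min/max are taken.
#' @return matrix of the same shape with mapped values in [0, 255].
#' @export
normalize_matrix <- function(values, scheme = list(scheme = "per_image"),
                             mask = NULL) {
  if (!all(is.finite(values))) stop("normalize_matrix: non-finite input")
  if (identical(scheme$scheme, "fixed")) {
    lo <- scheme$lo; hi <- scheme$hi
    if (hi <= lo) stop("fixed normalization range must have hi > lo")
    out <- 255 * (values - lo) / (hi - lo)
    return(pmin(pmax(out, 0), 255))
  }
  sel <- if (is.null(mask)) values else values[mask]
  if (length(sel) == 0L) return(values * 0)
  lo <- min(sel); hi <- max(sel)
  if (hi == lo) return(values * 0)
  pmin(pmax(255 * (values - lo) / (hi - lo), 0), 255)
}

# Which property occupies which cells in each channel, per generation
# type. `off` = off-diagonal cells, `diag` = diagonal cells, `both` = the
# full matrix of a property that is intrinsically defined on all cells.
channel_plan <- function(gen_type) {
  dist_ion <- list(off = "distance", diag = "ionization")
  switch(gen_type,
    A = list(red = dist_ion,
             green = list(off = "coulomb_reduced"),
             blue = list(off = "bond_order")),
    B = list(red = dist_ion,
             green = list(both = "coulomb_full"),
             blue = list(off = "bond_order")),
    C = list(red = list(off = "distance"),
             green = list(off = "coulomb_reduced"),
             blue = list(off = "bond_order")),
    D = list(red = list(off = "distance"),
             green = list(off = "coulomb_reduced"),
             blue = list(off = "bond_order", diag = "atomic_number")),
    E = list(red = list(diag = "ionization"),
             green = list(both = "coulomb_full"),
             blue = list(diag = "atomic_number")),
    F = list(red = dist_ion,
             green = list(both = "coulomb_full"),
             blue = list(diag = "atomic_number")),
    stop("gen_type must be one of A..F"))
}

compute_descriptor <- function(mol, tag, elements, params) {
  switch(tag,
    distance = distance_matrix(mol)$values,
    coulomb_full = coulomb_matrix(mol, "full", elements)$values,
    coulomb_reduced = coulomb_matrix(mol, "reduced", elements)$values,
    bond_order = bond_order_matrix(mol, params)$values,
    ionization = diagonal_matrix(mol, "ionization", elements)$values,
    atomic_number = diagonal_matrix(mol, "atomic_number", elements)$values,
    stop("unknown descriptor tag: ", tag))
}

norm_scheme_for <- function(cfg, tag) {
  nz <- cfg$normalization
  if (identical(nz$scheme, "fixed")) {
    rg <- nz$ranges[[tag]]
    if (is.null(rg)) stop(sprintf("fixed normalization: no range for '%s'", tag))
    return(list(scheme = "fixed", lo = rg[1], hi = rg[2]))
  }
  list(scheme = "per_image")
}

#' Compose the raw N x N x 3 image for a molecule
#'
#' Fills the red/green/blue planes per the generation type: off-diagonal
#' pair descriptors (distance, reduced Coulomb, bond order), diagonal atom
#' descriptors (ionization energy, atomic number) and the full Coulomb
#' matrix, each min-max normalized over the cells it occupies before
#' placement, so every plane lies in [0, 255].
#'
#' @param mol a [molecule].
#' @param cfg an [encoding_config()].
#' @param elements element constant table.
#' @param params bond-order pair parameters.
#' @return N x N x 3 numeric array in [0, 255].
#' @export
compose_channels <- function(mol, cfg = encoding_config(),
                             elements = element_table(),
                             params = load_pair_params()) {
  n <- n_atoms(mol)
  plan <- channel_plan(cfg$gen_type)
  off_mask <- !diag(TRUE, n)
  diag_mask <- diag(TRUE, n)
  raw <- array(0, dim = c(n, n, 3L))
  for (ch in 1:3) {
    cells <- plan[[ch]]
    plane <- matrix(0, n, n)
    if (!is.null(cells$both)) {
      v <- compute_descriptor(mol, cells$both, elements, params)
      plane <- normalize_matrix(v, norm_scheme_for(cfg, cells$both))
    } else if (cfg$combined_joint && !is.null(cells$off) && !is.null(cells$diag)) {
      v <- compute_descriptor(mol, cells$off, elements, params) * off_mask +
        compute_descriptor(mol, cells$diag, elements, params)
      plane <- normalize_matrix(v, norm_scheme_for(cfg, cells$off))
    } else {
      if (!is.null(cells$off)) {
        v <- compute_descriptor(mol, cells$off, elements, params)
        nv <- normalize_matrix(v, norm_scheme_for(cfg, cells$off), mask = off_mask)
        plane[off_mask] <- nv[off_mask]
      }
      if (!is.null(cells$diag)) {
        v <- compute_descriptor(mol, cells$diag, elements, params)
        nv <- normalize_matrix(v, norm_scheme_for(cfg, cells$diag), mask = diag_mask)
        plane[diag_mask] <- nv[diag_mask]
      }
    }
    raw[, , ch] <- plane
  }
  raw
}

#' Bilinear resize of one channel plane
#'
#' Half-pixel-centered sampling: output pixel i (0-based) reads source
#' coordinate (i + 0.5) * N / S - 0.5, clamped to the source grid. With
#' S = N this is the identity map.
#'
#' @param plane N x N numeric matrix.
#' @param size target side length S.
#' @return S x S matrix.
#' @export
bilinear_resize <- function(plane, size) {
  n <- nrow(plane)
  if (size == n) return(plane)
  src <- pmin(pmax((seq_len(size) - 0.5) * n / size - 0.5, 0), n - 1)
  i0 <- floor(src)
  frac <- src - i0
  i1 <- pmin(i0 + 1, n - 1)
  a <- plane[i0 + 1, i0 + 1, drop = FALSE]
  b <- plane[i1 + 1, i0 + 1, drop = FALSE]
  cc <- plane[i0 + 1, i1 + 1, drop = FALSE]
  d <- plane[i1 + 1, i1 + 1, drop = FALSE]
  wr <- matrix(frac, size, size)        # row fraction, varies down rows
  wc <- matrix(frac, size, size, byrow = TRUE)
  a * (1 - wr) * (1 - wc) + b * wr * (1 - wc) + cc * (1 - wr) * wc + d * wr * wc
}

#' Place a raw N x N x 3 block on the S x S canvas
#'
#' `resize`: bilinear upscale of each channel to S x S. `black`: the block
#' is placed at the offset and the remainder is 0. `average`: the
#' remainder equals the per-channel mean of the raw block. Offsets:
#' `fixed` puts the block at the top-left corner; `random` draws a uniform
#' position over all (r, c) with 0 <= r, c <= S - N from the current RNG
#' stream.
#'
#' @param raw N x N x 3 array in [0, 255].
#' @param cfg an [encoding_config()].
#' @return list with `pixels` (S x S x 3) and `offset` (0-based row, col).
#' @export
place_on_canvas <- function(raw, cfg) {
  n <- dim(raw)[1]
  s <- cfg$canvas_size
  if (cfg$margin_mode == "resize") {
    px <- array(0, dim = c(s, s, 3L))
    for (ch in 1:3) px[, , ch] <- bilinear_resize(raw[, , ch], s)
    return(list(pixels = px, offset = c(0L, 0L)))
  }
  if (n > s) {
    stop(sprintf("molecule block (N = %d) exceeds canvas (S = %d) under margin_mode '%s'",
                 n, s, cfg$margin_mode))
  }
  off <- c(0L, 0L)
  if (cfg$offset_mode == "random" && s > n) {
    off <- c(sample.int(s - n + 1L, 1L) - 1L, sample.int(s - n + 1L, 1L) - 1L)
  }
  px <- array(0, dim = c(s, s, 3L))
  if (cfg$margin_mode == "average") {
    for (ch in 1:3) px[, , ch] <- mean(raw[, , ch])
  }
  px[off[1] + seq_len(n), off[2] + seq_len(n), ] <- raw
  list(pixels = px, offset = off)
}

#' Encode one molecule as an image tensor
#'
#' The full per-molecule path: compose the channel planes (normalized per
#' property), place them on the canvas, then optionally quantize round
#' half up to integral 8-bit values. Deterministic given the molecule's
#' atom order, the configuration and the RNG state (only the random-offset
#' mode consumes randomness).
#'
#' @param mol a [molecule].
#' @param cfg an [encoding_config()].
#' @param elements element constant table.
#' @param params bond-order pair parameters.
#' @param permutation_index provenance: which permutation draw this is.
#' @return object of class `image_tensor`: `pixels` (S x S x 3 in
#'   [0, 255]), `molecule_id`, `permutation_index`, `offset`,
#'   `fingerprint`.
#' @export
encode_molecule <- function(mol, cfg = encoding_config(),
                            elements = element_table(),
                            params = load_pair_params(),
                            permutation_index = 0L) {
  raw <- compose_channels(mol, cfg, elements, params)
  placed <- place_on_canvas(raw, cfg)
  px <- placed$pixels
  if (cfg$quantize) px <- round_half_up(px)
  structure(list(pixels = px, molecule_id = mol$id,
                 permutation_index = as.integer(permutation_index),
                 offset = placed$offset,
                 fingerprint = config_fingerprint(cfg)),
            class = "image_tensor")
}

#' @export
print.image_tensor <- function(x, ...) {
  cat(sprintf("<image_tensor %d x %d x 3 | mol %s | perm %d | cfg %s>\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$molecule_id,
              x$permutation_index, x$fingerprint))
  invisible(x)
}

#' Fingerprint of an encoding configuration
#'
#' Short stable hash (FNV-1a over the deparsed configuration) recorded in
#' every manifest row so runs can be matched to the exact encoding that
#' produced them.
#'
#' @param cfg an [encoding_config()] (any serializable list works).
#' @return 8-hex-digit string.
#' @export
config_fingerprint <- function(cfg) {
  s <- paste(deparse(unclass(cfg)), collapse = "")
  fnv1a32(s)
}

fnv1a32 <- function(s) {
  bytes <- utf8ToInt(s)
  h <- 2166136261
  for (b in bytes) {
    low <- h %% 256
    h <- h - low + bitwXor(as.integer(low), as.integer(b %% 256))
    # multiply by the FNV prime 16777619 = 403 + 2^24, exactly, mod 2^32
    h <- ((h * 403) %% 4294967296 + (h %% 256) * 16777216) %% 4294967296
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}
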