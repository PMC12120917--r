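#' @title Atom-order shuffling and dataset expansion
#' @name augmentation
#' @description The four atom-order permutation strategies (none, groups,
#'   partial, full) and the images-per-molecule expansion that turns one
#'   molecule into several distinct training images. Because the encoding
#'   is order-dependent but the molecule is not, reordering atoms yields
#'   new, equally valid images of the same compound — data augmentation
#'   that teaches the network permutation invariance instead of imposing
#'   it architecturally.
NULL

#' Shuffle specification
#'
#' * `none` — atom order kept exactly as in the input file (one ordering).
#' * `groups` — uniformly random permutation within each element-symbol
#'   class; the element occupying every position is unchanged.
#' * `partial` — atoms split into heavy (C, O, N, F by default) and
#'   hydrogen groups; uniform permutation within each group's position
#'   set, never across the boundary.
#' * `full` — uniformly random permutation of all positions.
#'
#' @param kind one of `"none"`, `"groups"`, `"partial"`, `"full"`.
#' @param heavy_set elements forming the heavy group for `partial`.
#' @return object of class `shuffle_spec`.
#' @export
shuffle_spec <- function(kind = c("none", "groups", "partial", "full"),
                         heavy_set = c("C", "O", "N", "F")) {
  structure(list(kind = match.arg(kind), heavy_set = heavy_set),
            class = "shuffle_spec")
}

#' Draw a permutation of atom positions
#'
#' Returns the permutation vector `p` such that atom `p[i]` of the input
#' moves to position `i`; coordinates travel with their atoms. Uses the
#' current RNG stream.
#'
#' @param mol a [molecule].
#' @param spec a [shuffle_spec()].
#' @return integer permutation of `seq_len(n_atoms(mol))`.
#' @export
draw_permutation <- function(mol, spec = shuffle_spec()) {
  n <- n_atoms(mol)
  p <- seq_len(n)
  shuffle_within <- function(p, positions) {
    if (length(positions) > 1L) p[positions] <- positions[sample.int(length(positions))]
    p
  }
  switch(spec$kind,
    none = p,
    full = sample.int(n),
    groups = {
      for (sym in unique(mol$symbols)) {
        p <- shuffle_within(p, which(mol$symbols == sym))
      }
      p
    },
    partial = {
      heavy <- which(mol$symbols %in% spec$heavy_set)
      p <- shuffle_within(p, heavy)
      shuffle_within(p, setdiff(seq_len(n), heavy))
    })
}

#' Reorder a molecule's atoms
#'
#' @param mol a [molecule].
#' @param spec a [shuffle_spec()]; ignored when `perm` is supplied.
#' @param perm optional explicit permutation vector.
#' @return a reordered copy (id and label unchanged).
#' @export
permute_atoms <- function(mol, spec = shuffle_spec(), perm = NULL) {
  if (is.null(perm)) perm <- draw_permutation(mol, spec)
  molecule(mol$symbols[perm], mol$coords[perm, , drop = FALSE],
           id = mol$id, label = mol$label)
}

#' Number of distinct atom orderings a shuffle kind can produce
#'
#' Counts permutation vectors, treating atoms of the same element as
#' distinguishable (they carry different coordinates). Returns `Inf` when
#' the count exceeds the double-precision integer range.
#'
#' @param mol a [molecule].
#' @param spec a [shuffle_spec()].
#' @return count (possibly `Inf`).
#' @export
n_distinct_orderings <- function(mol, spec = shuffle_spec()) {
  lf <- switch(spec$kind,
    none = 0,
    full = lfactorial(n_atoms(mol)),
    groups = sum(lfactorial(table(mol$symbols))),
    partial = {
      nh <- sum(mol$symbols %in% spec$heavy_set)
      lfactorial(nh) + lfactorial(n_atoms(mol) - nh)
    })
  if (lf > log(.Machine$double.xmax)) return(Inf)
  round(exp(lf))
}

#' Plan the images-per-molecule expansion
#'
#' One molecule yields `k` images, each from an independent permutation
#' draw, so `n` molecules give `n * k` training points — how a fixed
#' corpus is stretched into a larger training set.
#'
#' @param n_molecules number of molecules.
#' @param k images per molecule.
#' @param shuffle_kind used only to warn: `k > 1` with `kind = "none"`
#'   duplicates identical images (allowed as a control).
#' @return list with `n_molecules`, `images_per_molecule`, `total_points`.
#' @export
plan_augmentation <- function(n_molecules, k, shuffle_kind = "groups") {
  n_molecules <- as.numeric(n_molecules)
  k <- as.numeric(k)
  if (n_molecules < 1 || k < 1) stop("need n_molecules >= 1 and k >= 1")
  if (k > 1 && identical(shuffle_kind, "none")) {
    warning("k > 1 with shuffle kind 'none' produces duplicate images (control setting)")
  }
  list(n_molecules = n_molecules, images_per_molecule = k,
       total_points = n_molecules * k)
}

#' Draw a random 1/N subset of a molecule corpus
#'
#' Emulates carving reduced databases out of a big one: a uniformly
#' random `floor(length(mols)/N)`-sized subset, drawn from the current
#' RNG stream.
#'
#' @param mols list of molecules (or any list).
#' @param denominator N; `N = 1` returns the whole set.
#' @return subset of `mols`.
#' @export
subset_database <- function(mols, denominator = 1L) {
  n <- length(mols)
  denominator <- as.integer(denominator)
  if (denominator < 1L) stop("denominator must be >= 1")
  size <- floor(n / denominator)
  if (size < 1L) stop(sprintf("1/%d of %d molecules is an empty subset", denominator, n))
  if (denominator == 1L) return(mols)
  mols[sort(sample.int(n, size))]
}

#' Generate an augmented image dataset
#'
#' Emits `k` images per molecule, each from an independent permutation
#' draw. Draws are deduplicated while the shuffle kind admits enough
#' distinct orderings; once exhausted (small or highly symmetric
#' molecules), duplicates are allowed with a warning. Every image
#' inherits its source molecule's label unchanged.
#'
#' @param mols list of [molecule]s (labels required for training use).
#' @param out_dir directory for PNG files (created if needed).
#' @param cfg an [encoding_config()].
#' @param spec a [shuffle_spec()].
#' @param k images per molecule.
#' @param elements,params constant tables.
#' @param write_png write PNG files (TRUE) or keep pixels in memory.
#' @return list: `manifest` data.frame and, when `write_png = FALSE`,
#'   `images` (list of image tensors).
#' @export
generate_dataset <- function(mols, out_dir, cfg = encoding_config(),
                             spec = shuffle_spec(), k = 1L,
                             elements = element_table(),
                             params = load_pair_params(),
                             write_png = TRUE) {
  if (write_png && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  fp <- config_fingerprint(cfg)
  rows <- vector("list", length(mols) * k)
  images <- if (write_png) NULL else vector("list", length(mols) * k)
  r <- 0L
  warned_dup <- FALSE
  for (mol in mols) {
    avail <- n_distinct_orderings(mol, spec)
    seen <- character(0)
    for (j in seq_len(k)) {
      perm <- draw_permutation(mol, spec)
      if (length(seen) < avail) {
        tries <- 0L
        while (paste(perm, collapse = ",") %in% seen && tries < 64L) {
          perm <- draw_permutation(mol, spec)
          tries <- tries + 1L
        }
      } else if (k > 1L && avail < k && !warned_dup) {
        warning(sprintf("molecule %s admits only %s distinct orderings (< k = %d); duplicates emitted",
                        mol$id, format(avail), k))
        warned_dup <- TRUE
      }
      seen <- c(seen, paste(perm, collapse = ","))
      img <- encode_molecule(permute_atoms(mol, perm = perm), cfg,
                             elements, params, permutation_index = j)
      fname <- sprintf("%s_p%03d.png", mol$id, j)
      path <- if (is.null(out_dir)) fname else file.path(out_dir, fname)
      if (write_png) write_image(img, path)
      r <- r + 1L
      rows[[r]] <- data.frame(image_path = path, molecule_id = mol$id,
                              permutation_index = j,
                              label = if (is.null(mol$label)) NA_real_ else mol$label,
                              encoding_fingerprint = fp,
                              stringsAsFactors = FALSE)
      if (!write_png) images[[r]] <- img
    }
  }
  manifest <- do.call(rbind, rows[seq_len(r)])
  out <- list(manifest = manifest)
  if (!write_png) out$images <- images[seq_len(r)]
  out
}
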