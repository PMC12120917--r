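#' @title Reading and writing xyz files, images and dataset manifests
#' @name xyz_io
#' @description Plain and QM9-dialect xyz parsing, PNG emission and the
#'   CSV manifest that ties generated images back to their source
#'   molecules and labels.
NULL

#' Hartree to electron-volt conversion factor (CODATA).
#' @export
HARTREE_TO_EV <- 27.211386

#' Parse an xyz-format string into a molecule
#'
#' Standard xyz layout: integer atom count, a comment line, then one
#' `symbol x y z` row per atom (extra per-atom columns, as in QM9 files,
#' are ignored). Atom order is preserved exactly as in the file. For the
#' `qm9` dialect the comment line carries whitespace-separated scalar
#' properties; the HOMO-LUMO gap is taken from a configurable field and
#' converted to eV.
#'
#' @param text xyz file content as a single string or character vector of lines.
#' @param dialect `"plain"` or `"qm9"`.
#' @param id molecule id to record.
#' @param gap_field for the qm9 dialect, 1-based index of the gap value
#'   among the numeric fields of the comment line. QM9 distributions vary;
#'   the default 9 matches comment lines laid out as
#'   `tag index A B C mu alpha homo lumo gap ...` once the leading tag/index
#'   tokens are dropped (non-numeric tokens are skipped automatically).
#' @param gap_unit `"hartree"` (converted to eV) or `"ev"`.
#' @return a [molecule].
#' @export
parse_xyz <- function(text, dialect = c("plain", "qm9"), id = "mol",
                      gap_field = 9L, gap_unit = c("hartree", "ev")) {
  dialect <- match.arg(dialect)
  gap_unit <- match.arg(gap_unit)
  lines <- if (length(text) == 1L) strsplit(text, "\n", fixed = TRUE)[[1]] else text
  if (length(lines) < 1L) stop("xyz parse error: empty input")
  n <- suppressWarnings(as.integer(trimws(lines[[1]])))
  if (is.na(n)) stop("xyz parse error: first line is not an integer atom count")
  if (length(lines) < n + 2L) {
    stop(sprintf("xyz parse error: declared %d atoms but only %d atom lines present",
                 n, max(0L, length(lines) - 2L)))
  }
  atom_lines <- lines[seq.int(3L, 2L + n)]
  toks <- lapply(atom_lines, function(l) strsplit(trimws(l), "\\s+")[[1]])
  bad <- which(vapply(toks, length, 1L) < 4L)
  if (length(bad) > 0L) {
    stop(sprintf("xyz parse error: atom line %d has fewer than 4 fields", bad[1]))
  }
  symbols <- vapply(toks, `[[`, "", 1L)
  coords <- t(vapply(toks, function(tk) {
    v <- suppressWarnings(as.numeric(tk[2:4]))
    if (any(is.na(v))) stop("xyz parse error: non-numeric coordinate")
    v
  }, numeric(3)))
  label <- NULL
  if (dialect == "qm9") {
    fields <- strsplit(trimws(lines[[2]]), "\\s+")[[1]]
    nums <- suppressWarnings(as.numeric(fields))
    nums <- nums[!is.na(nums)]
    if (length(nums) < gap_field) {
      stop(sprintf("qm9 parse error: comment line has %d numeric fields, gap_field = %d",
                   length(nums), gap_field))
    }
    label <- nums[[gap_field]]
    if (gap_unit == "hartree") label <- label * HARTREE_TO_EV
  }
  molecule(symbols, coords, id = id, label = label)
}

#' Read an xyz file from disk
#' @inheritParams parse_xyz
#' @param path file path; the basename (without extension) becomes the id
#'   unless `id` is given.
#' @return a [molecule].
#' @export
read_xyz <- function(path, dialect = c("plain", "qm9"), id = NULL, ...) {
  if (is.null(id)) id <- tools::file_path_sans_ext(basename(path))
  parse_xyz(readLines(path, warn = FALSE), dialect = match.arg(dialect), id = id, ...)
}

#' Format a molecule as plain xyz text
#' @param mol a [molecule].
#' @param comment comment line content.
#' @param digits printed coordinate precision.
#' @return single string in plain xyz format.
#' @export
format_xyz <- function(mol, comment = mol$id, digits = 8) {
  rows <- sprintf(paste0("%s %.", digits, "f %.", digits, "f %.", digits, "f"),
                  mol$symbols, mol$coords[, 1], mol$coords[, 2], mol$coords[, 3])
  paste(c(as.character(n_atoms(mol)), comment, rows), collapse = "\n")
}

#' Write a molecule to a plain xyz file
#' @inheritParams format_xyz
#' @param path output path.
#' @export
write_xyz <- function(mol, path, comment = mol$id, digits = 8) {
  writeLines(format_xyz(mol, comment = comment, digits = digits), path)
  invisible(path)
}

#' Write an image tensor to a lossless 8-bit RGB PNG
#'
#' Pixels must already lie in [0, 255]; they are quantized round-half-up
#' to 8 bits. Reading the file back yields exactly the quantized values.
#'
#' @param image an `image_tensor` or plain S x S x 3 array in [0, 255].
#' @param path output PNG path.
#' @export
write_image <- function(image, path) {
  px <- if (inherits(image, "image_tensor")) image$pixels else image
  if (length(dim(px)) != 3L || dim(px)[3] != 3L) stop("image must be S x S x 3")
  if (any(px < 0 | px > 255)) stop("pixel out of [0, 255]: contract violation")
  png::writePNG(round_half_up(px) / 255, target = path)
  invisible(path)
}

#' Read a PNG back as a 0-255 array
#' @param path PNG path.
#' @return S x S x 3 numeric array of integral values in [0, 255].
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(a, dim = c(dim(a), 1L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]  # drop alpha
  a * 255
}

round_half_up <- function(x) floor(x + 0.5)

manifest_columns <- c("image_path", "molecule_id", "permutation_index",
                      "label", "encoding_fingerprint")

#' Write a dataset manifest CSV
#'
#' One row per emitted image: path, source molecule id, index of the
#' permutation draw, inherited label and the fingerprint of the encoding
#' configuration that produced it. Image paths must be unique.
#'
#' @param rows data.frame with the manifest columns.
#' @param path output CSV path.
#' @export
write_manifest <- function(rows, path) {
  rows <- as.data.frame(rows)
  if (nrow(rows) == 0L) {
    rows <- as.data.frame(setNames(rep(list(character(0)), length(manifest_columns)),
                                   manifest_columns))
  }
  missing <- setdiff(manifest_columns, names(rows))
  if (length(missing) > 0L) stop(sprintf("manifest missing column(s): %s",
                                         paste(missing, collapse = ", ")))
  if (anyDuplicated(rows$image_path)) stop("duplicate image_path in manifest")
  utils::write.csv(rows[, manifest_columns, drop = FALSE], path, row.names = FALSE)
  invisible(path)
}

#' Read a dataset manifest CSV
#' @param path manifest path.
#' @return data.frame with the manifest columns.
#' @export
read_manifest <- function(path) {
  rows <- utils::read.csv(path, stringsAsFactors = FALSE,
                          colClasses = c(image_path = "character",
                                         molecule_id = "character",
                                         encoding_fingerprint = "character"))
  if (anyDuplicated(rows$image_path)) stop("duplicate image_path in manifest")
  rows
}

#' Read a label table keyed by molecule id
#'
#' Lets plain xyz corpora carry their targets in a separate CSV
#' (`molecule_id,label`), the first-class alternative to the QM9 comment
#' line.
#'
#' @param path CSV path with columns `molecule_id` and `label`.
#' @return named numeric vector of labels.
#' @export
read_labels_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = c(molecule_id = "character"))
  stopifnot(all(c("molecule_id", "label") %in% names(tab)))
  stats::setNames(as.numeric(tab$label), tab$molecule_id)
}
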