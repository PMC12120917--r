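#' Construct a molecule record
#'
#' The unit every other function consumes: an ordered set of atoms
#' (element symbols plus Cartesian coordinates in Angstrom) with an
#' optional scalar label such as the HOMO-LUMO gap in eV. Atom order is
#' significant throughout: the image encoding is order-dependent and the
#' shuffling strategies act on exactly this order.
#'
#' @param symbols character vector of element symbols (length N >= 1).
#' @param coords numeric N x 3 matrix of Cartesian coordinates (Angstrom).
#' @param id molecule identifier string.
#' @param label optional finite scalar target (e.g. HOMO-LUMO gap, eV).
#' @return An object of class `molecule`.
#' @export
molecule <- function(symbols, coords, id = "mol", label = NULL) {
  symbols <- as.character(symbols)
  coords <- matrix(as.numeric(coords), ncol = 3)
  n <- length(symbols)
  if (n < 1L) stop("a molecule needs at least one atom")
  if (nrow(coords) != n) {
    stop(sprintf("coords has %d rows but there are %d symbols", nrow(coords), n))
  }
  unknown <- setdiff(unique(symbols), supported_elements())
  if (length(unknown) > 0L) {
    stop(sprintf("unsupported element symbol(s): %s", paste(unknown, collapse = ", ")))
  }
  if (!all(is.finite(coords))) stop("coordinates must be finite")
  if (!is.null(label)) {
    label <- as.numeric(label)
    if (length(label) != 1L || !is.finite(label)) stop("label must be a finite scalar")
  }
  structure(
    list(id = as.character(id), symbols = symbols, coords = unname(coords),
         label = label),
    class = "molecule"
  )
}

#' @export
print.molecule <- function(x, ...) {
  comp <- table(x$symbols)
  formula <- paste0(names(comp), ifelse(comp > 1L, comp, ""), collapse = "")
  cat(sprintf("<molecule %s: %s, %d atoms%s>\n", x$id, formula,
              length(x$symbols),
              if (is.null(x$label)) "" else sprintf(", label = %.4f", x$label)))
  invisible(x)
}

n_atoms <- function(mol) length(mol$symbols)

#' Number of heavy (non-hydrogen) atoms
#' @param mol a `molecule`.
#' @return integer count of atoms that are not hydrogen.
#' @export
n_heavy_atoms <- function(mol) sum(mol$symbols != "H")
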