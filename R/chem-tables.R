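#' @title Element constants and bond-order pair parameters
#' @description Per-element constants (atomic number, first ionization
#'   energy) and per-pair ReaxFF-style bond-order parameters, including the
#'   suppression rule that disables fluorine interactions other than C-F.
#' @name chem_tables
NULL

.rgbchem_env <- new.env(parent = emptyenv())

element_table_path <- function() {
  system.file("extdata", "elements.csv", package = "rgbchem", mustWork = TRUE)
}

#' Load the shipped element constant table
#'
#' @param path CSV path; defaults to the versioned table shipped with the
#'   package (Z and first ionization energy in eV for H, C, N, O, F).
#' @return data.frame with columns `symbol`, `Z`, `ionization_energy`.
#' @export
element_table <- function(path = element_table_path()) {
  key <- paste0("elements:", path)
  if (!is.null(.rgbchem_env[[key]])) return(.rgbchem_env[[key]])
  tab <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("symbol", "Z", "ionization_energy") %in% names(tab)))
  if (any(tab$Z < 1 | tab$Z != round(tab$Z))) stop("Z must be a positive integer")
  if (any(tab$ionization_energy <= 0)) stop("ionization energies must be positive")
  .rgbchem_env[[key]] <- tab
  tab
}

supported_elements <- function() element_table()$symbol

#' Look up constants for one element
#'
#' @param symbol element symbol, e.g. `"C"`.
#' @param table element table (defaults to the shipped one).
#' @return list with `symbol`, `Z`, `ionization_energy` (eV).
#' @export
lookup_element <- function(symbol, table = element_table()) {
  i <- match(symbol, table$symbol)
  if (is.na(i)) stop(sprintf("unsupported element symbol: %s", symbol))
  as.list(table[i, , drop = FALSE])
}

pair_key <- function(a, b) paste(sort(c(a, b)), collapse = "-")

default_pair_params_path <- function() {
  system.file("extdata", "pair_params_synthetic.txt", package = "rgbchem",
              mustWork = TRUE)
}

#' Load bond-order pair parameters
#'
#' Parses the plain-text block format (`pair: C H` followed by `key=value`
#' lines) into a symmetric lookup table. Following the fluorine rule, the
#' radii of the O-F, F-N and F-H pairs are replaced by the -1 sentinel
#' regardless of file content, so those pairs contribute zero bond order;
#' fluorine interactions other than those with carbon essentially never
#' occur in QM9-like CHONF molecules. F-F is sentineled as well by
#' default, consistent with ignoring all non-carbon fluorine interactions.
#'
#' @param path parameter file; defaults to the synthetic representative set
#'   shipped with the package.
#' @param fluorine_override apply the O-F / F-N / F-H sentinel substitution.
#' @param sentinel_ff also sentinel the F-F pair (default TRUE).
#' @return object of class `pair_param_table`.
#' @export
load_pair_params <- function(path = default_pair_params_path(),
                             fluorine_override = TRUE,
                             sentinel_ff = TRUE) {
  lines <- readLines(path, warn = FALSE)
  table <- list()
  cur <- NULL
  cur_key <- NULL
  flush <- function() {
    if (!is.null(cur)) table[[cur_key]] <<- finalize_pair(cur, cur_key)
  }
  for (ln in seq_along(lines)) {
    line <- trimws(sub("#.*$", "", lines[[ln]]))
    if (line == "") next
    if (startsWith(line, "pair:")) {
      flush()
      els <- strsplit(trimws(sub("^pair:", "", line)), "\\s+")[[1]]
      if (length(els) != 2L) stop(sprintf("line %d: pair header needs two symbols", ln))
      cur_key <- pair_key(els[1], els[2])
      cur <- list(elements = sort(els))
    } else if (grepl("=", line, fixed = TRUE)) {
      if (is.null(cur)) stop(sprintf("line %d: key=value outside a pair block", ln))
      kv <- strsplit(line, "=", fixed = TRUE)[[1]]
      val <- suppressWarnings(as.numeric(trimws(kv[2])))
      if (is.na(val)) stop(sprintf("line %d: malformed numeric field '%s'", ln, trimws(kv[2])))
      cur[[trimws(kv[1])]] <- val
    } else {
      stop(sprintf("line %d: unrecognized content '%s'", ln, line))
    }
  }
  flush()
  out <- structure(list(pairs = table), class = "pair_param_table")
  if (fluorine_override) out <- apply_fluorine_override(out, sentinel_ff = sentinel_ff)
  out
}

finalize_pair <- function(p, key) {
  defaults <- list(r0_sigma = -1, r0_pi = -1, r0_pipi = -1,
                   pbo1 = 0, pbo2 = 1, pbo3 = 0, pbo4 = 1, pbo5 = 0, pbo6 = 1)
  for (nm in names(defaults)) if (is.null(p[[nm]])) p[[nm]] <- defaults[[nm]]
  for (r in c("r0_sigma", "r0_pi", "r0_pipi")) {
    if (p[[r]] <= 0 && p[[r]] != -1) {
      # treat any non-positive radius as the disable sentinel
      p[[r]] <- -1
    }
  }
  p
}

#' Apply the fluorine suppression rule
#'
#' Sets all three reference radii of O-F, F-N and F-H (and optionally F-F)
#' to the -1 sentinel, making their bond order exactly zero. Idempotent.
#'
#' @param table a `pair_param_table`.
#' @param sentinel_ff also sentinel F-F.
#' @return the modified table.
#' @export
apply_fluorine_override <- function(table, sentinel_ff = TRUE) {
  targets <- c(pair_key("O", "F"), pair_key("F", "N"), pair_key("F", "H"))
  if (sentinel_ff) targets <- c(targets, pair_key("F", "F"))
  for (key in targets) {
    if (!is.null(table$pairs[[key]])) {
      table$pairs[[key]]$r0_sigma <- -1
      table$pairs[[key]]$r0_pi <- -1
      table$pairs[[key]]$r0_pipi <- -1
    }
  }
  table
}

#' Look up bond-order parameters for an element pair
#'
#' Lookup is symmetric: `lookup_pair(t, "C", "H")` equals
#' `lookup_pair(t, "H", "C")`. A missing pair returns `NULL`; downstream
#' the bond order then degrades to zero with a warning.
#'
#' @param table a `pair_param_table`.
#' @param a,b element symbols.
#' @return parameter list or `NULL`.
#' @export
lookup_pair <- function(table, a, b) {
  table$pairs[[pair_key(a, b)]]
}

#' @export
print.pair_param_table <- function(x, ...) {
  cat(sprintf("<pair_param_table: %d pairs (%s)>\n", length(x$pairs),
              paste(names(x$pairs), collapse = ", ")))
  invisible(x)
}
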