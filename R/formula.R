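#' Elemental formulas and electron equivalents
#'
#' Organic substrates and biomass are described by their C/H/O/N composition.
#' Fractional subscripts are allowed, e.g. the bulk marine organic-matter pool
#' `"C6.6H10.9O2.6N"`. The electron equivalents of a formula are the electrons
#' released on complete oxidation of its carbon to CO2, with organic nitrogen
#' released at the ammonium oxidation level:
#' \deqn{e^- = 4\,C + H - 2\,O - 3\,N}
#'
#' @param c,h,o,n Moles of each element per mole of compound (non-negative
#'   reals).
#' @return An `elemental_formula`: a named numeric vector with elements
#'   `c`, `h`, `o`, `n`.
#' @examples
#' elemental_formula(5, 7, 2, 1)              # standard biomass, 20 e-
#' parse_chemical_formula("C6.6H10.9O2.6N")   # marine organic matter, 29.1 e-
#' @export
elemental_formula <- function(c, h, o, n) {
  x <- base::c(c = c, h = h, o = o, n = n)
  if (any(is.na(x)) || any(x < 0)) {
    stop("element counts must be non-negative numbers", call. = FALSE)
  }
  if (all(x == 0)) stop("at least one element count must be positive", call. = FALSE)
  structure(x, class = "elemental_formula")
}

#' Parse a chemical formula string
#'
#' Accepts strings of the form `"C6.6H10.9O2.6N"`: an element letter (C, H, O
#' or N) followed by an optional decimal count; a missing count means 1.
#'
#' @param x A single character string.
#' @return An [elemental_formula()].
#' @export
parse_chemical_formula <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  m <- gregexpr("([CHON])([0-9]*\\.?[0-9]*)", x, perl = TRUE)[[1]]
  parts <- regmatches(x, list(m))[[1]]
  if (length(parts) == 0L || sum(attr(m, "match.length")) != nchar(x)) {
    stop("cannot parse formula '", x, "': only C, H, O, N with numeric counts are supported",
         call. = FALSE)
  }
  counts <- base::c(c = 0, h = 0, o = 0, n = 0)
  for (p in parts) {
    el <- tolower(substr(p, 1, 1))
    num <- substr(p, 2, nchar(p))
    counts[[el]] <- counts[[el]] + if (nzchar(num)) as.numeric(num) else 1
  }
  elemental_formula(counts[["c"]], counts[["h"]], counts[["o"]], counts[["n"]])
}

as_elemental_formula <- function(x) {
  if (inherits(x, "elemental_formula")) return(x)
  if (is.character(x)) return(parse_chemical_formula(x))
  if (is.numeric(x) && length(x) == 4L && !is.null(names(x))) {
    return(elemental_formula(x[["c"]], x[["h"]], x[["o"]], x[["n"]]))
  }
  stop("cannot interpret input as an elemental formula", call. = FALSE)
}

#' @export
print.elemental_formula <- function(x, ...) {
  cat("<elemental_formula> C", x[["c"]], " H", x[["h"]], " O", x[["o"]],
      " N", x[["n"]], " (", format(electron_equivalents(x)),
      " e- equivalents)\n", sep = "")
  invisible(x)
}

#' Electron equivalents of a formula
#'
#' @param formula An [elemental_formula()] or a formula string.
#' @return Electron equivalents per mole (numeric scalar). An error is raised
#'   if the result is not positive, since such a compound cannot serve as an
#'   electron donor or as biomass.
#' @examples
#' electron_equivalents("C5H7O2N")  # 20
#' electron_equivalents("CH2O")     # 4
#' @export
electron_equivalents <- function(formula) {
  f <- as_elemental_formula(formula)
  eeq <- 4 * f[["c"]] + f[["h"]] - 2 * f[["o"]] - 3 * f[["n"]]
  if (eeq <= 0) {
    stop("formula has non-positive electron equivalents (", eeq,
         "); unusable as electron donor or biomass", call. = FALSE)
  }
  unname(eeq)
}

# Package-wide default compositions.
marine_om_formula <- function() parse_chemical_formula("C6.6H10.9O2.6N")
biomass_formula <- function() parse_chemical_formula("C5H7O2N")
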