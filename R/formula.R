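#' Parse molecular formulas into element counts
#'
#' Converts Hill-style molecular formulas (e.g. `"C8H9NO2"`) into a matrix of
#' element counts over the fixed element alphabet (see [element_alphabet()]).
#' Elements outside the alphabet are an error: the downstream model encodes
#' formulas as fixed-length count vectors and cannot represent them.
#'
#' @param formula Character vector of molecular formulas.
#'
#' @return Integer matrix with one row per formula and one column per element
#'   of the alphabet.
#' @export
#'
#' @examples
#' parse_formula(c("C6H6", "C2H5Cl"))
parse_formula <- function(formula) {
  stopifnot(is.character(formula))
  out <- matrix(0L, nrow = length(formula), ncol = length(ELEMENT_ALPHABET),
                dimnames = list(formula, ELEMENT_ALPHABET))
  for (i in seq_along(formula)) {
    f <- formula[[i]]
    if (is.na(f) || !nzchar(f)) {
      stop("empty or NA molecular formula at position ", i)
    }
    m <- gregexpr("([A-Z][a-z]?)([0-9]*)", f)[[1]]
    toks <- regmatches(f, gregexpr("([A-Z][a-z]?)([0-9]*)", f))[[1]]
    if (sum(attr(m, "match.length")) != nchar(f)) {
      stop("cannot parse molecular formula: '", f, "'")
    }
    for (tok in toks) {
      el <- sub("[0-9]*$", "", tok)
      n <- sub("^[A-Za-z]+", "", tok)
      n <- if (nzchar(n)) as.integer(n) else 1L
      if (!el %in% ELEMENT_ALPHABET) {
        stop("element '", el, "' in formula '", f,
             "' is outside the supported alphabet (",
             paste(ELEMENT_ALPHABET, collapse = ", "), ")")
      }
      out[i, el] <- out[i, el] + n
    }
  }
  out
}

#' Monoisotopic mass of a molecular formula
#'
#' @param formula Character vector of molecular formulas over the element
#'   alphabet.
#'
#' @return Numeric vector of monoisotopic masses in Da.
#' @export
#'
#' @examples
#' formula_mass("C6H6") # benzene, 78.04695
formula_mass <- function(formula) {
  counts <- parse_formula(formula)
  as.numeric(counts %*% ELEMENT_MASSES[colnames(counts)])
}

# Build a formula string from a named integer vector of element counts,
# in alphabet order, omitting zero counts and the "1" suffix.
format_formula <- function(counts) {
  stopifnot(all(names(counts) %in% ELEMENT_ALPHABET))
  counts <- counts[ELEMENT_ALPHABET[ELEMENT_ALPHABET %in% names(counts)]]
  counts <- counts[counts > 0]
  paste0(names(counts), ifelse(counts > 1, counts, ""), collapse = "")
}
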