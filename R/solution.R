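#' Single-strand molecular weight convention
#'
#' Average molecular weight of a single DNA strand of length `L`,
#' `MW(L) = 303.7 L + 79` g/mol (average base composition, 5'-OH), used to
#' convert between mass (g/l) and molar (mol/L) strand concentrations.
#'
#' @param L oligomer length.
#' @return molecular weight in g/mol.
#' @export
mw_ssdna <- function(L) 303.7 * L + 79

#' Pool specification
#'
#' Defines a random-sequence pool: oligomer length, strand concentration
#' (mass or molar, the other derived through [mw_ssdna()] or a custom
#' convention), sodium concentration and alphabet.
#'
#' @param L oligomer length (>= 2).
#' @param c_mass total strand concentration in g/l.
#' @param c_molar total strand concentration in mol/L (give one of the two).
#' @param na_molar sodium concentration in mol/L.
#' @param alphabet an [rs_alphabet()].
#' @param mw molecular-weight convention, a function of `L`.
#' @return object of class `solution_spec`.
#' @examples
#' solution_spec(L = 12, c_mass = 0.04, na_molar = 1)
#' @export
solution_spec <- function(L, c_mass = NULL, c_molar = NULL, na_molar = 1.0,
                          alphabet = dna_alphabet(), mw = mw_ssdna) {
  if (L < 2) stop("L must be at least 2", call. = FALSE)
  if (is.null(c_mass) == is.null(c_molar))
    stop("give exactly one of c_mass (g/l) or c_molar (mol/L)",
         call. = FALSE)
  if (is.null(c_molar)) c_molar <- c_mass / mw(L)
  if (is.null(c_mass)) c_mass <- c_molar * mw(L)
  if (c_molar <= 0) stop("concentration must be positive", call. = FALSE)
  if (na_molar <= 0) stop("sodium concentration must be positive",
                          call. = FALSE)
  structure(list(L = as.integer(L), c_mass = c_mass, c_molar = c_molar,
                 na_molar = na_molar, alphabet = alphabet, mw = mw),
            class = "solution_spec")
}

#' @export
print.solution_spec <- function(x, ...) {
  cat(sprintf("<solution_spec> %dN pool (%s alphabet, %s species)\n",
              x$L, x$alphabet$label,
              format(x$alphabet$n_b^x$L, big.mark = ",")))
  cat(sprintf("  c = %.4g g/l = %.4g mol/L strands; Na+ = %.3g M\n",
              x$c_mass, x$c_molar, x$na_molar))
  invisible(x)
}

#' Binomial composition distribution of a random pool
#'
#' Probability `p_L(f_CG) = choose(L, f_CG * L) / 2^L` of a random sequence
#' having each of the `L + 1` possible strong-base fractions; weights sum
#' to 1 exactly.
#'
#' @param L oligomer length.
#' @return data frame with columns `f_CG` and `p`.
#' @export
composition_weights <- function(L) {
  k <- 0:L
  data.frame(f_CG = k / L, p = choose(L, k) / 2^L)
}
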