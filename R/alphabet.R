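#' Complementary-pairing alphabets
#'
#' An alphabet is the base set over which sequences are written, together
#' with an involutive complement map (every base has exactly one partner)
#' and the set of "strong" bases whose fraction `f_CG` controls the averaged
#' stack energetics. The number of bases `n_b` must be even so that
#' complementary pairing is total; `n_b` enters the pool size (`n_b^L`) and
#' the degeneracy counting of defected duplexes.
#'
#' @param bases character vector of single-character base symbols.
#' @param complement named character vector mapping each base to its
#'   complement; must be an involution with no self-complementary base.
#' @param strong subset of `bases` counted as strong (C/G-class).
#' @param label short human-readable tag.
#' @return an object of class `rs_alphabet` with fields `bases`,
#'   `complement`, `strong`, `n_b`, `label`.
#' @seealso [dna_alphabet()], [two_letter_alphabet()], [expanded_alphabet()]
#' @export
rs_alphabet <- function(bases, complement, strong = character(0),
                        label = "custom") {
  bases <- as.character(bases)
  n_b <- length(bases)
  if (n_b < 2L || n_b %% 2L != 0L)
    stop("alphabet must have an even number (>= 2) of bases", call. = FALSE)
  if (anyDuplicated(bases))
    stop("duplicated base symbols", call. = FALSE)
  if (any(nchar(bases) != 1L))
    stop("bases must be single characters", call. = FALSE)
  if (!setequal(names(complement), bases) ||
      !setequal(unname(complement), bases))
    stop("complement map must cover every base exactly once", call. = FALSE)
  complement <- complement[bases]
  if (any(unname(complement[unname(complement)]) != bases))
    stop("complement map must be an involution", call. = FALSE)
  if (any(unname(complement) == bases))
    stop("self-complementary bases are not supported", call. = FALSE)
  if (!all(strong %in% bases))
    stop("strong bases must belong to the alphabet", call. = FALSE)
  structure(list(bases = bases, complement = complement, strong = strong,
                 n_b = n_b, label = label),
            class = "rs_alphabet")
}

#' @describeIn rs_alphabet the natural 4-letter DNA alphabet with
#'   Watson-Crick pairing A-T, C-G; strong bases are C and G.
#' @export
dna_alphabet <- function() {
  rs_alphabet(c("A", "C", "G", "T"),
              c(A = "T", C = "G", G = "C", T = "A"),
              strong = c("C", "G"), label = "DNA")
}

#' @describeIn rs_alphabet a counterfactual two-letter alphabet made of a
#'   single complementary pair P-Q (used with stack energetics intermediate
#'   between the AT and CG averages).
#' @export
two_letter_alphabet <- function() {
  rs_alphabet(c("P", "Q"), c(P = "Q", Q = "P"), label = "two-letter")
}

#' @describeIn rs_alphabet a counterfactual alphabet with `n_b` bases
#'   (even), paired consecutively (B1-B2, B3-B4, ...). For `n_b = 4` this
#'   returns the DNA alphabet.
#' @param n_b even number of bases.
#' @export
expanded_alphabet <- function(n_b) {
  if (n_b == 4L) return(dna_alphabet())
  if (n_b == 2L) return(two_letter_alphabet())
  if (n_b %% 2L != 0L || n_b < 2L)
    stop("n_b must be even and >= 2", call. = FALSE)
  if (n_b > 26L)
    stop("at most 26 bases supported", call. = FALSE)
  bases <- LETTERS[seq_len(n_b)]
  comp <- bases[as.vector(rbind(seq(2, n_b, 2), seq(1, n_b, 2)))]
  names(comp) <- bases
  rs_alphabet(bases, comp, label = sprintf("%d-letter", n_b))
}

#' @export
print.rs_alphabet <- function(x, ...) {
  cat(sprintf("<%s alphabet> %d bases: %s\n", x$label, x$n_b,
              paste(x$bases, collapse = " ")))
  cat("  complement:",
      paste(sprintf("%s-%s", x$bases, x$complement), collapse = " "), "\n")
  if (length(x$strong))
    cat("  strong:", paste(x$strong, collapse = " "), "\n")
  invisible(x)
}
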