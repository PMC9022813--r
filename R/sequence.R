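#' Sequence utilities
#'
#' Sequences are plain upper-case character strings over an alphabet's
#' bases, written 5' to 3'.
#'
#' @name sequences
NULL

.seq_chars <- function(seq) strsplit(toupper(seq), NULL)[[1L]]

.check_sequence <- function(seq, alphabet) {
  ch <- .seq_chars(seq)
  bad <- setdiff(unique(ch), alphabet$bases)
  if (length(bad))
    stop(sprintf("unknown symbol(s) %s for the %s alphabet",
                 paste(bad, collapse = ", "), alphabet$label),
         call. = FALSE)
  ch
}

#' Reverse complement of a sequence
#'
#' Returns the Watson-Crick reverse complement (the exact pairing partner)
#' of a 5'->3' sequence. Applying the operation twice returns the input.
#'
#' @param seq character string over the alphabet's bases.
#' @param alphabet an [rs_alphabet()]; defaults to DNA.
#' @return the reverse-complement sequence as a character string.
#' @examples
#' complement_sequence("ACAGTCCT")  # "AGGACTGT"
#' @export
complement_sequence <- function(seq, alphabet = dna_alphabet()) {
  ch <- .check_sequence(seq, alphabet)
  paste(rev(unname(alphabet$complement[ch])), collapse = "")
}

#' @rdname complement_sequence
#' @export
reverse_complement <- complement_sequence

#' Fraction of strong bases in a sequence
#'
#' The fraction `f_CG` of C/G-class (strong) bases, which parametrizes the
#' composition-averaged stack energetics.
#'
#' @inheritParams complement_sequence
#' @return numeric in `[0, 1]`.
#' @export
fraction_strong <- function(seq, alphabet = dna_alphabet()) {
  ch <- .check_sequence(seq, alphabet)
  if (!length(alphabet$strong)) return(0.5)
  mean(ch %in% alphabet$strong)
}

#' Random sequences from a pool
#'
#' Draws sequences with independent uniform bases, optionally constrained
#' to an exact strong-base fraction (`f_CG * L` must then be an integer).
#' Uses the current RNG state; set a seed for reproducibility.
#'
#' @param n number of sequences.
#' @param L sequence length (nucleotides).
#' @param f_CG optional exact strong-base fraction.
#' @param alphabet an [rs_alphabet()].
#' @return character vector of length `n`.
#' @export
random_sequences <- function(n, L, f_CG = NULL, alphabet = dna_alphabet()) {
  if (is.null(f_CG)) {
    return(vapply(seq_len(n), function(i)
      paste(sample(alphabet$bases, L, replace = TRUE), collapse = ""),
      character(1)))
  }
  k <- f_CG * L
  if (abs(k - round(k)) > 1e-9)
    stop("f_CG * L must be an integer", call. = FALSE)
  k <- as.integer(round(k))
  strong <- alphabet$strong
  weak <- setdiff(alphabet$bases, strong)
  if (!length(strong))
    stop("alphabet has no strong bases; cannot fix f_CG", call. = FALSE)
  vapply(seq_len(n), function(i) {
    ch <- character(L)
    pos <- sample.int(L, k)
    ch[pos] <- sample(strong, k, replace = TRUE)
    rest <- setdiff(seq_len(L), pos)
    if (length(rest)) ch[rest] <- sample(weak, length(rest), replace = TRUE)
    paste(ch, collapse = "")
  }, character(1))
}

#' Longest complementary run between two sequences
#'
#' Maximum number of consecutive Watson-Crick complementary positions
#' between `seqA` and `seqB`, maximized over all `2L - 1` mutual antiparallel
#' alignments. For two random 12-mers this is most often 3, the typical
#' outcome of a random collision in a random-sequence pool.
#'
#' @param seqA,seqB sequences of equal length.
#' @param alphabet an [rs_alphabet()].
#' @return integer, the longest run (0 if no position ever pairs).
#' @seealso [complementary_run_distribution()] for the sampling
#'   distribution over random pairs.
#' @export
max_complementary_run <- function(seqA, seqB, alphabet = dna_alphabet()) {
  a <- .check_sequence(seqA, alphabet)
  b <- .check_sequence(seqB, alphabet)
  if (length(a) != length(b)) stop("sequences must have equal length")
  bc <- rev(unname(alphabet$complement[b]))  # chars of reverse complement
  L <- length(a)
  best <- 0L
  for (s in -(L - 1L):(L - 1L)) {
    k <- max(1L, 1L + s):min(L, L + s)
    m <- a[k] == bc[k - s]
    run <- 0L
    for (mm in m) {
      run <- if (mm) run + 1L else 0L
      if (run > best) best <- run
    }
  }
  best
}

#' Sampling distribution of the longest complementary run
#'
#' Draws `n` independent pairs of uniform random length-`L` sequences and
#' tabulates the longest consecutive complementary run of each pair,
#' maximized over all mutual alignments (see [max_complementary_run()]);
#' computed with vectorised run bookkeeping across pairs. Uses the current
#' RNG state.
#'
#' @param n number of sampled pairs.
#' @param L sequence length.
#' @param alphabet an [rs_alphabet()].
#' @return integer vector of length `n` with the per-pair longest runs.
#' @export
complementary_run_distribution <- function(n, L, alphabet = dna_alphabet()) {
  n_b <- alphabet$n_b
  A <- matrix(sample.int(n_b, n * L, replace = TRUE), nrow = n)
  B <- matrix(sample.int(n_b, n * L, replace = TRUE), nrow = n)
  comp_int <- match(unname(alphabet$complement[alphabet$bases]),
                    alphabet$bases)
  BC <- matrix(comp_int[B[, L:1, drop = FALSE]], nrow = n)
  best <- integer(n)
  for (s in -(L - 1L):(L - 1L)) {
    k <- max(1L, 1L + s):min(L, L + s)
    run <- integer(n)
    for (j in seq_along(k)) {
      hit <- A[, k[j]] == BC[, k[j] - s]
      run <- ifelse(hit, run + 1L, 0L)
      best <- pmax(best, run)
    }
  }
  best
}
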