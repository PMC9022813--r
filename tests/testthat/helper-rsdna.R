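# Independent literal copy of the unified NN set (the ten unique duplex
# stacks, initiation split by terminal pair), used to hand-check the shipped
# parameter file without reading it.
unified_literal <- function() {
  dH <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
          CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  dS <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
          CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  # extend to all 16 ordered dimers via reverse-complement symmetry
  rc <- function(d) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    paste0(comp[substr(d, 2, 2)], comp[substr(d, 1, 1)])
  }
  for (d in names(dH)) {
    if (!(rc(d) %in% names(dH))) {
      dH[rc(d)] <- dH[[d]]
      dS[rc(d)] <- dS[[d]]
    }
  }
  list(dH = dH, dS = dS,
       init_dH = c(strong = 0.1, weak = 2.3),
       init_dS = c(strong = -2.8, weak = 4.1))
}

# hand NN summation for a complementary duplex at 1 M (no salt term)
hand_nn_sum <- function(seq) {
  u <- unified_literal()
  ch <- strsplit(seq, NULL)[[1]]
  dimers <- paste0(ch[-length(ch)], ch[-1])
  ends <- ifelse(ch[c(1, length(ch))] %in% c("C", "G"), "strong", "weak")
  c(dH = sum(u$dH[dimers]) + sum(u$init_dH[ends]),
    dS = sum(u$dS[dimers]) + sum(u$init_dS[ends]))
}

# all n_b^L sequences over an alphabet, as character strings
all_seqs <- function(L, alphabet = dna_alphabet()) {
  g <- do.call(expand.grid, rep(list(alphabet$bases), L))
  apply(as.matrix(g[, L:1, drop = FALSE]), 1, paste, collapse = "")
}

# brute-force census: classify every (partner, shift) against a reference
# and tally counts per defect vector
census_defects <- function(ref, alphabet = dna_alphabet()) {
  L <- nchar(ref)
  partners <- all_seqs(L, alphabet)
  out <- list()
  for (p in partners) {
    for (s in -(L - 1):(L - 1)) {
      a <- classify_duplex(ref, p, s, alphabet)
      if (!is.null(a)) {
        key <- paste(a, collapse = ",")
        out[[key]] <- (out[[key]] %||% 0L) + 1L
      }
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# draw n random sequences, dropping palindromic (self-complementary) ones
random_nonpalindromic <- function(n, L, f_CG = NULL) {
  out <- character(0)
  while (length(out) < n) {
    s <- random_sequences(2 * n, L, f_CG)
    s <- s[vapply(s, function(x) x != complement_sequence(x), logical(1))]
    out <- c(out, s)
  }
  out[seq_len(n)]
}
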