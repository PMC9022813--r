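#' Enumerate valid defect vectors
#'
#' A duplex between two length-`L` strands is classified by the defect
#' vector `alpha = (alpha_s, alpha_e1, alpha_e2, alpha_i)`: the alignment
#' shift, the counts of consecutive mismatched positions at the two duplex
#' ends, and the count of internal mismatches. A vector is valid when the
#' aligned overlap keeps at least two paired bases (one intact stack
#' boundary): `L - |alpha_s| - alpha_e1 - alpha_e2 - alpha_i >= 2`.
#' Enumeration is exhaustive and lexicographic in
#' `(alpha_s, alpha_e1, alpha_e2, alpha_i)`.
#'
#' @param L oligomer length (>= 2).
#' @return data frame with integer columns `alpha_s`, `alpha_e1`,
#'   `alpha_e2`, `alpha_i`.
#' @export
enumerate_defects <- function(L) {
  if (L < 2) stop("L must be at least 2", call. = FALSE)
  L <- as.integer(L)
  key <- paste0("defs", L)
  if (!is.null(.rs_cache[[key]])) return(.rs_cache[[key]])
  per_shift <- function(s) {
    n <- L - abs(s)
    if (n < 2L) return(NULL)
    m <- n - 2L
    g <- expand.grid(alpha_i = 0:m, alpha_e2 = 0:m, alpha_e1 = 0:m,
                     KEEP.OUT.ATTRS = FALSE)
    g <- g[g$alpha_e1 + g$alpha_e2 + g$alpha_i <= m, , drop = FALSE]
    g <- g[order(g$alpha_e1, g$alpha_e2, g$alpha_i), , drop = FALSE]
    data.frame(alpha_s = s, alpha_e1 = g$alpha_e1, alpha_e2 = g$alpha_e2,
               alpha_i = g$alpha_i)
  }
  out <- do.call(rbind, lapply(-(L - 1L):(L - 1L), per_shift))
  rownames(out) <- NULL
  .rs_cache[[key]] <- out
  out
}

.validate_defects <- function(L, alpha) {
  with(alpha, {
    bad <- abs(alpha_s) > L - 1 | alpha_e1 < 0 | alpha_e2 < 0 | alpha_i < 0 |
      L - 2 - abs(alpha_s) - alpha_e1 - alpha_e2 < alpha_i
    if (any(bad))
      stop(sprintf("invalid defect vector(s) for L = %d (e.g. row %d)",
                   L, which(bad)[1]), call. = FALSE)
  })
  invisible(TRUE)
}

#' Degeneracy of a defect class
#'
#' Number of partner sequences that form, with a fixed reference sequence
#' at a fixed alignment, a duplex of class `alpha`:
#' `g = n_b^|alpha_s| * (n_b - 1)^(alpha_e1 + alpha_e2 + alpha_i) *
#' choose(L - 2 - |alpha_s| - alpha_e1 - alpha_e2, alpha_i)`.
#' Overhang positions are unconstrained (`n_b` choices), every mismatched
#' position excludes the one complementary base (`n_b - 1` choices), and
#' the binomial places the internal mismatches among the interior positions
#' (the two paired positions bounding the mismatch-free terminal runs are
#' excluded). `g` does not depend on the reference sequence, and is
#' independent of `L` whenever `alpha_i = 0`.
#'
#' @param L oligomer length.
#' @param alpha a length-4 defect vector or a data frame of them.
#' @param n_b alphabet size (4 for DNA).
#' @return numeric vector of degeneracies (exact integers up to 2^53).
#' @export
degeneracy <- function(L, alpha, n_b = 4) {
  if (!is.data.frame(alpha))
    alpha <- data.frame(alpha_s = alpha[1], alpha_e1 = alpha[2],
                        alpha_e2 = alpha[3], alpha_i = alpha[4])
  .validate_defects(L, alpha)
  with(alpha,
       n_b^abs(alpha_s) * (n_b - 1)^(alpha_e1 + alpha_e2 + alpha_i) *
         choose(L - 2 - abs(alpha_s) - alpha_e1 - alpha_e2, alpha_i))
}

#' Classify a (partner, shift) combination into a defect vector
#'
#' Brute-force classifier used as the independent oracle for degeneracy
#' counting and for per-sequence melting: aligns `partner` antiparallel to
#' `ref` at the given shift, marks Watson-Crick matches over the overlap,
#' and reads off the defect vector. Mismatch runs touching a duplex end are
#' terminal (`alpha_e`); all other mismatched positions are internal
#' (`alpha_i`). Returns `NULL` when fewer than two positions pair (no
#' duplex).
#'
#' @param ref,partner equal-length sequences (5'->3').
#' @param shift alignment shift in `-(L-1) ... (L-1)`; 0 is perfect
#'   antiparallel register.
#' @param alphabet an [rs_alphabet()].
#' @return named integer vector `(alpha_s, alpha_e1, alpha_e2, alpha_i)` or
#'   `NULL`.
#' @export
classify_duplex <- function(ref, partner, shift, alphabet = dna_alphabet()) {
  a <- .check_sequence(ref, alphabet)
  b <- .check_sequence(partner, alphabet)
  L <- length(a)
  if (length(b) != L) stop("sequences must have equal length", call. = FALSE)
  if (abs(shift) > L - 1) stop("shift out of range", call. = FALSE)
  bc <- rev(unname(alphabet$complement[b]))
  k <- max(1L, 1L + shift):min(L, L + shift)
  m <- a[k] == bc[k - shift]
  .classify_matches(m, shift)
}

# row-wise classification of a logical match matrix (rows = partners,
# columns = aligned overlap positions) at a fixed shift; returns a
# data.frame of defect vectors for the rows forming a duplex, or NULL
.classify_matrix <- function(m, shift) {
  n <- nrow(m)
  k <- ncol(m)
  first <- integer(n)
  last <- integer(n)
  for (j in seq_len(k)) {
    hit <- m[, j]
    first[first == 0L & hit] <- j
    last[hit] <- j
  }
  matched <- rowSums(m)
  keep <- matched >= 2L
  if (!any(keep)) return(NULL)
  data.frame(alpha_s = shift,
             alpha_e1 = first[keep] - 1L,
             alpha_e2 = k - last[keep],
             alpha_i = (last[keep] - first[keep] + 1L) -
               as.integer(matched[keep]))
}

# classify a logical match vector over the aligned overlap
.classify_matches <- function(m, shift) {
  if (sum(m) < 2L) return(NULL)
  idx <- which(m)
  e1 <- idx[1L] - 1L
  e2 <- length(m) - idx[length(idx)]
  ai <- sum(!m[idx[1L]:idx[length(idx)]])
  c(alpha_s = as.integer(shift), alpha_e1 = e1, alpha_e2 = e2,
    alpha_i = as.integer(ai))
}

#' Boltzmann factor of a pairing
#'
#' `zeta = [c] * exp(-dG / (R T))`, with `[c]` the dimensionless value of
#' the total strand concentration in mol/L. Computed in log space.
#'
#' @param dG_val Gibbs energy (kcal/mol), vectorised.
#' @param T temperature in kelvin (> 0).
#' @param c_molar total strand concentration, mol/L (> 0).
#' @param log return the log factor instead.
#' @return positive numeric (or its log).
#' @export
boltzmann_factor <- function(dG_val, T, c_molar, log = FALSE) {
  if (any(c_molar <= 0)) stop("concentration must be positive", call. = FALSE)
  if (any(T <= 0)) stop("temperature must be positive kelvin", call. = FALSE)
  lz <- log(c_molar) - dG_val / (.R_GAS * T)
  if (log) lz else exp(lz)
}

# precomputed per-class energies for a pool at one composition
.class_energies <- function(L, f_CG, params, alphabet, na_molar) {
  def <- enumerate_defects(L)
  g <- degeneracy(L, def, n_b = alphabet$n_b)
  en <- .alpha_energy(L, def, f_CG, params, alphabet, na_molar)
  list(def = def, g = g, dH = en$dH, dS = en$dS)
}

# log of S = sum_alpha g * zeta at temperature T (kelvin)
.log_weight_sum <- function(ce, T, c_molar) {
  lz <- log(c_molar) - (ce$dH - T * ce$dS / 1000) / (.R_GAS * T)
  M <- max(lz)
  M + log(sum(ce$g * exp(lz - M)))
}

# theta from log S via the pool-level two-state form
# theta = 1 - 2 / (1 + sqrt(1 + 4 S / n_b^L)), computed stably
.theta_from_logS <- function(logS, L, n_b) {
  x <- log(4) - L * log(n_b) + logS
  ifelse(x > 500, 1 - 2 * exp(-x / 2), 1 - 2 / (1 + sqrt(1 + exp(x))))
}

#' Statistical-weight table over defect classes
#'
#' Evaluates, for every defect class of a pool of length-`L` oligomers at
#' composition `f_CG`, the degeneracy `g`, the averaged free energy, the
#' Boltzmann factor `zeta` and the statistical weight `g * zeta`, at a
#' single temperature. The attribute `partition_sum` holds
#' `S = sum_alpha g * zeta` (also as `log_partition_sum`), the quantity
#' entering the pool melting formula.
#'
#' @param L oligomer length.
#' @param f_CG strong-base fraction.
#' @param T temperature in kelvin.
#' @param c_molar total strand concentration, mol/L.
#' @param params an [nn_params()] object.
#' @param alphabet an [rs_alphabet()].
#' @param na_molar sodium concentration, mol/L.
#' @return data frame of class `weight_table` with columns `alpha_s`,
#'   `alpha_e1`, `alpha_e2`, `alpha_i`, `g`, `dH`, `dS`, `dG`, `zeta`,
#'   `weight`.
#' @export
partition_sum <- function(L, f_CG, T, c_molar, params = nn_params(),
                          alphabet = dna_alphabet(),
                          na_molar = params$na_molar) {
  if (c_molar <= 0) stop("concentration must be positive", call. = FALSE)
  ce <- .class_energies(L, f_CG, params, alphabet, na_molar)
  dGv <- ce$dH - T * ce$dS / 1000
  zeta <- boltzmann_factor(dGv, T, c_molar)
  out <- cbind(ce$def, g = ce$g, dH = ce$dH, dS = ce$dS, dG = dGv,
               zeta = zeta, weight = ce$g * zeta)
  attr(out, "partition_sum") <- sum(out$weight)
  attr(out, "log_partition_sum") <- .log_weight_sum(ce, T, c_molar)
  attr(out, "T") <- T
  class(out) <- c("weight_table", "data.frame")
  out
}
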