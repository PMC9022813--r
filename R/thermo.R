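#' Free-energy objects
#'
#' A duplex free energy is stored as its enthalpy `dH` (kcal/mol) and
#' entropy `dS` (cal/(mol K)); the Gibbs energy at temperature `T` (kelvin)
#' is `dG(T) = dH - T * dS / 1000` (kcal/mol).
#'
#' @param dH enthalpy, kcal/mol.
#' @param dS entropy, cal/(mol K).
#' @param label optional tag.
#' @return object of class `free_energy`.
#' @export
free_energy <- function(dH, dS, label = NULL) {
  structure(list(dH = unname(dH), dS = unname(dS), label = label),
            class = "free_energy")
}

#' @rdname free_energy
#' @param fe a `free_energy` object.
#' @param T temperature(s) in kelvin.
#' @export
dG <- function(fe, T) fe$dH - T * fe$dS / 1000

#' @export
print.free_energy <- function(x, ...) {
  cat(sprintf("<free_energy%s> dH = %.2f kcal/mol, dS = %.2f cal/(mol K), dG(37C) = %.2f kcal/mol\n",
              if (is.null(x$label)) "" else paste0(": ", x$label),
              x$dH, x$dS, dG(x, kelvin(37))))
  invisible(x)
}

#' @export
`+.free_energy` <- function(e1, e2) free_energy(e1$dH + e2$dH, e1$dS + e2$dS)

#' Nearest-neighbor free energy of a complementary duplex
#'
#' Sequence-specific NN summation for a defectless duplex: the `L - 1`
#' stack terms read off the top strand, plus the two terminal initiation
#' contributions, with the entropy-only salt correction applied over the
#' `L - 1` stacks. `seqB` must be the exact reverse complement of `seqA`;
#' mismatched or shifted pairs are handled by the averaged defect-vector
#' parametrization instead (see [delta_g_parametrized()]).
#'
#' @param seqA,seqB mutually reverse-complementary sequences (5'->3').
#' @param params an [nn_params()] object (its `na_molar` sets the salt).
#' @param alphabet an [rs_alphabet()] with a full stack table.
#' @return a [free_energy()].
#' @export
nn_free_energy_pair <- function(seqA, seqB, params = nn_params(),
                                alphabet = dna_alphabet()) {
  ch <- .check_sequence(seqA, alphabet)
  .check_sequence(seqB, alphabet)
  if (!identical(complement_sequence(seqA, alphabet), toupper(seqB)))
    stop("seqB is not the reverse complement of seqA", call. = FALSE)
  L <- length(ch)
  if (L < 2) stop("need at least 2 nucleotides", call. = FALSE)
  if (!is.null(params$stack_override))
    stop("sequence-specific energies need a full stack table", call. = FALSE)
  .validate_quartets(params, alphabet)
  dimers <- paste0(ch[-L], ch[-1L])
  ends <- ifelse(ch[c(1L, L)] %in% alphabet$strong, "strong", "weak")
  dH <- sum(params$stack_dH[dimers]) + sum(params$init_dH[ends])
  dS <- sum(params$stack_dS[dimers]) + sum(params$init_dS[ends])
  dS <- salt_correct(dS, L - 1L, params$na_molar, params$salt_coeff)
  free_energy(dH, dS, label = sprintf("%s/%s", toupper(seqA), toupper(seqB)))
}

# vectorised dH/dS of the defect-vector parametrization; alpha is a
# data.frame with columns alpha_s, alpha_e1, alpha_e2, alpha_i
.alpha_energy <- function(L, alpha, f_CG, params, alphabet, na_molar) {
  av <- averaged_nn_params(f_CG, params, alphabet)
  n <- L - abs(alpha$alpha_s)
  e12 <- alpha$alpha_e1 + alpha$alpha_e2
  stacks <- pmax(0L, (n - e12 - 1L) - 2L * alpha$alpha_i)
  dangles <- 2 * (abs(alpha$alpha_s) > 0)
  # one terminal-mismatch term per defected duplex end: only the first
  # mismatched position stacks onto the helix, the rest of the run is an
  # unpaired flap (its cost is the stacks it removes)
  mm_runs <- (alpha$alpha_e1 > 0) + (alpha$alpha_e2 > 0)
  dH <- stacks * av$stack[["dH"]] + av$init[["dH"]] +
    mm_runs * av$mm_term[["dH"]] + alpha$alpha_i * av$mm_int[["dH"]] +
    dangles * av$dangle[["dH"]]
  dS <- stacks * av$stack[["dS"]] + av$init[["dS"]] +
    mm_runs * av$mm_term[["dS"]] + alpha$alpha_i * av$mm_int[["dS"]] +
    dangles * av$dangle[["dS"]]
  dS <- salt_correct(dS, stacks, na_molar, params$salt_coeff)
  list(dH = dH, dS = dS, n_stacks = stacks)
}

#' Averaged free energy of a duplex with a given defect vector
#'
#' Builds the duplex free energy from the defect vector alone, without
#' knowledge of the sequences involved: (intact stacks) x (composition-
#' averaged stack) + averaged initiation + one averaged dangling-end term
#' per overhanging duplex end (present when the alignment shift is nonzero)
#' + one averaged terminal-mismatch increment per consecutive terminal
#' mismatch + one averaged internal-mismatch increment per internal
#' mismatch. Each internal mismatch also breaks its two flanking stacks;
#' each terminal mismatch and each unit of shift removes one stack. The
#' salt correction acts on the intact stacks.
#'
#' @param L oligomer length.
#' @param alpha defect vector: numeric of length 4
#'   `(alpha_s, alpha_e1, alpha_e2, alpha_i)`, or a data frame with those
#'   columns (vectorised).
#' @param f_CG strong-base fraction of the reference sequence.
#' @param T optional temperature(s) in kelvin; when supplied the Gibbs
#'   energies are attached as attribute `dG`.
#' @param params an [nn_params()] object.
#' @param alphabet an [rs_alphabet()].
#' @param na_molar sodium concentration; defaults to `params$na_molar`.
#' @return a [free_energy()] (or, for a data-frame `alpha`, a list of
#'   vectors `dH`, `dS`).
#' @export
delta_g_parametrized <- function(L, alpha, f_CG, T = NULL,
                                 params = nn_params(),
                                 alphabet = dna_alphabet(),
                                 na_molar = params$na_molar) {
  single <- !is.data.frame(alpha)
  if (single) {
    alpha <- as.numeric(alpha)
    if (length(alpha) != 4L)
      stop("alpha must have 4 components", call. = FALSE)
    alpha <- data.frame(alpha_s = alpha[1], alpha_e1 = alpha[2],
                        alpha_e2 = alpha[3], alpha_i = alpha[4])
  }
  .validate_defects(L, alpha)
  en <- .alpha_energy(L, alpha, f_CG, params, alphabet, na_molar)
  if (single) {
    fe <- free_energy(en$dH, en$dS,
                      label = sprintf("L=%d alpha=(%g,%g,%g,%g) f=%.2g", L,
                                      alpha$alpha_s, alpha$alpha_e1,
                                      alpha$alpha_e2, alpha$alpha_i, f_CG))
    if (!is.null(T)) attr(fe, "dG") <- dG(fe, T)
    return(fe)
  }
  en
}

#' Two-state melting of an equimolar complementary pair
#'
#' Mass-action equilibrium `A + B <-> AB` for a non-self-complementary pair
#' with each strand at concentration `c_each` (mol/L). The hybridized
#' fraction is `theta = 1 - 2 / (1 + sqrt(1 + 4 K c_each))` with
#' `K = exp(-dG / RT)` -- the closed-form root of the mass-action
#' quadratic. `two_state_tm()` gives the closed-form melting temperature
#' `Tm = dH / (dS + R ln(c_each / 2))`.
#'
#' @param fe duplex [free_energy()].
#' @param c_each per-strand molar concentration (> 0).
#' @param T_grid temperatures in kelvin.
#' @return `two_state_curve()`: a [melting_curve] object;
#'   `two_state_tm()`: kelvin.
#' @export
two_state_curve <- function(fe, c_each, T_grid = melting_grid()) {
  if (c_each <= 0) stop("concentration must be positive", call. = FALSE)
  fun <- function(T) {
    logKc <- -dG(fe, T) / (.R_GAS * T) + log(c_each)
    x <- log(4) + logKc
    ifelse(x > 500, 1 - 2 * exp(-x / 2), 1 - 2 / (1 + sqrt(1 + exp(x))))
  }
  new_melting_curve(T_grid, fun(T_grid), fun,
                    label = sprintf("two-state pair, c = %.3g M", c_each))
}

#' @rdname two_state_curve
#' @export
two_state_tm <- function(fe, c_each) {
  if (c_each <= 0) stop("concentration must be positive", call. = FALSE)
  fe$dH / (fe$dS / 1000 + .R_GAS * log(c_each / 2))
}

#' Melting curve of two complementary strands
#'
#' Sequence-specific two-state melting of an equimolar pair, the standard
#' NN reference against which pool melting is compared.
#'
#' @inheritParams nn_free_energy_pair
#' @param c_each molar concentration of each strand.
#' @param T_grid temperatures in kelvin.
#' @return a [melting_curve] object.
#' @export
pair_melting_curve <- function(seqA, seqB, c_each, params = nn_params(),
                               T_grid = melting_grid(),
                               alphabet = dna_alphabet()) {
  fe <- nn_free_energy_pair(seqA, seqB, params, alphabet)
  two_state_curve(fe, c_each, T_grid)
}
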