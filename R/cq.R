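#' Stoichiometric ratio of a spiked sequence
#'
#' Ratio `phi` between the concentration of an added tagged strand and the
#' concentration at which that same sequence is already present in the
#' random pool (`c_pool / n_b^L` per species):
#' `phi = c_fluo / (c_pool_molar / n_b^L)`.
#'
#' @param c_fluo molar concentration of each tagged strand.
#' @param c_mass pool mass concentration, g/l.
#' @param L oligomer length.
#' @param n_b alphabet size.
#' @param mw molecular-weight convention (function of `L`).
#' @return dimensionless ratio.
#' @examples
#' stoichiometric_ratio(100e-9, 16, L = 8)  # ~ 1
#' @export
stoichiometric_ratio <- function(c_fluo, c_mass, L, n_b = 4,
                                 mw = mw_ssdna) {
  if (c_fluo <= 0 || c_mass <= 0)
    stop("concentrations must be positive", call. = FALSE)
  c_fluo / ((c_mass / mw(L)) / n_b^L)
}

#' Contact-quenching experiment specification
#'
#' A pair of mutually complementary tagged strands (`seqA`, `seqB`) spiked
#' at `c_fluo` each into a random pool. The tagged-duplex free energy
#' defaults to the sequence-specific NN value of the untagged pair; the
#' fluorophores' terminal stabilization can be supplied as an additive
#' `c(dH, dS)` offset, optionally with an uncertainty band (a list of two
#' offsets bounding the stabilization).
#'
#' @param seqA,seqB mutually reverse-complementary sequences.
#' @param c_fluo molar concentration of each tagged strand.
#' @param pool a [solution_spec()] for the surrounding random pool (same
#'   `L`).
#' @param dG_offset additive `c(dH, dS)` applied to the tagged-duplex
#'   energy (fluorophore stabilization); default none.
#' @param dG_band optional list of two `c(dH, dS)` offsets (band edges).
#' @param params an [nn_params()] object used for the tagged-duplex NN sum.
#' @return object of class `cq_spec` with the derived `phi`.
#' @export
cq_spec <- function(seqA, seqB, c_fluo, pool, dG_offset = c(dH = 0, dS = 0),
                    dG_band = NULL, params = nn_params()) {
  alphabet <- pool$alphabet
  if (!identical(complement_sequence(seqA, alphabet), toupper(seqB)))
    stop("seqB must be the reverse complement of seqA", call. = FALSE)
  if (nchar(seqA) != pool$L)
    stop("tagged strands must match the pool length", call. = FALSE)
  if (c_fluo <= 0) stop("c_fluo must be positive", call. = FALSE)
  params$na_molar <- pool$na_molar
  base_fe <- nn_free_energy_pair(seqA, seqB, params, alphabet)
  fe <- free_energy(base_fe$dH + dG_offset[["dH"]],
                    base_fe$dS + dG_offset[["dS"]],
                    label = "tagged duplex")
  band <- NULL
  if (!is.null(dG_band))
    band <- lapply(dG_band, function(off)
      free_energy(base_fe$dH + off[["dH"]], base_fe$dS + off[["dS"]]))
  structure(list(seqA = toupper(seqA), seqB = toupper(seqB),
                 c_fluo = c_fluo, pool = pool,
                 phi = c_fluo / (pool$c_molar / alphabet$n_b^pool$L),
                 f_CG = fraction_strong(seqA, alphabet),
                 fe_ab = fe, fe_band = band,
                 offset = dG_offset, band_offsets = dG_band),
            class = "cq_spec")
}

#' @export
print.cq_spec <- function(x, ...) {
  cat(sprintf("<cq_spec> %s / %s at %.3g nM each in a %dN pool (%.3g g/l)\n",
              x$seqA, x$seqB, x$c_fluo * 1e9, x$pool$L, x$pool$c_mass))
  cat(sprintf("  phi = %.4g; tagged-duplex dH = %.2f, dS = %.2f\n",
              x$phi, x$fe_ab$dH, x$fe_ab$dS))
  invisible(x)
}

# log of phi * zeta_AB and log of the pool weight sum at temperature T
.cq_terms <- function(cq, T, params, fe = cq$fe_ab) {
  pool <- cq$pool
  ce <- .class_energies(pool$L, cq$f_CG, params, pool$alphabet,
                        pool$na_molar)
  function(Ti) {
    lab <- log(cq$phi) + log(pool$c_molar) - dG(fe, Ti) / (.R_GAS * Ti)
    lS <- .log_weight_sum(ce, Ti, pool$c_molar)
    c(lab = lab, lS = lS)
  }
}

#' Total pairing of the tagged strands amid the pool
#'
#' Fraction of tagged strands paired to anything -- their exact partner or
#' any pool oligomer: the pool melting form with the tagged-pair weight
#' `phi * zeta_AB` added to the defect-class weight sum. As `phi` grows it
#' converges to the two-state melting curve of the pair alone; at `phi = 0`
#' it reduces to the fixed-composition pool curve.
#'
#' @param cq a [cq_spec()].
#' @param T_grid temperatures in kelvin.
#' @param params an [nn_params()] object.
#' @return a [new_melting_curve()] object.
#' @export
theta_e_cq <- function(cq, T_grid = melting_grid(), params = nn_params()) {
  terms <- .cq_terms(cq, NULL, params)
  pool <- cq$pool
  n_b <- pool$alphabet$n_b
  fun <- function(T) {
    vapply(T, function(Ti) {
      tt <- terms(Ti)
      M <- max(tt)
      .theta_from_logS(M + log(sum(exp(tt - M))), pool$L, n_b)
    }, numeric(1))
  }
  new_melting_curve(T_grid, fun(T_grid), fun, label = "theta_e^(CQ)")
}

#' Fraction of tagged strands paired to their exact partner
#'
#' The contact-quenching observable: the share of the total tagged-strand
#' pairing captured by the exact complementary duplex,
#' `theta_AB = phi zeta_AB / (phi zeta_AB + sum_alpha g zeta) *
#' theta_e^(CQ)`. When the specification carries an uncertainty band on the
#' tagged-duplex energy, band curves are attached as `theta_lower` /
#' `theta_upper` attributes.
#'
#' @inheritParams theta_e_cq
#' @return a [new_melting_curve()] object (with optional band attributes).
#' @export
theta_ab <- function(cq, T_grid = melting_grid(), params = nn_params()) {
  pool <- cq$pool
  n_b <- pool$alphabet$n_b
  make_fun <- function(fe) {
    terms <- .cq_terms(cq, NULL, params, fe)
    function(T) {
      vapply(T, function(Ti) {
        tt <- terms(Ti)
        M <- max(tt)
        logS <- M + log(sum(exp(tt - M)))
        share <- exp(tt[["lab"]] - logS)
        share * .theta_from_logS(logS, pool$L, n_b)
      }, numeric(1))
    }
  }
  fun <- make_fun(cq$fe_ab)
  out <- new_melting_curve(T_grid, fun(T_grid), fun, label = "theta_A*B*")
  if (!is.null(cq$fe_band)) {
    bands <- lapply(cq$fe_band, function(fe) make_fun(fe)(T_grid))
    lo <- pmin(bands[[1]], bands[[2]])
    hi <- pmax(bands[[1]], bands[[2]])
    attr(out, "theta_lower") <- lo
    attr(out, "theta_upper") <- hi
  }
  out
}

#' Salt sensitivity of the tagged-pair yield
#'
#' Evaluates `theta_AB` at a fixed (low) temperature across a grid of
#' stoichiometric ratios `phi` (realized by diluting the pool at fixed
#' tagged-strand concentration) for several sodium concentrations, and
#' reports the largest absolute spread across salts. Because the salt
#' correction is proportional to the intact-stack count, it largely cancels
#' between the tagged-pair weight and the dominant (nearly full-length)
#' pool weights, so the spread is small even where the ensemble melting
#' temperature shifts strongly with salt.
#'
#' @param cq a [cq_spec()] (its pool sets `L`, alphabet and MW convention).
#' @param T temperature in kelvin.
#' @param salts sodium concentrations, mol/L.
#' @param phi_grid stoichiometric ratios (log-spaced recommended).
#' @param params an [nn_params()] object.
#' @return data frame with columns `phi`, one `theta` column per salt;
#'   attribute `max_spread`.
#' @export
salt_sensitivity_ab <- function(cq, T = kelvin(15),
                                salts = c(0.15, 1.0),
                                phi_grid = 10^seq(-2, 2, length.out = 9),
                                params = nn_params()) {
  pool <- cq$pool
  out <- data.frame(phi = phi_grid)
  for (s in salts) {
    th <- vapply(phi_grid, function(phi) {
      c_molar <- cq$c_fluo * pool$alphabet$n_b^pool$L / phi
      pool_s <- solution_spec(pool$L, c_molar = c_molar, na_molar = s,
                              alphabet = pool$alphabet, mw = pool$mw)
      cq_s <- cq_spec(cq$seqA, cq$seqB, cq$c_fluo, pool_s,
                      dG_offset = cq$offset, params = params)
      theta_ab(cq_s, T_grid = c(T, T + 1), params = params)$theta[1]
    }, numeric(1))
    out[[sprintf("theta_%gM", s)]] <- th
  }
  if (length(salts) > 1) {
    m <- as.matrix(out[, -1, drop = FALSE])
    attr(out, "max_spread") <- max(apply(m, 1, function(r)
      diff(range(r))))
  }
  out
}
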