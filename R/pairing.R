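#' Defect-class fractions at fixed composition
#'
#' Fraction of strands (with strong-base fraction `f_CG`) engaged in a
#' duplex of each defect class at temperature `T`: the total hybridized
#' fraction is split across classes in proportion to their statistical
#' weights `g * zeta`, so the class fractions sum exactly to the
#' fixed-composition melting value.
#'
#' @param spec a [solution_spec()].
#' @param f_CG strong-base fraction.
#' @param T temperature in kelvin (scalar).
#' @param params an [nn_params()] object.
#' @return data frame of class `defect_distribution` with the defect-vector
#'   columns, `g` and `theta`; attributes `T`, `theta_e` (the matching
#'   total) and `L`.
#' @export
defect_fractions_fcg <- function(spec, f_CG, T, params = nn_params()) {
  ce <- .class_energies(spec$L, f_CG, params, spec$alphabet, spec$na_molar)
  lz <- log(spec$c_molar) - (ce$dH - T * ce$dS / 1000) / (.R_GAS * T)
  M <- max(lz)
  w <- ce$g * exp(lz - M)
  logS <- M + log(sum(w))
  theta_e <- .theta_from_logS(logS, spec$L, spec$alphabet$n_b)
  out <- cbind(ce$def, g = ce$g, theta = w / sum(w) * theta_e)
  attr(out, "T") <- T
  attr(out, "theta_e") <- theta_e
  attr(out, "L") <- spec$L
  class(out) <- c("defect_distribution", "data.frame")
  out
}

#' Ensemble defect-class fractions
#'
#' Composition-weighted average of [defect_fractions_fcg()] over the
#' binomial composition classes of the pool: the fraction `theta_alpha` of
#' all pool strands in duplexes of each defect class. Summing over classes
#' recovers the ensemble hybridized fraction at the same temperature.
#'
#' @inheritParams defect_fractions_fcg
#' @return a `defect_distribution` data frame (see
#'   [defect_fractions_fcg()]).
#' @export
defect_fractions_ensemble <- function(spec, T, params = nn_params()) {
  comp <- .composition_classes(spec$L, params, spec$alphabet)
  acc <- NULL
  theta_e <- 0
  for (i in seq_len(nrow(comp))) {
    d <- defect_fractions_fcg(spec, comp$f_CG[i], T, params)
    if (is.null(acc)) {
      acc <- d
      acc$theta <- comp$p[i] * d$theta
    } else {
      acc$theta <- acc$theta + comp$p[i] * d$theta
    }
    theta_e <- theta_e + comp$p[i] * attr(d, "theta_e")
  }
  attr(acc, "theta_e") <- theta_e
  acc
}

#' @export
print.defect_distribution <- function(x, ..., n = 6L) {
  cat(sprintf("<defect_distribution> L = %d, T = %.2f C, theta_e = %.4f, %d classes\n",
              attr(x, "L"), celsius(attr(x, "T")), attr(x, "theta_e"),
              nrow(x)))
  print.data.frame(utils::head(rank_motifs(x, n), n))
  invisible(x)
}

#' Aggregate defect fractions by total error count
#'
#' Sums the class fractions over all defect vectors sharing the same total
#' number of pairing errors `|alpha| = |alpha_s| + alpha_e1 + alpha_e2 +
#' alpha_i`.
#'
#' @param dist a `defect_distribution`.
#' @return data frame with columns `total` and `theta`, ascending in
#'   `total`.
#' @export
total_error_fractions <- function(dist) {
  tot <- abs(dist$alpha_s) + dist$alpha_e1 + dist$alpha_e2 + dist$alpha_i
  agg <- tapply(dist$theta, tot, sum)
  data.frame(total = as.integer(names(agg)), theta = as.numeric(agg))
}

#' Most probable duplex motifs
#'
#' Top-`k` defect classes by fraction, ties broken lexicographically in the
#' defect vector; returned fractions are non-increasing.
#'
#' @param dist a `defect_distribution`.
#' @param k number of motifs (>= 1).
#' @return data frame of `k` rows (fewer if the distribution is smaller).
#' @export
rank_motifs <- function(dist, k) {
  if (k < 1) stop("k must be at least 1", call. = FALSE)
  ord <- order(-dist$theta, dist$alpha_s, dist$alpha_e1, dist$alpha_e2,
               dist$alpha_i)
  out <- as.data.frame(dist)[ord, , drop = FALSE]
  rownames(out) <- NULL
  utils::head(out, k)
}

#' Defectless-duplex fraction across temperature
#'
#' The fraction `theta_0` of pool strands in perfect (defect-free) duplexes
#' as a function of temperature -- the pool's "perfect pairing" yield.
#' `counterfactual_theta_perfect()` evaluates the same quantity under
#' modified chemistry: `"all_CG"` replaces every stack by the CG-quartet
#' average (keeping the four-letter degeneracies), `"n_bases"` switches to
#' an `n_b`-letter alphabet (two-letter energetics intermediate between the
#' AT and CG averages; composition-uniform averaged energetics above four
#' letters, where no stacking tables exist).
#'
#' @param spec a [solution_spec()].
#' @param T_grid temperatures in kelvin.
#' @param params an [nn_params()] object.
#' @return a [new_melting_curve()]-classed object whose `theta` is
#'   `theta_0(T)` (it need not cross 1/2).
#' @export
theta_perfect_curve <- function(spec, T_grid = melting_grid(),
                                params = nn_params()) {
  comp <- .composition_classes(spec$L, params, spec$alphabet)
  ces <- lapply(comp$f_CG, function(f)
    .class_energies(spec$L, f, params, spec$alphabet, spec$na_molar))
  perfect <- which(ces[[1]]$def$alpha_s == 0 & ces[[1]]$def$alpha_e1 == 0 &
                     ces[[1]]$def$alpha_e2 == 0 & ces[[1]]$def$alpha_i == 0)
  n_b <- spec$alphabet$n_b
  fun <- function(T) {
    vapply(T, function(Ti) {
      th0 <- vapply(ces, function(ce) {
        lz <- log(spec$c_molar) - (ce$dH - Ti * ce$dS / 1000) / (.R_GAS * Ti)
        M <- max(lz)
        w <- ce$g * exp(lz - M)
        logS <- M + log(sum(w))
        w[perfect] / sum(w) * .theta_from_logS(logS, spec$L, n_b)
      }, numeric(1))
      sum(comp$p * th0)
    }, numeric(1))
  }
  th <- fun(T_grid)
  out <- new_melting_curve(T_grid, th, fun,
                           label = sprintf("theta_0, %dN, %.3g g/l",
                                           spec$L, spec$c_mass))
  out
}

#' @rdname theta_perfect_curve
#' @param variant `"all_CG"` or `"n_bases"`.
#' @param n_b alphabet size for `variant = "n_bases"`.
#' @export
counterfactual_theta_perfect <- function(spec, T_grid = melting_grid(),
                                         variant = c("all_CG", "n_bases"),
                                         n_b = 2,
                                         params = nn_params()) {
  variant <- match.arg(variant)
  if (variant == "all_CG") {
    params2 <- all_cg_params(params)
    spec2 <- spec
  } else {
    alphabet <- expanded_alphabet(n_b)
    params2 <- if (n_b == 2) two_base_params(params)
               else if (n_b == 4) params
               else uniform_avg_params(params)
    spec2 <- solution_spec(spec$L, c_mass = spec$c_mass,
                           na_molar = spec$na_molar, alphabet = alphabet,
                           mw = spec$mw)
  }
  theta_perfect_curve(spec2, T_grid, params2)
}
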