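#' Melting-curve objects
#'
#' A melting curve stores the hybridized fraction `theta` on a kelvin grid
#' together with the continuous model function it was evaluated from, so
#' that the melting temperature can be located by root finding on the model
#' rather than by grid interpolation.
#'
#' @param T_K temperature grid, kelvin (strictly increasing).
#' @param theta hybridized fractions in `[0, 1]`.
#' @param theta_fun vectorised function of kelvin temperature returning
#'   `theta`; may be `NULL` for purely tabulated curves, in which case a
#'   monotone interpolant is used.
#' @param label short description.
#' @return object of class `melting_curve` with fields `T_K`, `theta`,
#'   `theta_fun`, `label`.
#' @export
new_melting_curve <- function(T_K, theta, theta_fun = NULL, label = "") {
  if (is.unsorted(T_K, strictly = TRUE))
    stop("temperature grid must be strictly increasing", call. = FALSE)
  if (any(theta < -1e-9 | theta > 1 + 1e-9))
    stop("theta outside [0, 1]", call. = FALSE)
  theta <- pmin(1, pmax(0, theta))
  if (is.null(theta_fun))
    theta_fun <- stats::approxfun(T_K, theta, rule = 2)
  structure(list(T_K = T_K, theta = theta, theta_fun = theta_fun,
                 label = label),
            class = "melting_curve")
}

#' @export
print.melting_curve <- function(x, ...) {
  cat(sprintf("<melting_curve%s> %d points, %.1f-%.1f C\n",
              if (nzchar(x$label)) paste0(": ", x$label) else "",
              length(x$T_K), celsius(min(x$T_K)), celsius(max(x$T_K))))
  tm <- tryCatch(melting_temperature(x), error = function(e) NA_real_)
  if (is.na(tm)) {
    cat(sprintf("  theta in [%.3f, %.3f]; no crossing of 1/2 in range\n",
                min(x$theta), max(x$theta)))
  } else {
    cat(sprintf("  Tm = %.2f C\n", celsius(tm)))
  }
  invisible(x)
}

#' @export
plot.melting_curve <- function(x, ..., add = FALSE, col = 1, lty = 1,
                               xlab = "T (°C)",
                               ylab = expression(theta)) {
  if (add) {
    graphics::lines(celsius(x$T_K), x$theta, col = col, lty = lty, ...)
  } else {
    graphics::plot(celsius(x$T_K), x$theta, type = "l", col = col,
                   lty = lty, xlab = xlab, ylab = ylab, ylim = c(0, 1), ...)
    graphics::abline(h = 0.5, col = "grey", lty = 3)
  }
  invisible(x)
}

#' @export
as.data.frame.melting_curve <- function(x, ...) {
  data.frame(T_C = celsius(x$T_K), theta = x$theta)
}

#' Melting temperature of a curve
#'
#' Temperature at which `theta` crosses 1/2, located by bisection
#' (`uniroot`) on the curve's continuous model function, to a default
#' tolerance of 0.01 degrees.
#'
#' @param curve a [new_melting_curve()] object.
#' @param tol root tolerance in degrees.
#' @return melting temperature in kelvin.
#' @export
melting_temperature <- function(curve, tol = 0.01) {
  f <- function(T) curve$theta_fun(T) - 0.5
  lo <- min(curve$T_K); hi <- max(curve$T_K)
  flo <- f(lo); fhi <- f(hi)
  if (is.na(flo) || is.na(fhi) || flo < 0 || fhi > 0)
    stop(sprintf(
      "theta does not cross 1/2 in [%.1f, %.1f] C (theta: %.4f at the low end, %.4f at the high end)",
      celsius(lo), celsius(hi), flo + 0.5, fhi + 0.5), call. = FALSE)
  stats::uniroot(f, c(lo, hi), tol = tol)$root
}

# compositions entering the ensemble average: the L+1 binomial classes for
# a 4-letter alphabet with sequence-resolved energetics, otherwise a single
# composition-free class
.composition_classes <- function(L, params, alphabet) {
  if (alphabet$n_b == 4L && is.null(params$stack_override) &&
      length(alphabet$strong)) {
    composition_weights(L)
  } else {
    data.frame(f_CG = 0.5, p = 1)
  }
}

#' Pool melting curve at fixed composition
#'
#' Hybridized fraction of the sequences with strong-base fraction `f_CG`
#' in a random pool:
#' `theta = 1 - 2 / (1 + sqrt(1 + (4 / n_b^L) * sum_alpha g * zeta))`,
#' with the statistical weights from [partition_sum()].
#'
#' @param spec a [solution_spec()].
#' @param f_CG strong-base fraction; `f_CG * L` must be an integer.
#' @param T_grid temperatures in kelvin.
#' @param params an [nn_params()] object.
#' @return a [new_melting_curve()] object.
#' @export
theta_fcg <- function(spec, f_CG, T_grid = melting_grid(),
                      params = nn_params()) {
  if (abs(f_CG * spec$L - round(f_CG * spec$L)) > 1e-9)
    stop("f_CG * L must be an integer", call. = FALSE)
  ce <- .class_energies(spec$L, f_CG, params, spec$alphabet, spec$na_molar)
  n_b <- spec$alphabet$n_b
  fun <- function(T) {
    vapply(T, function(Ti)
      .theta_from_logS(.log_weight_sum(ce, Ti, spec$c_molar), spec$L, n_b),
      numeric(1))
  }
  new_melting_curve(T_grid, fun(T_grid), fun,
                    label = sprintf("%dN, f_CG = %.3g", spec$L, f_CG))
}

#' Ensemble melting curve of a random pool
#'
#' Binomial-composition average of the fixed-composition curves: the
#' fraction of all pool strands engaged in a duplex of any quality, the
#' quantity measured by UV hyperchromicity.
#'
#' @inheritParams theta_fcg
#' @return a [new_melting_curve()] object.
#' @export
theta_ensemble <- function(spec, T_grid = melting_grid(),
                           params = nn_params()) {
  comp <- .composition_classes(spec$L, params, spec$alphabet)
  ces <- lapply(comp$f_CG, function(f)
    .class_energies(spec$L, f, params, spec$alphabet, spec$na_molar))
  n_b <- spec$alphabet$n_b
  fun <- function(T) {
    vapply(T, function(Ti) {
      th <- vapply(ces, function(ce)
        .theta_from_logS(.log_weight_sum(ce, Ti, spec$c_molar), spec$L, n_b),
        numeric(1))
      sum(comp$p * th)
    }, numeric(1))
  }
  new_melting_curve(T_grid, fun(T_grid), fun,
                    label = sprintf("%dN ensemble, %.3g g/l, %.3g M Na+",
                                    spec$L, spec$c_mass, spec$na_molar))
}

# integer partner matrix of all n_b^L sequences (rows), cached
.all_partners <- function(L, alphabet) {
  key <- sprintf("partners_%s_%d", alphabet$label, L)
  if (!is.null(.rs_cache[[key]])) return(.rs_cache[[key]])
  grid <- do.call(expand.grid,
                  c(rep(list(seq_len(alphabet$n_b)), L),
                    list(KEEP.OUT.ATTRS = FALSE)))
  m <- as.matrix(grid)
  dimnames(m) <- NULL
  .rs_cache[[key]] <- m
  m
}

#' Per-sequence melting curve (small-pool oracle)
#'
#' Melting curve of one reference sequence amid the full pool, evaluated by
#' explicit summation over partner sequences and alignment shifts: each
#' (partner, shift) combination is classified into its defect vector and
#' assigned the averaged parametrized energy at the reference composition.
#' `mode = "exhaustive"` enumerates all `n_b^L` partners (refused above
#' `L = 6`; use sampling instead); `mode = "sampled"` draws `n_samples`
#' uniform partners and rescales the weight sum by `n_b^L / n_samples`.
#' Averaged over references, this validates the closed-form
#' [theta_ensemble()] summation.
#'
#' @param ref_seq reference sequence.
#' @param spec a [solution_spec()].
#' @param T_grid temperatures in kelvin.
#' @param params an [nn_params()] object.
#' @param mode `"exhaustive"` or `"sampled"`.
#' @param n_samples partners drawn in sampled mode.
#' @param seed optional RNG seed for sampled mode.
#' @return a [new_melting_curve()] object.
#' @export
theta_sequence_oracle <- function(ref_seq, spec, T_grid = melting_grid(),
                                  params = nn_params(),
                                  mode = c("exhaustive", "sampled"),
                                  n_samples = 2000, seed = NULL) {
  mode <- match.arg(mode)
  alphabet <- spec$alphabet
  a <- .check_sequence(ref_seq, alphabet)
  L <- length(a)
  if (L != spec$L) stop("reference length must match the pool", call. = FALSE)
  n_b <- alphabet$n_b
  if (mode == "exhaustive") {
    if (L > 6)
      stop(paste("exhaustive mode enumerates n_b^L partners and is",
                 "restricted to L <= 6; use mode = 'sampled'"), call. = FALSE)
    partners <- .all_partners(L, alphabet)
    rescale <- 1
  } else {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(seed)
    }
    partners <- matrix(sample.int(n_b, n_samples * L, replace = TRUE),
                       nrow = n_samples)
    rescale <- n_b^L / n_samples
  }
  comp_int <- match(unname(alphabet$complement[alphabet$bases]),
                    alphabet$bases)
  ai <- match(a, alphabet$bases)
  # reverse-complement rows of the partner matrix
  pc <- matrix(comp_int[partners[, L:1, drop = FALSE]],
               nrow = nrow(partners))
  f_CG <- fraction_strong(ref_seq, alphabet)
  # collect the defect vector of every classifiable (partner, shift);
  # classification is vectorised over partners, one shift at a time
  alphas <- vector("list", 2L * L - 1L)
  for (s in -(L - 1L):(L - 1L)) {
    k <- max(1L, 1L + s):min(L, L + s)
    m <- pc[, k - s, drop = FALSE] == matrix(ai[k], nrow(pc), length(k),
                                             byrow = TRUE)
    cl <- .classify_matrix(m, s)
    if (!is.null(cl)) alphas[[s + L]] <- cl
  }
  alpha_df <- do.call(rbind, alphas[!vapply(alphas, is.null, logical(1))])
  en <- .alpha_energy(L, alpha_df, f_CG, params, alphabet, spec$na_molar)
  ce <- list(g = rep(rescale, nrow(alpha_df)), dH = en$dH, dS = en$dS)
  fun <- function(T) {
    vapply(T, function(Ti)
      .theta_from_logS(.log_weight_sum(ce, Ti, spec$c_molar), L, n_b),
      numeric(1))
  }
  new_melting_curve(T_grid, fun(T_grid), fun,
                    label = sprintf("sequence %s (%s)", ref_seq, mode))
}

#' Most stable alignment of a specific pair
#'
#' Matrix-level view of the interaction between two specific strands: every
#' alignment shift is classified into its defect vector, the averaged
#' parametrized free energy is attached, and the minimum-`dG` alignment is
#' returned (ties broken by smaller `|alpha_s|`, then negative shift).
#' Pool-level formulas sum over all shifts instead.
#'
#' @param ref,partner equal-length sequences.
#' @param T temperature in kelvin at which `dG` ranks the alignments.
#' @param params an [nn_params()] object.
#' @param alphabet an [rs_alphabet()].
#' @param na_molar sodium concentration.
#' @return list with `best` (one-row data frame) and `all` (every
#'   classifiable shift with its defect vector and `dG`), or `NULL` when no
#'   shift forms a duplex.
#' @export
best_alignment <- function(ref, partner, T = kelvin(37),
                           params = nn_params(),
                           alphabet = dna_alphabet(),
                           na_molar = params$na_molar) {
  L <- nchar(ref)
  rows <- list()
  for (s in -(L - 1L):(L - 1L)) {
    al <- classify_duplex(ref, partner, s, alphabet)
    if (!is.null(al)) rows[[length(rows) + 1L]] <- al
  }
  if (!length(rows)) return(NULL)
  df <- as.data.frame(do.call(rbind, rows))
  en <- .alpha_energy(L, df, fraction_strong(ref, alphabet), params,
                      alphabet, na_molar)
  df$dG <- en$dH - T * en$dS / 1000
  ord <- order(df$dG, abs(df$alpha_s), df$alpha_s >= 0)
  list(best = df[ord[1L], , drop = FALSE], all = df)
}
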