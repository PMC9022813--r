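#' Read sequences from a FASTA file
#'
#' Thin wrapper over `Biostrings::readBStringSet()` returning upper-case
#' character strings named by the record identifier (the description is
#' dropped after the first whitespace).
#'
#' @param file path to a FASTA file.
#' @param alphabet optional [rs_alphabet()]; when given, every sequence is
#'   validated against it.
#' @return named character vector of sequences.
#' @export
read_fasta <- function(file, alphabet = NULL) {
  if (!requireNamespace("Biostrings", quietly = TRUE))
    stop("reading FASTA requires the Biostrings package", call. = FALSE)
  x <- Biostrings::readBStringSet(file)
  out <- toupper(as.character(x))
  names(out) <- sub("\\s.*$", "", names(out))
  if (!is.null(alphabet))
    invisible(lapply(out, .check_sequence, alphabet = alphabet))
  out
}

#' Melting-curve CSV round trip
#'
#' Curves are written as `T_C,theta` with six significant digits and read
#' back as tabulated [new_melting_curve()] objects.
#'
#' @param curve a melting curve.
#' @param file path.
#' @return `write_curve_csv()` returns the path invisibly;
#'   `read_curve_csv()` a melting curve.
#' @export
write_curve_csv <- function(curve, file) {
  df <- as.data.frame(curve)
  df$T_C <- signif(df$T_C, 6)
  df$theta <- signif(df$theta, 6)
  utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(file) {
  df <- utils::read.csv(file)
  if (!all(c("T_C", "theta") %in% names(df)))
    stop("expected columns T_C and theta", call. = FALSE)
  new_melting_curve(kelvin(df$T_C), df$theta, label = basename(file))
}

#' Synthetic absorbance trace
#'
#' Builds a hyperchromicity trace from a known melting curve and two linear
#' baselines: `A(T) = A_lower(T) + (A_upper(T) - A_lower(T)) * (1 -
#' theta(T))` plus optional seeded Gaussian noise. Fully hybridized samples
#' sit on the lower (hypochromic) baseline. Used to exercise the
#' normalization round trip and to generate test fixtures.
#'
#' @param curve a melting curve (tabulated on its grid).
#' @param baseline_low,baseline_high `c(intercept, slope)` of the lower and
#'   upper absorbance baselines as functions of temperature in Celsius.
#' @param noise_sd Gaussian noise standard deviation (absorbance units).
#' @param seed optional RNG seed (restores the RNG state afterwards).
#' @return object of class `absorbance_trace`: data frame `T_C`, `A` with
#'   attribute `direction`.
#' @export
synthesize_absorbance <- function(curve, baseline_low = c(0.50, 0.0004),
                                  baseline_high = c(0.70, 0.0004),
                                  noise_sd = 0, seed = NULL) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv()))
      get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(seed)
  }
  t_c <- celsius(curve$T_K)
  lower <- baseline_low[1] + baseline_low[2] * t_c
  upper <- baseline_high[1] + baseline_high[2] * t_c
  A <- lower + (upper - lower) * (1 - curve$theta)
  if (noise_sd > 0) A <- A + stats::rnorm(length(A), sd = noise_sd)
  structure(data.frame(T_C = t_c, A = A),
            direction = "heating", class = c("absorbance_trace",
                                             "data.frame"))
}

#' Normalize an absorbance melting trace
#'
#' Standard two-baseline reduction of hyperchromicity data: straight lines
#' are fitted to a low- and a high-temperature window, and the hybridized
#' fraction is `theta(T) = (A_upper(T) - A(T)) / (A_upper(T) -
#' A_lower(T))`, clipped to `[0, 1]`. Windows default to the lowest and
#' highest 15% of the measured span and must contain at least five points.
#'
#' @param trace an `absorbance_trace` (or data frame with `T_C`, `A`).
#' @param low_window,high_window `c(min, max)` temperature windows in
#'   Celsius for the baseline fits.
#' @return a [new_melting_curve()] object.
#' @export
normalize_absorbance <- function(trace, low_window = NULL,
                                 high_window = NULL) {
  t_c <- trace$T_C
  A <- trace$A
  if (is.unsorted(t_c, strictly = TRUE) && is.unsorted(rev(t_c),
                                                       strictly = TRUE))
    stop("temperature must be strictly monotone", call. = FALSE)
  if (any(!is.finite(A))) stop("absorbance must be finite", call. = FALSE)
  span <- range(t_c)
  if (is.null(low_window))
    low_window <- c(span[1], span[1] + 0.15 * diff(span))
  if (is.null(high_window))
    high_window <- c(span[2] - 0.15 * diff(span), span[2])
  fit_window <- function(w, what) {
    if (w[1] < span[1] - 1e-9 || w[2] > span[2] + 1e-9)
      stop(sprintf("%s baseline window [%g, %g] outside the data span",
                   what, w[1], w[2]), call. = FALSE)
    sel <- t_c >= w[1] & t_c <= w[2]
    if (sum(sel) < 5)
      stop(sprintf("%s baseline window has %d points; need >= 5",
                   what, sum(sel)), call. = FALSE)
    if (stats::sd(t_c[sel]) == 0)
      stop(sprintf("%s baseline window is degenerate", what), call. = FALSE)
    stats::lm(A ~ T_C, data = data.frame(T_C = t_c[sel], A = A[sel]))
  }
  fit_lo <- fit_window(low_window, "lower")
  fit_hi <- fit_window(high_window, "upper")
  pred <- function(fit) stats::predict(fit,
                                       newdata = data.frame(T_C = t_c))
  lower <- pred(fit_lo)
  upper <- pred(fit_hi)
  if (any(abs(upper - lower) < 1e-12))
    stop("baselines coincide; cannot normalize", call. = FALSE)
  theta <- pmin(1, pmax(0, (upper - A) / (upper - lower)))
  ord <- order(t_c)
  new_melting_curve(kelvin(t_c[ord]), theta[ord],
                    label = "normalized absorbance")
}
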