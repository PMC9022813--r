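#' Nearest-neighbor thermodynamic parameters
#'
#' Loads a plain-text table of unified nearest-neighbor (NN) stack
#' enthalpies/entropies, duplex initiation terms, averaged defect increments
#' (dangling end, terminal mismatch, internal mismatch) and the sodium
#' correction coefficient. The package ships the SantaLucia unified DNA/DNA
#' set at the 1 M NaCl reference state in
#' `system.file("extdata", "nn_unified_dna.tsv", package = "rsdna")`; the
#' file header documents units, conventions and the provenance of the
#' averaged increments.
#'
#' @param file path to a parameter table; `NULL` loads the shipped set.
#' @param na_molar sodium concentration in mol/L used by operations that do
#'   not take an explicit solution specification.
#' @return an object of class `nn_params`: named vectors `stack_dH`,
#'   `stack_dS` (one entry per ordered quartet, keyed by the top-strand
#'   dimer), `init_dH`/`init_dS` (per-terminal, `strong` and `weak`),
#'   increments `dangle`, `mm_term`, `mm_int` (each `c(dH, dS)`),
#'   `salt_coeff` and `na_molar`. Optional fields `stack_override` /
#'   `init_override` replace the composition-averaged stack/initiation with
#'   fixed values (used by the counterfactual alphabets).
#' @export
nn_params <- function(file = NULL, na_molar = 1.0) {
  if (is.null(file))
    file <- system.file("extdata", "nn_unified_dna.tsv", package = "rsdna")
  tab <- utils::read.table(file, header = FALSE, comment.char = "#",
                           col.names = c("key", "dH", "dS"),
                           stringsAsFactors = FALSE)
  row <- function(key) {
    i <- match(key, tab$key)
    if (is.na(i)) stop(sprintf("parameter table lacks row '%s'", key),
                       call. = FALSE)
    c(dH = tab$dH[i], dS = tab$dS[i])
  }
  special <- c("INIT_STRONG", "INIT_WEAK", "DANGLE_AVG", "MM_TERM_AVG",
               "MM_INT_AVG", "SALT_COEFF")
  stacks <- tab[!(tab$key %in% special), ]
  if (any(nchar(stacks$key) != 2L))
    stop("stack rows must be keyed by base dimers", call. = FALSE)
  stack_dH <- stats::setNames(stacks$dH, stacks$key)
  stack_dS <- stats::setNames(stacks$dS, stacks$key)
  if (any(stack_dH >= 0))
    stop("stabilizing stacks must have negative enthalpy", call. = FALSE)
  p <- structure(list(
    stack_dH = stack_dH, stack_dS = stack_dS,
    init_dH = c(strong = row("INIT_STRONG")[["dH"]],
                weak = row("INIT_WEAK")[["dH"]]),
    init_dS = c(strong = row("INIT_STRONG")[["dS"]],
                weak = row("INIT_WEAK")[["dS"]]),
    dangle = row("DANGLE_AVG"),
    mm_term = row("MM_TERM_AVG"),
    mm_int = row("MM_INT_AVG"),
    salt_coeff = row("SALT_COEFF")[["dH"]],
    na_molar = na_molar,
    stack_override = NULL, init_override = NULL,
    source = file), class = "nn_params")
  .validate_quartets(p, dna_alphabet())
  p
}

.validate_quartets <- function(params, alphabet) {
  if (!is.null(params$stack_override)) return(invisible(TRUE))
  need <- as.vector(outer(alphabet$bases, alphabet$bases, paste0))
  miss <- setdiff(need, names(params$stack_dH))
  if (length(miss))
    stop(sprintf("stack table lacks quartet(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' @export
print.nn_params <- function(x, ...) {
  cat("<nn_params>", if (is.null(x$stack_override))
    sprintf("%d stacked quartets", length(x$stack_dH))
    else sprintf("uniform stack (dH %.2f, dS %.2f)",
                 x$stack_override[["dH"]], x$stack_override[["dS"]]),
    sprintf("| Na+ %.3g M\n", x$na_molar))
  cat(sprintf("  increments (dH kcal/mol, dS cal/mol/K): dangle %.2f/%.2f, term mm %.2f/%.2f, int mm %.2f/%.2f\n",
              x$dangle[["dH"]], x$dangle[["dS"]],
              x$mm_term[["dH"]], x$mm_term[["dS"]],
              x$mm_int[["dH"]], x$mm_int[["dS"]]))
  invisible(x)
}

#' Entropy-only sodium correction
#'
#' Applies the unified NN salt correction
#' `dS(Na+) = dS(1 M) + salt_coeff * n_stacks * ln([Na+])`. The enthalpy is
#' left unchanged; at 1 M the correction vanishes.
#'
#' @param dS entropy at the 1 M reference, cal/(mol K).
#' @param n_stacks number of intact stacks of the duplex.
#' @param na_molar sodium concentration, mol/L (> 0).
#' @param salt_coeff correction coefficient, cal/(mol K) per stack.
#' @return corrected entropy, cal/(mol K).
#' @export
salt_correct <- function(dS, n_stacks, na_molar, salt_coeff = 0.368) {
  if (any(na_molar <= 0))
    stop("sodium concentration must be positive", call. = FALSE)
  dS + salt_coeff * n_stacks * log(na_molar)
}

# mean stack over the dimers built from a base subset
.subset_stack_mean <- function(params, bases) {
  dimers <- as.vector(outer(bases, bases, paste0))
  c(dH = mean(params$stack_dH[dimers]), dS = mean(params$stack_dS[dimers]))
}

#' Counterfactual energetics
#'
#' `all_cg_params()` replaces every stack by the average over the CG-only
#' quartets (all pairing energies as strong as C-G). `two_base_params()`
#' builds the energetics of a two-letter alphabet: a single stack value
#' intermediate between the AT-average and CG-average (their arithmetic
#' mean) and a composition-free initiation. `uniform_avg_params()` freezes
#' the stack at the composition-uniform (`f_CG = 0.5`) average, used for
#' alphabets with more than four bases, for which no measured stacking
#' tables exist.
#'
#' @param params an [nn_params()] object to derive from.
#' @return an `nn_params` object with `stack_override` (and, where noted,
#'   `init_override`) set; the averaged defect increments are inherited.
#' @export
all_cg_params <- function(params = nn_params()) {
  params$stack_override <- .subset_stack_mean(params, c("C", "G"))
  params
}

#' @rdname all_cg_params
#' @export
two_base_params <- function(params = nn_params()) {
  at <- .subset_stack_mean(params, c("A", "T"))
  cg <- .subset_stack_mean(params, c("C", "G"))
  params$stack_override <- (at + cg) / 2
  params$init_override <- c(dH = mean(params$init_dH),
                            dS = mean(params$init_dS))
  params
}

#' @rdname all_cg_params
#' @export
uniform_avg_params <- function(params = nn_params()) {
  params$stack_override <- c(dH = mean(params$stack_dH),
                             dS = mean(params$stack_dS))
  params$init_override <- c(dH = mean(params$init_dH),
                            dS = mean(params$init_dS))
  params
}

#' Composition-averaged nearest-neighbor parameters
#'
#' Expectation of the stack enthalpy/entropy over quartets whose bases are
#' drawn independently -- strong bases with total probability `f_CG`
#' (uniform within the strong class), weak with `1 - f_CG` -- together with
#' the composition-averaged duplex initiation (both termini) and the
#' averaged per-defect increments. This is the energetic backbone of the
#' defect-vector parametrization: detailed sequences are replaced by their
#' composition class.
#'
#' @param f_CG strong-base fraction in `[0, 1]`.
#' @param params an [nn_params()] object.
#' @param alphabet an [rs_alphabet()].
#' @return list with components `stack`, `init` (both termini), `dangle`,
#'   `mm_term`, `mm_int`, each a `c(dH, dS)` vector.
#' @export
averaged_nn_params <- function(f_CG, params = nn_params(),
                               alphabet = dna_alphabet()) {
  if (f_CG < 0 || f_CG > 1) stop("f_CG must lie in [0, 1]", call. = FALSE)
  if (is.null(params$stack_override)) {
    .validate_quartets(params, alphabet)
    b <- alphabet$bases
    strong <- b %in% alphabet$strong
    p <- ifelse(strong, f_CG / sum(strong), (1 - f_CG) / sum(!strong))
    names(p) <- b
    dimers <- names(params$stack_dH)
    w <- p[substr(dimers, 1, 1)] * p[substr(dimers, 2, 2)]
    stack <- c(dH = sum(w * params$stack_dH), dS = sum(w * params$stack_dS))
  } else {
    stack <- params$stack_override
  }
  if (is.null(params$init_override)) {
    init <- 2 * c(dH = f_CG * params$init_dH[["strong"]] +
                    (1 - f_CG) * params$init_dH[["weak"]],
                  dS = f_CG * params$init_dS[["strong"]] +
                    (1 - f_CG) * params$init_dS[["weak"]])
  } else {
    init <- 2 * params$init_override
  }
  list(stack = stack, init = init, dangle = params$dangle,
       mm_term = params$mm_term, mm_int = params$mm_int)
}
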