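#' Parameters of the reduced gene circuit
#'
#' Bundles the parameters of the reduced model of a bursty, self-activating
#' gene titrated by decoy binding sites. Time is measured in units of the free
#' protein lifetime, so the free-protein decay rate constant is 1 by
#' construction and is not a parameter; concentrations are in molecules per
#' cell.
#'
#' @param a0 Basal transcription (burst) rate, bursts per free-protein
#'   lifetime. Non-negative.
#' @param a1 Regulable transcription rate increment: the difference between
#'   the fully up-regulated and the basal burst rate, bursts per lifetime.
#'   Non-negative.
#' @param kp Dissociation constant for protein binding at its own promoter,
#'   molecules. Positive.
#' @param b Mean burst size, molecules. Positive.
#' @param y Total decoy binding-site concentration, molecules; constant in
#'   time. Non-negative.
#' @param kb Dissociation constant for protein binding at decoy sites,
#'   molecules. Positive.
#' @param gamma_b Decay rate constant of decoy-bound protein relative to free
#'   protein. `gamma_b = 1` means binding does not affect degradation;
#'   `gamma_b = 0` means bound protein is fully protected from decay.
#'
#' @return An object of class `gene_params`: a named list with the seven
#'   fields above.
#' @examples
#' ## The bimodal reference circuit (tight decoys, weak promoter):
#' gene_params(a0 = 0.75, a1 = 25, kp = 500, b = 50, y = 100, kb = 1)
#' @export
gene_params <- function(a0, a1, kp, b, y = 0, kb = 1, gamma_b = 1) {
  p <- list(a0 = a0, a1 = a1, kp = kp, b = b, y = y, kb = kb,
            gamma_b = gamma_b)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("'", nm, "' must be a single finite numeric value")
  }
  if (a0 < 0 || a1 < 0 || y < 0 || gamma_b < 0)
    stop("'a0', 'a1', 'y' and 'gamma_b' must be non-negative")
  if (kp <= 0 || kb <= 0 || b <= 0)
    stop("'kp', 'kb' and 'b' must be positive")
  structure(p, class = "gene_params")
}

#' @export
print.gene_params <- function(x, ...) {
  cat("Gene circuit parameters (time unit: free-protein lifetime)\n")
  cat(sprintf("  burst rate     : a0 = %g, a1 = %g (bursts/lifetime), kp = %g\n",
              x$a0, x$a1, x$kp))
  cat(sprintf("  burst size     : b = %g molecules (exponential mean)\n", x$b))
  cat(sprintf("  decoy sites    : y = %g, kb = %g\n", x$y, x$kb))
  cat(sprintf("  bound decay    : gamma_b = %g (free protein decays at rate 1)\n",
              x$gamma_b))
  invisible(x)
}

as_gene_params <- function(params) {
  if (inherits(params, "gene_params")) return(params)
  if (is.list(params) || is.numeric(params)) {
    params <- as.list(params)
    return(do.call(gene_params, params[intersect(
      names(params), c("a0", "a1", "kp", "b", "y", "kb", "gamma_b"))]))
  }
  stop("'params' must be a gene_params object or a named list")
}

#' Free, bound and total protein at quasi-steady-state binding
#'
#' The binding and unbinding of protein at decoy sites is assumed to
#' equilibrate instantaneously (quasi-steady-state), which ties the free
#' concentration `xf`, the bound concentration `xb` and the total `x = xf + xb`
#' together algebraically: `xb = y * xf / (xf + kb)`.
#'
#' `free_from_total()` inverts this relation, giving
#' `xf = (x - y - kb + sqrt((kb + y - x)^2 + 4 kb x)) / 2`; the evaluation is
#' rearranged to avoid cancellation when `x < y + kb`. `total_from_free()` and
#' `bound_from_free()` are the forward maps.
#'
#' @param x Total protein concentration(s), molecules; non-negative.
#' @param xf Free protein concentration(s), molecules; non-negative.
#' @param params A [gene_params()] object.
#'
#' @return Numeric vector of the same length as the input concentration.
#'   `free_from_total()` lies in `[max(0, x - y), x]`; `bound_from_free()`
#'   lies in `[0, y)`.
#' @examples
#' p <- gene_params(a0 = 0.75, a1 = 25, kp = 500, b = 50, y = 100, kb = 1)
#' free_from_total(101, p)        # ~10: most protein is sequestered
#' total_from_free(1, p)          # 51: half of the decoys are occupied
#' @export
free_from_total <- function(x, params) {
  params <- as_gene_params(params)
  if (any(x < 0)) stop("total protein 'x' must be non-negative")
  d <- params$kb + params$y - x
  s <- sqrt(d^2 + 4 * params$kb * x)
  # rationalized branch where the naive difference cancels (d > 0)
  ifelse(d > 0, 2 * params$kb * x / (s + d), (s - d) / 2)
}

#' @rdname free_from_total
#' @export
total_from_free <- function(xf, params) {
  params <- as_gene_params(params)
  if (any(xf < 0)) stop("free protein 'xf' must be non-negative")
  xf + params$y * xf / (xf + params$kb)
}

#' @rdname free_from_total
#' @export
bound_from_free <- function(xf, params) {
  params <- as_gene_params(params)
  if (any(xf < 0)) stop("free protein 'xf' must be non-negative")
  params$y * xf / (xf + params$kb)
}

#' Degradation and burst rates of the reduced process
#'
#' `degradation_rate()` is the total protein decay flux
#' `c(x) = xf + gamma_b * (x - xf)`: free protein decays at rate 1 (the time
#' unit), bound protein at rate `gamma_b`. `burst_rate()` is the
#' state-dependent burst hazard `a(x) = a0 + a1 * xf / (kp + xf)` of
#' non-cooperative positive autoregulation, bounded in `[a0, a0 + a1]`.
#' Both take total protein `x` and resolve the free fraction via
#' [free_from_total()].
#'
#' @inheritParams free_from_total
#' @return Numeric vector of rates, same length as `x`.
#' @examples
#' p <- gene_params(a0 = 0.75, a1 = 25, kp = 500, b = 50, y = 100, kb = 1)
#' degradation_rate(101, p)  # equals 101 since gamma_b = 1
#' burst_rate(0, p)          # basal rate a0
#' @export
degradation_rate <- function(x, params) {
  params <- as_gene_params(params)
  if (any(x < 0)) stop("total protein 'x' must be non-negative")
  xf <- free_from_total(x, params)
  xf + params$gamma_b * (x - xf)
}

#' @rdname degradation_rate
#' @export
burst_rate <- function(x, params) {
  params <- as_gene_params(params)
  if (any(x < 0)) stop("total protein 'x' must be non-negative")
  xf <- free_from_total(x, params)
  params$a0 + params$a1 * xf / (params$kp + xf)
}
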