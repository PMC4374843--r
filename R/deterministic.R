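#' Deterministic rate equation of the reduced circuit
#'
#' Neglecting fluctuations, the total protein concentration obeys the
#' autonomous rate equation `dx/dt = b*a(x) - c(x)`: mean burst influx
#' balancing the total decay flux. `ode_rhs()` evaluates the right-hand side.
#'
#' @param x Total protein concentration(s), non-negative.
#' @param params A [gene_params()] object.
#' @return Numeric vector, same length as `x`.
#' @export
ode_rhs <- function(x, params) {
  p <- as_gene_params(params)
  p$b * burst_rate(x, p) - degradation_rate(x, p)
}

#' Steady states and bistability of the deterministic model
#'
#' Solves the steady-state balance `b*a = c` in the free-protein coordinate,
#' \deqn{b a_0 + b a_1 x_f/(k_p+x_f) = x_f + \gamma_b y x_f/(x_f+k_b),}
#' by a sign scan over a log-spaced grid followed by bisection (the same
#' root-finding strategy as the modality analysis, for cross-module
#' comparability). Stability is read off from the sign of the rate `dx/dt`
#' just below and just above each steady state in the total-protein
#' coordinate. With no decoys (`y = 0`) or fully protected bound protein
#' (`gamma_b = 0`) the balance has exactly one solution and bistability is
#' impossible; with equal decay (`gamma_b = 1`) the steady-state condition
#' coincides, up to the factor `b`, with the log-scale extremum condition of
#' [extremum_function()], so bistability is equivalent to log-scale
#' bimodality.
#'
#' @param params A [gene_params()] object.
#' @param xf_range,n_scan Root-scan window and resolution.
#' @return An object of class `steady_state_set`: list with `roots_xf`,
#'   `roots_x`, `stability` (`"stable"`/`"unstable"`), and logical
#'   `bistable`.
#' @examples
#' p <- gene_params(a0 = 0.75, a1 = 25, kp = 500, b = 50, y = 100, kb = 1)
#' steady_states(p)   # three states, outer two stable
#' @export
steady_states <- function(params, xf_range = c(1e-8, 1e8), n_scan = 2000) {
  p <- as_gene_params(params)
  g <- function(xf) {
    p$b * (p$a0 + p$a1 * xf / (p$kp + xf)) - xf -
      p$gamma_b * p$y * xf / (xf + p$kb)
  }
  grid <- exp(seq(base::log(xf_range[1]), base::log(xf_range[2]),
                  length.out = n_scan))
  v <- g(grid)
  s <- sign(v)
  idx <- which(s[-1] * s[-length(s)] < 0)
  roots_xf <- vapply(idx, function(i) {
    stats::uniroot(g, c(grid[i], grid[i + 1]),
                   tol = .Machine$double.eps^0.75 * grid[i + 1])$root
  }, numeric(1))
  if (p$a0 == 0 && g(grid[1]) <= 0) roots_xf <- c(0, roots_xf)
  roots_x <- total_from_free(roots_xf, p)
  stability <- vapply(roots_x, function(x0) {
    eps <- max(x0, 1) * 1e-4
    lo <- ode_rhs(max(x0 - eps, 0), p)
    hi <- ode_rhs(x0 + eps, p)
    if (lo > 0 && hi < 0) "stable" else "unstable"
  }, character(1))
  structure(list(roots_xf = roots_xf, roots_x = roots_x,
                 stability = stability,
                 bistable = sum(stability == "stable") >= 2),
            class = "steady_state_set")
}

#' @export
print.steady_state_set <- function(x, ...) {
  cat(sprintf("Deterministic steady states (%d found)%s\n", length(x$roots_x),
              if (x$bistable) " - bistable" else ""))
  if (length(x$roots_x))
    print(data.frame(xf = signif(x$roots_xf, 6), x = signif(x$roots_x, 6),
                     stability = x$stability))
  invisible(x)
}

#' Bistability versus log-scale bimodality
#'
#' For equal decay of free and bound protein (`gamma_b = 1`), deterministic
#' bistability and bimodality of the log10-scale stationary density are
#' equivalent: the steady-state balance is `b` times the log-scale extremum
#' function. This helper computes both classifications independently (one
#' from [steady_states()], one from [count_modes()]) so the equivalence can
#' be checked rather than assumed.
#'
#' @param params A [gene_params()] object with `gamma_b = 1`.
#' @param xf_range,n_scan Root-scan window and resolution, shared by both
#'   classifications (a mismatch in scan windows, not in the mathematics,
#'   would otherwise be able to produce spurious disagreements near
#'   tangencies or at extreme roots).
#' @return Named logical vector `c(bistable = , log_bimodal = )`.
#' @export
bistability_equivalence <- function(params, xf_range = c(1e-8, 1e8),
                                    n_scan = 2000) {
  p <- as_gene_params(params)
  if (p$gamma_b != 1)
    stop("the bistability/bimodality equivalence holds for gamma_b = 1 only")
  ss <- steady_states(p, xf_range = xf_range, n_scan = n_scan)
  md <- count_modes(p, "log10", xf_range = xf_range, n_scan = n_scan)
  c(bistable = ss$bistable, log_bimodal = md$n_modes >= 2)
}
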