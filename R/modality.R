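#' Extremum and tangency conditions for the stationary density
#'
#' For equal decay of free and bound protein (`gamma_b = 1`, where the total
#' decay flux is simply `c = x`), the locations of local extrema of the
#' stationary density reduce to root-finding in the free-protein coordinate.
#' On the linear scale, `dp/dx = 0` at the `x` associated with `xf` iff
#' \deqn{a_0 + a_1 x_f/(k_p+x_f) - x_f/b - y x_f/(b(x_f+k_b)) - 1 = 0;}
#' on the log10 scale the same expression without the trailing `-1` applies.
#' The number of extrema changes where the extremum function crosses zero
#' tangentially, i.e. where its `xf`-derivative
#' \deqn{a_1 k_p/(k_p+x_f)^2 - 1/b - y k_b/(b(x_f+k_b)^2)}
#' vanishes as well; the tangency condition is shared by both scales because
#' the two extremum functions differ only by an additive constant.
#'
#' @param xf Free protein concentration(s), positive.
#' @param params A [gene_params()] object with `gamma_b = 1` (the analytic
#'   conditions are derived for equal decay; for other `gamma_b` use the
#'   numeric route in [count_modes()]).
#' @param scale `"linear"` or `"log10"`.
#' @return Numeric vector of function values.
#' @export
extremum_function <- function(xf, params, scale = c("linear", "log10")) {
  scale <- match.arg(scale)
  p <- as_gene_params(params)
  if (p$gamma_b != 1)
    stop("analytic extremum conditions require gamma_b = 1; ",
         "use count_modes(..., method = \"numeric\") otherwise")
  if (any(xf <= 0)) stop("'xf' must be positive")
  v <- p$a0 + p$a1 * xf / (p$kp + xf) - xf / p$b -
    p$y * xf / (p$b * (xf + p$kb))
  if (scale == "linear") v - 1 else v
}

#' @rdname extremum_function
#' @export
tangency_function <- function(xf, params) {
  p <- as_gene_params(params)
  if (p$gamma_b != 1)
    stop("analytic tangency condition requires gamma_b = 1")
  if (any(xf <= 0)) stop("'xf' must be positive")
  p$a1 * p$kp / (p$kp + xf)^2 - 1 / p$b - p$y * p$kb / (p$b * (xf + p$kb)^2)
}

## sign-scan + bisection root finder on a log-spaced xf grid.
## Returns data.frame(xf, kind) with kind in {maximum, minimum} by
## crossing direction (+ -> - is a maximum of the density).
scan_roots <- function(f, xf_range = c(1e-4, 1e6), n_scan = 2000) {
  grid <- exp(seq(base::log(xf_range[1]), base::log(xf_range[2]),
                  length.out = n_scan))
  v <- f(grid)
  s <- sign(v)
  idx <- which(s[-1] * s[-length(s)] < 0)
  if (!length(idx))
    return(data.frame(xf = numeric(0), kind = character(0)))
  roots <- vapply(idx, function(i) {
    stats::uniroot(f, c(grid[i], grid[i + 1]),
                   tol = .Machine$double.eps^0.75 * grid[i + 1])$root
  }, numeric(1))
  kind <- ifelse(v[idx] > 0, "maximum", "minimum")
  data.frame(xf = roots, kind = kind, stringsAsFactors = FALSE)
}

#' Count the modes of the stationary density
#'
#' Classifies the stationary density of total protein as unimodal,
#' bimodal, ... on the linear or log10 scale. For `gamma_b = 1` the analytic
#' extremum conditions of [extremum_function()] are used; otherwise the modes
#' are located numerically on a [stationary_density()] grid. On the linear
#' scale a power-law divergence of the density at zero (origin exponent
#' `q1 = a0*(kb+y)/(kb+gamma_b*y) < 1`) counts as a low-expression singular
#' mode; at `q1 >= 1` the origin is not a mode. On the log10 scale the density
#' always vanishes at the lower end (for `a0 > 0`), so only interior maxima
#' count.
#'
#' @param params A [gene_params()] object with `a0 > 0`.
#' @param scale `"linear"` or `"log10"` (of total protein).
#' @param method `"auto"` (analytic when `gamma_b = 1`), `"analytic"`, or
#'   `"numeric"`.
#' @param xf_range,n_scan Root-scan window and resolution (analytic route).
#' @param n_grid Grid size for the numeric route.
#' @return An object of class `modality_report`: list with `scale`,
#'   `n_modes`, `mode_locations_x` (0 denotes the singular origin mode),
#'   `origin_behavior` (`"singular"`, `"finite"`, `"vanishing"`), `extrema`
#'   (data.frame of interior extrema), and `method`.
#' @examples
#' p <- gene_params(a0 = 0.75, a1 = 25, kp = 500, b = 50, y = 100, kb = 1)
#' count_modes(p, "log10")$n_modes   # 2: basal and up-regulated mode
#' @export
count_modes <- function(params, scale = c("linear", "log10"),
                        method = c("auto", "analytic", "numeric"),
                        xf_range = c(1e-4, 1e6), n_scan = 2000,
                        n_grid = 2048) {
  scale <- match.arg(scale)
  method <- match.arg(method)
  p <- as_gene_params(params)
  if (p$a0 <= 0)
    stop("mode counting requires a0 > 0 (the stationary law is ",
         "non-normalizable at a0 = 0)")
  if (method == "auto") method <- if (p$gamma_b == 1) "analytic" else "numeric"
  q1 <- origin_exponent(p)
  origin <- if (q1 < 1 - 1e-12) "singular"
            else if (q1 <= 1 + 1e-12) "finite" else "vanishing"
  if (method == "analytic") {
    ext <- scan_roots(function(u) extremum_function(u, p, scale),
                      xf_range, n_scan)
    ext$x <- total_from_free(ext$xf, p)
  } else {
    g <- stationary_density(p, n_grid = n_grid)
    v <- if (scale == "linear") g$density else g$density * g$x
    n <- length(v)
    i <- 2:(n - 1)
    is_max <- v[i] > v[i - 1] & v[i] >= v[i + 1] &
      v[i] > 1e-12 * max(v)       # relative prominence floor
    xm <- g$x[i][is_max]
    ## interior minima between consecutive maxima (for the report only)
    ext <- data.frame(xf = free_from_total(xm, p), kind = rep("maximum",
                      length(xm)), x = xm, stringsAsFactors = FALSE)
  }
  maxima_x <- ext$x[ext$kind == "maximum"]
  if (scale == "linear" && origin == "singular") {
    n_modes <- length(maxima_x) + 1L
    locs <- c(0, maxima_x)
  } else {
    n_modes <- length(maxima_x)
    locs <- maxima_x
  }
  structure(list(scale = scale, n_modes = n_modes, mode_locations_x = locs,
                 origin_behavior = origin, extrema = ext, method = method),
            class = "modality_report")
}

#' @export
print.modality_report <- function(x, ...) {
  cat(sprintf("Stationary density on the %s scale: %d mode(s) at x = %s\n",
              x$scale, x$n_modes,
              paste(signif(x$mode_locations_x, 4), collapse = ", ")))
  cat(sprintf("  origin: %s; method: %s\n", x$origin_behavior, x$method))
  invisible(x)
}

#' Unimodal/bimodal boundary curves in the (a0, kp) plane
#'
#' Traces the curves along which the number of modes of the stationary
#' density changes, in the cross-section of parameter space spanned by the
#' basal rate `a0` and the promoter dissociation constant `kp` (all other
#' parameters held fixed, equal decay `gamma_b = 1`). The curves are
#' parameterized by the free-protein level `xf` at which the extremum
#' function crosses zero tangentially: for each `xf` the tangency condition
#' is a quadratic in `kp`,
#' `R*kp^2 + (2*R*xf - a1)*kp + R*xf^2 = 0` with
#' `R = (1 + y*kb/(xf+kb)^2)/b`, yielding up to two positive roots (branches
#' `"plus"` and `"minus"` by the sign in the quadratic formula); `a0` then
#' follows from the extremum condition. The log-scale boundary is the
#' linear-scale boundary translated by exactly 1 leftward along the `a0`
#' axis. In the reference cross-sections only the `"plus"` family is
#' physical (`a0 > 0`); viewed in the `(a0, kp)` plane it folds back on
#' itself, and the two sides of the fold are the two boundary arcs that
#' enclose the bimodal region when decoys are present.
#'
#' @param a1,b,y,kb Fixed circuit parameters (`gamma_b = 1` implied).
#' @param xf Parameterizing free-protein grid; default log-spaced.
#' @param scale `"linear"` or `"log10"`.
#' @param drop_invalid Drop points with `a0 <= 0` (outside the physical
#'   quadrant)? Set `FALSE` to keep full matched sweeps across scales.
#' @return A data.frame of class `boundary_curve` with columns `scale`,
#'   `branch` (`"plus"`/`"minus"`), `xf`, `kp`, `a0`; zero rows when no
#'   tangency exists (no bimodal region).
#' @examples
#' bc <- boundary_curve(a1 = 25, b = 50, y = 100, kb = 1)
#' ## the physical family folds in kp, enclosing the bimodal region
#' range(bc$kp)
#' @export
boundary_curve <- function(a1, b, y = 0, kb = 1,
                           xf = 10^seq(-3, 6, length.out = 600),
                           scale = c("linear", "log10"),
                           drop_invalid = TRUE) {
  scale <- match.arg(scale)
  stopifnot(all(xf > 0), !is.unsorted(xf))
  R <- (1 + y * kb / (xf + kb)^2) / b
  disc <- a1 * (a1 - 4 * R * xf)
  ok <- disc >= 0
  if (!any(ok))
    return(structure(data.frame(scale = character(0), branch = character(0),
                                xf = numeric(0), kp = numeric(0),
                                a0 = numeric(0)),
                     class = c("boundary_curve", "data.frame")))
  xf <- xf[ok]; R <- R[ok]; disc <- disc[ok]
  kp_up <- ((a1 - 2 * R * xf) + sqrt(disc)) / (2 * R)
  kp_lo <- ((a1 - 2 * R * xf) - sqrt(disc)) / (2 * R)
  shift <- if (scale == "linear") 1 else 0
  a0_of <- function(kp) {
    shift + xf / b + y * xf / (b * (xf + kb)) - a1 * xf / (kp + xf)
  }
  out <- rbind(
    data.frame(scale = scale, branch = "plus", xf = xf, kp = kp_up,
               a0 = a0_of(kp_up), stringsAsFactors = FALSE),
    data.frame(scale = scale, branch = "minus", xf = xf, kp = kp_lo,
               a0 = a0_of(kp_lo), stringsAsFactors = FALSE))
  out <- out[out$kp > 0, , drop = FALSE]
  if (drop_invalid) out <- out[out$a0 > 0, , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("boundary_curve", "data.frame"))
}

#' Mode-count phase diagram over the (a0, kp) plane
#'
#' Evaluates [count_modes()] on a rectangular grid of basal rates `a0` and
#' promoter dissociation constants `kp`, all other parameters fixed. For
#' `gamma_b = 1` the analytic route is used; otherwise each cell is
#' classified numerically from its density grid.
#'
#' @param a1,b,y,kb,gamma_b Fixed circuit parameters.
#' @param a0,kp Numeric vectors of grid values (positive).
#' @param scale `"linear"` or `"log10"`.
#' @param ... Passed on to [count_modes()].
#' @return A data.frame with columns `a0`, `kp`, `n_modes`.
#' @export
phase_diagram <- function(a1, b, y = 0, kb = 1, gamma_b = 1,
                          a0 = seq(0.1, 4, length.out = 20),
                          kp = seq(25, 1500, length.out = 20),
                          scale = c("linear", "log10"), ...) {
  scale <- match.arg(scale)
  stopifnot(all(a0 > 0), all(kp > 0))
  cells <- expand.grid(a0 = a0, kp = kp)
  cells$n_modes <- vapply(seq_len(nrow(cells)), function(i) {
    p <- gene_params(a0 = cells$a0[i], a1 = a1, kp = cells$kp[i], b = b,
                     y = y, kb = kb, gamma_b = gamma_b)
    count_modes(p, scale, ...)$n_modes
  }, integer(1))
  cells
}
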