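#' Closed-form exponents of the stationary density
#'
#' The stationary density of total protein for the reduced burst process can
#' be written, up to normalization, as
#' \deqn{p(x) \propto e^{-x/b}\, x_f^{q_1-1} (x_f+k_p)^{q_2}
#'       (x_f+k_b)^{q_3+1} (x_f+k_b+\gamma_b y)^{q_4-1},}
#' where `xf` is the free-protein concentration associated with `x`. The four
#' exponents are the partial-fraction residues of the integrand `a(x)/c(x)`
#' expressed in the free-protein coordinate:
#' \deqn{q_1 = a_0 (k_b+y)/(k_b+\gamma_b y)}
#' \deqn{q_2 = \frac{a_1 (k_p-k_b)}{k_p-k_b-\gamma_b y}
#'            \left(1 + \frac{y k_b}{(k_p-k_b)^2}\right)}
#' \deqn{q_3 = (a_1 k_b/(k_p-k_b) - a_0)/\gamma_b}
#' \deqn{q_4 = \frac{\gamma_b^2 y + k_b}{\gamma_b}
#'            \left(\frac{a_0}{k_b+\gamma_b y} +
#'                  \frac{a_1}{k_b-k_p+\gamma_b y}\right)}
#'
#' The closed form breaks down (repeated or coincident poles) when
#' `kp = kb`, `kp = kb + gamma_b*y`, or `gamma_b*y = 0`; in those cases the
#' returned object is flagged invalid and the quadrature path
#' ([unnormalized_density_quadrature()]) must be used instead.
#'
#' @param params A [gene_params()] object.
#' @param tol Relative tolerance used to detect the degenerate parameter
#'   combinations above.
#' @return An object of class `q_exponents`: list with fields `q1`--`q4`
#'   (NA when invalid) and a logical `valid`.
#' @examples
#' q_exponents(gene_params(a0 = 0.75, a1 = 25, kp = 500, b = 50, y = 100, kb = 1))
#' @export
q_exponents <- function(params, tol = 1e-9) {
  p <- as_gene_params(params)
  scale_k <- max(p$kp, p$kb, p$gamma_b * p$y)
  degenerate <- (abs(p$kp - p$kb) <= tol * scale_k) ||
    (abs(p$kp - p$kb - p$gamma_b * p$y) <= tol * scale_k) ||
    (p$gamma_b * p$y <= tol * (p$kb + p$y))
  if (degenerate) {
    return(structure(list(q1 = NA_real_, q2 = NA_real_, q3 = NA_real_,
                          q4 = NA_real_, valid = FALSE),
                     class = "q_exponents"))
  }
  gy <- p$gamma_b * p$y
  q1 <- p$a0 * (p$kb + p$y) / (p$kb + gy)
  q2 <- p$a1 * (p$kp - p$kb) / (p$kp - p$kb - gy) *
    (1 + p$y * p$kb / (p$kp - p$kb)^2)
  q3 <- (p$a1 * p$kb / (p$kp - p$kb) - p$a0) / p$gamma_b
  q4 <- (p$gamma_b^2 * p$y + p$kb) / p$gamma_b *
    (p$a0 / (p$kb + gy) + p$a1 / (p$kb - p$kp + gy))
  structure(list(q1 = q1, q2 = q2, q3 = q3, q4 = q4, valid = TRUE),
            class = "q_exponents")
}

#' @export
print.q_exponents <- function(x, ...) {
  if (!x$valid) {
    cat("Closed-form exponents unavailable (degenerate parameters);",
        "use the quadrature path.\n")
  } else {
    cat(sprintf("Stationary-density exponents: q1 = %.6g, q2 = %.6g, q3 = %.6g, q4 = %.6g\n",
                x$q1, x$q2, x$q3, x$q4))
  }
  invisible(x)
}

## exponent governing p(x) ~ x^(q-1) as x -> 0; defined for every gamma_b >= 0
origin_exponent <- function(params) {
  p <- as_gene_params(params)
  p$a0 * (p$kb + p$y) / (p$kb + p$gamma_b * p$y)
}

#' Unnormalized stationary density of total protein
#'
#' Two independent evaluation routes for the (unnormalized) stationary
#' density of total protein concentration. The closed form uses the exponents
#' of [q_exponents()]; the quadrature route evaluates
#' \deqn{p(x) \propto \frac{1}{c(x)}
#'   \exp\left(-x/b + \int^x a(x')/c(x')\,dx'\right)}
#' by adaptive quadrature of `a/c` in the free-protein coordinate (which tames
#' the integrable singularity at zero), with the arbitrary lower reference
#' point fixed at `x = 1` and absorbed into the normalization constant. The
#' quadrature route works for every parameter set, including the degenerate
#' combinations and `gamma_b = 0`; the two routes agree up to a single
#' multiplicative constant wherever both apply.
#'
#' @param x Total protein concentration(s), strictly positive.
#' @param params A [gene_params()] object.
#' @param q Optional precomputed [q_exponents()].
#' @param log If `TRUE`, return the log density (recommended for extreme
#'   parameter sets, where the unnormalized density over- or underflows).
#' @param rel_tol Relative tolerance of the adaptive quadrature.
#' @return Numeric vector of (log) unnormalized density values.
#' @seealso [stationary_density()] for the normalized density on a grid.
#' @export
unnormalized_density_closed <- function(x, params, q = q_exponents(params),
                                        log = FALSE) {
  p <- as_gene_params(params)
  if (!q$valid)
    stop("closed-form exponents are invalid for these parameters; ",
         "use unnormalized_density_quadrature()")
  if (any(x <= 0)) stop("'x' must be strictly positive")
  xf <- free_from_total(x, p)
  lf <- -x / p$b + (q$q1 - 1) * base::log(xf) +
    q$q2 * base::log(xf + p$kp) +
    (q$q3 + 1) * base::log(xf + p$kb) +
    (q$q4 - 1) * base::log(xf + p$kb + p$gamma_b * p$y)
  if (log) lf else exp(lf)
}

#' @rdname unnormalized_density_closed
#' @export
unnormalized_density_quadrature <- function(x, params, log = FALSE,
                                            rel_tol = 1e-10) {
  p <- as_gene_params(params)
  if (any(x <= 0)) stop("'x' must be strictly positive")
  integrand <- function(xf) {
    (p$a0 + p$a1 * xf / (p$kp + xf)) /
      (xf + p$gamma_b * p$y * xf / (xf + p$kb)) *
      (1 + p$y * p$kb / (xf + p$kb)^2)
  }
  xf_ref <- free_from_total(1, p)
  xf <- free_from_total(x, p)
  cx <- degradation_rate(x, p)
  lf <- vapply(seq_along(x), function(i) {
    I <- stats::integrate(integrand, xf_ref, xf[i],
                          rel.tol = rel_tol, abs.tol = 0)$value
    -base::log(cx[i]) - x[i] / p$b + I
  }, numeric(1))
  if (log) lf else exp(lf)
}

## composite 5-point Gauss-Legendre cumulative integral of f over the
## (increasing) knot sequence xs; returns I(xs[i]) with I(xs[1]) = 0
gl5_cumint <- function(f, xs) {
  gl_x <- c(-0.906179845938664, -0.5384693101056831, 0,
            0.5384693101056831, 0.906179845938664)
  gl_w <- c(0.2369268850561891, 0.4786286704993665, 0.5688888888888889,
            0.4786286704993665, 0.2369268850561891)
  a <- xs[-length(xs)]
  b <- xs[-1]
  h <- (b - a) / 2
  m <- (a + b) / 2
  panel <- numeric(length(h))
  for (j in seq_along(gl_x)) {
    panel <- panel + gl_w[j] * f(m + h * gl_x[j])
  }
  c(0, cumsum(panel * h))
}

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))

#' Normalized stationary density on a grid
#'
#' Evaluates the stationary density of total protein on a log-spaced grid and
#' normalizes it to unit mass. The closed form is used when available,
#' otherwise the quadrature route. The density may have an integrable
#' power-law singularity at zero (exponent `q1 - 1` with
#' `q1 = a0*(kb+y)/(kb+gamma_b*y)`, singular when `q1 < 1`); the probability
#' mass on `(0, x_lo]` is accounted for by an analytic power-law panel rather
#' than by brute-force gridding.
#'
#' @param params A [gene_params()] object with `a0 > 0` (at `a0 = 0` all
#'   stationary mass collapses onto zero and no density exists).
#' @param x_max Upper end of the grid; defaults to
#'   `max(20*b*(a0+a1), 10*(y+kb))`, which covers both the basal and the
#'   fully up-regulated expression scale.
#' @param n_grid Number of grid points.
#' @param x_lo Lower end of the explicit grid; mass below is handled
#'   analytically.
#' @return An object of class `density_grid`: list with fields `variable`
#'   (`"total_linear"`), `x` (abscissae), `density`, `log_kappa` (log of the
#'   normalization constant applied to the unnormalized form), `origin_mass`
#'   (probability mass on `(0, x_lo]`), `origin_exponent`, `normalized`,
#'   `method` (`"closed"` or `"quadrature"`), and `params`.
#' @examples
#' p <- gene_params(a0 = 0.75, a1 = 25, kp = 500, b = 50, y = 100, kb = 1)
#' g <- stationary_density(p)
#' plot(g$x, g$density, type = "l", log = "x")
#' @export
stationary_density <- function(params, x_max = NULL, n_grid = 4096,
                               x_lo = 1e-4) {
  p <- as_gene_params(params)
  if (p$a0 <= 0)
    stop("a0 = 0 gives a non-normalizable stationary law (all mass at 0)")
  if (is.null(x_max))
    x_max <- max(20 * p$b * (p$a0 + p$a1), 10 * (p$y + p$kb))
  xs <- exp(seq(base::log(x_lo), base::log(x_max), length.out = n_grid))
  q <- q_exponents(p)
  if (q$valid) {
    lf <- unnormalized_density_closed(xs, p, q, log = TRUE)
    method <- "closed"
  } else {
    ## cumulative quadrature of a/c in the free-protein coordinate;
    ## the reference constant is absorbed by the normalization
    integrand <- function(xf) {
      (p$a0 + p$a1 * xf / (p$kp + xf)) /
        (xf + p$gamma_b * p$y * xf / (xf + p$kb)) *
        (1 + p$y * p$kb / (xf + p$kb)^2)
    }
    xfs <- free_from_total(xs, p)
    I <- gl5_cumint(integrand, xfs)
    lf <- -base::log(degradation_rate(xs, p)) - xs / p$b + I
    method <- "quadrature"
  }
  shift <- max(lf)
  f <- exp(lf - shift)
  q1 <- origin_exponent(p)
  mass0 <- f[1] * xs[1] / q1   # \int_0^{x_lo} A t^{q1-1} dt with A matched at x_lo
  Z <- mass0 + trapz(xs, f)
  structure(list(variable = "total_linear", x = xs, density = f / Z,
                 log_kappa = -shift - base::log(Z), origin_mass = mass0 / Z,
                 origin_exponent = q1, normalized = TRUE, method = method,
                 params = p),
            class = "density_grid")
}

#' @export
print.density_grid <- function(x, ...) {
  cat(sprintf("Stationary density grid (%s, %d points on [%.3g, %.3g], %s form)\n",
              x$variable, length(x$x), min(x$x), max(x$x), x$method))
  cat(sprintf("  origin exponent %.4g (%s at 0), mass below grid %.3g\n",
              x$origin_exponent,
              if (x$origin_exponent < 1) "singular" else "bounded",
              x$origin_mass))
  invisible(x)
}

#' @export
as.data.frame.density_grid <- function(x, ...) {
  data.frame(variable = x$variable, abscissa = x$x, density = x$density)
}

#' Transform a stationary density to the free-protein variable
#'
#' Change of variables from total to free protein:
#' `p_free(xf) = p(x(xf)) * (1 + y*kb/(xf+kb)^2)`, the factor being the
#' Jacobian `dx/dxf` of the quasi-steady-state map. Probability mass is
#' conserved.
#'
#' @param grid A normalized `density_grid` with `variable = "total_linear"`.
#' @return A `density_grid` with `variable = "free_linear"`, abscissae on the
#'   free-protein axis.
#' @export
density_free <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  if (grid$variable != "total_linear")
    stop("density_free() expects a total_linear grid")
  p <- grid$params
  xf <- free_from_total(grid$x, p)
  jac <- 1 + p$y * p$kb / (xf + p$kb)^2
  out <- grid
  out$variable <- "free_linear"
  out$x <- xf
  out$density <- grid$density * jac
  out
}

#' Transform a stationary density to the log10 scale
#'
#' Change of variables to `z = log10(x)`:
#' `p_log(z) = p(10^z) * 10^z * ln(10)`. Applies to either the total- or the
#' free-protein linear density; probability mass is conserved. Even when the
#' linear density diverges at zero, the log-scale density vanishes as
#' `z -> -Inf` whenever `a0 > 0`.
#'
#' @param grid A normalized `density_grid` on a linear variable.
#' @return A `density_grid` on the corresponding `*_log10` variable.
#' @export
density_log10 <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  if (!grid$variable %in% c("total_linear", "free_linear"))
    stop("density_log10() expects a linear-variable grid")
  out <- grid
  out$variable <- sub("linear", "log10", grid$variable)
  out$x <- log10(grid$x)
  out$density <- grid$density * grid$x * base::log(10)
  out
}

#' Residual of the stationary balance equation
#'
#' The stationary density satisfies the first-order balance
#' `d/dx[c(x) p(x)] + c(x) p(x)/b = a(x) p(x)`. This helper evaluates the
#' residual of that identity on the interior of a density grid by central
#' differences; it is a verification device, not a user-facing computation.
#'
#' @param grid A `density_grid` with `variable = "total_linear"`.
#' @return Numeric vector of residuals at the interior grid points
#'   (length `length(grid$x) - 2`).
#' @export
stationary_ode_residual <- function(grid) {
  stopifnot(inherits(grid, "density_grid"))
  if (grid$variable != "total_linear")
    stop("residual is defined on the total_linear grid")
  p <- grid$params
  xs <- grid$x
  pv <- grid$density
  cp <- degradation_rate(xs, p) * pv
  n <- length(xs)
  dcp <- (cp[3:n] - cp[1:(n - 2)]) / (xs[3:n] - xs[1:(n - 2)])
  i <- 2:(n - 1)
  dcp + cp[i] / p$b - burst_rate(xs[i], p) * pv[i]
}

#' Cumulative distribution and quantile functions from a density grid
#'
#' Builds an interpolating CDF from a normalized total-protein density grid,
#' including the analytic power-law mass below the gridded range. The
#' quantile function is its numerical inverse on the grid.
#'
#' @param grid A normalized `density_grid` with `variable = "total_linear"`.
#' @return `stationary_cdf()`: a vectorized function `F(x)`;
#'   `stationary_quantile()`: a vectorized function `Q(p)`.
#' @export
stationary_cdf <- function(grid) {
  stopifnot(inherits(grid, "density_grid"), grid$variable == "total_linear")
  xs <- grid$x
  Fv <- grid$origin_mass +
    c(0, cumsum((grid$density[-1] + grid$density[-length(xs)]) / 2 * diff(xs)))
  Fv <- pmin(Fv, 1)
  fa <- stats::approxfun(xs, Fv, yright = Fv[length(Fv)], rule = 2)
  x_lo <- xs[1]
  m0 <- grid$origin_mass
  q1 <- grid$origin_exponent
  function(x) {
    out <- fa(pmax(x, x_lo))
    small <- x < x_lo
    if (any(small)) out[small] <- m0 * (pmax(x[small], 0) / x_lo)^q1
    out
  }
}

#' @rdname stationary_cdf
#' @export
stationary_quantile <- function(grid) {
  stopifnot(inherits(grid, "density_grid"), grid$variable == "total_linear")
  xs <- grid$x
  Fv <- grid$origin_mass +
    c(0, cumsum((grid$density[-1] + grid$density[-length(xs)]) / 2 * diff(xs)))
  keep <- c(TRUE, diff(Fv) > 0)
  qa <- stats::approxfun(Fv[keep], xs[keep], rule = 2)
  x_lo <- xs[1]
  m0 <- grid$origin_mass
  q1 <- grid$origin_exponent
  function(prob) {
    out <- qa(prob)
    small <- prob < m0
    if (any(small)) out[small] <- x_lo * (prob[small] / m0)^(1 / q1)
    out
  }
}
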