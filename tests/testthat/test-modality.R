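test_that("extremum and tangency functions have the stated roots and limits", {
  p <- fig1_params(y = 100)

  # small-xf limit of the log-scale extremum function is a0
  expect_equal(extremum_function(1e-9, p, "log10"), p$a0, tolerance = 1e-6)
  # the two scales differ by the constant 1
  xf <- 10^seq(-3, 5, length.out = 50)
  expect_equal(extremum_function(xf, p, "log10") -
                 extremum_function(xf, p, "linear"),
               rep(1, length(xf)))

  # linear scale: two sign changes, in the known brackets
  f <- function(u) extremum_function(u, p, "linear")
  expect_lt(f(100) * f(150), 0)
  expect_lt(f(300) * f(600), 0)
  # log scale: three sign changes
  g <- function(u) extremum_function(u, p, "log10")
  expect_lt(g(0.5) * g(0.7), 0)
  expect_lt(g(10) * g(50), 0)
  expect_lt(g(600) * g(1000), 0)

  # closed-form tangency root without decoys: xf = sqrt(a1*kp*b) - kp
  p0 <- fig1_params(y = 0)
  root <- sqrt(25 * 500 * 50) - 500
  expect_equal(tangency_function(root, p0), 0, tolerance = 1e-12)
  # limits: negative at large xf, always negative without feedback
  expect_lt(tangency_function(1e9, p), 0)
  pn <- gene_params(a0 = 1, a1 = 0, kp = 500, b = 50, y = 100, kb = 1)
  expect_true(all(tangency_function(10^seq(-3, 6, length.out = 40), pn) < 0))

  pg <- fig1_params(gamma_b = 0.5)
  expect_error(extremum_function(1, pg), "gamma_b = 1")
  expect_error(tangency_function(1, pg), "gamma_b = 1")
})

test_that("mode counting matches the known classifications", {
  # reference circuit: unimodal on log scale without decoys, bimodal with
  expect_equal(count_modes(fig1_params(y = 0), "log10")$n_modes, 1L)
  m <- count_modes(fig1_params(y = 100), "log10")
  expect_equal(m$n_modes, 2L)
  expect_equal(m$extrema$kind, c("maximum", "minimum", "maximum"))

  # gamma law: single interior mode at b*(a0-1)
  pg <- gene_params(a0 = 2, a1 = 0, kp = 500, b = 50)
  mg <- count_modes(pg, "linear")
  expect_equal(mg$n_modes, 1L)
  expect_equal(mg$mode_locations_x, 50, tolerance = 1e-6)
  expect_equal(mg$origin_behavior, "vanishing")

  # singular origin counts as a linear-scale mode below the a0 threshold;
  # the density falls from the singularity, dips, and peaks again
  ms <- count_modes(fig1_params(y = 100), "linear")
  expect_equal(ms$origin_behavior, "singular")
  expect_equal(ms$extrema$kind, c("minimum", "maximum"))
  expect_equal(ms$n_modes, 2L)          # singular origin + one interior peak
  expect_equal(ms$mode_locations_x[1], 0)

  # numeric route agrees with the analytic route at gamma_b = 1
  for (p in list(fig1_params(y = 100), fig1_params(y = 0), pg)) {
    for (s in c("linear", "log10")) {
      expect_equal(count_modes(p, s, method = "numeric", n_grid = 4096)$n_modes,
                   count_modes(p, s, method = "analytic")$n_modes,
                   info = paste(s, "y =", p$y))
    }
  }
  expect_error(count_modes(gene_params(a0 = 0, a1 = 5, kp = 10, b = 5),
                           "linear"), "a0 > 0")
})

test_that("extremum roots alternate in kind with the boundary limits", {
  set.seed(31)
  for (i in 1:40) {
    p <- gene_params(a0 = runif(1, 0.05, 4), a1 = runif(1, 0, 50),
                     kp = runif(1, 1, 1500), b = sample(c(10, 50, 100), 1),
                     y = runif(1, 0, 300), kb = runif(1, 0.1, 10))
    for (s in c("linear", "log10")) {
      ext <- count_modes(p, s)$extrema
      if (nrow(ext) > 1)
        expect_true(all(ext$kind[-1] != ext$kind[-nrow(ext)]))
      # parity: root count is odd iff the function changes overall sign
      f0 <- extremum_function(1e-4, p, s)
      finf <- extremum_function(1e6, p, s)
      expect_equal(nrow(ext) %% 2 == 1, sign(f0) != sign(finf))
    }
  }
})

test_that("boundary curves delimit the bimodal region and shift by 1 across scales", {
  # with decoys: the physical family folds back in the (a0, kp) plane,
  # enclosing the bimodal region between its two arcs; at a fixed a0 inside
  # the region the mode count changes exactly at the two curve crossings
  bc <- boundary_curve(a1 = 25, b = 50, y = 100, kb = 1,
                       xf = 10^seq(-3, 6, length.out = 4000))
  expect_true(all(bc$kp > 0) && all(bc$a0 > 0))
  expect_gt(max(bc$kp), 1000)
  pl <- bc[bc$branch == "plus", ]    # ordered by the xf parameterization
  cross <- which(diff(sign(pl$a0 - 2)) != 0)
  kp_cross <- sort(vapply(cross, function(i) {
    w <- (2 - pl$a0[i]) / (pl$a0[i + 1] - pl$a0[i])
    pl$kp[i] + w * (pl$kp[i + 1] - pl$kp[i])
  }, numeric(1)))
  expect_length(kp_cross, 2)    # the curve crosses a0 = 2 on two arcs
  kps <- c(kp_cross[1] * c(0.95, 1.05), kp_cross[2] * c(0.95, 1.05))
  nm <- vapply(kps, function(k)
    count_modes(gene_params(a0 = 2, a1 = 25, kp = k, b = 50, y = 100,
                            kb = 1), "linear")$n_modes, integer(1))
  expect_equal(nm, c(1L, 2L, 2L, 1L))

  # without decoys: the right edge of the bimodal region sits at a0 = 1
  bc0 <- boundary_curve(a1 = 25, b = 50, y = 0)
  expect_lt(max(bc0$a0), 1 + 1e-6)
  expect_gt(max(bc0$a0), 1 - 1e-3)

  # log-scale boundary = linear-scale boundary shifted 1 left in a0
  xf <- 10^seq(-2, 4, length.out = 150)
  lin <- boundary_curve(25, 50, 100, 1, xf = xf, scale = "linear",
                        drop_invalid = FALSE)
  lg <- boundary_curve(25, 50, 100, 1, xf = xf, scale = "log10",
                       drop_invalid = FALSE)
  expect_equal(nrow(lin), nrow(lg))
  expect_equal(lin$a0 - lg$a0, rep(1, nrow(lin)), tolerance = 1e-12)
  expect_equal(lin$kp, lg$kp)

  # no feedback: no tangency, empty boundary
  expect_equal(nrow(boundary_curve(a1 = 0, b = 50, y = 100)), 0L)

  # crossing the boundary transversally changes the mode count by exactly one
  pick <- bc[bc$branch == "plus" & bc$xf > 1 & bc$xf < 10, ]
  pick <- pick[seq(1, nrow(pick), length.out = 4), ]
  for (i in seq_len(nrow(pick))) {
    n_in <- count_modes(gene_params(a0 = pick$a0[i], a1 = 25,
                                    kp = pick$kp[i] * 0.99, b = 50, y = 100,
                                    kb = 1), "linear")$n_modes
    n_out <- count_modes(gene_params(a0 = pick$a0[i], a1 = 25,
                                     kp = pick$kp[i] * 1.01, b = 50, y = 100,
                                     kb = 1), "linear")$n_modes
    expect_equal(abs(n_in - n_out), 1L)
  }
})

test_that("phase diagrams are consistent with the boundary curves", {
  # log scale without decoys: unimodal everywhere
  pd0 <- phase_diagram(a1 = 25, b = 50, y = 0,
                       a0 = seq(0.25, 4, length.out = 8),
                       kp = seq(100, 1500, length.out = 8), scale = "log10")
  expect_true(all(pd0$n_modes == 1L))

  # with decoys: a non-empty bimodal region on the linear scale
  pd1 <- phase_diagram(a1 = 25, b = 50, y = 100,
                       a0 = seq(0.25, 4, length.out = 10),
                       kp = seq(100, 1500, length.out = 10), scale = "linear")
  expect_gt(sum(pd1$n_modes >= 2), 0)

  # protected decay (gamma_b = 0, numeric route): strictly smaller
  # multimodal region than equal decay on the same grid
  a0g <- seq(0.25, 4, length.out = 8)
  kpg <- seq(100, 1500, length.out = 8)
  pd_eq <- phase_diagram(a1 = 25, b = 50, y = 100, gamma_b = 1,
                         a0 = a0g, kp = kpg, scale = "linear")
  pd_pr <- phase_diagram(a1 = 25, b = 50, y = 100, gamma_b = 0,
                         a0 = a0g, kp = kpg, scale = "linear",
                         n_grid = 1024)
  expect_lt(sum(pd_pr$n_modes >= 2), sum(pd_eq$n_modes >= 2))
})
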