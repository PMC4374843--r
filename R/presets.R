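#' Reference parameter presets
#'
#' Named parameter sets for the worked examples shipped with the package.
#' The base circuit has a low basal rate (`a0 = 0.75` bursts per lifetime), a
#' strong regulable rate (`a1 = 25`), weak promoter binding (`kp = 500`),
#' tight decoy binding (`kb = 1`), and mean burst size `b = 50`:
#'
#' * `"fig1"` — the base circuit at decoy counts `y = 0, 50, 80, 100, 120`
#'   (a list of parameter sets); `"fig1-y0"` ... `"fig1-y120"` select one.
#' * `"fig2"` — the `(a0, kp)` cross-section fixed set without decoys
#'   (`a1 = 25`, `b = 50`, `y = 0`).
#' * `"fig3"` — the cross-section fixed set with `y = 100` decoys, equal
#'   decay (`gamma_b = 1`).
#' * `"fig4"` — as `"fig3"` but with decoy-bound protein protected from
#'   degradation (`gamma_b = 0`).
#' * `"s1fig"` — perturbations of the `"fig3"` set in `a1` and `b`,
#'   including a pair with the maximal regulable production `a1*b` held
#'   constant (a list of parameter sets).
#'
#' @param name Preset name (see above).
#' @return A [gene_params()] object, or a named list of them for the
#'   multi-set presets.
#' @examples
#' figure_preset("fig1-y100")
#' names(figure_preset("fig1"))
#' @export
figure_preset <- function(name) {
  base <- function(y, a1 = 25, b = 50, gamma_b = 1)
    gene_params(a0 = 0.75, a1 = a1, kp = 500, b = b, y = y, kb = 1,
                gamma_b = gamma_b)
  ys <- c(0, 50, 80, 100, 120)
  single <- grepl("^fig1-y[0-9]+$", name)
  if (single) {
    y <- as.numeric(sub("^fig1-y", "", name))
    if (!y %in% ys) stop("available fig1 decoy counts: ",
                         paste(ys, collapse = ", "))
    return(base(y))
  }
  switch(name,
    fig1 = stats::setNames(lapply(ys, base), paste0("y", ys)),
    fig2 = base(y = 0),
    fig3 = base(y = 100),
    fig4 = base(y = 100, gamma_b = 0),
    s1fig = list(
      reference  = base(y = 100),
      b25        = base(y = 100, b = 25),
      b100       = base(y = 100, b = 100),
      a1_12.5    = base(y = 100, a1 = 12.5),
      a1_50      = base(y = 100, a1 = 50),
      a1b_const1 = base(y = 100, a1 = 12.5, b = 100),
      a1b_const2 = base(y = 100, a1 = 50, b = 25)),
    stop("unknown preset '", name, "'")
  )
}
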