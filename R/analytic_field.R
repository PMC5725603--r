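#' Analytic surface-field fixtures with exact Laplacians
#'
#' Closed-form planar fields paired with their exact in-plane Laplacians,
#' used to verify the electrode estimators independently of the volume
#' solver.  Families:
#' \describe{
#'   \item{constant}{`v = k`; Laplacian 0.}
#'   \item{linear}{`v = a0 + ax x + ay y`; Laplacian 0.}
#'   \item{quadratic}{`v = x^2 + y^2`; Laplacian 4.}
#'   \item{monomial}{`v = x^px y^py`; Laplacian by term-wise
#'     differentiation.}
#'   \item{dipole}{surface potential of a point dipole of moment `m`
#'     (normal to the plane) at depth `d` below the plane in a homogeneous
#'     conductor `sigma`:
#'     `v = m d / (4 pi sigma (rho^2 + d^2)^{3/2})`.  Its in-plane
#'     Laplacian is `3 m d (3 rho^2 - 2 d^2) / (4 pi sigma (rho^2 +
#'     d^2)^{7/2})`; the full 3-D potential is harmonic away from the
#'     source.}
#' }
#'
#' @param family Field family name.
#' @param ... Family parameters: `value` (constant); `a0`, `ax`, `ay`
#'   (linear); `px`, `py` (monomial); `depth`, `moment`, `sigma` (dipole).
#' @return An object of class `analytic_field` with elements `surface`
#'   (function of x, y) and `laplacian` (function of x, y).
#' @export
make_analytic_field <- function(family = c("constant", "linear", "quadratic",
                                           "monomial", "dipole"), ...) {
  family <- match.arg(family)
  p <- list(...)
  f <- switch(family,
    constant = {
      k <- if (is.null(p$value)) 1 else p$value
      list(surface = function(x, y) rep(k, length(x)),
           laplacian = function(x, y) rep(0, length(x)))
    },
    linear = {
      a0 <- if (is.null(p$a0)) 0 else p$a0
      ax <- if (is.null(p$ax)) 1 else p$ax
      ay <- if (is.null(p$ay)) 0 else p$ay
      list(surface = function(x, y) a0 + ax * x + ay * y,
           laplacian = function(x, y) rep(0, length(x)))
    },
    quadratic = list(surface = function(x, y) x^2 + y^2,
                     laplacian = function(x, y) rep(4, length(x))),
    monomial = {
      px <- p$px; py <- p$py
      if (is.null(px) || is.null(py)) stop("monomial family needs `px` and `py`")
      d2 <- function(n, u) if (n < 2) rep(0, length(u)) else n * (n - 1) * u^(n - 2)
      list(surface = function(x, y) x^px * y^py,
           laplacian = function(x, y) d2(px, x) * y^py + x^px * d2(py, y))
    },
    dipole = {
      d <- if (is.null(p$depth)) 20 else p$depth
      m <- if (is.null(p$moment)) 1 else p$moment
      sg <- if (is.null(p$sigma)) 0.35 else p$sigma
      A <- m * d / (4 * pi * sg)
      list(surface = function(x, y) A * (x^2 + y^2 + d^2)^(-3 / 2),
           laplacian = function(x, y) {
             u <- x^2 + y^2 + d^2
             3 * A * (3 * (x^2 + y^2) - 2 * d^2) * u^(-7 / 2)
           })
    })
  structure(list(family = family, params = p,
                 surface = f$surface, laplacian = f$laplacian),
            class = "analytic_field")
}

#' @export
surface_fun.analytic_field <- function(field, ...) field$surface

#' @export
print.analytic_field <- function(x, ...) {
  cat(sprintf("Analytic surface field (family: %s)\n", x$family))
  invisible(x)
}
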