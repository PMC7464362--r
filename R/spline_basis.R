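## Natural cubic spline basis with an exact analytic derivative.
##
## The basis is the usual B-spline design with the two second-derivative
## boundary constraints projected out (the same construction splines::ns
## uses), but the projection matrix is kept so that derivative bases can be
## evaluated exactly from splineDesign(..., derivs = 1). Milestone
## extraction roots the derivative, so an analytic derivative (piecewise
## quadratic) is essential.

#' Natural cubic spline basis definition
#'
#' Defines a natural cubic spline basis on an age axis (months) with the
#' given interior and boundary knots. The returned object evaluates the
#' basis and its exact first derivative at arbitrary ages inside the
#' boundary knots.
#'
#' @param interior_knots strictly increasing interior knot ages (months);
#'   at least 4 are required so fitted curves can hold two interior
#'   stationary points (an infancy maximum and a childhood minimum).
#' @param boundary_knots length-2 ages bracketing all interior knots.
#' @return an object of class `ns_basis` with `$df` basis columns.
#' @export
ns_basis <- function(interior_knots = c(3, 9, 18, 36, 66, 96),
                     boundary_knots = c(0.25, 130)) {
  stop_if(length(boundary_knots) != 2 || diff(boundary_knots) <= 0,
          "`boundary_knots` must be two increasing ages")
  stop_if(length(interior_knots) < 4,
          "need at least 4 interior knots for two interior stationary points")
  stop_if(any(diff(interior_knots) <= 0), "interior knots must be strictly increasing")
  stop_if(any(interior_knots <= boundary_knots[1]) ||
            any(interior_knots >= boundary_knots[2]),
          "interior knots must lie strictly inside the boundary knots")
  aknots <- sort(c(rep(boundary_knots, 4L), interior_knots))
  ## drop the first B-spline column (the constant is carried by the model
  ## intercept) before projecting out the two boundary constraints
  const <- splines::splineDesign(aknots, boundary_knots, ord = 4L,
                                 derivs = c(2L, 2L))[, -1L, drop = FALSE]
  qr_const <- qr(t(const))
  structure(list(interior_knots = interior_knots,
                 boundary_knots = boundary_knots,
                 aknots = aknots,
                 qr_const = qr_const,
                 df = length(interior_knots) + 1L),
            class = "ns_basis")
}

#' Evaluate a natural spline basis (or its derivative)
#'
#' @param basis an [ns_basis()] object.
#' @param x ages (months); must lie within the boundary knots (no
#'   extrapolation).
#' @param deriv 0 for the basis itself, 1 for its first derivative.
#' @return numeric matrix, `length(x)` rows by `basis$df` columns.
#' @export
ns_eval <- function(basis, x, deriv = 0L) {
  stopifnot(inherits(basis, "ns_basis"))
  stop_if(any(!is.finite(x)), "ages must be finite")
  stop_if(any(x < basis$boundary_knots[1] | x > basis$boundary_knots[2]),
          sprintf("ages outside boundary knots [%g, %g]: no extrapolation",
                  basis$boundary_knots[1], basis$boundary_knots[2]))
  des <- splines::splineDesign(basis$aknots, x, ord = 4L,
                               derivs = rep(as.integer(deriv),
                                            length(x)))[, -1L, drop = FALSE]
  out <- t(qr.qty(basis$qr_const, t(des)))[, -(1:2), drop = FALSE]
  colnames(out) <- paste0("ns", seq_len(ncol(out)))
  out
}
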