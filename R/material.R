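#' Passive myocardial material parameters
#'
#' Exponential (Fung-type) strain-energy law W = (C/2)(e^Q - 1) with
#' Q = b1*Eff^2 + b2*(Err^2 + Ecc^2 + 2*Erc^2) + 2*b3*(Efr^2 + Efc^2),
#' strains expressed in the local fiber coordinate system (f fiber,
#' r radial/sheet, c cross-fiber). Defaults: C = 2 kPa, b1 = 8 (fiber),
#' b2 = 2 (transverse), b3 = 4 (fiber shear).
#'
#' @param c_kpa stress scale C (kPa), > 0
#' @param b1,b2,b3 dimensionless exponent coefficients, > 0
#' @return a `material_params` object
#' @export
material_params <- function(c_kpa = 2, b1 = 8, b2 = 2, b3 = 4) {
  vals <- c(c_kpa = c_kpa, b1 = b1, b2 = b2, b3 = b3)
  if (!all(is.finite(vals)) || any(vals <= 0))
    stop("all material parameters must be positive and finite",
         call. = FALSE)
  structure(as.list(vals), class = "material_params")
}

#' Green-Lagrange strain state at a material point
#'
#' Each shear component is stored once; its factor-2 weight is applied inside
#' the energy function.
#'
#' @param e_ff,e_rr,e_cc,e_rc,e_fr,e_fc strain components (dimensionless)
#' @return a `strain_state` object
#' @export
strain_state <- function(e_ff = 0, e_rr = 0, e_cc = 0,
                         e_rc = 0, e_fr = 0, e_fc = 0) {
  vals <- c(e_ff = e_ff, e_rr = e_rr, e_cc = e_cc,
            e_rc = e_rc, e_fr = e_fr, e_fc = e_fc)
  if (!all(is.finite(vals)))
    stop("strain components must be finite", call. = FALSE)
  structure(as.list(vals), class = "strain_state")
}

material_Q <- function(e, p) {
  p$b1 * e$e_ff^2 +
    p$b2 * (e$e_rr^2 + e$e_cc^2 + 2 * e$e_rc^2) +
    2 * p$b3 * (e$e_fr^2 + e$e_fc^2)
}

#' Passive strain energy
#'
#' @param e a [strain_state()]
#' @param p a [material_params()]; defaults to the canonical constants
#' @return strain energy W (kPa); zero at zero strain, always >= 0
#' @export
strain_energy <- function(e, p = material_params()) {
  stopifnot(inherits(e, "strain_state"), inherits(p, "material_params"))
  q <- material_Q(e, p)
  if (q > 700)
    stop(sprintf("strain-energy exponent overflow: Q = %.3g > 700", q),
         call. = FALSE)
  p$c_kpa / 2 * (exp(q) - 1)
}

#' Second Piola-Kirchhoff stress of the passive law
#'
#' Closed-form gradient S_ij = dW/dE_ij of [strain_energy()]; shear
#' components carry their factor-2 weights from the energy exponent.
#'
#' @inheritParams strain_energy
#' @return named numeric vector of stress components (kPa)
#' @export
pk2_stress <- function(e, p = material_params()) {
  stopifnot(inherits(e, "strain_state"), inherits(p, "material_params"))
  q <- material_Q(e, p)
  if (q > 700)
    stop(sprintf("stress exponent overflow: Q = %.3g > 700", q),
         call. = FALSE)
  k <- p$c_kpa * exp(q)  # (C/2) * e^Q * dQ/dE, with dQ/dE carrying the 2s
  c(s_ff = k * p$b1 * e$e_ff,
    s_rr = k * p$b2 * e$e_rr,
    s_cc = k * p$b2 * e$e_cc,
    s_rc = k * p$b2 * 2 * e$e_rc,
    s_fr = k * 2 * p$b3 * e$e_fr,
    s_fc = k * 2 * p$b3 * e$e_fc)
}
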