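#' Physical properties of the device materials
#'
#' Returns the default material property table used throughout the transport
#' solver: density \eqn{\rho}, dynamic viscosity \eqn{\mu} (informational;
#' channel flow is never solved, flows are parameterized by Peclet number),
#' oxygen diffusivity \eqn{D} and oxygen solubility \eqn{S}. The aqueous
#' phases (culture medium and collagen gel) share \eqn{D} and \eqn{S}; the
#' polycarbonate (PC) barrier film shares the PDMS solubility but has a
#' roughly 2000-fold lower diffusivity, which is what lets it block
#' atmospheric oxygen ingress. Glass carries no transport properties: the
#' coverslip floor is treated as a zero-flux boundary.
#'
#' Oxygen tension is expressed in percent of 1 atm throughout (21 = ambient
#' air), so the permeability governing steady flux in partial-pressure form
#' is \eqn{k = D S} per material, and dissolved concentration follows
#' Henry's law, \eqn{c = S \, (\phi/100)} mM.
#'
#' @return A data frame with one row per material (`medium`, `gas`, `gel`,
#'   `PDMS`, `PC_film`, `glass`) and columns `density` (kg/m^3), `viscosity`
#'   (Pa s), `D` (m^2/s), `S` (mM/atm) and `k` (= D*S). `NA` marks properties
#'   that are undefined for a material.
#' @examples
#' default_materials()
#' @export
default_materials <- function() {
  m <- data.frame(
    name      = c("medium", "gas", "gel", "PDMS", "PC_film", "glass"),
    density   = c(1.0e3, 1, 1.0e3, NA, NA, NA),
    viscosity = c(1.0e-3, 1.0e-5, NA, NA, NA, NA),
    D         = c(2.0e-9, 2.0e-5, 2.0e-9, 4.0e-9, 2.0e-12, NA),
    S         = c(0.218, NA, 0.218, 1.25, 1.25, NA),
    stringsAsFactors = FALSE
  )
  m$k <- m$D * m$S
  m
}

#' Look up one material's properties
#'
#' @param name One of `"medium"`, `"gas"`, `"gel"`, `"PDMS"`, `"PC_film"`,
#'   `"glass"`.
#' @param materials Property table, by default [default_materials()].
#' @return A one-row data frame.
#' @export
material_properties <- function(name, materials = default_materials()) {
  i <- match(name, materials$name)
  if (anyNA(i)) {
    stop("unknown material(s): ", paste(setdiff(name, materials$name), collapse = ", "))
  }
  materials[i, , drop = FALSE]
}
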