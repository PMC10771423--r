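# Published steady-state kinetic constants and melting temperatures for the
# characterized alditol oxidases. These printed values are inputs to the
# downstream arithmetic (catalytic efficiencies, improvement factors, thermal
# shifts); they are not computed by this package.

#' Steady-state kinetic constants of characterized alditol oxidases
#'
#' Glycerol kinetics (oxygen-electrode assay) of the wild-type enzymes and
#' tunnel-mouth double mutants: Michaelis constant (mM) and turnover number
#' (1/s). Enzymes are identified by the source organism shorthand: Ab
#' (*Actinobacteria* bacterium), Ch (*Thermostaphylospora chromogena*), St
#' (*Streptomyces thermoviolaceus*), Tf (*Thermopolyspora flexuosa*), plus
#' the Tf V258L_P259I and Ab V257L_P258I double mutants.
#'
#' @return A tibble: `enzyme`, `substrate`, `km_mM`, `kcat_per_s`.
#' @export
aldo_kinetic_constants <- function() {
  tibble(
    enzyme = c("AldO_Tf", "AldO_Tf_V258L_P259I", "AldO_Ab", "AldO_Ch",
               "AldO_St", "AldO_Ab_V257L_P258I"),
    substrate = "glycerol",
    km_mM = c(50, 41, 184, 143, 523, 157),
    kcat_per_s = c(1.6, 4.0, 2.6, 2.0, 4.2, 1.4)
  )
}

#' Melting temperatures of characterized alditol oxidases
#'
#' Thermal-shift (flavin fluorescence) melting temperatures in 50 mM buffers
#' across pH 5.0-9.0, degC.
#'
#' @return A tibble: `buffer`, `ph`, one column per enzyme.
#' @export
aldo_melting_temperatures <- function() {
  tibble(
    buffer = c("citrate", "citrate", "KPi", "KPi", "KPi", "KPi",
               "Tris-HCl", "Tris-HCl", "Tris-HCl"),
    ph = c(5.0, 5.5, 6.0, 6.5, 7.0, 7.5, 8.0, 8.5, 9.0),
    AldO_Ab = c(68, 77, 80, 80, 82, 82, 81, 82, 81),
    AldO_Ch = c(62, 73, 75, 76, 77, 78, 77, 77, 76),
    AldO_St = c(70, 80, 82, 84, 85, 85, 84, 84, 84),
    AldO_Tf = c(61, 71, 72, 73, 75, 76, 76, 76, 75),
    AldO_Tf_V258L_P259I = c(65, 75, 77, 79, 81, 81, 80, 80, 80)
  )
}

#' Bound-flavin extinction coefficients of characterized alditol oxidases
#'
#' 452 nm extinction coefficients (1/(mM cm)) determined by native vs
#' SDS-denatured flavin absorbance against free FAD.
#'
#' @return A named numeric vector.
#' @export
aldo_extinction_coefficients <- function() {
  c(AldO_Tf = 12.5, AldO_Ab = 12.2, AldO_Ch = 12.3, AldO_St = 15.7)
}
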