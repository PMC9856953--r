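#' Feedback-voltage to field calibration map
#'
#' Linear calibration between controller feedback voltage and peak
#' alternating-magnetic-field (AMF) amplitude, with saturation. The
#' reference calibration is 0--1.25 V to 0--9.8 kA/m peak at 160 kHz; the
#' hardware control signal spans 0--5 V, so voltages above `v_full` clamp
#' at `H_full`, and a scenario may impose a stricter field cap `H_cap`
#' (e.g. 8 kA/m for a first in vivo session).
#'
#' @param v_zero Voltage giving zero field, V (default 0).
#' @param v_full Voltage giving `H_full`, V.
#' @param H_full Field at `v_full`, A/m peak.
#' @param frequency Operating frequency, Hz.
#' @param H_cap Scenario field cap, A/m peak (default `H_full`).
#' @return An object of class `actuator_map`.
#' @export
#' @examples
#' amap <- actuator_map(v_full = 1.25, H_full = 9800, frequency = 160e3)
#' voltage_to_field(1.25, amap)  # 9800 A/m
actuator_map <- function(v_zero = 0, v_full, H_full, frequency,
                         H_cap = H_full) {
  stopifnot(is.finite(v_zero), is.finite(v_full), is.finite(H_full),
            is.finite(frequency), is.finite(H_cap))
  if (!(v_full > v_zero)) stop("actuator_map: v_full must exceed v_zero", call. = FALSE)
  if (!(H_full > 0)) stop("actuator_map: H_full must be positive", call. = FALSE)
  if (H_cap < 0) stop("actuator_map: H_cap must be non-negative", call. = FALSE)
  structure(list(v_zero = v_zero, v_full = v_full, H_full = H_full,
                 frequency = frequency, H_cap = H_cap),
            class = "actuator_map")
}

#' Convert feedback voltage to peak field amplitude
#'
#' `H = min(H_cap, H_full * clamp((u - v_zero)/(v_full - v_zero), 0, 1))`:
#' linear in the calibrated window, clamped outside it, and capped by the
#' scenario limit.
#'
#' @param u Feedback voltage, V (vectorised).
#' @param map An [actuator_map()].
#' @return Peak field amplitude in A/m.
#' @export
voltage_to_field <- function(u, map) {
  if (!inherits(map, "actuator_map")) stop("map must be an actuator_map", call. = FALSE)
  if (!all(is.finite(u))) {
    stop(structure(class = c("mhtsim_actuator_fault", "error", "condition"),
                   list(message = "voltage_to_field: non-finite voltage",
                        call = sys.call())))
  }
  frac <- pmin(pmax((u - map$v_zero) / (map$v_full - map$v_zero), 0), 1)
  pmin(map$H_cap, map$H_full * frac)
}

#' Magnetic-nanoparticle heat source
#'
#' Volumetric heating by intratumoral iron-oxide nanoparticles. The
#' specific loss power (SLP, W per g Fe) is referenced at field `H_ref`
#' and scaled quadratically below it (linear-response regime), constant
#' above; multiplied by the local iron concentration it yields a power
#' density. The spatial profile (for the radial plant) is a Gaussian of
#' standard deviation `sigma_s` about the source locus, emulating an
#' infusion-centred particle distribution.
#'
#' @param SLP_ref SLP at the reference field, W/g Fe.
#' @param H_ref Reference field, A/m peak.
#' @param cFe Iron concentration, g Fe/m^3 (80 mg Fe/mL = 8e4 g/m^3).
#' @param sigma_s Gaussian spatial spread, m (default 3e-3).
#' @return An object of class `mnp_source`.
#' @export
mnp_source <- function(SLP_ref, H_ref, cFe, sigma_s = 3e-3) {
  stopifnot(SLP_ref > 0, H_ref > 0, cFe > 0, sigma_s > 0)
  structure(list(SLP_ref = SLP_ref, H_ref = H_ref, cFe = cFe,
                 sigma_s = sigma_s),
            class = c("mnp_source", "heat_source"))
}

#' Nanoparticle power density at a given field
#'
#' `P = SLP_ref * (min(H, H_ref)/H_ref)^2 * cFe` in W/m^3: quadratic
#' low-field scaling capped at the reference field, zero at zero field.
#'
#' @param H Field amplitude, A/m peak (vectorised, non-negative).
#' @param src An [mnp_source()].
#' @return Power density, W/m^3.
#' @export
mnp_power_density <- function(H, src) {
  stopifnot(inherits(src, "mnp_source"), all(H >= 0))
  frac <- pmin(H, src$H_ref) / src$H_ref
  src$SLP_ref * frac^2 * src$cFe
}

#' Copper-wire equivalent heat source
#'
#' A NIST-traceable Cu wire segment is the standard reference heat source
#' for verifying induced-heating setups: a wire of fixed mass with a known
#' specific absorption rate (SAR, W/g) at a reference field stands in for
#' a nanoparticle deposit of equal volumetric power.
#'
#' @param SAR_Cu Specific absorption rate at the reference field, W/g.
#' @param mass Wire mass, g (reference segment 0.104 g).
#' @param rho_Cu Copper density, g/m^3 (default 8.96e6).
#' @param H_ref Reference field at which `SAR_Cu` applies, A/m peak
#'   (used by the engine for quadratic field scaling).
#' @return An object of class `cu_source`.
#' @export
cu_source <- function(SAR_Cu, mass = 0.104, rho_Cu = 8.96e6, H_ref = 9800) {
  stopifnot(SAR_Cu >= 0, mass > 0, rho_Cu > 0, H_ref > 0)
  structure(list(SAR_Cu = SAR_Cu, mass = mass, rho_Cu = rho_Cu,
                 H_ref = H_ref),
            class = c("cu_source", "heat_source"))
}

#' Copper-wire equivalent power density
#'
#' `P = SAR_Cu * rho_Cu` in W/m^3 at the reference field. When
#' `SLP_ref * cFe == SAR_Cu * rho_Cu` the nanoparticle and wire sources
#' deposit identical volumetric power, which is the equivalence used to
#' verify controller performance without nanoparticle standards.
#'
#' @param src A [cu_source()].
#' @return Power density, W/m^3.
#' @export
cu_equivalent_power <- function(src) {
  stopifnot(inherits(src, "cu_source"))
  src$SAR_Cu * src$rho_Cu
}

#' Eddy-current heating parameters
#'
#' Off-target Joule heating induced in conductive tissue by the AMF. The
#' induced power density follows the classical closed form for a
#' conducting cylinder, `P(r) = prefactor * sigma_e * (mu0 pi f H r)^2 / 2`,
#' increasing quadratically with conductivity-path radius product and with
#' the field-frequency product, hence maximal at the tissue periphery.
#'
#' @param sigma_e Tissue electrical conductivity, S/m.
#' @param r Eddy-current path radius, m.
#' @param prefactor Dimensionless shape factor (default 1).
#' @return An object of class `eddy_params`.
#' @export
eddy_params <- function(sigma_e, r, prefactor = 1) {
  stopifnot(sigma_e >= 0, r >= 0, prefactor >= 0)
  structure(list(sigma_e = sigma_e, r = r, prefactor = prefactor),
            class = c("eddy_params", "heat_source"))
}

MU0 <- 4e-7 * pi

#' Eddy-current power density
#'
#' @param H Field amplitude, A/m peak (non-negative).
#' @param f Frequency, Hz (non-negative).
#' @param params An [eddy_params()] object.
#' @param r Optional path radius overriding `params$r`, m.
#' @return Power density, W/m^3.
#' @export
eddy_power_density <- function(H, f, params, r = params$r) {
  stopifnot(inherits(params, "eddy_params"), all(H >= 0), all(f >= 0),
            all(r >= 0))
  params$prefactor * params$sigma_e * (MU0 * pi * f * H * r)^2 / 2
}

#' Field-frequency exposure compliance
#'
#' Checks the consensus patient-exposure limit on the field-frequency
#' product for induced eddy-current heating (4.85e8 A/(m s) for a 30 cm
#' torso diameter). Compliance is the strict inequality `H * f < limit`.
#'
#' @param H Field amplitude, A/m peak.
#' @param f Frequency, Hz.
#' @param limit Exposure limit on `H * f`, A/(m s) (default 4.85e8).
#' @return List with `compliant` (logical) and `margin` (`H*f/limit`).
#' @export
#' @examples
#' hf_compliance(9800, 160e3)  # margin ~3.2, non-compliant
hf_compliance <- function(H, f, limit = 4.85e8) {
  stopifnot(H >= 0, f >= 0, limit > 0)
  margin <- H * f / limit
  list(compliant = (H * f) < limit, margin = margin)
}

#' Power density applied by a heat source at a given field
#'
#' Engine-facing dispatch: nanoparticle sources scale quadratically below
#' their reference field ([mnp_power_density()]); copper-wire sources
#' scale their reference-field equivalent power the same way (induced
#' heating is quadratic in the applied field in the low-field regime);
#' eddy-current sources use the closed-form induced power at the path
#' radius.
#'
#' @param src A heat source object.
#' @param H Field amplitude, A/m peak (vectorised).
#' @param f Frequency in Hz (needed for eddy sources).
#' @return Power density, W/m^3.
#' @export
source_power <- function(src, H, f = NULL) UseMethod("source_power")

#' @export
source_power.mnp_source <- function(src, H, f = NULL) {
  mnp_power_density(H, src)
}

#' @export
source_power.cu_source <- function(src, H, f = NULL) {
  frac <- pmin(H, src$H_ref) / src$H_ref
  cu_equivalent_power(src) * frac^2
}

#' @export
source_power.eddy_params <- function(src, H, f = NULL) {
  if (is.null(f)) stop("source_power: eddy source needs a frequency", call. = FALSE)
  eddy_power_density(H, f, src)
}
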