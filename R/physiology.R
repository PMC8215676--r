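#' Absolute humidity from temperature and relative humidity
#'
#' Magnus-type approximation:
#' `AH = 6.112 * exp(17.67 T / (T + 243.5)) * RH * 2.1674 / (273.15 + T)`.
#'
#' @param temp_c Air temperature, degrees C (> -243.5).
#' @param rh_pct Relative humidity, percent in `[0, 100]`.
#' @return Absolute humidity, g/m^3 (vectorised).
#' @export
absolute_humidity <- function(temp_c, rh_pct) {
  if (any(temp_c <= -243.5)) stop("temperature out of range")
  if (any(rh_pct < 0 | rh_pct > 100)) stop("RH must be within [0, 100] %")
  6.112 * exp(17.67 * temp_c / (temp_c + 243.5)) * rh_pct * 2.1674 /
    (273.15 + temp_c)
}

#' Moisture content percentage
#'
#' `MCP = (FW - DW) / FW * 100` with fresh and dry weight of the same
#' seedling in the same mass unit.
#'
#' @param fw Fresh weight (mg). @param dw Dry weight (mg), `0 < dw <= fw`.
#' @return Moisture content, percent.
#' @export
moisture_content <- function(fw, dw) {
  if (any(dw <= 0)) stop("dry weight must be positive")
  if (any(dw > fw)) stop("inconsistent weights: DW exceeds FW")
  (fw - dw) / fw * 100
}

#' Tray planting geometry
#'
#' The germination-tray layout of the measurement design: a 0.55 m x 0.28 m
#' tray with 50 cavities of 0.05 m x 0.05 m footprint, lit 12 h per day
#' (43,200 s).
#'
#' @param tray_length_m,tray_width_m Tray dimensions, m.
#' @param cavities Seedling cavities per tray.
#' @param photoperiod_s Illuminated seconds per day.
#' @return Named list with the geometry fields.
#' @export
planting_geometry <- function(tray_length_m = 0.55, tray_width_m = 0.28,
                              cavities = 50, photoperiod_s = 43200) {
  list(tray_length_m = tray_length_m, tray_width_m = tray_width_m,
       cavities = cavities, cavity_m = 0.05, photoperiod_s = photoperiod_s)
}

#' Seedlings per square metre of cultivation area
#'
#' `cavities / (tray length x width)`, rounded to the nearest integer:
#' 325 for the default 50-cavity 0.55 m x 0.28 m tray.
#'
#' @param geometry A [planting_geometry()].
#' @return Integer seedlings per m^2.
#' @export
seedlings_per_m2 <- function(geometry = planting_geometry()) {
  as.integer(round(geometry$cavities /
                   (geometry$tray_length_m * geometry$tray_width_m)))
}

#' Dry-mass productivity per cultivation area
#'
#' `PDY = (M_N - M_0) / N` with areal dry masses in g/m^2 and duration in
#' days.
#'
#' @param m_n,m_0 Dry mass of seedlings per area on day N and day 0, g/m^2
#'   (`m_n >= m_0 >= 0`).
#' @param n_days Cultivation duration, days (> 0).
#' @return Productivity, g/(m^2 d).
#' @export
productivity <- function(m_n, m_0, n_days) {
  if (any(n_days <= 0)) stop("duration must be positive")
  if (any(m_0 < 0) || any(m_n < m_0)) stop("need m_n >= m_0 >= 0")
  (m_n - m_0) / n_days
}

#' Relative growth rate on a dry-weight basis
#'
#' `RGR = (ln DW_N - ln DW_0) / N`, (g/g)/d.
#'
#' @param dw_n,dw_0 Whole-seedling dry weights on day N and day 0, mg
#'   (both > 0; the ratio is unit-free).
#' @param n_days Duration, days (> 0).
#' @return RGR, (g/g)/d.
#' @export
rgr <- function(dw_n, dw_0, n_days) {
  if (any(dw_n <= 0) || any(dw_0 <= 0)) stop("dry weights must be positive")
  if (any(n_days <= 0)) stop("duration must be positive")
  (log(dw_n) - log(dw_0)) / n_days
}

#' Net assimilation rate
#'
#' Whole-seedling dry-mass gain per unit leaf area per day,
#' `NAR = ((DW_N - DW_0)/1000) / (TLA * N)`: dry weights enter in mg and
#' are converted to g so the result is on the conventional g/(m^2 d) scale.
#'
#' @param dw_n,dw_0 Dry weights, mg. @param tla Total leaf area on day N,
#'   m^2 (> 0). @param n_days Duration, days (> 0).
#' @return NAR, g/(m^2 d).
#' @export
nar <- function(dw_n, dw_0, tla, n_days) {
  if (any(tla <= 0)) stop("leaf area must be positive")
  if (any(n_days <= 0)) stop("duration must be positive")
  ((dw_n - dw_0) / 1000) / (tla * n_days)
}

#' Net photosynthetic rate proxy from leaf dry-mass gain
#'
#' `Pn = (LDW_N - LDW_L) / (TLA * (N - L) * 43200)`: leaf dry-weight gain
#' (ug) between the first-true-leaf day `L` and harvest day `N`, per unit
#' leaf area per illuminated second (12 h photoperiod).
#'
#' @param ldw_n,ldw_l Total leaf dry weight on day N and day L, ug.
#' @param tla Total leaf area on day N, m^2 (> 0).
#' @param n_day Harvest day. @param l_day First-true-leaf day (`n_day >
#'   l_day`).
#' @param photoperiod_s Illuminated seconds per day (default 43,200).
#' @return Pn, ug/(m^2 s).
#' @export
pn <- function(ldw_n, ldw_l, tla, n_day, l_day, photoperiod_s = 43200) {
  if (any(n_day <= l_day)) stop("harvest day must exceed first-leaf day")
  if (any(tla <= 0)) stop("leaf area must be positive")
  (ldw_n - ldw_l) / (tla * (n_day - l_day) * photoperiod_s)
}

# Planck constant (J s), speed of light (m/s), Avogadro number (1/mol)
.h_planck <- 6.626e-34
.c_light  <- 2.998e8
.n_avogadro <- 6.022e23

#' Radiant energy flux of a photon-flux spectrum
#'
#' Converts a 380-780 nm photon-flux spectrum (umol/(m^2 s) per wavelength
#' or per band) into radiant energy flux:
#' `E_I = h c N_A 1e3 * sum(I_lambda / lambda)` with lambda in nm.  Band
#' rows (no explicit wavelength) are assigned a representative wavelength,
#' by default the band midpoint — an approximation documented in the
#' methods vignette and tunable through `band_wavelengths`.
#'
#' @param spectrum Data frame with either columns `wavelength_nm` and
#'   `flux` or columns `band` (one of "uv", "blue", "green", "red",
#'   "far_red") and `flux`.
#' @param band_wavelengths Named vector of representative wavelengths (nm)
#'   per band; default band midpoints of 380-399, 400-499, 500-599,
#'   600-700, 701-780 nm.
#' @return Energy flux `E_I`, J/(m^2 s).  Zero (with a warning) for an
#'   all-zero or empty spectrum.
#' @export
spectral_energy <- function(spectrum,
                            band_wavelengths = c(uv = 389.5, blue = 449.5,
                                                 green = 549.5, red = 650,
                                                 far_red = 740.5)) {
  if (!nrow(spectrum) || all(spectrum$flux == 0)) {
    warning("empty spectrum: zero energy flux")
    return(0)
  }
  if (any(spectrum$flux < 0)) stop("photon fluxes must be >= 0")
  if ("wavelength_nm" %in% names(spectrum)) {
    wl <- spectrum$wavelength_nm
  } else if ("band" %in% names(spectrum)) {
    wl <- band_wavelengths[as.character(spectrum$band)]
    if (anyNA(wl)) stop("unknown band label in spectrum")
  } else stop("spectrum needs a 'wavelength_nm' or 'band' column")
  if (any(wl < 380 | wl > 780))
    stop("wavelengths must lie within [380, 780] nm")
  .h_planck * .c_light * .n_avogadro * 1e3 * sum(spectrum$flux / wl)
}

#' Photon-to-energy ratio of a light source
#'
#' `I / E_I` in umol/J: photon flux divided by the radiant energy flux it
#' carries.  For the white-LED spectrum of the measurement design this
#' ratio sits between 4.3 and 4.5 across intensity levels.
#'
#' @param i_total Total photon flux, umol/(m^2 s).
#' @param e_i Energy flux, J/(m^2 s) (> 0).
#' @return Ratio, umol/J.
#' @export
photon_energy_ratio <- function(i_total, e_i) {
  if (any(e_i <= 0)) stop("energy flux must be positive")
  i_total / e_i
}

#' Energy content assumption for the edible portion
#'
#' Under unstressed growth, 100 g of fresh edible portion at 94.2%
#' moisture (5.8 g dry matter) contains 49 kJ, implying a dry-mass energy
#' density of 49/5.8 kJ/g.
#'
#' @param kj_per_100g_fresh Energy per 100 g fresh mass, kJ.
#' @param moisture_pct Reference moisture content, percent.
#' @return List with the two assumptions and the derived
#'   `kj_per_g_dry`.
#' @export
energy_assumption <- function(kj_per_100g_fresh = 49, moisture_pct = 94.2) {
  list(kj_per_100g_fresh = kj_per_100g_fresh, moisture_pct = moisture_pct,
       kj_per_g_dry = kj_per_100g_fresh / (100 * (1 - moisture_pct / 100)))
}

#' Photosynthetic efficiency
#'
#' Percentage of the delivered light energy stored as chemical energy in
#' shoot dry biomass:
#' `PE = 100 * (shoot_dw_area * energy density) / (E_I * photoperiod_s *
#' N)`.  The cumulative light energy uses illuminated seconds only (12 h/d
#' photoperiod), since the lamps are off half of each day.
#'
#' @param shoot_dw_area Shoot dry mass per area on day N, g/m^2.
#' @param e_i_flux Lamp energy flux, J/(m^2 s).
#' @param n_days Cultivation duration, days.
#' @param assumption An [energy_assumption()].
#' @param photoperiod_s Illuminated seconds per day.
#' @return PE, percent.
#' @export
photosynthetic_efficiency <- function(shoot_dw_area, e_i_flux, n_days,
                                      assumption = energy_assumption(),
                                      photoperiod_s = 43200) {
  if (any(e_i_flux <= 0) || any(n_days <= 0) || photoperiod_s <= 0)
    stop("energy flux, duration and photoperiod must be positive")
  e_b <- shoot_dw_area * assumption$kj_per_g_dry * 1000  # J/m^2
  100 * e_b / (e_i_flux * photoperiod_s * n_days)
}
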