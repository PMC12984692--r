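# CO2 mass-balance emission estimation for naturally ventilated barns.
#
# The indirect method: the herd's metabolic CO2 production, derived from
# heat-production equations, is divided by the indoor-outdoor CO2
# concentration difference to give the air-exchange (ventilation) rate Q.
# Multiplying Q by the indoor-outdoor gradient of a target gas (NH3, CH4)
# gives that gas's emission rate, optionally normalised per livestock unit
# (LU, 500 kg of animal mass).

GAS_MOLAR_MASS <- c(NH3 = 17.031, CH4 = 16.043, CO2 = 44.010) # g mol^-1
R_GAS <- 8.314462618  # J mol^-1 K^-1
LU_MASS_KG <- 500     # one livestock unit = 500 kg animal mass

#' Herd state descriptor
#'
#' Bundles the herd covariates consumed by the heat-production and CO2
#' excretion equations.
#'
#' @param n_cows number of cows housed in the barn (N, >= 1).
#' @param mean_mass average animal mass (kg per cow, > 0).
#' @param days_insemination days after insemination (p, >= 0).
#' @param milk_yield milk yield (kg per day, >= 0).
#' @return an object of class `herd_state`.
#' @examples
#' herd_state(56, 620, 120, 28)
#' @export
herd_state <- function(n_cows = 56, mean_mass = 620, days_insemination = 120,
                       milk_yield = 28) {
  stopifnot(
    is.numeric(n_cows), length(n_cows) == 1L, is.finite(n_cows), n_cows >= 1,
    is.numeric(mean_mass), length(mean_mass) == 1L, is.finite(mean_mass),
    mean_mass > 0,
    is.numeric(days_insemination), length(days_insemination) == 1L,
    is.finite(days_insemination), days_insemination >= 0,
    is.numeric(milk_yield), length(milk_yield) == 1L, is.finite(milk_yield),
    milk_yield >= 0
  )
  structure(
    list(n_cows = n_cows, mean_mass = mean_mass,
         days_insemination = days_insemination, milk_yield = milk_yield),
    class = "herd_state"
  )
}

#' @export
print.herd_state <- function(x, ...) {
  cat(sprintf(
    "<herd_state> N = %g cows, mass = %g kg, %g d after insemination, %g kg/d milk\n",
    x$n_cows, x$mean_mass, x$days_insemination, x$milk_yield
  ))
  invisible(x)
}

#' Total heat production of a cow
#'
#' Metabolic heat production (W) of one dairy cow:
#' `qt = 5.6 m^0.75 + 1.6e-5 p^3 + 22 y`, with `m` the animal mass (kg),
#' `p` days after insemination and `y` milk yield (kg/d).
#'
#' @param herd a [herd_state()].
#' @return heat production in watts (single cow).
#' @examples
#' heat_production(herd_state(56, 625, 100, 25))  # 1266 W
#' @export
heat_production <- function(herd) {
  stopifnot(inherits(herd, "herd_state"))
  5.6 * herd$mean_mass^0.75 +
    1.6e-5 * herd$days_insemination^3 +
    22 * herd$milk_yield
}

#' Temperature correction factor for heat production
#'
#' `CF = 4e-5 (20 - Ti)^3 + 1`, where `Ti` is indoor air temperature
#' in degrees Celsius. Equal to 1 at 20 C, above 1 in colder air.
#'
#' @param t_indoor indoor air temperature (degrees C); vectorised.
#' @return dimensionless correction factor.
#' @examples
#' temperature_correction(c(10, 20, 30))  # 1.04 1.00 0.96
#' @export
temperature_correction <- function(t_indoor) {
  stopifnot(is.numeric(t_indoor), all(is.finite(t_indoor)))
  4e-5 * (20 - t_indoor)^3 + 1
}

#' Per-cow CO2 excretion rate
#'
#' Corrects total heat production for indoor temperature
#' (`qcor = qt * CF`) and converts it to a CO2 excretion rate with the
#' fixed proportionality `P_CO2 = 0.299 qcor` (g CO2 per cow per hour).
#'
#' @param herd a [herd_state()].
#' @param t_indoor indoor air temperature (degrees C); vectorised.
#' @return a data frame with columns `qt` (W), `CF`, `qcor` (W) and
#'   `P_CO2` (g cow^-1 h^-1), one row per temperature.
#' @examples
#' co2_excretion_rate(herd_state(56, 625, 100, 25), 10)
#' @export
co2_excretion_rate <- function(herd, t_indoor) {
  qt <- heat_production(herd)
  cf <- temperature_correction(t_indoor)
  qcor <- qt * cf
  data.frame(qt = qt, CF = cf, qcor = qcor, P_CO2 = 0.299 * qcor)
}

#' Barn ventilation rate from the CO2 balance
#'
#' `Q = P_CO2 * N / (C_CO2in - C_CO2out)` in m^3 h^-1, with concentrations
#' in g m^-3. Hours whose indoor-outdoor CO2 gradient does not exceed
#' `min_gradient` are flagged `invalid_gradient` and return `NA` rather
#' than failing, so series processing continues.
#'
#' @param p_co2 per-cow CO2 excretion rate (g cow^-1 h^-1); vectorised.
#' @param n_cows number of cows.
#' @param co2_in,co2_out indoor / outdoor CO2 concentrations (g m^-3).
#' @param min_gradient smallest usable gradient (g m^-3, default 1e-6).
#' @return data frame with columns `Q` (m^3 h^-1) and `flag`
#'   (`"ok"` or `"invalid_gradient"`).
#' @export
ventilation_rate <- function(p_co2, n_cows, co2_in, co2_out,
                             min_gradient = 1e-6) {
  stopifnot(min_gradient >= 0)
  grad <- co2_in - co2_out
  bad <- !is.finite(grad) | grad <= min_gradient
  q <- ifelse(bad, NA_real_, p_co2 * n_cows / grad)
  data.frame(Q = q,
             flag = ifelse(bad, "invalid_gradient", "ok"),
             stringsAsFactors = FALSE)
}

#' Gas emission rate from ventilation and concentration gradient
#'
#' `Et = Q * (C_in - C_out)` in g h^-1. Negative gradients produce a
#' negative rate; the caller decides the policy (see
#' [estimate_emissions_series()]).
#'
#' @param q ventilation rate (m^3 h^-1).
#' @param c_in,c_out indoor / outdoor concentrations of the target gas
#'   (g m^-3).
#' @return emission rate (g h^-1); vectorised.
#' @export
emission_rate <- function(q, c_in, c_out) {
  q * (c_in - c_out)
}

#' Emission rate per livestock unit
#'
#' `E = Et * LU / (N * m)` with LU the 500 kg reference animal mass,
#' expressing emissions per standardised animal mass for cross-study
#' comparison.
#'
#' @param et emission rate (g h^-1).
#' @param herd a [herd_state()].
#' @return emission in g LU^-1 h^-1.
#' @export
emission_per_lu <- function(et, herd) {
  stopifnot(inherits(herd, "herd_state"))
  et * LU_MASS_KG / (herd$n_cows * herd$mean_mass)
}

#' Convert gas concentration between ppm and g m^-3
#'
#' Ideal-gas conversion: 1 ppm (micromole per mole of air) corresponds to
#' `1e-6 * M * P / (R T)` g m^-3, with M the molar mass of the gas. The two
#' functions are exact inverses of each other.
#'
#' @param x concentration (ppm for `ppm_to_gm3`, g m^-3 for `gm3_to_ppm`);
#'   vectorised.
#' @param gas one of `"NH3"`, `"CH4"`, `"CO2"`.
#' @param temperature air temperature (degrees C) at the measurement point.
#' @param pressure air pressure (kPa, default standard atmosphere).
#' @return the converted concentration.
#' @examples
#' ppm_to_gm3(1, "CO2", temperature = 0)  # ~1.963e-3 g m^-3
#' @export
ppm_to_gm3 <- function(x, gas, temperature = 20, pressure = 101.325) {
  m <- gas_molar_mass(gas)
  stopifnot(all(temperature > -273.15), all(pressure > 0), all(x >= 0, na.rm = TRUE))
  x * 1e-6 * m * (pressure * 1000) / (R_GAS * (temperature + 273.15))
}

#' @rdname ppm_to_gm3
#' @export
gm3_to_ppm <- function(x, gas, temperature = 20, pressure = 101.325) {
  m <- gas_molar_mass(gas)
  stopifnot(all(temperature > -273.15), all(pressure > 0))
  x / (1e-6 * m * (pressure * 1000) / (R_GAS * (temperature + 273.15)))
}

gas_molar_mass <- function(gas) {
  gas <- toupper(gas)
  if (!gas %in% names(GAS_MOLAR_MASS)) {
    stop("unknown gas: ", gas, " (expected NH3, CH4 or CO2)", call. = FALSE)
  }
  GAS_MOLAR_MASS[[gas]]
}

#' Hour-by-hour emission estimation for a record table
#'
#' Applies the CO2 mass-balance chain to every row of an hourly record
#' table: per-cow CO2 excretion from the herd state and indoor
#' temperature, ventilation rate from the CO2 gradient, target-gas
#' emission rate from the gas gradient, and per-LU normalisation.
#' Concentration columns are in ppm (sensor units) and are converted to
#' g m^-3 at the row's indoor (indoor columns) or outdoor (outdoor
#' columns) temperature. When several indoor sampling-point columns are
#' present (e.g. `nh3_in_1`, `nh3_in_2`, ...), their mean is used as the
#' indoor concentration.
#'
#' @param records data frame with columns `T_in`, `T_out`, `co2_in`,
#'   `co2_out` and `<gas>_in`, `<gas>_out` (ppm), as written by
#'   [gen_study()]; sampling-point variants `<base>_1 ... <base>_k` are
#'   averaged.
#' @param herd a [herd_state()].
#' @param gas `"NH3"` or `"CH4"`.
#' @param negative_policy what to do with hours whose gas gradient is
#'   negative: `"keep"` (default; value kept, flagged
#'   `negative_emission`), `"zero"` (set to 0) or `"drop"` (set to `NA`).
#' @param min_gradient smallest usable CO2 gradient (g m^-3).
#' @param pressure air pressure (kPa) for unit conversion.
#' @return a data frame with one row per record: `Q`, `Et`, `E`, `qt`,
#'   `CF`, `qcor`, `P_CO2` and `flag` (`ok`, `invalid_gradient` or
#'   `negative_emission`).
#' @export
estimate_emissions_series <- function(records, herd, gas = c("NH3", "CH4"),
                                      negative_policy = c("keep", "zero", "drop"),
                                      min_gradient = 1e-6,
                                      pressure = 101.325) {
  gas <- match.arg(gas)
  negative_policy <- match.arg(negative_policy)
  stopifnot(is.data.frame(records), inherits(herd, "herd_state"))
  gl <- tolower(gas)

  need <- c("T_in", "T_out")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols)) {
    stop("records is missing required column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  co2_in_ppm <- indoor_concentration(records, "co2_in")
  co2_out_ppm <- column_or_stop(records, "co2_out")
  gas_in_ppm <- indoor_concentration(records, paste0(gl, "_in"))
  gas_out_ppm <- column_or_stop(records, paste0(gl, "_out"))

  co2_in <- ppm_to_gm3(co2_in_ppm, "CO2", records$T_in, pressure)
  co2_out <- ppm_to_gm3(co2_out_ppm, "CO2", records$T_out, pressure)
  c_in <- ppm_to_gm3(gas_in_ppm, gas, records$T_in, pressure)
  c_out <- ppm_to_gm3(gas_out_ppm, gas, records$T_out, pressure)

  ex <- co2_excretion_rate(herd, records$T_in)
  vent <- ventilation_rate(ex$P_CO2, herd$n_cows, co2_in, co2_out,
                           min_gradient = min_gradient)
  et <- emission_rate(vent$Q, c_in, c_out)
  flag <- vent$flag
  neg <- !is.na(et) & et < 0 & flag == "ok"
  flag[neg] <- "negative_emission"
  if (negative_policy == "zero") et[neg] <- 0
  if (negative_policy == "drop") et[neg] <- NA_real_
  e_lu <- emission_per_lu(et, herd)

  data.frame(Q = vent$Q, Et = et, E = e_lu,
             qt = ex$qt, CF = ex$CF, qcor = ex$qcor, P_CO2 = ex$P_CO2,
             flag = flag, stringsAsFactors = FALSE)
}

# Mean over the indoor sampling-point columns present for `base`:
# either a single column `base` or numbered columns `base_1 ... base_k`.
indoor_concentration <- function(records, base) {
  if (base %in% names(records)) return(records[[base]])
  multi <- grep(paste0("^", base, "_[0-9]+$"), names(records), value = TRUE)
  if (length(multi) == 0L) {
    stop("records is missing required column(s): ", base, call. = FALSE)
  }
  rowMeans(records[multi])
}

column_or_stop <- function(records, nm) {
  if (!nm %in% names(records)) {
    stop("records is missing required column(s): ", nm, call. = FALSE)
  }
  records[[nm]]
}
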