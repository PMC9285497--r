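#' Tissue property registry
#'
#' Baseline material constants for the seven materials of the model: the
#' metallic electrode, its plastic insulation, the nidus (tumour core), the
#' sclerotic reactive layer, trabecular bone, cortical bone and muscle.
#' Values are at body temperature (37 degrees C) and ~500 kHz. Units:
#' density kg/m^3, electrical conductivity S/m, specific heat J/(kg K),
#' thermal conductivity W/(m K), perfusion coefficient 1/s, water fraction
#' dimensionless in `[0, 1]`.
#'
#' The registry ships as a plain-text table under `inst/extdata`, so property
#' overrides are data, not code.
#'
#' @param overrides Named list of per-tissue overrides, e.g.
#'   `list(nidus = list(sigma = 0.5))`. Allowed fields: `density`, `sigma`,
#'   `specific_heat`, `thermal_conductivity`, `perfusion`, `water_fraction`.
#' @return A data.frame with one row per material, class `tissue_registry`.
#' @examples
#' reg <- tissue_registry()
#' reg[reg$tissue == "nidus", "sigma"]  # 0.22 S/m
#' @export
tissue_registry <- function(overrides = list()) {
  path <- system.file("extdata", "tissue_properties.tsv", package = "ooablate")
  reg <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (length(overrides)) {
    stopifnot(is.list(overrides))
    for (tis in names(overrides)) {
      i <- match(tis, reg$tissue)
      if (is.na(i)) stop("unknown tissue in overrides: '", tis, "'")
      for (fld in names(overrides[[tis]])) {
        if (!fld %in% names(reg)[-1])
          stop("unknown property field in overrides: '", fld, "'")
        val <- overrides[[tis]][[fld]]
        if (!is.numeric(val) || length(val) != 1L || val < 0)
          stop("override ", tis, "$", fld, " must be a nonnegative number")
        reg[i, fld] <- val
      }
    }
  }
  stopifnot(all(reg$water_fraction <= 1))
  class(reg) <- c("tissue_registry", "data.frame")
  reg
}

#' Physical model constants
#'
#' Constants shared by the temperature-dependent property models, the
#' perfusion sink and the vaporization (enthalpy) model:
#' relative electrical-conductivity slope (+1.5% of baseline per degree C),
#' absolute thermal-conductivity slope (0.003 W/m/K per degree C),
#' vaporized-tissue conductivity, density and specific heat, latent heat of
#' vaporization, and blood density/specific heat/temperature. Blood constants
#' are not tissue-specific literature-settled values; the defaults
#' (rho_b = 1050 kg/m^3, c_b = 3617 J/kg/K) are standard in RF-ablation
#' modelling and are exposed here so sensitivity to the choice is checkable.
#'
#' @param body_temp_C Body (and blood) temperature in degrees C; 37 by
#'   default, 35 for the ex-vivo style validation scenario.
#' @param ... Named overrides of any constant.
#' @return Named list of constants.
#' @export
model_constants <- function(body_temp_C = 37, ...) {
  cst <- list(
    d_sigma_rel = 0.015,       # fraction of baseline sigma per degree C
    d_k_abs     = 0.003,       # W/(m K) per degree C
    d_k_relative = FALSE,      # alternative reading: 0.003 fraction per deg C
    sigma_vap   = 10e-3,       # S/m
    rho_vap     = 370,         # kg/m^3
    c_vap       = 2156,        # J/(kg K)
    h_fg        = 2.25e6,      # J/kg latent heat of vaporization
    rho_blood   = 1050,        # kg/m^3
    c_blood     = 3617,        # J/(kg K)
    T_blood     = body_temp_C, # degrees C
    body_temp   = body_temp_C, # degrees C
    gas_constant = 8.314462618 # J/(mol K)
  )
  dots <- list(...)
  for (nm in names(dots)) {
    if (!nm %in% names(cst)) stop("unknown model constant: '", nm, "'")
    cst[[nm]] <- dots[[nm]]
  }
  stopifnot(all(vapply(cst[c("sigma_vap", "rho_vap", "c_vap", "h_fg",
                             "rho_blood", "c_blood")], function(x) x > 0,
                       logical(1))))
  cst
}

.tissue_row <- function(registry, tissue) {
  i <- match(tissue, registry$tissue)
  if (anyNA(i)) stop("unknown tissue: '", tissue[which(is.na(i))[1L]], "'")
  i
}

## Vectorized kernels over (row index into registry, temperature).
## These are the hot path of the per-element property evaluation, so they
## take precomputed baseline vectors rather than names.

.sigma_T <- function(sigma0, T, cst) {
  T <- pmax(T, 0)
  s100 <- sigma0 * (1 + cst$d_sigma_rel * (100 - 37))
  low  <- sigma0 * (1 + cst$d_sigma_rel * (T - 37))
  ramp <- s100 + (cst$sigma_vap - s100) * (T - 100) / 5
  out <- ifelse(T <= 100, low, ifelse(T <= 105, ramp, cst$sigma_vap))
  pmax(out, 1e-12)  # keep the electric operator positive definite
}

.k_T <- function(k0, T, cst) {
  dk <- if (isTRUE(cst$d_k_relative)) cst$d_k_abs * k0 else cst$d_k_abs
  k0 + dk * (pmin(T, 100) - 37)
}

## Volumetric enthalpy relative to 37 degrees C and its derivative
## (apparent volumetric heat capacity, J/(m^3 K)).
## Branches: sensible rho*c up to 99 C; latent ramp over (99, 100] adding
## rho*h_fg*C_w in total; vapor branch rho_vap*c_vap above 100 C.
## Extended linearly below 37 C with the sensible slope.
.enthalpy_T <- function(rho, c, Cw, T, cst) {
  rc <- rho * c
  h99 <- rc * (99 - 37)
  lat <- rho * cst$h_fg * Cw
  h100 <- h99 + lat
  ifelse(T <= 99, rc * (T - 37),
    ifelse(T <= 100, h99 + lat * (T - 99),
      h100 + cst$rho_vap * cst$c_vap * (T - 100)))
}

.heat_capacity_T <- function(rho, c, Cw, T, cst) {
  rc <- rho * c
  ifelse(T <= 99, rc,
    ifelse(T <= 100, rho * cst$h_fg * Cw,
      cst$rho_vap * cst$c_vap))
}

#' Temperature-dependent electrical conductivity
#'
#' Linear increase of 1.5% of the 37-degree baseline per degree C up to
#' 100 C, then a linear vaporization drop over (100, 105] C down to the
#' vaporized-tissue value sigma_vap = 0.01 S/m, constant beyond. Continuous
#' everywhere.
#'
#' @param tissue Tissue name(s) present in the registry.
#' @param T_celsius Temperature(s), degrees C (recycled against `tissue`).
#' @param registry A [tissue_registry()].
#' @param constants A [model_constants()] list.
#' @return Conductivity in S/m.
#' @examples
#' electrical_conductivity("nidus", 37)   # 0.22
#' electrical_conductivity("muscle", 57)  # 0.446 * 1.30
#' @export
electrical_conductivity <- function(tissue, T_celsius,
                                    registry = tissue_registry(),
                                    constants = model_constants()) {
  if (any(T_celsius < 0)) stop("temperature below 0 degrees C")
  i <- .tissue_row(registry, tissue)
  .sigma_T(registry$sigma[i], T_celsius, constants)
}

#' Temperature-dependent thermal conductivity
#'
#' Linear increase of 0.003 W/(m K) per degree C above 37 C, capped at its
#' 100-degree value for any higher temperature. A relative reading of the
#' slope (0.003 of baseline per degree C) is available via
#' `model_constants(d_k_relative = TRUE)`.
#'
#' @inheritParams electrical_conductivity
#' @return Thermal conductivity in W/(m K).
#' @export
thermal_conductivity <- function(tissue, T_celsius,
                                 registry = tissue_registry(),
                                 constants = model_constants()) {
  if (any(T_celsius < 0)) stop("temperature below 0 degrees C")
  i <- .tissue_row(registry, tissue)
  .k_T(registry$thermal_conductivity[i], T_celsius, constants)
}

#' Volumetric enthalpy and apparent heat capacity
#'
#' Enthalpy method for tissue vaporization: sensible branch
#' rho*c*(T - 37) up to 99 C, a latent ramp over (99, 100] C adding
#' rho*h_fg*C_w in total (C_w the tissue water fraction), and a vapor branch
#' with slope rho_vap*c_vap above 100 C. Strictly increasing and continuous;
#' extended linearly below 37 C so simulations may start at 35 C.
#'
#' @inheritParams electrical_conductivity
#' @param derivative If `TRUE`, return the apparent volumetric heat capacity
#'   (the piecewise slope, J/(m^3 K)) instead of the enthalpy.
#' @return Enthalpy in J/m^3 relative to 37 C, or its derivative.
#' @export
enthalpy <- function(tissue, T_celsius, registry = tissue_registry(),
                     constants = model_constants(), derivative = FALSE) {
  i <- .tissue_row(registry, tissue)
  f <- if (derivative) .heat_capacity_T else .enthalpy_T
  f(registry$density[i], registry$specific_heat[i],
    registry$water_fraction[i], T_celsius, constants)
}

#' Blood-perfusion heat sink
#'
#' Pennes perfusion term Q_p = omega_i * rho_b * c_b * (T - T_b) for living
#' tissue; exactly zero once the cell is dead (the damage model gates the
#' `alive` flag) and always zero for non-perfused materials (electrode,
#' plastic, cortical bone).
#'
#' @inheritParams electrical_conductivity
#' @param alive Logical, recycled; dead tissue contributes exactly 0.
#' @return Heat-loss density in W/m^3 (positive above blood temperature).
#' @export
perfusion_sink <- function(tissue, T_celsius, alive = TRUE,
                           registry = tissue_registry(),
                           constants = model_constants()) {
  i <- .tissue_row(registry, tissue)
  w <- registry$perfusion[i]
  q <- w * constants$rho_blood * constants$c_blood *
    (T_celsius - constants$T_blood)
  q * ifelse(alive, 1, 0)
}
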