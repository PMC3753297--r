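# Deterministic four-pool carbon accounting.
#
# All pool functions are vectorized over the rows of the province table and
# return stocks in Tg C. The model is multilinear: every pool is a sum of
# products of its inputs, which the sensitivity and uncertainty modules rely
# on.

check_model_inputs <- function(provinces, fields) {
  for (col in fields) {
    x <- provinces[[col]]
    if (is.null(x)) stop("missing input field '", col, "'", call. = FALSE)
    if (!is.numeric(x) || any(!is.finite(x))) {
      stop("input field '", col, "' must be finite numeric", call. = FALSE)
    }
    if (any(x < 0)) {
      stop("input field '", col, "' must be non-negative", call. = FALSE)
    }
  }
  invisible(NULL)
}

# Impervious cover defaults to the complement of green space; an explicit
# impervious_frac column (used by the one-at-a-time sensitivity analysis)
# overrides it.
impervious_fraction <- function(provinces) {
  if (!is.null(provinces$impervious_frac)) {
    provinces$impervious_frac
  } else {
    1 - provinces$green_frac
  }
}

#' Vegetation carbon stock of urban green spaces
#'
#' Stock = urban area x green-space fraction x vegetation carbon density,
#' i.e. `area_urban` (km^2) x `green_frac` x `d_green` (kg C m^-2), converted
#' to Tg C (1 kg C m^-2 over 1 km^2 = 1e-3 Tg C).
#'
#' @param provinces province table (see [validate_provinces()]); may be a
#'   single row.
#' @param constants a [model_constants()] object (unused by this pool, kept
#'   for a uniform signature).
#' @return numeric vector, Tg C per province.
#' @export
vegetation_carbon <- function(provinces, constants = model_constants()) {
  check_model_inputs(provinces, c("area_urban", "green_frac", "d_green"))
  kg <- provinces$area_urban * M2_PER_KM2 * provinces$green_frac *
    provinces$d_green
  kg_to_tg(kg)
}

#' Soil carbon stock beneath green space and impervious surfaces
#'
#' All urban soil is assumed to lie under either green space or impervious
#' cover: stock = area x (green_frac x d_sgreen + impervious_frac x d_simp),
#' with the impervious fraction equal to `1 - green_frac` unless an explicit
#' `impervious_frac` column is present. Densities are integrated to 100 cm
#' depth.
#'
#' @inheritParams vegetation_carbon
#' @return numeric vector, Tg C per province.
#' @export
soil_carbon <- function(provinces, constants = model_constants()) {
  check_model_inputs(provinces,
                     c("area_urban", "green_frac", "d_sgreen", "d_simp"))
  imp <- impervious_fraction(provinces)
  kg <- provinces$area_urban * M2_PER_KM2 *
    (provinces$green_frac * provinces$d_sgreen + imp * provinces$d_simp)
  kg_to_tg(kg)
}

#' Carbon stock in human bodies
#'
#' Stock = urban population x average body weight x dry-matter fraction x
#' carbon fraction of dry matter.
#'
#' @inheritParams vegetation_carbon
#' @return numeric vector, Tg C per province.
#' @export
human_carbon <- function(provinces, constants = model_constants()) {
  check_model_inputs(provinces, "pop_urban")
  kg <- provinces$pop_urban * constants$weight_ave * constants$f1 *
    constants$f2
  kg_to_tg(kg)
}

#' Carbon stock in buildings (construction wood and furniture)
#'
#' Construction wood volume is residential floor area x `f3` plus commercial
#' floor area x `f5` (commercial = total - residential; floor areas are
#' tabulated in 10^4 m^2). Furniture wood volume is sets per household x
#' households x pieces per set x the mix-weighted wood volume per piece
#' (`f7*f8 + f9*f10`). Both volumes are converted to mass with the wood bulk
#' density `f4` (t m^-3) and to carbon with the wood carbon fraction `f2`.
#'
#' @inheritParams vegetation_carbon
#' @param breakdown if `TRUE`, return a data.frame with `c_constru`,
#'   `c_furn`, and `c_building` columns instead of the total vector.
#' @return numeric vector of totals (Tg C), or a data.frame if
#'   `breakdown = TRUE`.
#' @export
building_carbon <- function(provinces, constants = model_constants(),
                            breakdown = FALSE) {
  check_model_inputs(provinces,
                     c("floor_resid", "floor_total", "n_set", "n_household"))
  if (any(provinces$floor_resid > provinces$floor_total * (1 + 1e-12))) {
    stop("input field 'floor_resid' must not exceed 'floor_total'",
         call. = FALSE)
  }
  floor_comm <- pmax(provinces$floor_total - provinces$floor_resid, 0)
  wood_constru_m3 <- (provinces$floor_resid * constants$f3 +
                        floor_comm * constants$f5) * M2_PER_FLOOR_UNIT
  wood_furn_m3 <- provinces$n_set * provinces$n_household * constants$f6 *
    (constants$f7 * constants$f8 + constants$f9 * constants$f10)
  to_carbon_kg <- function(vol_m3) {
    vol_m3 * constants$f4 * KG_PER_TONNE * constants$f2
  }
  c_constru <- kg_to_tg(to_carbon_kg(wood_constru_m3))
  c_furn <- kg_to_tg(to_carbon_kg(wood_furn_m3))
  if (breakdown) {
    data.frame(c_constru = c_constru, c_furn = c_furn,
               c_building = c_constru + c_furn)
  } else {
    c_constru + c_furn
  }
}

#' Per-province pool breakdown
#'
#' Computes all four pools, their total, the areal carbon density, and the
#' per-pool fractions of the total for every province.
#'
#' For a province whose total stock is zero the pool fractions are undefined;
#' they are reported as 0 and flagged in the logical column `zero_total`.
#'
#' @inheritParams vegetation_carbon
#' @return data.frame with one row per province: `province_id`, `region`,
#'   `area_urban` (km^2), `c_veg`, `c_soil`, `c_human`, `c_building`,
#'   `c_total` (Tg C), `density` (kg C m^-2), `frac_veg`, `frac_soil`,
#'   `frac_human`, `frac_building`, `zero_total`.
#' @examples
#' prov <- data.frame(
#'   province_id = "P1", region = "East", area_urban = 1000,
#'   green_frac = 0.31, d_green = 1.5, d_sgreen = 8, d_simp = 6,
#'   sd_simp = 1.5, pop_urban = 2e7, floor_resid = 30000,
#'   floor_total = 50000, n_set = 1, n_household = 6e6
#' )
#' province_pools(prov)
#' @export
province_pools <- function(provinces, constants = model_constants()) {
  c_veg <- vegetation_carbon(provinces, constants)
  c_soil <- soil_carbon(provinces, constants)
  c_human <- human_carbon(provinces, constants)
  c_building <- building_carbon(provinces, constants)
  c_total <- c_veg + c_soil + c_human + c_building
  # Tg over km^2 -> kg m^-2: 1e9 kg / 1e6 m^2
  density <- ifelse(provinces$area_urban > 0,
                    c_total / provinces$area_urban * 1e3, 0)
  zero_total <- c_total == 0
  safe_total <- ifelse(zero_total, 1, c_total)
  data.frame(
    province_id = provinces$province_id,
    region = provinces$region,
    area_urban = provinces$area_urban,
    c_veg = c_veg, c_soil = c_soil, c_human = c_human,
    c_building = c_building, c_total = c_total,
    density = density,
    frac_veg = ifelse(zero_total, 0, c_veg / safe_total),
    frac_soil = ifelse(zero_total, 0, c_soil / safe_total),
    frac_human = ifelse(zero_total, 0, c_human / safe_total),
    frac_building = ifelse(zero_total, 0, c_building / safe_total),
    zero_total = zero_total,
    stringsAsFactors = FALSE
  )
}
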