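# Regional and national roll-up, storage-area regression, global
# extrapolation, and context ratios against the national terrestrial stock.

#' Aggregate provincial pool breakdowns to regions and the nation
#'
#' Totals are sums over member provinces; densities are total over area;
#' pool fractions are pool-sum over total. When per-province Monte Carlo
#' results are supplied, regional and national 95% half-widths are obtained
#' by summing draws across member provinces ([combine_provinces()]).
#'
#' @param pools per-province breakdown from [province_pools()].
#' @param mc optional named list of `"uncertainty_result"` objects keyed by
#'   `province_id` (e.g. from [mc_provinces()]); every province must be
#'   present.
#' @param national_label label for the all-region row (default `"National"`).
#' @return data.frame with one row per region plus the national row: region,
#'   number of provinces, area (km^2), per-pool and total stocks (Tg C),
#'   density (kg C m^-2), pool fractions, and — with `mc` —
#'   `total_hw95` and `density_hw95` columns.
#' @export
aggregate_provinces <- function(pools, mc = NULL, national_label = "National") {
  stopifnot(is.data.frame(pools),
            all(c("region", "area_urban", "c_veg", "c_soil", "c_human",
                  "c_building", "c_total") %in% names(pools)))
  if (any(is.na(pools$region) | !nzchar(pools$region))) {
    stop("every province must carry a region label", call. = FALSE)
  }
  regions <- unique(pools$region)
  summarize_group <- function(rows, label) {
    area <- sum(rows$area_urban)
    tot <- sum(rows$c_total)
    hw <- hw_density <- NA_real_
    if (!is.null(mc)) {
      missing <- setdiff(rows$province_id, names(mc))
      if (length(missing) > 0L) {
        stop("no Monte Carlo result for province(s): ",
             paste(missing, collapse = ", "), call. = FALSE)
      }
      comb <- combine_provinces(mc[rows$province_id])
      hw <- comb$half_width_95
      hw_density <- if (area > 0) hw / area * 1e3 else NA_real_
    }
    data.frame(
      region = label, n_provinces = nrow(rows), area = area,
      c_veg = sum(rows$c_veg), c_soil = sum(rows$c_soil),
      c_human = sum(rows$c_human), c_building = sum(rows$c_building),
      c_total = tot,
      density = if (area > 0) tot / area * 1e3 else 0,
      frac_veg = if (tot > 0) sum(rows$c_veg) / tot else 0,
      frac_soil = if (tot > 0) sum(rows$c_soil) / tot else 0,
      frac_human = if (tot > 0) sum(rows$c_human) / tot else 0,
      frac_building = if (tot > 0) sum(rows$c_building) / tot else 0,
      total_hw95 = hw, density_hw95 = hw_density,
      stringsAsFactors = FALSE
    )
  }
  per_region <- lapply(regions, function(r) {
    summarize_group(pools[pools$region == r, , drop = FALSE], r)
  })
  national <- summarize_group(pools, national_label)
  out <- do.call(rbind, c(per_region, list(national)))
  if (is.null(mc)) out$total_hw95 <- out$density_hw95 <- NULL
  rownames(out) <- NULL
  out
}

#' National pool fractions from regional fractions and totals
#'
#' The national share of each pool is the total-weighted mean of the
#' regional shares: `share_p = sum_r frac_rp * total_r / sum_r total_r`.
#'
#' @param region_fracs matrix or data.frame of regional pool fractions, one
#'   row per region, one column per pool (fractions or percentages — the
#'   result is on the same scale).
#' @param region_totals regional total stocks (same row order).
#' @return named vector of national pool shares.
#' @export
national_fractions_from_regions <- function(region_fracs, region_totals) {
  fr <- as.matrix(region_fracs)
  if (nrow(fr) != length(region_totals)) {
    stop("one total per region row is required", call. = FALSE)
  }
  if (any(region_totals < 0)) stop("totals must be >= 0", call. = FALSE)
  grand <- sum(region_totals)
  if (grand == 0) stop("grand total is zero", call. = FALSE)
  colSums(fr * region_totals) / grand
}

#' Ordinary least squares fit of urban carbon storage on urban area
#'
#' Regresses provincial total stock (Tg C) on urban area expressed in units
#' of 1,000 km^2, so the slope is the specific urban carbon storage in
#' Tg C per 1,000 km^2 of urban land. Provinces with non-positive area are
#' excluded.
#'
#' @param totals provincial total stocks, Tg C.
#' @param areas provincial urban areas, km^2.
#' @param intercept include an intercept (default `TRUE`); the
#'   through-origin variant is available because the specific-storage slope
#'   is ratio-like and either convention is defensible.
#' @return list of class `"storage_area_fit"` with `slope` (Tg C per 1,000
#'   km^2), `intercept` (Tg C; 0 for through-origin), `r_squared`,
#'   `slope_se`, `n`, and the underlying `stats::lm` fit.
#' @export
fit_storage_area <- function(totals, areas, intercept = TRUE) {
  keep <- is.finite(totals) & is.finite(areas) & areas > 0
  y <- totals[keep]
  x <- areas[keep] / 1000
  if (length(y) < 3L) {
    stop("at least 3 provinces with positive area are required",
         call. = FALSE)
  }
  if (stats::sd(x) == 0) {
    stop("degenerate regressor: all areas are equal", call. = FALSE)
  }
  fit <- if (intercept) stats::lm(y ~ x) else stats::lm(y ~ x + 0)
  coefs <- stats::coef(fit)
  slope_name <- "x"
  # summary.lm warns on numerically perfect fits; the coefficient table is
  # still what we need
  sm <- suppressWarnings(summary(fit))
  structure(
    list(slope = unname(coefs[[slope_name]]),
         intercept = if (intercept) unname(coefs[["(Intercept)"]]) else 0,
         r_squared = sm$r.squared,
         slope_se = sm$coefficients[slope_name, "Std. Error"],
         n = length(y), lm = fit),
    class = "storage_area_fit"
  )
}

#' @export
print.storage_area_fit <- function(x, ...) {
  cat(sprintf(
    "storage-area fit (n = %d): slope %.2f Tg C per 1,000 km^2 (SE %.2f), intercept %.2f Tg C, R^2 = %.3f\n",
    x$n, x$slope, x$slope_se, x$intercept, x$r_squared))
  invisible(x)
}

#' Extrapolate the specific urban carbon storage to a global area range
#'
#' Multiplies the storage-area slope by the bracketing estimates of global
#' urban area and converts to Pg C.
#'
#' @param slope specific storage, Tg C per 1,000 km^2.
#' @param area_lo,area_hi lower and upper global urban area estimates, km^2.
#' @return named vector `c(lo =, hi =)` in Pg C.
#' @examples
#' extrapolate_global(16, 276000, 3524000) # 4.4 to 56.4 Pg C
#' @export
extrapolate_global <- function(slope, area_lo, area_hi) {
  if (slope < 0) stop("slope must be non-negative", call. = FALSE)
  if (area_lo > area_hi) stop("area_lo must not exceed area_hi", call. = FALSE)
  tg <- slope * c(lo = area_lo, hi = area_hi) / 1000
  tg / 1000 # Tg -> Pg
}

#' Urban share of the national carbon stock and land area
#'
#' Computes the urban stock as a percentage of the national terrestrial
#' stock, the urban area as a percentage of the national land area, and the
#' ratio of urban to national mean carbon density (identically the ratio of
#' the two shares).
#'
#' @param urban_total urban carbon stock, Tg C.
#' @param urban_area urban land area, km^2.
#' @param national_stock national terrestrial carbon stock, Pg C (default
#'   77.4, the literature value for China's terrestrial ecosystems).
#' @param national_area national land area, km^2 (default 9.60e6, China).
#' @return list with `stock_share` (%), `area_share` (%), `density_ratio`.
#' @examples
#' context_ratios(577, 33697)
#' @export
context_ratios <- function(urban_total, urban_area,
                           national_stock = 77.4, national_area = 9.60e6) {
  if (national_stock <= 0 || national_area <= 0 || urban_area <= 0) {
    stop("denominators must be positive", call. = FALSE)
  }
  stock_share <- 100 * urban_total / (national_stock * 1000)
  area_share <- 100 * urban_area / national_area
  list(stock_share = stock_share, area_share = area_share,
       density_ratio = stock_share / area_share)
}

#' Published national and regional reference table (stocks and densities)
#'
#' The 2006 reference estimates for China's urban areas: six regions plus
#' the national row, with area (km^2), total stock and 95% half-width
#' (Tg C), and carbon density and half-width (kg C m^-2). Shipped as cited
#' constants for internal-consistency checks and comparisons; the package
#' never recomputes these from the original yearbook inputs, which are not
#' redistributable.
#'
#' @return data.frame with columns `region`, `area`, `total`, `total_hw95`,
#'   `density`, `density_hw95`.
#' @export
china_region_table <- function() {
  data.frame(
    region = c("North", "Northeast", "East", "Central-south", "Southwest",
               "Northwest", "China"),
    area = c(4775, 4340, 10756, 8691, 2929, 2205, 33697),
    total = c(70.2, 88.8, 181.4, 147.1, 61.7, 27.8, 577.0),
    total_hw95 = c(12.8, 38.4, 23.8, 32.4, 18.2, 5.3, 60.1),
    density = c(14.7, 20.5, 16.9, 16.9, 21.1, 12.6, 17.1),
    density_hw95 = c(2.7, 8.9, 2.2, 3.7, 6.2, 2.4, 1.8),
    stringsAsFactors = FALSE
  )
}

#' Published pool-fraction reference table (percent of total stock)
#'
#' The 2006 reference partitioning of China's urban carbon among the four
#' pools by region and nationally, in percent. Shipped as cited constants.
#'
#' @return data.frame with columns `region`, `vegetation`, `soil`, `humans`,
#'   `buildings` (percent).
#' @export
china_pool_fractions <- function() {
  data.frame(
    region = c("North", "Northeast", "East", "Central-south", "Southwest",
               "Northwest", "China"),
    vegetation = c(4.9, 7.1, 10.3, 6.9, 4.8, 3.0, 7.3),
    soil = c(55.3, 69.8, 49.9, 55.7, 57.5, 53.1, 56.1),
    humans = c(0.8, 0.7, 1.0, 1.1, 1.0, 1.1, 1.0),
    buildings = c(39.0, 22.4, 38.8, 36.3, 36.7, 42.8, 35.6),
    stringsAsFactors = FALSE
  )
}
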