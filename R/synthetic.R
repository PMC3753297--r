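# Synthetic provincial-statistics generator.
#
# Emulates the structure of a national urban yearbook table: 31 provinces
# in 6 regions, urban areas spanning roughly two orders of magnitude and
# rescaled to a national target, green fractions around the national mean,
# log-normal-like density variation, and population / floor areas that
# co-vary with area. A calibration mode rescales the pools so the national
# point estimate reproduces published aggregates, for fixture-style tests.

#' Configuration for the synthetic province generator
#'
#' Defaults describe China's 656-city urban system in 2006: 31 provincial
#' units in six regions summing to 33,697 km^2 of urban land with a national
#' green-space fraction around 0.31. Density ranges follow the magnitudes
#' reported for Chinese urban systems: vegetation carbon of green space
#' 0.4-2.5 kg C m^-2, soil carbon to 100 cm of several to ~15 kg C m^-2,
#' so that provincial urban carbon densities land in the observed
#' 8.6-28.9 kg C m^-2 envelope. Population density, per-capita floor space
#' and household size are set to early-2000s Chinese urban magnitudes.
#'
#' @param n_provinces number of provinces (default 31).
#' @param regions named integer vector: provinces per region label. If the
#'   counts do not sum to `n_provinces` they are rescaled proportionally.
#' @param national_area_target total urban area to rescale to, km^2.
#' @param area_sdlog log-scale SD of the province-area distribution (1.0
#'   spans roughly two orders of magnitude across 31 draws).
#' @param green_frac_center,green_frac_halfwidth green fraction is uniform
#'   on `center +/- halfwidth` (defaults 0.31 +/- 0.14).
#' @param d_green_range,d_sgreen_range,d_simp_range (low, high) ranges,
#'   kg C m^-2, for log-normally drawn densities (draws are clamped to the
#'   range).
#' @param simp_cv coefficient of variation used to set `sd_simp` from the
#'   drawn `d_simp` (emulating a database-derived absolute SD).
#' @param pop_density_range urban population density range, persons km^-2.
#' @param floor_per_capita total building floor space per person, m^2.
#' @param resid_frac_range residential share of total floor area.
#' @param household_size persons per urban household.
#' @param n_set_range composite furniture sets per household.
#' @return list of class `"generator_config"`.
#' @export
generator_config <- function(n_provinces = 31,
                             regions = c("North" = 5, "Northeast" = 3,
                                         "East" = 7, "Central-south" = 6,
                                         "Southwest" = 5, "Northwest" = 5),
                             national_area_target = 33697,
                             area_sdlog = 1.0,
                             green_frac_center = 0.31,
                             green_frac_halfwidth = 0.14,
                             d_green_range = c(0.4, 2.5),
                             d_sgreen_range = c(4, 16),
                             d_simp_range = c(3, 12),
                             simp_cv = 0.3,
                             pop_density_range = c(8000, 30000),
                             floor_per_capita = 30,
                             resid_frac_range = c(0.5, 0.8),
                             household_size = 3,
                             n_set_range = c(0.5, 2)) {
  cfg <- list(
    n_provinces = as.integer(n_provinces), regions = regions,
    national_area_target = national_area_target, area_sdlog = area_sdlog,
    green_frac_center = green_frac_center,
    green_frac_halfwidth = green_frac_halfwidth,
    d_green_range = d_green_range, d_sgreen_range = d_sgreen_range,
    d_simp_range = d_simp_range, simp_cv = simp_cv,
    pop_density_range = pop_density_range,
    floor_per_capita = floor_per_capita,
    resid_frac_range = resid_frac_range,
    household_size = household_size, n_set_range = n_set_range
  )
  if (cfg$n_provinces < 1) stop("n_provinces must be >= 1", call. = FALSE)
  if (is.null(names(cfg$regions)) || any(!nzchar(names(cfg$regions)))) {
    stop("regions must be a named vector of province counts", call. = FALSE)
  }
  for (rg in c("d_green_range", "d_sgreen_range", "d_simp_range",
               "pop_density_range", "resid_frac_range", "n_set_range")) {
    r <- cfg[[rg]]
    if (length(r) != 2L || any(r <= 0) || r[1] > r[2]) {
      stop(rg, " must be a positive ordered (low, high) pair", call. = FALSE)
    }
  }
  if (cfg$national_area_target <= 0 || cfg$area_sdlog <= 0 ||
      cfg$simp_cv < 0 || cfg$floor_per_capita <= 0 ||
      cfg$household_size <= 0 ||
      cfg$green_frac_center - cfg$green_frac_halfwidth < 0 ||
      cfg$green_frac_center + cfg$green_frac_halfwidth > 1) {
    stop("infeasible generator configuration", call. = FALSE)
  }
  structure(cfg, class = "generator_config")
}

# Allocate n provinces to region labels proportionally to configured counts.
assign_regions <- function(cfg) {
  labels <- names(cfg$regions)
  counts <- as.numeric(cfg$regions)
  n <- cfg$n_provinces
  if (sum(counts) == n) {
    rep(labels, times = counts)
  } else {
    alloc <- floor(counts / sum(counts) * n)
    rem <- n - sum(alloc)
    if (rem > 0) {
      extra <- order(counts / sum(counts) * n - alloc, decreasing = TRUE)
      alloc[extra[seq_len(rem)]] <- alloc[extra[seq_len(rem)]] + 1
    }
    rep(labels, times = alloc)
  }
}

# Log-normal draw centered on the geometric mean of the range, clamped to it.
draw_in_range <- function(n, range, spread = 4) {
  meanlog <- mean(log(range))
  sdlog <- (log(range[2]) - log(range[1])) / spread
  pmin(pmax(stats::rlnorm(n, meanlog, sdlog), range[1]), range[2])
}

#' Generate a synthetic provincial-statistics table
#'
#' Draws a province table with the covariance structure of a real urban
#' yearbook (larger provinces carry proportionally more people, floor space
#' and households) and attaches the generator's own per-province pool
#' bookkeeping — computed by direct arithmetic inside the generator — as the
#' `"truth"` attribute for closed-loop recovery tests.
#'
#' @param cfg a [generator_config()].
#' @param seed integer seed; identical seeds give identical tables.
#' @return validated province data.frame with attribute `"truth"` (list with
#'   the config, seed, and a per-province data.frame of expected pool stocks
#'   in Tg C).
#' @export
generate_provinces <- function(cfg = generator_config(), seed = 1L) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(seed)
  n <- cfg$n_provinces
  region <- assign_regions(cfg)

  area_raw <- stats::rlnorm(n, meanlog = 0, sdlog = cfg$area_sdlog)
  area_urban <- area_raw / sum(area_raw) * cfg$national_area_target
  green_frac <- stats::runif(n, cfg$green_frac_center - cfg$green_frac_halfwidth,
                             cfg$green_frac_center + cfg$green_frac_halfwidth)
  d_green <- draw_in_range(n, cfg$d_green_range)
  d_sgreen <- draw_in_range(n, cfg$d_sgreen_range)
  d_simp <- draw_in_range(n, cfg$d_simp_range)
  sd_simp <- cfg$simp_cv * d_simp
  pop_density <- stats::runif(n, cfg$pop_density_range[1],
                              cfg$pop_density_range[2])
  pop_urban <- area_urban * pop_density
  floor_total <- pop_urban * cfg$floor_per_capita / 1e4
  resid_frac <- stats::runif(n, cfg$resid_frac_range[1],
                             cfg$resid_frac_range[2])
  floor_resid <- resid_frac * floor_total
  n_household <- pop_urban / cfg$household_size
  n_set <- stats::runif(n, cfg$n_set_range[1], cfg$n_set_range[2])

  provinces <- data.frame(
    province_id = sprintf("SP%02d", seq_len(n)),
    region = region,
    area_urban = area_urban, green_frac = green_frac,
    d_green = d_green, d_sgreen = d_sgreen, d_simp = d_simp,
    sd_simp = sd_simp, pop_urban = pop_urban,
    floor_resid = floor_resid, floor_total = floor_total,
    n_set = n_set, n_household = n_household,
    stringsAsFactors = FALSE
  )
  validate_provinces(provinces)

  # independent bookkeeping of the stocks implied by the drawn parameters,
  # written out term by term (kg -> Tg by 1e-9)
  cst <- model_constants()
  veg <- area_urban * 1e6 * green_frac * d_green * 1e-9
  soil <- area_urban * 1e6 *
    (green_frac * d_sgreen + (1 - green_frac) * d_simp) * 1e-9
  hum <- pop_urban * cst$weight_ave * cst$f1 * cst$f2 * 1e-9
  constru <- (floor_resid * cst$f3 + (floor_total - floor_resid) * cst$f5) *
    1e4 * cst$f4 * 1e3 * cst$f2 * 1e-9
  furn <- n_set * n_household * cst$f6 *
    (cst$f7 * cst$f8 + cst$f9 * cst$f10) * cst$f4 * 1e3 * cst$f2 * 1e-9
  truth <- list(
    config = cfg, seed = seed,
    pools = data.frame(province_id = provinces$province_id,
                       c_veg = veg, c_soil = soil, c_human = hum,
                       c_building = constru + furn,
                       c_total = veg + soil + hum + constru + furn,
                       stringsAsFactors = FALSE)
  )
  attr(provinces, "truth") <- truth
  provinces
}

#' Calibrate a synthetic table to published national aggregates
#'
#' Deterministically rescales the inputs that each pool is linear in —
#' `d_green` for vegetation; `d_sgreen`, `d_simp` (and `sd_simp`) for soil;
#' `pop_urban` for humans; floor areas and `n_set` for buildings — so the
#' national point-estimate run reproduces a target total stock and target
#' pool fractions exactly (closed form; pool stocks are linear in these
#' scale factors). Areas and the green fraction are untouched, so the
#' national density follows as `total / area`.
#'
#' @param provinces province table (typically from [generate_provinces()]).
#' @param constants a [model_constants()] object.
#' @param total_target national total stock, Tg C (default 577.0).
#' @param fractions_target per-pool shares of the total, summing to 1
#'   (default `c(0.073, 0.561, 0.010, 0.356)` for vegetation, soil, humans,
#'   buildings).
#' @return rescaled province table with attribute `"scales"` (the four
#'   multiplicative factors applied).
#' @export
calibrate_national <- function(provinces, constants = model_constants(),
                               total_target = 577.0,
                               fractions_target = c(veg = 0.073, soil = 0.561,
                                                    human = 0.010,
                                                    building = 0.356)) {
  validate_provinces(provinces)
  if (abs(sum(fractions_target) - 1) > 1e-9) {
    stop("fractions_target must sum to 1", call. = FALSE)
  }
  pools <- province_pools(provinces, constants)
  nat <- colSums(pools[, c("c_veg", "c_soil", "c_human", "c_building")])
  targets <- total_target * fractions_target
  if (any(nat == 0 & targets > 0)) {
    stop("cannot calibrate a pool whose generated stock is zero",
         call. = FALSE)
  }
  scales <- ifelse(nat > 0, targets / nat, 1)
  out <- provinces
  out$d_green <- out$d_green * scales[[1]]
  out$d_sgreen <- out$d_sgreen * scales[[2]]
  out$d_simp <- out$d_simp * scales[[2]]
  out$sd_simp <- out$sd_simp * scales[[2]]
  out$pop_urban <- out$pop_urban * scales[[3]]
  out$floor_resid <- out$floor_resid * scales[[4]]
  out$floor_total <- out$floor_total * scales[[4]]
  out$n_set <- out$n_set * scales[[4]]
  attr(out, "truth") <- NULL
  attr(out, "scales") <- stats::setNames(
    as.numeric(scales), c("vegetation", "soil", "human", "building"))
  out
}
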