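# Fixed model coefficients and unit conversions.
#
# Internal mass unit is kg C throughout; stocks are reported in Tg C
# (1 Tg = 1e9 kg) and densities in kg C m^-2. All unit conversions are
# centralized here so pool formulas stay in natural yearbook units
# (areas in km^2, floor areas in 1e4 m^2, wood volumes in m^3).

KG_PER_TG <- 1e9
M2_PER_KM2 <- 1e6
M2_PER_FLOOR_UNIT <- 1e4 # floor areas are tabulated in 10^4 m^2
KG_PER_TONNE <- 1e3

#' Convert a carbon mass from kg to Tg
#'
#' @param x numeric vector, kg C.
#' @return numeric vector, Tg C.
#' @export
kg_to_tg <- function(x) x / KG_PER_TG

#' Convert a carbon mass from Tg to kg
#'
#' @param x numeric vector, Tg C.
#' @return numeric vector, kg C.
#' @export
tg_to_kg <- function(x) x * KG_PER_TG

#' Model constants for the urban carbon bookkeeping model
#'
#' Returns the full set of fixed coefficients used by the four-pool model,
#' with literature defaults. Any coefficient can be overridden by name.
#'
#' The coefficients are:
#' \describe{
#'   \item{weight_ave}{average human body weight, kg (60)}
#'   \item{f1}{dry organic matter fraction of the human body (0.3)}
#'   \item{f2}{carbon fraction of dry organic matter and of wood (0.5)}
#'   \item{f3}{wood use per unit residential floor area, m^3 m^-2 (0.045)}
#'   \item{f4}{average bulk density of wood, t m^-3 (0.4)}
#'   \item{f5}{wood use per unit commercial floor area, m^3 m^-2 (0.055)}
#'   \item{f6}{pieces per composite furniture set (20; plausible range 10-30)}
#'   \item{f7}{wood-furniture fraction of composite furniture (0.8)}
#'   \item{f8}{wood volume per wood-furniture piece, m^3 (0.067)}
#'   \item{f9}{steel-furniture fraction of composite furniture (0.2)}
#'   \item{f10}{wood volume per steel-furniture piece, m^3 (0.026)}
#'   \item{beta}{coefficient of variation applied to inputs without a
#'     reported standard deviation in the Monte Carlo analysis (0.15)}
#' }
#'
#' @param ... named overrides of individual coefficients, e.g. `beta = 0.2`.
#' @param overrides optional named list of overrides (e.g. parsed from a
#'   YAML/JSON config file); `...` takes precedence over `overrides`.
#' @return a named list of class `"model_constants"`.
#' @examples
#' cst <- model_constants()
#' cst$f6
#' model_constants(f6 = 30)$f6
#' @export
model_constants <- function(..., overrides = NULL) {
  defaults <- list(
    weight_ave = 60,
    f1 = 0.3, f2 = 0.5,
    f3 = 0.045, f4 = 0.4, f5 = 0.055,
    f6 = 20, f7 = 0.8, f8 = 0.067, f9 = 0.2, f10 = 0.026,
    beta = 0.15
  )
  cst <- defaults
  for (src in list(overrides, list(...))) {
    if (is.null(src) || length(src) == 0L) next
    nm <- names(src)
    if (is.null(nm) || any(!nzchar(nm))) {
      stop("constant overrides must be named", call. = FALSE)
    }
    unknown <- setdiff(nm, names(defaults))
    if (length(unknown) > 0L) {
      stop("unknown model constant(s): ", paste(unknown, collapse = ", "),
           call. = FALSE)
    }
    cst[nm] <- src[nm]
  }
  validate_constants(cst)
  structure(cst, class = "model_constants")
}

validate_constants <- function(cst) {
  num <- vapply(cst, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num)) {
    stop("model constants must be finite numeric scalars: ",
         paste(names(cst)[!num], collapse = ", "), call. = FALSE)
  }
  pos <- setdiff(names(cst), "beta")
  bad <- pos[vapply(cst[pos], function(x) x <= 0, logical(1))]
  if (length(bad) > 0L) {
    stop("model constants must be positive: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (cst$beta < 0) stop("beta must be >= 0", call. = FALSE)
  for (f in c("f1", "f2", "f7", "f9")) {
    if (cst[[f]] >= 1) stop(f, " must lie in (0, 1)", call. = FALSE)
  }
  if (abs(cst$f7 + cst$f9 - 1) > 1e-10) {
    stop("f7 + f9 must equal 1 (complementary furniture fractions)",
         call. = FALSE)
  }
  invisible(cst)
}

#' Read model-constant overrides from a YAML or JSON config file
#'
#' Fields absent from the file keep their defaults.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file whose top-level keys
#'   are constant names.
#' @return a `"model_constants"` object.
#' @export
read_constants <- function(path) {
  if (!file.exists(path)) stop("constants file not found: ", path, call. = FALSE)
  overrides <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  model_constants(overrides = overrides)
}
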