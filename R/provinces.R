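# Provincial input table: schema, validation, and I/O.

province_fields <- function() {
  c("province_id", "region", "area_urban", "green_frac", "d_green",
    "d_sgreen", "d_simp", "sd_simp", "pop_urban", "floor_resid",
    "floor_total", "n_set", "n_household")
}

numeric_province_fields <- function() {
  setdiff(province_fields(), c("province_id", "region"))
}

#' Validate a provincial-statistics table
#'
#' Checks the schema and physical invariants of a province table:
#' one row per province with urban land area (`area_urban`, km^2), green-space
#' fraction (`green_frac`, in \[0, 1\]), vegetation carbon density of green
#' space (`d_green`, kg C m^-2), soil carbon densities to 100 cm beneath green
#' space and impervious surfaces (`d_sgreen`, `d_simp`, kg C m^-2) with an
#' absolute standard deviation for the impervious density (`sd_simp`), urban
#' population (`pop_urban`), residential and total building floor areas
#' (`floor_resid`, `floor_total`, 10^4 m^2), composite furniture sets per
#' household (`n_set`), household count (`n_household`), and a `region` label.
#' An optional `impervious_frac` column (defaulting to `1 - green_frac`) is
#' accepted for sensitivity experiments.
#'
#' @param provinces data.frame with the columns above.
#' @return the validated data.frame, invisibly usable downstream.
#' @export
validate_provinces <- function(provinces) {
  if (!is.data.frame(provinces)) {
    stop("provinces must be a data.frame", call. = FALSE)
  }
  if (nrow(provinces) == 0L) {
    stop("province table is empty", call. = FALSE)
  }
  missing <- setdiff(province_fields(), names(provinces))
  if (length(missing) > 0L) {
    stop("province table is missing column(s): ",
         paste(missing, collapse = ", "),
         "; expected schema: ", paste(province_fields(), collapse = ", "),
         call. = FALSE)
  }
  for (col in numeric_province_fields()) {
    x <- provinces[[col]]
    if (!is.numeric(x)) {
      stop("column '", col, "' must be numeric", call. = FALSE)
    }
    if (any(!is.finite(x))) {
      stop("column '", col, "' contains non-finite values (rows ",
           paste(which(!is.finite(x)), collapse = ", "), ")", call. = FALSE)
    }
  }
  check_nonneg <- c("area_urban", "d_green", "d_sgreen", "d_simp", "sd_simp",
                    "pop_urban", "floor_resid", "floor_total", "n_set",
                    "n_household")
  for (col in check_nonneg) {
    if (any(provinces[[col]] < 0)) {
      stop("column '", col, "' must be non-negative", call. = FALSE)
    }
  }
  if (any(provinces$area_urban <= 0)) {
    stop("column 'area_urban' must be positive", call. = FALSE)
  }
  if (any(provinces$green_frac < 0 | provinces$green_frac > 1)) {
    stop("column 'green_frac' must lie in [0, 1]", call. = FALSE)
  }
  if (any(provinces$floor_resid > provinces$floor_total * (1 + 1e-12))) {
    stop("column 'floor_resid' must not exceed 'floor_total'", call. = FALSE)
  }
  if ("impervious_frac" %in% names(provinces)) {
    im <- provinces$impervious_frac
    if (!is.numeric(im) || any(!is.finite(im)) || any(im < 0)) {
      stop("column 'impervious_frac' must be non-negative and finite",
           call. = FALSE)
    }
  }
  if (anyDuplicated(provinces$province_id)) {
    stop("duplicated province_id values", call. = FALSE)
  }
  provinces
}

#' Read a provincial-statistics table from CSV
#'
#' Expects UTF-8, '.' decimal separator, and columns named exactly as in
#' [validate_provinces()]. Green-space percentages from statistical yearbooks
#' must be divided by 100 before ingest; `green_frac` is a fraction.
#'
#' @param path CSV file path.
#' @return validated province data.frame.
#' @export
read_provinces <- function(path) {
  if (!file.exists(path)) stop("province file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  for (col in intersect(numeric_province_fields(), names(df))) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))) &
                     !is.na(df[[col]]))
      stop("non-numeric cells in column '", col, "' (rows ",
           paste(bad, collapse = ", "), ")", call. = FALSE)
    }
  }
  validate_provinces(df)
}

#' Write a table to CSV at full double precision
#'
#' Numeric columns survive a read/write round trip at better than 12
#' significant digits (values are written with 17 digits, the shortest
#' representation that is lossless for doubles).
#'
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(df, path) {
  out <- df
  for (col in names(out)) {
    if (is.numeric(out[[col]])) {
      out[[col]] <- trimws(formatC(out[[col]], digits = 17, format = "g"))
    }
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE,
                   fileEncoding = "UTF-8")
  invisible(path)
}
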