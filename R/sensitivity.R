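# One-at-a-time sensitivity of the national total to a +10% input change.
#
# The point-estimate model is multilinear, so a variable entering only as a
# linear factor of pools with combined national share s responds by exactly
# 10 * s percent. Sensitivity therefore runs on the deterministic model, not
# on Monte Carlo draws.

#' The registered perturbable variables
#'
#' Eleven province-level inputs plus ten global model coefficients (21 in
#' total). The impervious fraction is registered as an independently
#' perturbable quantity: at baseline it equals `1 - green_frac`, and its
#' perturbation scales it without changing `green_frac`. Residential and
#' commercial floor areas are likewise independent (perturbing one leaves
#' the other fixed). `f7` is complementary to `f9`; perturbing it re-derives
#' `f9 = 1 - f7`, so `f9` is not registered separately.
#'
#' @return character vector of variable names.
#' @export
sensitivity_registry <- function() {
  c("area_urban", "green_frac", "impervious_frac", "d_green", "d_sgreen",
    "d_simp", "pop_urban", "floor_resid", "floor_commercial", "n_set",
    "n_household",
    "weight_ave", "f1", "f2", "f3", "f4", "f5", "f6", "f7", "f8", "f10")
}

national_total <- function(provinces, constants) {
  sum(province_pools(provinces, constants)$c_total)
}

apply_perturbation <- function(name, provinces, constants, factor,
                               couple_fractions = FALSE) {
  p <- provinces
  cst <- unclass(constants)
  if (name %in% c("weight_ave", "f1", "f2", "f3", "f4", "f5", "f6", "f7",
                  "f8", "f10")) {
    cst[[name]] <- cst[[name]] * factor
    if (name == "f7") cst$f9 <- 1 - cst$f7
  } else if (name == "impervious_frac") {
    base_imp <- if (is.null(p$impervious_frac)) 1 - p$green_frac else
      p$impervious_frac
    p$impervious_frac <- base_imp * factor
  } else if (name == "green_frac") {
    if (is.null(p$impervious_frac)) p$impervious_frac <- 1 - p$green_frac
    p$green_frac <- p$green_frac * factor
    if (couple_fractions) p$impervious_frac <- 1 - p$green_frac
  } else if (name == "floor_resid") {
    comm <- p$floor_total - p$floor_resid
    p$floor_resid <- p$floor_resid * factor
    p$floor_total <- p$floor_resid + comm
  } else if (name == "floor_commercial") {
    comm <- p$floor_total - p$floor_resid
    p$floor_total <- p$floor_resid + comm * factor
  } else if (name %in% names(p)) {
    p[[name]] <- p[[name]] * factor
  } else {
    stop("unknown perturbation variable '", name, "'; registered variables: ",
         paste(sensitivity_registry(), collapse = ", "), call. = FALSE)
  }
  list(provinces = p, constants = structure(cst, class = "model_constants"))
}

#' Relative response of the national total to one perturbed variable
#'
#' Multiplies the named variable by `1 + delta` in every province
#' simultaneously (model coefficients are global and scaled once),
#' recomputes the national point-estimate total, and returns
#' `100 * (C' - C) / C` in percent. The baseline inputs are never modified.
#'
#' @param name a variable from [sensitivity_registry()].
#' @param provinces province table.
#' @param constants a [model_constants()] object.
#' @param delta relative increase (default `0.10` for +10%).
#' @param couple_fractions if `TRUE`, perturbing `green_frac` re-derives the
#'   impervious fraction as `1 - green_frac` (the land-cover tradeoff, under
#'   which greening can *reduce* total carbon when impervious soil is
#'   carbon-richer than green space plus its soil); if `FALSE` (default) the
#'   two fractions are independent, matching the registry.
#' @return percent change of the national total (scalar).
#' @export
perturb_variable <- function(name, provinces, constants = model_constants(),
                             delta = 0.10, couple_fractions = FALSE) {
  if (!name %in% sensitivity_registry()) {
    stop("unknown perturbation variable '", name, "'; registered variables: ",
         paste(sensitivity_registry(), collapse = ", "), call. = FALSE)
  }
  validate_provinces(provinces)
  base <- national_total(provinces, constants)
  if (base == 0) stop("baseline national total is zero", call. = FALSE)
  pert <- apply_perturbation(name, provinces, constants, 1 + delta,
                             couple_fractions = couple_fractions)
  perturbed <- national_total(pert$provinces, pert$constants)
  100 * (perturbed - base) / base
}

#' Full one-at-a-time sensitivity table
#'
#' Applies [perturb_variable()] to every registered variable and ranks the
#' responses in descending order.
#'
#' @inheritParams perturb_variable
#' @param variables variables to perturb (default: the full registry).
#' @return data.frame with `variable`, `relative_response` (percent), and
#'   `rank`, sorted by decreasing response.
#' @export
sensitivity_table <- function(provinces, constants = model_constants(),
                              delta = 0.10,
                              variables = sensitivity_registry(),
                              couple_fractions = FALSE) {
  responses <- vapply(
    variables,
    function(v) perturb_variable(v, provinces, constants, delta = delta,
                                 couple_fractions = couple_fractions),
    numeric(1)
  )
  out <- data.frame(variable = variables, relative_response = responses,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$relative_response), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}
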