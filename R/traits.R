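#' Define a trait and its desired selection direction
#'
#' A trait specification names a measured trait, records its units and the
#' desired direction of selection. The direction fixes the rescaling targets
#' used when traits are mapped to a common 0-100 scale: for traits where
#' gains are desired (`sense = "increase"`) the observed maximum maps to 100
#' and the minimum to 0; for traits to be reduced (`sense = "decrease"`) the
#' mapping is reversed so that 100 always means "best".
#'
#' @param name short unique trait identifier (e.g. `"HTW"`).
#' @param units free-text measurement units (e.g. `"g"`, `"count"`, `"%"`).
#' @param sense desired selection direction, `"increase"` or `"decrease"`.
#' @return an object of class `trait_spec` with fields `name`, `units`,
#'   `sense`, and the rescale targets `new_max`, `new_min`.
#' @export
#' @examples
#' trait_spec("HTW", "g", "increase")
trait_spec <- function(name, units = "", sense = c("increase", "decrease")) {
  sense <- match.arg(sense)
  if (!is.character(name) || length(name) != 1 || !nzchar(name)) {
    stop("`name` must be a non-empty string", call. = FALSE)
  }
  structure(
    list(
      name = name, units = units, sense = sense,
      new_max = if (sense == "increase") 100 else 0,
      new_min = if (sense == "increase") 0 else 100
    ),
    class = "trait_spec"
  )
}

#' @export
print.trait_spec <- function(x, ...) {
  cat(sprintf("<trait %s [%s], sense: %s>\n", x$name,
              if (nzchar(x$units)) x$units else "unitless", x$sense))
  invisible(x)
}

# build a named list of trait_spec from vectors; recycles units/sense
trait_spec_list <- function(names, units = "", sense = "increase") {
  units <- rep_len(units, length(names))
  sense <- rep_len(sense, length(names))
  if (anyDuplicated(names)) stop("trait names must be unique", call. = FALSE)
  specs <- Map(trait_spec, names, units, sense)
  names(specs) <- names
  specs
}

trait_names <- function(specs) vapply(specs, `[[`, character(1), "name")
trait_senses <- function(specs) vapply(specs, `[[`, character(1), "sense")

#' Classify a tuber by its length-to-width ratio
#'
#' Tubers are categorised as oval (ratio below 1.3), ovoid (1.3 to 1.8,
#' both boundaries included) or oblong (above 1.8).
#'
#' @param lw_ratio positive length/width ratio(s).
#' @return character vector in `c("oval", "ovoid", "oblong")`.
#' @export
#' @examples
#' classify_tuber_shape(c(1.2, 1.3, 1.8, 2.45))
classify_tuber_shape <- function(lw_ratio) {
  if (any(!is.finite(lw_ratio)) || any(lw_ratio <= 0)) {
    stop("`lw_ratio` must be positive and finite", call. = FALSE)
  }
  ifelse(lw_ratio < 1.3, "oval", ifelse(lw_ratio <= 1.8, "ovoid", "oblong"))
}

#' Classify coefficients of variation or heritability
#'
#' Applies the conventional banding used in plant-breeding variability
#' reports. For GCV/PCV (percent): below 10 is low, 10 to below 20
#' intermediate, 20 and above high. For broad-sense heritability (percent):
#' below 30 low, 30 to 60 intermediate, above 60 high.
#'
#' @param value_pct value(s) on the percent scale.
#' @param kind `"gcv_pcv"` or `"heritability"`.
#' @return character vector in `c("low", "intermediate", "high")`.
#' @export
#' @examples
#' classify_variability(c(5, 10, 29), "gcv_pcv")
#' classify_variability(c(29, 60, 98), "heritability")
classify_variability <- function(value_pct, kind = c("gcv_pcv", "heritability")) {
  kind <- match.arg(kind)
  if (any(!is.finite(value_pct)) || any(value_pct < 0)) {
    stop("`value_pct` must be non-negative and finite", call. = FALSE)
  }
  if (kind == "heritability" && any(value_pct > 100)) {
    stop("heritability percent cannot exceed 100", call. = FALSE)
  }
  if (kind == "gcv_pcv") {
    ifelse(value_pct < 10, "low", ifelse(value_pct < 20, "intermediate", "high"))
  } else {
    ifelse(value_pct < 30, "low", ifelse(value_pct <= 60, "intermediate", "high"))
  }
}
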