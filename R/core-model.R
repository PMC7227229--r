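#' Synthetic nitrogen fertilizer products
#'
#' The four synthetic N fertilizer products tracked by the inventory:
#' urea, compound fertilizer (CF, N:P2O5:K2O multi-nutrient product),
#' diammonium phosphate (DAP) and ammonium bicarbonate (ABC).
#'
#' @return A tibble with columns `code` (machine code, one of
#'   `"urea"`, `"cf"`, `"dap"`, `"abc"`) and `label` (display name).
#' @export
#' @examples
#' fertilizer_products()
fertilizer_products <- function() {
  tibble::tibble(
    code  = c("urea", "cf", "dap", "abc"),
    label = c(
      "Urea",
      "Compound fertilizer (CF)",
      "Diammonium phosphate (DAP)",
      "Ammonium bicarbonate (ABC)"
    )
  )
}

#' Product codes in canonical order
#' @return Character vector `c("urea", "cf", "dap", "abc")`.
#' @export
product_codes <- function() fertilizer_products()$code

#' Upland crops covered by the inventory
#'
#' @return Character vector of crop codes: `"wheat"` and `"maize"`.
#' @export
crop_codes <- function() c("wheat", "maize")

#' Agricultural region codes
#'
#' The five agricultural regions partitioning the studied provinces:
#' Northeast China (NEC), North China (NC), Middle and lower reaches of
#' the Yangtze River (MLYR), Northwest China (NWC), and South and
#' Southwest China (SSWC).
#'
#' @return Character vector of the five region codes.
#' @export
region_codes <- function() c("NEC", "NC", "MLYR", "NWC", "SSWC")

# Alternate spellings seen in official statistics, mapped to one
# canonical form ("Shannxi" and "Shaanxi" are the same province).
.province_spellings <- c(
  "shannxi"        = "Shaanxi",
  "shaanxi"        = "Shaanxi",
  "innermongolia"  = "Inner Mongolia",
  "neimenggu"      = "Inner Mongolia"
)

#' Normalise a province name to canonical spelling
#'
#' Trims whitespace, collapses case, and resolves alternate romanised
#' spellings (e.g. "Shannxi" and "Shaanxi" both denote Shaanxi).
#'
#' @param province Character vector of province names.
#' @return Character vector of canonical province names.
#' @export
#' @examples
#' normalize_province(c(" shannxi", "HEBEI"))
normalize_province <- function(province) {
  stopifnot(is.character(province))
  key <- tolower(gsub("[[:space:]]+", "", province))
  out <- unname(.province_spellings[key])
  miss <- is.na(out)
  if (any(miss)) {
    # title-case unknown keys so "hebei" -> "Hebei"
    words <- trimws(gsub("[[:space:]]+", " ", province[miss]))
    out[miss] <- vapply(words, function(w) {
      parts <- strsplit(tolower(w), " ", fixed = TRUE)[[1]]
      paste(toupper(substring(parts, 1, 1)), substring(parts, 2),
            sep = "", collapse = " ")
    }, character(1), USE.NAMES = FALSE)
  }
  out
}

#' Default province-to-region map
#'
#' The fixed assignment of the 19 studied provinces to the five
#' agricultural regions. Thirteen of the provinces grow wheat in the
#' benchmark dataset; all nineteen grow maize (the three NEC provinces,
#' Chongqing, Guizhou and Guangxi are maize-only).
#'
#' @return A tibble with columns `province` and `region`.
#' @export
#' @examples
#' default_region_map()
default_region_map <- function() {
  tibble::tibble(
    province = c(
      "Liaoning", "Jilin", "Heilongjiang",
      "Hebei", "Shanxi", "Shandong", "Henan", "Inner Mongolia",
      "Jiangsu", "Anhui", "Hubei",
      "Shaanxi", "Gansu", "Xinjiang",
      "Chongqing", "Sichuan", "Guizhou", "Yunnan", "Guangxi"
    ),
    region = c(
      rep("NEC", 3), rep("NC", 5), rep("MLYR", 3),
      rep("NWC", 3), rep("SSWC", 5)
    )
  )
}

#' Provinces growing a given crop in the benchmark dataset
#'
#' @param crop `"wheat"` or `"maize"`.
#' @return Character vector of province names. All 19 provinces grow
#'   maize; the 13 wheat provinces exclude the NEC provinces,
#'   Chongqing, Guizhou and Guangxi.
#' @export
crop_provinces <- function(crop = c("wheat", "maize")) {
  crop <- match.arg(crop)
  map <- default_region_map()
  if (crop == "maize") return(map$province)
  setdiff(map$province[map$region != "NEC"],
          c("Chongqing", "Guizhou", "Guangxi"))
}

#' Resolve the agricultural region of a province
#'
#' @param province Province name(s); normalised via
#'   [normalize_province()] before lookup.
#' @param map Region map tibble (`province`, `region`); defaults to
#'   [default_region_map()].
#' @return Character vector of region codes.
#' @export
#' @examples
#' resolve_region("Jiangsu")      # "MLYR"
#' resolve_region("Heilongjiang") # "NEC"
resolve_region <- function(province, map = default_region_map()) {
  prov <- normalize_province(province)
  idx <- match(prov, map$province)
  if (anyNA(idx)) {
    bad <- unique(prov[is.na(idx)])
    stop("unknown province(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  map$region[idx]
}

#' Nitrogen content of compound fertilizer from total nutrient mass
#'
#' Compound fertilizer (CF) application statistics are reported as total
#' nutrient mass. With the commonly used nutrient proportion
#' N:P2O5:K2O = 1:1:1, nitrogen is one third of the total nutrient mass.
#' This helper is an input-preparation step; activity tables carry
#' N already (kg N per hectare).
#'
#' @param total_nutrient Total nutrient application, kg nutrient per
#'   hectare (non-negative).
#' @return `total_nutrient / 3`, kg N per hectare.
#' @export
#' @examples
#' cf_n_from_nutrient(216) # 72 kg N / ha
cf_n_from_nutrient <- function(total_nutrient) {
  if (!is.numeric(total_nutrient) || any(is.na(total_nutrient)) ||
      any(total_nutrient < 0)) {
    stop("total_nutrient must be non-negative", call. = FALSE)
  }
  total_nutrient / 3
}
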