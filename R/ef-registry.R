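#' Emission-factor registry
#'
#' Bundles the coefficients that drive the inventory:
#' \describe{
#'   \item{`ef_m`}{Manufacture emission factors, kg CO2-eq per kg
#'     fertilizer-N, one per product. Cradle-to-product life-cycle
#'     factors covering fossil-fuel mining and transport, ammonia
#'     synthesis and product conversion.}
#'   \item{`ef_d`}{Direct soil N2O emission factors, kg N2O-N per kg
#'     applied N, indexed by (agricultural region, crop). Pairs without
#'     an established factor (NEC wheat) are absent, not zero.}
#'   \item{`gwp_n2o`}{100-year global warming potential of N2O relative
#'     to CO2 (default 298).}
#'   \item{`n_to_n2o`}{Stoichiometric mass conversion from N2O-N to N2O
#'     (default 44/28, kept as the exact ratio).}
#' }
#'
#' @param ef_m Named numeric vector of manufacture EFs, names are
#'   product codes; all values > 0.
#' @param ef_d Tibble/data frame with columns `region`, `crop`, `ef`
#'   (kg N2O-N per kg N, >= 0); one row per available (region, crop).
#' @param gwp_n2o Positive scalar GWP of N2O.
#' @param n_to_n2o Positive scalar N-to-N2O mass ratio.
#' @return An object of class `ef_registry`.
#' @seealso [default_ef_registry()] for the shipped default values.
#' @export
ef_registry <- function(ef_m, ef_d, gwp_n2o = 298, n_to_n2o = 44 / 28) {
  stopifnot(is.numeric(ef_m), !is.null(names(ef_m)))
  if (!all(names(ef_m) %in% product_codes())) {
    stop("ef_m names must be product codes (",
         paste(product_codes(), collapse = ", "), ")", call. = FALSE)
  }
  if (anyDuplicated(names(ef_m)) || any(ef_m <= 0)) {
    stop("ef_m must be positive with unique product names", call. = FALSE)
  }
  ef_d <- tibble::as_tibble(ef_d)
  stopifnot(all(c("region", "crop", "ef") %in% names(ef_d)))
  if (any(!ef_d$region %in% region_codes()) ||
      any(!ef_d$crop %in% crop_codes())) {
    stop("ef_d region/crop codes not recognised", call. = FALSE)
  }
  if (anyDuplicated(ef_d[, c("region", "crop")])) {
    stop("duplicate (region, crop) rows in ef_d", call. = FALSE)
  }
  if (any(ef_d$ef < 0)) stop("ef_d values must be >= 0", call. = FALSE)
  stopifnot(is.numeric(gwp_n2o), length(gwp_n2o) == 1, gwp_n2o > 0,
            is.numeric(n_to_n2o), length(n_to_n2o) == 1, n_to_n2o > 0)
  structure(
    list(ef_m = ef_m[intersect(product_codes(), names(ef_m))],
         ef_d = ef_d[order(match(ef_d$region, region_codes()),
                           match(ef_d$crop, crop_codes())), ],
         gwp_n2o = gwp_n2o, n_to_n2o = n_to_n2o),
    class = "ef_registry"
  )
}

#' Default emission-factor registry for Chinese uplands
#'
#' Manufacture EFs: urea 8.1, CF 7.4, DAP 10.3, ABC 7.2 kg CO2-eq per kg
#' N, from Chinese life-cycle studies of the N fertilizer industry.
#' Direct N2O EFs are region- and crop-specific values for Chinese
#' upland fields; NEC has a maize factor only (no wheat factor exists
#' for that region, and looking it up is an error rather than a zero).
#'
#' @return An `ef_registry` object.
#' @export
#' @examples
#' reg <- default_ef_registry()
#' ef_d_lookup(reg, "MLYR", "wheat") # 0.0086
default_ef_registry <- function() {
  ef_registry(
    ef_m = c(urea = 8.1, cf = 7.4, dap = 10.3, abc = 7.2),
    ef_d = tibble::tribble(
      ~region, ~crop,   ~ef,
      "NEC",   "maize", 0.0051,
      "NC",    "wheat", 0.0028,
      "NC",    "maize", 0.0070,
      "MLYR",  "wheat", 0.0086,
      "MLYR",  "maize", 0.0067,
      "NWC",   "wheat", 0.0032,
      "NWC",   "maize", 0.0057,
      "SSWC",  "wheat", 0.0050,
      "SSWC",  "maize", 0.0047
    )
  )
}

#' @export
print.ef_registry <- function(x, ...) {
  cat("<ef_registry>\n")
  cat("  manufacture EFs (kg CO2-eq / kg N): ",
      paste(names(x$ef_m), x$ef_m, sep = "=", collapse = ", "), "\n")
  cat("  direct N2O EFs: ", nrow(x$ef_d), " (region, crop) pairs\n",
      sep = "")
  cat("  GWP(N2O) = ", x$gwp_n2o, ", N->N2O = 44/28\n", sep = "")
  invisible(x)
}

#' Look up a manufacture emission factor
#'
#' @param registry An `ef_registry`.
#' @param product Product code(s).
#' @return Numeric EF(s), kg CO2-eq per kg N.
#' @export
ef_m_lookup <- function(registry, product) {
  stopifnot(inherits(registry, "ef_registry"))
  out <- registry$ef_m[product]
  if (anyNA(out)) {
    stop("no manufacture emission factor for product(s): ",
         paste(unique(product[is.na(out)]), collapse = ", "),
         call. = FALSE)
  }
  unname(out)
}

#' Look up a direct N2O emission factor
#'
#' Raises a "no-factor" error for (region, crop) pairs without an
#' established factor (e.g. NEC wheat) instead of returning zero.
#'
#' @param registry An `ef_registry`.
#' @param region Region code(s).
#' @param crop Crop code(s).
#' @return Numeric EF(s), kg N2O-N per kg N.
#' @export
ef_d_lookup <- function(registry, region, crop) {
  stopifnot(inherits(registry, "ef_registry"))
  key  <- paste(region, crop, sep = "/")
  have <- paste(registry$ef_d$region, registry$ef_d$crop, sep = "/")
  idx  <- match(key, have)
  if (anyNA(idx)) {
    stop("no direct N2O emission factor for: ",
         paste(unique(key[is.na(idx)]), collapse = ", "),
         call. = FALSE)
  }
  registry$ef_d$ef[idx]
}

#' Write an emission-factor registry to a YAML config file
#'
#' The file has sections `ef_m` (product -> kg CO2-eq per kg N), `ef_d`
#' (list of region/crop/ef entries, kg N2O-N per kg N) and `constants`
#' (`gwp_n2o`, `n_to_n2o`). Values are serialised at full precision so
#' the default registry round-trips bit-identically.
#'
#' @param registry An `ef_registry`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_ef_config <- function(registry, path) {
  stopifnot(inherits(registry, "ef_registry"))
  cfg <- list(
    units = list(
      ef_m = "kg CO2-eq per kg fertilizer-N",
      ef_d = "kg N2O-N per kg applied N"
    ),
    ef_m = as.list(registry$ef_m),
    ef_d = purrr::pmap(registry$ef_d, function(region, crop, ef) {
      list(region = region, crop = crop, ef = ef)
    }),
    constants = list(gwp_n2o = registry$gwp_n2o,
                     n_to_n2o = registry$n_to_n2o)
  )
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

#' Read an emission-factor registry from a YAML config file
#'
#' @param path Path to a file written by [write_ef_config()] (or
#'   hand-authored in the same layout).
#' @return An `ef_registry`.
#' @export
read_ef_config <- function(path) {
  if (!file.exists(path)) stop("no such EF config: ", path, call. = FALSE)
  cfg <- yaml::read_yaml(path)
  for (sec in c("ef_m", "ef_d")) {
    if (is.null(cfg[[sec]])) {
      stop("EF config missing section '", sec, "'", call. = FALSE)
    }
  }
  ef_d <- dplyr::bind_rows(lapply(cfg$ef_d, tibble::as_tibble))
  ef_registry(
    ef_m = unlist(cfg$ef_m),
    ef_d = ef_d,
    gwp_n2o = cfg$constants$gwp_n2o %||% 298,
    n_to_n2o = cfg$constants$n_to_n2o %||% (44 / 28)
  )
}
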