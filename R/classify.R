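#' Convert a standard error to a standard deviation
#'
#' Study tables often report the standard error of an arm mean rather than
#' the arm standard deviation. For an arm of size `n`, `sd = se * sqrt(n)`.
#'
#' @param se Standard error(s), non-negative and finite.
#' @param n Arm sample size(s), integer-valued and at least 1.
#' @return Numeric vector of standard deviations.
#' @examples
#' se_to_sd(2, 4)    # 4
#' se_to_sd(0.5, 7)  # 0.5 * sqrt(7)
#' @export
se_to_sd <- function(se, n) {
  if (length(se) == 0L || length(n) == 0L) return(numeric(0))
  if (any(!is.finite(se)) || any(se < 0)) {
    stop("'se' must be finite and non-negative", call. = FALSE)
  }
  if (any(!is.finite(n)) || any(n < 1) || any(n != floor(n))) {
    stop("'n' must be an integer >= 1", call. = FALSE)
  }
  se * sqrt(n)
}

#' Assign soil depths to analysis bins
#'
#' Depths are binned to the nominal sampling depths 5, 10, and 15 cm by
#' nearest value, with exact midpoints (7.5, 12.5 cm) rounded down to the
#' shallower bin; depths beyond 15 cm form a single "below 15 cm" bin.
#' Missing depths map to `"UNKNOWN"` and are kept in all analyses except
#' depth subgroup comparisons.
#'
#' @param depth_cm Numeric vector of depths in cm; `NA` allowed.
#' @return Character vector with levels `D5`, `D10`, `D15`, `BELOW15`,
#'   `UNKNOWN`.
#' @examples
#' classify_depth(c(2.1, 4.5, 10.3, 10.6))  # D5 D5 D10 D10
#' @export
classify_depth <- function(depth_cm) {
  if (any(depth_cm < 0, na.rm = TRUE)) {
    stop("negative soil depth", call. = FALSE)
  }
  out <- rep("UNKNOWN", length(depth_cm))
  ok <- !is.na(depth_cm)
  d <- depth_cm[ok]
  out[ok] <- ifelse(d > 15, "BELOW15",
             ifelse(d <= 7.5, "D5",
             ifelse(d <= 12.5, "D10", "D15")))
  out
}

#' Assign latitudes to bands
#'
#' Bands are high northern (> 50 N), intermediate (50 N to 50 S, inclusive
#' of the boundaries), and high southern (< -50). Latitude is signed,
#' positive north.
#'
#' @param latitude_deg Numeric vector in \[-90, 90\].
#' @return Character vector with levels `HIGH_N`, `INTERMEDIATE`, `HIGH_S`.
#' @export
classify_latitude <- function(latitude_deg) {
  bad <- !is.na(latitude_deg) & (abs(latitude_deg) > 90)
  if (any(bad)) stop("latitude outside [-90, 90]", call. = FALSE)
  out <- rep(NA_character_, length(latitude_deg))
  ok <- !is.na(latitude_deg)
  out[ok] <- ifelse(latitude_deg[ok] > 50, "HIGH_N",
             ifelse(latitude_deg[ok] < -50, "HIGH_S", "INTERMEDIATE"))
  out
}

#' Default biome-boundary configuration
#'
#' Climate-envelope boundaries in the MAT (mean annual temperature, deg C)
#' by MAP (mean annual precipitation, mm) plane. Below `desert_map_mm` the
#' vegetated-desert override applies: tundra when MAT < `tundra_mat_c`,
#' otherwise grassland. At or above `desert_map_mm`, sites with
#' MAT < `tundra_mat_c` are tundra; the grassland/forest split is
#' `MAP < grassland_map_base_mm + grassland_map_slope_mm_per_c *
#' (MAT - tundra_mat_c)`, a moisture demand that grows with temperature;
#' remaining (forest) sites are boreal when MAT < `boreal_max_mat_c`, else
#' temperate. The numbers are editable defaults, not a claim about any one
#' published boundary curve.
#'
#' @return A named list of class `biome_config`.
#' @export
default_biome_config <- function() {
  structure(list(
    desert_map_mm = 260,
    tundra_mat_c = -5,
    boreal_max_mat_c = 3,
    grassland_map_base_mm = 350,
    grassland_map_slope_mm_per_c = 30
  ), class = "biome_config")
}

#' Read or write a biome-boundary configuration as JSON
#'
#' @param path File path.
#' @param config A `biome_config` list.
#' @return `read_biome_config` returns a `biome_config`.
#' @export
read_biome_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- names(default_biome_config())
  miss <- setdiff(need, names(cfg))
  if (length(miss)) {
    stop("biome config missing fields: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  structure(cfg[need], class = "biome_config")
}

#' @rdname read_biome_config
#' @export
write_biome_config <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Classify sites into biomes from MAT and MAP
#'
#' Deterministic climate-envelope classification into tundra, boreal,
#' temperate, or grassland. See [default_biome_config()] for the boundary
#' rules.
#'
#' @param mat_c Mean annual temperature, deg C.
#' @param map_mm Mean annual precipitation, mm (non-negative).
#' @param config Boundary configuration; defaults to
#'   [default_biome_config()].
#' @return Character vector with levels `TUNDRA`, `BOREAL`, `TEMPERATE`,
#'   `GRASSLAND`; `NA` where MAT or MAP is missing.
#' @examples
#' classify_biome(-2, 303)   # GRASSLAND (dry site, desertward of forest)
#' classify_biome(-10, 100)  # TUNDRA (desert override, MAT < -5)
#' @export
classify_biome <- function(mat_c, map_mm, config = default_biome_config()) {
  if (any(map_mm < 0, na.rm = TRUE)) {
    stop("MAP must be non-negative", call. = FALSE)
  }
  n <- max(length(mat_c), length(map_mm))
  mat <- rep_len(mat_c, n)
  map <- rep_len(map_mm, n)
  out <- rep(NA_character_, n)
  ok <- !is.na(mat) & !is.na(map)
  grass_thr <- config$grassland_map_base_mm +
    config$grassland_map_slope_mm_per_c * (mat - config$tundra_mat_c)
  out[ok] <- ifelse(mat[ok] < config$tundra_mat_c, "TUNDRA",
             ifelse(map[ok] < pmax(grass_thr[ok], config$desert_map_mm),
                    "GRASSLAND",
             ifelse(mat[ok] < config$boreal_max_mat_c, "BOREAL",
                    "TEMPERATE")))
  out
}

#' Attach depth, latitude, and biome stratum labels to a study table
#'
#' Adds `depth_bin`, `latitude_band`, and `biome` columns. Records lacking
#' the metadata needed for a label keep `NA` (depth: `"UNKNOWN"`) and are
#' listed in the `"missing_labels"` attribute so downstream subgroup
#' analyses can exclude rather than silently drop them.
#'
#' @param records A study table (see [read_study_table()]).
#' @param config Biome boundary configuration.
#' @return The study table with label columns added.
#' @export
label_records <- function(records, config = default_biome_config()) {
  records$depth_bin <- classify_depth(records$depth_cm)
  records$latitude_band <- classify_latitude(records$latitude_deg)
  records$biome <- classify_biome(records$mat_c, records$map_mm, config)
  miss <- data.frame(
    row = integer(0), field = character(0), stringsAsFactors = FALSE)
  for (f in c("latitude_band", "biome")) {
    i <- which(is.na(records[[f]]))
    if (length(i)) {
      miss <- rbind(miss, data.frame(row = i, field = f,
                                     stringsAsFactors = FALSE))
    }
  }
  i <- which(records$depth_bin == "UNKNOWN")
  if (length(i)) {
    miss <- rbind(miss, data.frame(row = i, field = "depth_bin",
                                   stringsAsFactors = FALSE))
  }
  attr(records, "missing_labels") <- miss
  records
}
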