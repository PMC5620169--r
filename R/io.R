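#' Read and validate a sampling-location table
#'
#' Locations CSV schema: `location_id,x_mm,y_mm,z_mm,rho,theta_deg`
#' (and optionally `segment`). Either coordinate set may be omitted; the
#' missing one is recomputed from the geometry. When both are present the
#' polar coordinates are recomputed from the Cartesian ones and
#' cross-checked.
#'
#' @param path CSV file path.
#' @param geometry An [lv_geometry()] used for conversion/cross-checks.
#' @param tolerance Maximum allowed |recomputed - stored| for `rho` and
#'   `theta_deg`.
#' @return A validated location data.frame with both coordinate sets and a
#'   `segment` column.
#' @export
read_locations_csv <- function(path, geometry = lv_geometry(), tolerance = 1e-6) {
  loc <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"location_id" %in% names(loc))
    stop("locations file lacks column 'location_id': ", path)
  if (anyDuplicated(loc$location_id))
    stop("duplicated location ids in ", path)
  has_cart <- all(c("x_mm", "y_mm", "z_mm") %in% names(loc))
  has_polar <- all(c("rho", "theta_deg") %in% names(loc))
  if (!has_cart && !has_polar)
    stop("locations file needs x_mm/y_mm/z_mm and/or rho/theta_deg columns")
  if (has_cart) {
    pol <- cartesian_to_polar(loc$x_mm, loc$y_mm, loc$z_mm, geometry)
    if (has_polar) {
      drho <- abs(pol$rho - loc$rho)
      dth <- abs((pol$theta_deg - loc$theta_deg + 180) %% 360 - 180)
      dth[pol$rho < 1e-9] <- 0  # apex theta is conventional
      bad <- which(drho > tolerance | dth > tolerance * 360)
      if (length(bad) > 0)
        stop("polar/Cartesian coordinates disagree for location(s): ",
             paste(utils::head(loc$location_id[bad]), collapse = ", "))
    }
    loc$rho <- pol$rho
    loc$theta_deg <- pol$theta_deg
  } else {
    xyz <- polar_to_cartesian(loc$rho, loc$theta_deg, geometry)
    loc$x_mm <- xyz$x_mm; loc$y_mm <- xyz$y_mm; loc$z_mm <- xyz$z_mm
  }
  if (!"segment" %in% names(loc))
    loc$segment <- assign_segment(loc$rho, loc$theta_deg)
  loc
}

#' Write a sampling-location table
#'
#' @param locations Location data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_locations_csv <- function(locations, path) {
  cols <- intersect(c("location_id", "x_mm", "y_mm", "z_mm", "rho",
                      "theta_deg", "segment"), names(locations))
  utils::write.csv(locations[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and validate a raw Ct table
#'
#' Long-format CSV: `sample_id,animal_id,group,gene,replicate,ct`. Ct values
#' must lie in (0, 45\] and `(animal_id, sample_id, gene, replicate)` must
#' be unique.
#'
#' @param path CSV file path.
#' @return A validated data.frame of Ct records.
#' @export
read_ct_csv <- function(path) {
  ct <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample_id", "animal_id", "group", "gene", "replicate", "ct")
  miss <- setdiff(need, names(ct))
  if (length(miss) > 0)
    stop("Ct file lacks column(s) ", paste(miss, collapse = ", "), ": ", path)
  bad <- which(!is.finite(ct$ct) | ct$ct <= 0 | ct$ct > 45)
  if (length(bad) > 0)
    stop(sprintf("Ct values outside (0, 45] at row(s) %s of %s",
                 paste(utils::head(bad), collapse = ", "), path))
  key <- paste(ct$animal_id, ct$sample_id, ct$gene, ct$replicate)
  if (anyDuplicated(key))
    stop("duplicated (animal, sample, gene, replicate) records in ", path)
  ct
}

#' Write a Ct table
#' @param ct Ct data.frame.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_ct_csv <- function(ct, path) {
  utils::write.csv(ct, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a zone polygon from JSON
#'
#' Schema: `{"label": "...", "source_group": "...",
#' "vertices": [[u, v], ...]}`.
#'
#' @param path JSON file path.
#' @return A [zone_polygon()].
#' @export
read_zone_json <- function(path) {
  z <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(z$vertices)) stop("zone file lacks 'vertices': ", path)
  V <- z$vertices
  if (is.list(V)) V <- do.call(rbind, V)
  zone_polygon(V,
               label = z$label %||% "ischemic",
               source_group = z$source_group %||% "ir5h")
}

#' Write a zone polygon to JSON
#' @param zone A [zone_polygon()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_zone_json <- function(zone, path) {
  stopifnot(inherits(zone, "zone_polygon"))
  jsonlite::write_json(
    list(label = zone$label, source_group = zone$source_group,
         vertices = zone$vertices),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a pipeline configuration (YAML or JSON)
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return A named list.
#' @export
read_config_file <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) yaml::read_yaml(path)
  else if (ext == "json") jsonlite::read_json(path, simplifyVector = TRUE)
  else stop("unsupported config format: ", ext)
}

#' Geometry from a configuration list
#'
#' Recognized keys: `apex_base_length_mm`, `basal_radius_mm`,
#' `base_truncation` (all optional).
#'
#' @param cfg Named list (e.g. from [read_config_file()]).
#' @return An [lv_geometry()].
#' @export
geometry_from_config <- function(cfg = list()) {
  lv_geometry(
    apex_base_length_mm = cfg$apex_base_length_mm %||% 80,
    basal_radius_mm = cfg$basal_radius_mm %||% 30,
    base_truncation = cfg$base_truncation %||% 1)
}
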