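#' Run the full image-omics pipeline
#'
#' Executes the analysis end to end: replicate collapse and delta-delta-Ct
#' quantification, bulls-eye display mapping per gene and group, ischemic /
#' remote zone statistics (ANOVA + Holm-Sidak), and the 17-segment 2xSD
#' relevance analysis. Writes expression, zone-statistics, segment-summary
#' and flag CSVs, optional per-gene maps, and a JSON run manifest with the
#' seed, a config hash and checksums of every output.
#'
#' @param locations Location data.frame (see [read_locations_csv()]).
#' @param ct Raw replicate-level Ct table (see [read_ct_csv()]).
#' @param zone A [zone_polygon()] delineating the ischemic area (drawn on
#'   the 5h map).
#' @param out_dir Output directory (created if missing).
#' @param panel A [qpcr_panel()].
#' @param geometry An [lv_geometry()].
#' @param colors A [display_color_scale()].
#' @param anchor_id Optional location id pinned to display value 20
#'   (e.g. a basal posterior reference location).
#' @param resolution Bulls-eye grid resolution.
#' @param sd_rule Relevance-flag variability rule (see [relevance_flags()]).
#' @param alpha Significance level for the zone comparisons.
#' @param render Write PNG maps per gene x group (default TRUE).
#' @param interpolate_fold_changes If `TRUE`, interpolate raw fold changes
#'   and rescale the grid afterwards; default rescales per-location values
#'   first and interpolates display values (convert, then map).
#' @param seed Seed recorded in the manifest (the pipeline itself is
#'   deterministic).
#' @return Invisibly, a list with the computed tables, per-gene grids and
#'   the manifest.
#' @export
run_pipeline <- function(locations, ct, zone, out_dir,
                         panel = qpcr_panel(), geometry = lv_geometry(),
                         colors = display_color_scale(), anchor_id = NULL,
                         resolution = 121, sd_rule = "pooled_sd",
                         alpha = 0.05, render = TRUE,
                         interpolate_fold_changes = FALSE, seed = 0) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
  }
  t0 <- Sys.time()
  timings <- list()
  tick <- function(name) {
    timings[[name]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    t0 <<- Sys.time()
  }

  collapsed <- stage("qpcr", collapse_replicates(ct, panel$sd_flag_cycles))
  expression <- stage("qpcr", delta_delta_ct(collapsed, panel))
  tick("qpcr")

  if (!"segment" %in% names(locations))
    locations$segment <- assign_segment(locations$rho, locations$theta_deg)
  uv <- polar_to_disk(locations$rho, locations$theta_deg)
  tick("geometry")

  groups <- unique(expression$group)
  grids <- list()
  files <- character(0)
  expr_path <- file.path(out_dir, "expression.csv")
  utils::write.csv(expression, expr_path, row.names = FALSE, quote = FALSE)
  files <- c(files, expr_path)
  for (gene in panel$targets) {
    for (grp in groups) {
      eg <- expression[expression$gene == gene & expression$group == grp, ]
      if (nrow(eg) == 0) next
      # group map: per-location mean fold change over the group's animals
      fc <- tapply(eg$fold_change, eg$sample_id, mean)
      m <- match(names(fc), locations$location_id)
      if (any(is.na(m))) stop("imageomics stage: unknown location ids")
      vals <- stats::setNames(as.numeric(fc), names(fc))
      grid <- stage("imageomics", {
        if (interpolate_fold_changes) {
          g <- idw_interpolate(uv[m, 1], uv[m, 2], vals, resolution)
          disp <- rescale_display(g$values[g$mask], anchor = NULL)
          g$values[g$mask] <- disp
          g
        } else {
          disp <- rescale_display(vals, anchor = anchor_id)
          idw_interpolate(uv[m, 1], uv[m, 2], disp, resolution)
        }
      })
      grids[[paste(gene, grp, sep = ".")]] <- grid
      if (render) {
        f <- file.path(out_dir, sprintf("map_%s_%s.png", gene, grp))
        stage("imageomics",
              render_bullseye(grid, colors, file = f,
                              title = sprintf("%s (%s)", gene, grp),
                              zones = if (grp %in% c(zone$source_group, "control", "ir24h"))
                                zone else NULL))
        files <- c(files, f)
      }
    }
  }
  tick("imageomics")

  classification <- stage("zonestats", transpose_zone(zone, locations))
  zs <- stage("zonestats", zone_summaries(expression, classification))
  comp <- stage("zonestats", compare_zone_groups(zs, alpha))
  zone_path <- file.path(out_dir, "zone_statistics.csv")
  utils::write.csv(comp, zone_path, row.names = FALSE, quote = FALSE)
  files <- c(files, zone_path)
  tick("zonestats")

  seg <- stage("segments", segment_summaries(expression, locations))
  flags <- list()
  ctrl <- seg[seg$group == "control", ]
  for (grp in setdiff(groups, "control")) {
    trt <- seg[seg$group == grp, ]
    if (nrow(trt) == 0) next
    flags[[grp]] <- stage("segments", relevance_flags(ctrl, trt, rule = sd_rule))
  }
  flags <- do.call(rbind, flags)
  seg_path <- file.path(out_dir, "segment_summaries.csv")
  flag_path <- file.path(out_dir, "segment_flags.csv")
  utils::write.csv(seg, seg_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(flags, flag_path, row.names = FALSE, quote = FALSE)
  files <- c(files, seg_path, flag_path)
  tick("segments")

  manifest <- list(
    package = "cardimap",
    version = as.character(utils::packageVersion("cardimap")),
    seed = seed,
    config_hash = config_hash(list(
      panel = unclass(panel),
      geometry = list(apex_base_length_mm = geometry$apex_base_length_mm,
                      basal_radius_mm = geometry$basal_radius_mm,
                      base_truncation = geometry$base_truncation),
      anchor_id = anchor_id, resolution = resolution,
      sd_rule = sd_rule, alpha = alpha,
      interpolate_fold_changes = interpolate_fold_changes)),
    stage_seconds = timings,
    outputs = as.list(tools::md5sum(files)))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE, digits = NA)

  invisible(list(expression = expression, grids = grids,
                 classification = classification,
                 zone_summaries = zs, zone_comparisons = comp,
                 segment_summaries = seg, segment_flags = flags,
                 manifest = manifest, manifest_path = manifest_path))
}

# md5 of the canonical JSON serialization of a config list
config_hash <- function(cfg) {
  f <- tempfile(fileext = ".json")
  on.exit(unlink(f))
  jsonlite::write_json(cfg, f, auto_unbox = TRUE, digits = NA)
  unname(tools::md5sum(f))
}
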