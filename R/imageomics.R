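#' Rescale fold changes to the 0-100 display range
#'
#' Electroanatomical voltage maps cannot display negative values, so fold
#' changes are mapped onto a 0-100 display scale: the minimum (strongest
#' down-regulation) maps to 0 and the maximum (strongest up-regulation) to
#' 100. When an anchor value is supplied (the fold change of a reference
#' location, conventionally basal posterior), the map is piecewise linear
#' with the anchor pinned at `anchor_target` (default 20), so the reference
#' point lands on the same display value for every gene.
#'
#' @param values Positive fold changes; may be named by location id.
#' @param anchor Optional anchor: the name of an element of `values`, or a
#'   numeric fold change within `[min(values), max(values)]`.
#' @param anchor_target Display value of the anchor (default 20).
#' @return Numeric vector of display values in \[0, 100\], same names as
#'   `values`. Constant input maps entirely to `anchor_target` with a
#'   degenerate-scale warning.
#' @export
rescale_display <- function(values, anchor = NULL, anchor_target = 20) {
  values <- if (is.list(values)) unlist(values) else values
  if (length(values) < 1) stop("at least one value is required")
  if (any(!is.finite(values)) || any(values <= 0))
    stop("fold changes must be finite and > 0")
  stopifnot(anchor_target >= 0, anchor_target <= 100)
  lo <- min(values); hi <- max(values)
  if (hi == lo) {
    warning("degenerate display scale: constant input mapped to anchor target")
    return(stats::setNames(rep(anchor_target, length(values)), names(values)))
  }
  if (is.null(anchor)) {
    out <- (values - lo) / (hi - lo) * 100
  } else {
    av <- if (is.character(anchor)) {
      if (!anchor %in% names(values)) stop("anchor id not found in values: ", anchor)
      unname(values[anchor])
    } else as.numeric(anchor)
    if (!is.finite(av) || av < lo || av > hi)
      stop("anchor value must lie within [min(values), max(values)]")
    out <- numeric(length(values))
    left <- values <= av
    out[left] <- if (av > lo)
      (values[left] - lo) / (av - lo) * anchor_target else anchor_target
    out[!left] <- anchor_target +
      (values[!left] - av) / (hi - av) * (100 - anchor_target)
  }
  stats::setNames(pmin(100, pmax(0, out)), names(values))
}

#' Inverse-distance-weighted interpolation onto a bulls-eye grid
#'
#' Interpolates scattered location values onto a regular grid over the unit
#' disk using inverse-distance weighting with exponent `power`. IDW is exact
#' at the sample points, bounded by the input range, and parameter-light —
#' properties shared with the continuous maps produced by clinical mapping
#' consoles from point-wise measurements.
#'
#' @param u,v Disk coordinates of the samples (`u = rho cos(theta)`,
#'   `v = rho sin(theta)`), inside the unit disk.
#' @param values Values at the samples (display units or fold changes).
#' @param resolution Grid nodes per axis (default 121).
#' @param power IDW exponent (default 2).
#' @return An object of class `polar_grid`: axes `u`, `v`, a
#'   `resolution x resolution` matrix `values` (NA outside the disk),
#'   logical `mask`, and the input `points`.
#' @export
idw_interpolate <- function(u, v, values, resolution = 121, power = 2) {
  u <- as.numeric(u); v <- as.numeric(v); values <- as.numeric(values)
  n <- length(values)
  if (n < 1 || length(u) != n || length(v) != n)
    stop("u, v and values must be non-empty and of equal length")
  if (any(!is.finite(u)) || any(!is.finite(v)) || any(!is.finite(values)))
    stop("non-finite inputs")
  if (any(u^2 + v^2 > 1 + 1e-9)) stop("sample points must lie inside the unit disk")
  stopifnot(resolution >= 2, power > 0)
  ax <- seq(-1, 1, length.out = resolution)
  gu <- rep(ax, times = resolution)       # column-major: rows = u, cols = v
  gv <- rep(ax, each = resolution)
  mask <- gu^2 + gv^2 <= 1 + 1e-12
  vals <- rep(NA_real_, length(gu))
  if (diff(range(values)) == 0) {  # constant field, exact by construction
    vals[mask] <- values[1]
    return(structure(
      list(u = ax, v = ax, values = matrix(vals, nrow = resolution),
           mask = matrix(mask, nrow = resolution),
           resolution = as.integer(resolution), power = power,
           points = data.frame(u = u, v = v, value = values)),
      class = "polar_grid"))
  }
  d2 <- outer(gu[mask], u, function(a, b) (a - b)^2) +
        outer(gv[mask], v, function(a, b) (a - b)^2)
  d <- sqrt(d2)
  hit <- d < 1e-12
  w <- 1 / d^power
  w[hit] <- NA  # handled exactly below
  num <- rowSums(sweep(ifelse(is.na(w), 0, w), 2, values, `*`))
  den <- rowSums(ifelse(is.na(w), 0, w))
  est <- num / den
  any_hit <- rowSums(hit) > 0
  if (any(any_hit))
    est[any_hit] <- values[apply(hit[any_hit, , drop = FALSE], 1, which.max)]
  vals[mask] <- est
  structure(
    list(u = ax, v = ax,
         values = matrix(vals, nrow = resolution),
         mask = matrix(mask, nrow = resolution),
         resolution = as.integer(resolution), power = power,
         points = data.frame(u = u, v = v, value = values)),
    class = "polar_grid")
}

#' @export
print.polar_grid <- function(x, ...) {
  cat(sprintf("Bulls-eye grid %dx%d, %d sample points, value range [%.3g, %.3g]\n",
              x$resolution, x$resolution, nrow(x$points),
              min(x$values, na.rm = TRUE), max(x$values, na.rm = TRUE)))
  invisible(x)
}

#' Display color scale
#'
#' Piecewise-linear color interpolation over ordered display-value stops.
#' The default reproduces mapping-console semantics reconciled with the
#' display convention used here: strong down-regulation (0) in red, 10 in
#' yellow, the reference/baseline anchor (20) in green, up-regulation in
#' blue (60) up to pink/magenta (100).
#'
#' @param stops Named character vector: names are display values (strictly
#'   increasing), values are hex colors.
#' @return An object of class `color_scale`.
#' @export
display_color_scale <- function(stops = c("0" = "#D7191C", "10" = "#FFE200",
                                          "20" = "#1A9641", "60" = "#2C7BB6",
                                          "100" = "#F448E0")) {
  pos <- as.numeric(names(stops))
  if (any(is.na(pos)) || is.unsorted(pos, strictly = TRUE))
    stop("color stops must have strictly increasing numeric names")
  structure(list(positions = pos, colors = unname(stops)), class = "color_scale")
}

#' Map display values to colors
#'
#' @param scale A [display_color_scale()].
#' @param values Numeric display values; values outside the stop range are
#'   clamped to the end colors.
#' @return Character vector of hex colors (`NA` values give `"#FFFFFF"`).
#' @export
scale_colors <- function(scale, values) {
  stopifnot(inherits(scale, "color_scale"))
  rgb_mat <- grDevices::col2rgb(scale$colors)
  vv <- pmin(max(scale$positions), pmax(min(scale$positions), values))
  chan <- vapply(1:3, function(k)
    stats::approx(scale$positions, rgb_mat[k, ], xout = vv, rule = 2)$y,
    numeric(length(values)))
  chan <- matrix(chan, ncol = 3)
  out <- rep("#FFFFFF", length(values))
  ok <- is.finite(values)
  out[ok] <- grDevices::rgb(chan[ok, 1], chan[ok, 2], chan[ok, 3], maxColorValue = 255)
  out
}

#' Render a bulls-eye polar map
#'
#' Draws an interpolated bulls-eye disk (apex at center, base at rim) with
#' optional AHA segment boundaries, sample markers, zone polygon overlays
#' and a color bar. Writes PNG or SVG when `file` is given, otherwise draws
#' on the active device.
#'
#' @param grid A [idw_interpolate()] result.
#' @param colors A [display_color_scale()].
#' @param file Optional output path ending in `.png` or `.svg`.
#' @param title Plot title.
#' @param segments Draw AHA 17-segment boundaries (default TRUE).
#' @param show_points Mark the sample locations (default TRUE).
#' @param zones Optional list of zone polygons (see [zone_polygon()]).
#' @param color_bar Draw the color bar (default TRUE).
#' @param width,height Device size in pixels (PNG) or inches (SVG = px/100).
#' @return Invisibly, the color raster matrix.
#' @export
render_bullseye <- function(grid, colors = display_color_scale(), file = NULL,
                            title = "", segments = TRUE, show_points = TRUE,
                            zones = NULL, color_bar = TRUE,
                            width = 640, height = 560) {
  stopifnot(inherits(grid, "polar_grid"))
  if (all(is.na(grid$values))) stop("unpopulated grid")
  col_mat <- matrix(scale_colors(colors, as.vector(grid$values)),
                    nrow = grid$resolution)
  col_mat[!grid$mask] <- NA
  # raster rows run top-to-bottom = decreasing v; matrix is [u, v]
  ras <- grDevices::as.raster(t(col_mat)[rev(seq_len(grid$resolution)), ])
  dev_open <- open_device(file, width, height)
  if (dev_open) on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(1, 1, if (nzchar(title)) 2.5 else 1, if (color_bar) 5 else 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(NA, xlim = c(-1.05, 1.05), ylim = c(-1.05, 1.05), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = title)
  graphics::rasterImage(ras, -1, -1, 1, 1, interpolate = FALSE)
  tt <- seq(0, 2 * pi, length.out = 361)
  graphics::lines(cos(tt), sin(tt), lwd = 1.5)
  if (segments) {
    sch <- aha17_scheme()
    for (r in sch$ring_breaks[c(2, 3, 4)])
      graphics::lines(r * cos(tt), r * sin(tt), col = "grey25", lwd = 0.8)
    for (ring in sch$rings[c("apical", "mid", "basal")]) {
      r0 <- switch(as.character(ring$first), "13" = 0.25, "7" = 0.5, "1" = 0.75)
      r1 <- switch(as.character(ring$first), "13" = 0.5, "7" = 0.75, "1" = 1)
      th <- (ring$theta0 + ring$sector_width * seq_len(ring$n_sectors)) * pi / 180
      graphics::segments(r0 * cos(th), r0 * sin(th), r1 * cos(th), r1 * sin(th),
                         col = "grey25", lwd = 0.8)
    }
  }
  if (show_points)
    graphics::points(grid$points$u, grid$points$v, pch = 21, bg = "white",
                     cex = 0.6, lwd = 0.5)
  if (!is.null(zones)) {
    if (inherits(zones, "zone_polygon")) zones <- list(zones)
    for (z in zones)
      graphics::polygon(z$vertices[, 1], z$vertices[, 2], border = "black",
                        lwd = 2, lty = 2)
  }
  if (color_bar) draw_color_bar(colors)
  invisible(col_mat)
}

open_device <- function(file, width, height) {
  if (is.null(file)) return(FALSE)
  ext <- tolower(tools::file_ext(file))
  switch(ext,
         png = grDevices::png(file, width = width, height = height, res = 96),
         svg = grDevices::svg(file, width = width / 100, height = height / 100),
         stop("unsupported image format: ", ext))
  TRUE
}

draw_color_bar <- function(colors, n = 101) {
  usr <- graphics::par("usr")
  vals <- seq(min(colors$positions), max(colors$positions), length.out = n)
  x0 <- usr[2] + 0.06; x1 <- usr[2] + 0.14
  yy <- seq(-0.8, 0.8, length.out = n + 1)
  op <- graphics::par(xpd = NA)
  on.exit(graphics::par(op))
  graphics::rect(x0, yy[-(n + 1)], x1, yy[-1],
                 col = scale_colors(colors, vals), border = NA)
  graphics::rect(x0, -0.8, x1, 0.8)
  at <- colors$positions
  ay <- -0.8 + 1.6 * (at - min(at)) / diff(range(at))
  graphics::text(x1 + 0.05, ay, labels = format(at), adj = 0, cex = 0.7)
}

#' Build a colored 3D LV surface mesh
#'
#' Tessellates the parametric LV surface on a regular (rho, theta) grid,
#' interpolates per-vertex display values by IDW on the flattened bulls-eye
#' disk, and attaches colors. The mesh is watertight except for the basal
#' opening.
#'
#' @param u,v Disk coordinates of the sample locations.
#' @param values Display values at the samples.
#' @param geometry An [lv_geometry()].
#' @param colors A [display_color_scale()].
#' @param n_rho,n_theta Tessellation: number of rho bands and theta steps.
#' @param power IDW exponent.
#' @return An object of class `lv_mesh`: `vertices` (N x 3, mm), `faces`
#'   (M x 3, 1-based triangle indices), `values`, `colors`.
#' @export
render_3d_surface <- function(u, v, values, geometry = lv_geometry(),
                              colors = display_color_scale(),
                              n_rho = 36, n_theta = 72, power = 2) {
  if (length(values) < 1) stop("at least one value is required")
  stopifnot(n_rho >= 2, n_theta >= 3)
  rho_b <- seq(0, 1, length.out = n_rho + 1)[-1]
  th <- seq(0, 360, length.out = n_theta + 1)[-(n_theta + 1)]
  gr <- expand.grid(theta = th, rho = rho_b)
  xyz <- polar_to_cartesian(gr$rho, gr$theta, geometry)
  vertices <- rbind(c(0, 0, -geometry$apex_base_length_mm), as.matrix(xyz))
  vu <- c(0, gr$rho * cos(gr$theta * pi / 180))
  vv <- c(0, gr$rho * sin(gr$theta * pi / 180))
  vert_vals <- idw_point_estimate(vu, vv, u, v, values, power)

  faces <- list()
  # apex fan: apex vertex 1 to first rho band
  ring0 <- 1 + seq_len(n_theta)
  faces[[1]] <- cbind(1, ring0, ring0[c(2:n_theta, 1)])
  for (i in seq_len(n_rho - 1)) {
    a <- 1 + (i - 1) * n_theta + seq_len(n_theta)
    b <- a + n_theta
    a2 <- a[c(2:n_theta, 1)]; b2 <- b[c(2:n_theta, 1)]
    faces[[i + 1]] <- rbind(cbind(a, b, b2), cbind(a, b2, a2))
  }
  structure(
    list(vertices = unname(vertices),
         faces = do.call(rbind, faces),
         values = vert_vals,
         colors = scale_colors(colors, vert_vals),
         geometry = geometry),
    class = "lv_mesh")
}

# plain IDW estimate at arbitrary points (exact where coincident)
idw_point_estimate <- function(pu, pv, u, v, values, power = 2) {
  if (diff(range(values)) == 0) return(rep(values[1], length(pu)))
  vapply(seq_along(pu), function(i) {
    d <- sqrt((pu[i] - u)^2 + (pv[i] - v)^2)
    j <- which(d < 1e-12)
    if (length(j) > 0) return(values[j[1]])
    w <- 1 / d^power
    sum(w * values) / sum(w)
  }, numeric(1))
}

#' @export
print.lv_mesh <- function(x, ...) {
  cat(sprintf("LV surface mesh: %d vertices, %d triangles, value range [%.3g, %.3g]\n",
              nrow(x$vertices), nrow(x$faces), min(x$values), max(x$values)))
  invisible(x)
}

#' Export a mesh to PLY
#'
#' Writes an `lv_mesh` with per-vertex colors as ASCII (default) or
#' binary-little-endian PLY.
#'
#' @param mesh An [render_3d_surface()] result.
#' @param path Output file path.
#' @param binary Write binary little-endian PLY instead of ASCII.
#' @return `path`, invisibly.
#' @export
write_mesh_ply <- function(mesh, path, binary = FALSE) {
  stopifnot(inherits(mesh, "lv_mesh"))
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  rgbm <- t(grDevices::col2rgb(mesh$colors))
  header <- c("ply",
              sprintf("format %s 1.0",
                      if (binary) "binary_little_endian" else "ascii"),
              sprintf("element vertex %d", nv),
              "property float x", "property float y", "property float z",
              "property uchar red", "property uchar green", "property uchar blue",
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices",
              "end_header")
  if (!binary) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    writeLines(paste(format(mesh$vertices[, 1], trim = TRUE),
                     format(mesh$vertices[, 2], trim = TRUE),
                     format(mesh$vertices[, 3], trim = TRUE),
                     rgbm[, 1], rgbm[, 2], rgbm[, 3]), con)
    writeLines(paste(3, mesh$faces[, 1] - 1, mesh$faces[, 2] - 1,
                     mesh$faces[, 3] - 1), con)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    for (i in seq_len(nv)) {
      writeBin(as.numeric(mesh$vertices[i, ]), con, size = 4, endian = "little")
      writeBin(as.raw(rgbm[i, ]), con)
    }
    for (i in seq_len(nf)) {
      writeBin(as.raw(3), con)
      writeBin(as.integer(mesh$faces[i, ] - 1), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' Export a mesh to Wavefront OBJ
#'
#' @inheritParams write_mesh_ply
#' @return `path`, invisibly.
#' @export
write_mesh_obj <- function(mesh, path) {
  stopifnot(inherits(mesh, "lv_mesh"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("# LV surface mesh", con)
  writeLines(paste("v", format(mesh$vertices[, 1], trim = TRUE),
                   format(mesh$vertices[, 2], trim = TRUE),
                   format(mesh$vertices[, 3], trim = TRUE)), con)
  writeLines(paste("f", mesh$faces[, 1], mesh$faces[, 2], mesh$faces[, 3]), con)
  invisible(path)
}
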