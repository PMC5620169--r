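#' Left-ventricular surface geometry
#'
#' Models the LV epicardial surface as a (possibly truncated) prolate
#' hemiellipsoid with the apex pointing down the negative z axis, the way an
#' explanted heart sits apex-down on a mounting tube during in vitro surface
#' mapping. The meridian is parameterised by the polar angle `phi` from the
#' apex (`phi = 0`) to the basal rim; the normalized bulls-eye radius `rho`
#' is the fraction of meridional arc length travelled from apex to base, so
#' `rho` increases strictly and uniformly-in-distance along any meridian.
#'
#' @param apex_base_length_mm Semi-axis of the ellipsoid along z (mm); the
#'   apex sits at `(0, 0, -apex_base_length_mm)`.
#' @param basal_radius_mm Equatorial semi-axis (mm); the radius of the basal
#'   rim when `base_truncation = 1`.
#' @param base_truncation Fraction of the hemiellipsoid meridian kept,
#'   counted from the apex, in (0, 1]. `1` keeps the full hemiellipsoid
#'   (rim in the z = 0 plane).
#' @return An object of class `lv_geometry`.
#' @examples
#' geom <- lv_geometry()
#' polar_to_cartesian(0.5, 90, geom)
#' @export
lv_geometry <- function(apex_base_length_mm = 80, basal_radius_mm = 30,
                        base_truncation = 1) {
  stopifnot(is.numeric(apex_base_length_mm), length(apex_base_length_mm) == 1,
            is.numeric(basal_radius_mm), length(basal_radius_mm) == 1,
            is.numeric(base_truncation), length(base_truncation) == 1)
  if (!is.finite(apex_base_length_mm) || apex_base_length_mm <= 0)
    stop("apex_base_length_mm must be > 0")
  if (!is.finite(basal_radius_mm) || basal_radius_mm <= 0)
    stop("basal_radius_mm must be > 0")
  if (!is.finite(base_truncation) || base_truncation <= 0 || base_truncation > 1)
    stop("base_truncation must lie in (0, 1]")

  a <- basal_radius_mm
  c <- apex_base_length_mm
  phi_max <- base_truncation * pi / 2

  # Meridian arc length s(phi) = int_0^phi sqrt(a^2 cos^2 t + c^2 sin^2 t) dt,
  # tabulated on a fine grid and interpolated with a monotone spline. Both
  # directions of the polar<->Cartesian conversion use this same spline, so
  # round trips are exact up to the root-finder tolerance.
  n_knots <- 4001L
  phi <- seq(0, phi_max, length.out = n_knots)
  integrand <- function(t) sqrt(a^2 * cos(t)^2 + c^2 * sin(t)^2)
  h <- phi[2] - phi[1]
  f <- integrand(phi)
  fm <- integrand(phi[-n_knots] + h / 2)
  # composite Simpson on each sub-interval
  s <- c(0, cumsum(h / 6 * (f[-n_knots] + 4 * fm + f[-1])))
  arc_fun <- stats::splinefun(phi, s, method = "hyman")

  structure(
    list(apex_base_length_mm = apex_base_length_mm,
         basal_radius_mm = basal_radius_mm,
         base_truncation = base_truncation,
         phi_max = phi_max,
         arc_fun = arc_fun,
         total_arc = s[n_knots]),
    class = "lv_geometry")
}

#' @export
print.lv_geometry <- function(x, ...) {
  cat(sprintf(
    "LV geometry: prolate hemiellipsoid, apex-base %.1f mm, basal radius %.1f mm, truncation %.2f\n",
    x$apex_base_length_mm, x$basal_radius_mm, x$base_truncation))
  invisible(x)
}

phi_from_rho <- function(rho, geometry) {
  target <- rho * geometry$total_arc
  vapply(target, function(tg) {
    if (tg <= 0) return(0)
    if (tg >= geometry$total_arc) return(geometry$phi_max)
    stats::uniroot(function(p) geometry$arc_fun(p) - tg,
                   lower = 0, upper = geometry$phi_max,
                   tol = 1e-14 * geometry$phi_max)$root
  }, numeric(1))
}

#' Convert bulls-eye polar-map coordinates to Cartesian surface points
#'
#' `rho` is the arc-length-normalized apex-to-base position (0 = apex,
#' 1 = basal rim) and `theta` the bulls-eye angle in degrees, counted
#' counterclockwise with 90 degrees at the center of the anterior wall
#' (anterior at 12 o'clock, septum at 9 o'clock in the displayed map).
#'
#' @param rho Numeric vector in \[0, 1\].
#' @param theta_deg Numeric vector in \[0, 360).
#' @param geometry An [lv_geometry()].
#' @return A data.frame with columns `x_mm`, `y_mm`, `z_mm`.
#' @export
polar_to_cartesian <- function(rho, theta_deg, geometry = lv_geometry()) {
  stopifnot(inherits(geometry, "lv_geometry"))
  n <- max(length(rho), length(theta_deg))
  rho <- rep_len(as.numeric(rho), n)
  theta_deg <- rep_len(as.numeric(theta_deg), n)
  if (any(!is.finite(rho)) || any(rho < 0 | rho > 1))
    stop("rho must lie in [0, 1]")
  if (any(!is.finite(theta_deg)) || any(theta_deg < 0 | theta_deg >= 360))
    stop("theta_deg must lie in [0, 360)")
  phi <- phi_from_rho(rho, geometry)
  th <- theta_deg * pi / 180
  data.frame(x_mm = geometry$basal_radius_mm * sin(phi) * cos(th),
             y_mm = geometry$basal_radius_mm * sin(phi) * sin(th),
             z_mm = -geometry$apex_base_length_mm * cos(phi))
}

#' Convert Cartesian surface points to bulls-eye polar-map coordinates
#'
#' Inverts [polar_to_cartesian()]. Points must lie on the geometry surface
#' within `tolerance` (relative deviation of the ellipsoid equation).
#' The apex is angularly degenerate; its `theta` is returned as 0.
#'
#' @param x_mm,y_mm,z_mm Numeric vectors of Cartesian coordinates (mm).
#' @param geometry An [lv_geometry()].
#' @param tolerance Maximum allowed relative deviation from the surface.
#' @return A data.frame with columns `rho`, `theta_deg`.
#' @export
cartesian_to_polar <- function(x_mm, y_mm, z_mm, geometry = lv_geometry(),
                               tolerance = 1e-6) {
  stopifnot(inherits(geometry, "lv_geometry"))
  n <- max(length(x_mm), length(y_mm), length(z_mm))
  x <- rep_len(as.numeric(x_mm), n)
  y <- rep_len(as.numeric(y_mm), n)
  z <- rep_len(as.numeric(z_mm), n)
  a <- geometry$basal_radius_mm
  c <- geometry$apex_base_length_mm
  dev <- abs((x / a)^2 + (y / a)^2 + (z / c)^2 - 1)
  if (any(dev > tolerance))
    stop(sprintf("point(s) off the LV surface beyond tolerance (max deviation %.3g)",
                 max(dev)))
  if (any(z > 0 + tolerance * c))
    stop("points above the basal plane are not on the kept surface")
  phi <- acos(pmin(1, pmax(-1, -z / c)))
  if (any(phi > geometry$phi_max + 1e-9))
    stop("point(s) beyond the basal truncation of the geometry")
  phi <- pmin(phi, geometry$phi_max)
  rho <- geometry$arc_fun(phi) / geometry$total_arc
  theta <- (atan2(y, x) * 180 / pi) %% 360
  theta[sin(phi) < 1e-12] <- 0  # apex: theta undefined, reported as 0
  data.frame(rho = pmin(1, pmax(0, rho)), theta_deg = theta)
}

#' AHA 17-segment scheme on the bulls-eye disk
#'
#' Standard American Heart Association left-ventricular segmentation mapped
#' to normalized bulls-eye coordinates: an apical cap (segment 17) for
#' `rho < 0.25`, an apical ring of four 90-degree sectors (13-16) for
#' `rho` in \[0.25, 0.5), a mid-cavity ring of six 60-degree sectors (7-12)
#' for \[0.5, 0.75) and a basal ring of six 60-degree sectors (1-6) for
#' \[0.75, 1\]. Sectors are half-open in `theta`; the anterior wall is
#' centered at 90 degrees and numbering proceeds counterclockwise
#' (anterior, anteroseptal/septal, inferoseptal, inferior, inferolateral,
#' anterolateral).
#'
#' @return An object of class `segment_scheme` with ring boundaries, sector
#'   offsets and the 17 segment names.
#' @export
aha17_scheme <- function() {
  structure(
    list(
      ring_breaks = c(0, 0.25, 0.5, 0.75, 1),
      rings = list(
        apex   = list(first = 17L, n_sectors = 1L, sector_width = 360, theta0 = 0),
        apical = list(first = 13L, n_sectors = 4L, sector_width = 90,  theta0 = 45),
        mid    = list(first = 7L,  n_sectors = 6L, sector_width = 60,  theta0 = 60),
        basal  = list(first = 1L,  n_sectors = 6L, sector_width = 60,  theta0 = 60)),
      segment_names = c(
        "basal anterior", "basal anteroseptal", "basal inferoseptal",
        "basal inferior", "basal inferolateral", "basal anterolateral",
        "mid anterior", "mid anteroseptal", "mid inferoseptal",
        "mid inferior", "mid inferolateral", "mid anterolateral",
        "apical anterior", "apical septal", "apical inferior",
        "apical lateral", "apex")),
    class = "segment_scheme")
}

#' Assign AHA segments to bulls-eye coordinates
#'
#' @param rho,theta_deg Numeric vectors of bulls-eye coordinates
#'   (`rho` in \[0,1\], `theta_deg` in \[0,360)).
#' @param scheme A segment scheme, by default [aha17_scheme()].
#' @return Integer vector of segment ids (1-17). Boundary ownership follows
#'   the half-open convention (a point on a ring or sector boundary belongs
#'   to the outer-`rho` / higher-index side that opens at it); `rho = 1`
#'   belongs to the basal ring.
#' @export
assign_segment <- function(rho, theta_deg, scheme = aha17_scheme()) {
  stopifnot(inherits(scheme, "segment_scheme"))
  n <- max(length(rho), length(theta_deg))
  rho <- rep_len(as.numeric(rho), n)
  theta <- rep_len(as.numeric(theta_deg), n) %% 360
  if (any(!is.finite(rho)) || any(rho < 0 | rho > 1))
    stop("rho must lie in [0, 1]")
  br <- scheme$ring_breaks
  ring <- findInterval(rho, br, rightmost.closed = TRUE)  # 1..4, rho=1 -> basal
  out <- integer(n)
  for (r in seq_along(scheme$rings)) {
    ri <- scheme$rings[[r]]
    idx <- ring == r
    if (!any(idx)) next
    sector <- floor(((theta[idx] - ri$theta0) %% 360) / ri$sector_width)
    sector <- pmin(sector, ri$n_sectors - 1)  # guard exact 360 wrap
    out[idx] <- ri$first + as.integer(sector)
  }
  out
}

#' Generate a quasi-uniform LV sampling scheme
#'
#' Places `n` sampling locations on the LV surface in concentric bulls-eye
#' rings, emulating equal distribution of biopsy sites over the whole left
#' ventricle. The default `n = 52` uses the deterministic ring layout
#' 4/12/16/20 (apex to base) at ring radii `rho` = 0.125, 0.375, 0.625,
#' 0.875, which puts at least one location in every AHA segment. Other `n`
#' are distributed over the four rings by largest remainder of the same
#' proportions. Locations are reproducible without a seed; supplying
#' `jitter_seed` adds small random perturbations in `rho` and `theta`.
#'
#' @param n Number of locations (>= 1). `n = 1` returns the apex alone.
#' @param geometry An [lv_geometry()].
#' @param jitter_seed Optional integer; if given, jitter the deterministic
#'   layout.
#' @param scheme Segment scheme used for labelling.
#' @return A data.frame with columns `location_id`, `x_mm`, `y_mm`, `z_mm`,
#'   `rho`, `theta_deg`, `segment`.
#' @export
generate_sampling_scheme <- function(n = 52, geometry = lv_geometry(),
                                     jitter_seed = NULL,
                                     scheme = aha17_scheme()) {
  if (!is.numeric(n) || length(n) != 1 || !is.finite(n) || n < 1)
    stop("n must be a single integer >= 1")
  n <- as.integer(n)
  if (n == 1L) {
    loc <- data.frame(location_id = "r0p01", rho = 0, theta_deg = 0)
  } else {
    ring_rho <- c(0.125, 0.375, 0.625, 0.875)
    weights <- c(4, 12, 16, 20) / 52
    counts <- floor(n * weights)
    rem <- n - sum(counts)
    if (rem > 0) {
      extra <- order(n * weights - counts, decreasing = TRUE)[seq_len(rem)]
      counts[extra] <- counts[extra] + 1L
    }
    rows <- list()
    for (r in seq_along(ring_rho)) {
      k <- counts[r]
      if (k == 0) next
      pos <- seq_len(k)
      rows[[r]] <- data.frame(
        location_id = sprintf("r%dp%02d", r, pos),
        rho = rep(ring_rho[r], k),
        theta_deg = (90 + (pos - 1) * 360 / k) %% 360)
    }
    loc <- do.call(rbind, rows)
    if (!is.null(jitter_seed)) {
      old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
      set.seed(as.integer(jitter_seed))
      loc$rho <- pmin(1, pmax(0.01, loc$rho + stats::runif(nrow(loc), -0.03, 0.03)))
      loc$theta_deg <- (loc$theta_deg + stats::runif(nrow(loc), -5, 5)) %% 360
    }
  }
  xyz <- polar_to_cartesian(loc$rho, loc$theta_deg, geometry)
  loc <- cbind(loc[, "location_id", drop = FALSE], xyz,
               loc[, c("rho", "theta_deg")])
  loc$segment <- assign_segment(loc$rho, loc$theta_deg, scheme)
  rownames(loc) <- NULL
  loc
}

# Disk (u, v) coordinates of bulls-eye points: u = rho cos(theta), v = rho sin(theta)
polar_to_disk <- function(rho, theta_deg) {
  th <- theta_deg * pi / 180
  cbind(u = rho * cos(th), v = rho * sin(th))
}
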