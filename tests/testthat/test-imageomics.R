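test_that("display rescale hits the worked examples exactly", {
  expect_equal(unname(rescale_display(c(0.5, 1.0, 4.5))), c(0, 12.5, 100))
  expect_equal(unname(rescale_display(c(0.5, 1.0, 4.5), anchor = 1.0)),
               c(0, 20, 100))
  v <- c(a = 0.5, b = 1.0, c = 4.5)
  expect_equal(unname(rescale_display(v, anchor = "b")), c(0, 20, 100))
  expect_warning(out <- rescale_display(rep(1, 5)), "degenerate")
  expect_equal(unname(out), rep(20, 5))
  expect_error(rescale_display(c(1, -2)), "> 0")
  expect_error(rescale_display(c(a = 1, b = 2), anchor = "z"), "anchor id")
})

test_that("display rescale is monotone with exact endpoints", {
  set.seed(5)
  for (i in 1:200) {
    v <- exp(rnorm(50, 0, 1))
    anchor <- sample(sort(v)[2:49], 1)  # interior anchor, as in practice
    for (out in list(rescale_display(v), rescale_display(v, anchor = anchor))) {
      expect_equal(min(out), 0)
      expect_equal(max(out), 100)
      expect_true(all(diff(out[order(v)]) >= -1e-12))
      expect_true(all(out >= 0 & out <= 100))
    }
  }
})

test_that("IDW is exact at nodes, bounded, and constant for one point", {
  g1 <- idw_interpolate(0.2, -0.1, 42, resolution = 41)
  expect_true(all(g1$values[g1$mask] == 42))

  # grid node exactly at a sample point takes its value
  g2 <- idw_interpolate(c(0, 0.5), c(0, 0), c(7.3, 50), resolution = 41)
  expect_equal(g2$values[21, 21], 7.3)  # node (0, 0)

  # symmetry forces the mean at the center
  g3 <- idw_interpolate(c(-0.5, 0.5, 0, 0), c(0, 0, -0.5, 0.5),
                        c(1, 1, 3, 3), resolution = 41)
  expect_equal(g3$values[21, 21], 2)

  set.seed(8)
  u <- runif(30, -0.6, 0.6); v <- runif(30, -0.6, 0.6)
  val <- runif(30, 0, 100)
  g4 <- idw_interpolate(u, v, val, resolution = 61, power = 2)
  expect_gte(min(g4$values, na.rm = TRUE), min(val))
  expect_lte(max(g4$values, na.rm = TRUE), max(val))
  expect_true(all(is.na(g4$values[!g4$mask])))
  # determinism: bit-identical on identical input
  g5 <- idw_interpolate(u, v, val, resolution = 61, power = 2)
  expect_identical(g4$values, g5$values)

  expect_error(idw_interpolate(numeric(0), numeric(0), numeric(0)), "non-empty")
  expect_error(idw_interpolate(2, 0, 1), "unit disk")
})

test_that("color scale interpolates the configured stops", {
  cs <- display_color_scale()
  at_stops <- scale_colors(cs, cs$positions)
  expect_equal(toupper(at_stops), toupper(cs$colors))
  # midpoint of two stops is the channel-wise average (up to rgb rounding)
  mid <- scale_colors(cs, 5)
  expect_lte(max(abs(grDevices::col2rgb(mid) -
                       (grDevices::col2rgb(cs$colors[1]) +
                          grDevices::col2rgb(cs$colors[2])) / 2)), 1)
  # clamped outside the range
  expect_equal(scale_colors(cs, c(-10, 400)), scale_colors(cs, c(0, 100)))
  expect_error(display_color_scale(c("10" = "#000000", "5" = "#FFFFFF")),
               "strictly increasing")
})

test_that("bulls-eye rendering writes an image with the expected dominant color", {
  skip_if_not_installed("png")
  grid <- idw_interpolate(c(0, 0.5), c(0, 0), c(20, 20), resolution = 61)
  f <- file.path(tempdir(), "const20.png")
  render_bullseye(grid, file = f, segments = FALSE, show_points = FALSE,
                  color_bar = FALSE)
  expect_true(file.exists(f) && file.info(f)$size > 0)
  img <- png::readPNG(f)
  green <- grDevices::col2rgb(display_color_scale()$colors[3]) / 255
  hit <- abs(img[, , 1] - green[1]) < 0.02 & abs(img[, , 2] - green[2]) < 0.02 &
    abs(img[, , 3] - green[3]) < 0.02
  expect_gt(mean(hit), 0.3)  # the disk covers well over a third of the canvas
  unlink(f)
})

test_that("synthetic 5h map separates ischemic core from remote display values", {
  st <- simulate_study(seed = 4)
  ex <- delta_delta_ct(collapse_replicates(st$ct))
  hk <- ex[ex$gene == "HK2" & ex$group == "ir5h", ]
  fc <- tapply(hk$fold_change, hk$sample_id, mean)
  loc <- st$locations[match(names(fc), st$locations$location_id), ]
  uv <- cbind(loc$rho * cospi(loc$theta_deg / 180), loc$rho * sinpi(loc$theta_deg / 180))
  disp <- rescale_display(as.numeric(fc))
  grid <- idw_interpolate(uv[, 1], uv[, 2], disp, resolution = 81)
  gu <- matrix(rep(grid$u, times = 81), 81)
  gv <- matrix(rep(grid$v, each = 81), 81)
  core <- sqrt(gu^2 + (gv - 0.35)^2) < 0.25 & grid$mask
  remote <- sqrt(gu^2 + (gv - 0.35)^2) > 0.55 & grid$mask
  expect_gt(mean(grid$values[core]) - mean(grid$values[remote]), 20)
})

test_that("3D surface mesh lies on the geometry with bounded IDW values", {
  g <- lv_geometry()
  set.seed(9)
  loc <- generate_sampling_scheme(20, g)
  uv <- cbind(loc$rho * cospi(loc$theta_deg / 180),
              loc$rho * sinpi(loc$theta_deg / 180))
  vals <- runif(20, 10, 90)
  mesh <- render_3d_surface(uv[, 1], uv[, 2], vals, g, n_rho = 12, n_theta = 24)
  expect_identical(nrow(mesh$vertices), 1L + 12L * 24L)
  dev <- (mesh$vertices[, 1] / g$basal_radius_mm)^2 +
    (mesh$vertices[, 2] / g$basal_radius_mm)^2 +
    (mesh$vertices[, 3] / g$apex_base_length_mm)^2 - 1
  expect_lt(max(abs(dev)), 1e-9)
  # vertices project back into the unit disk
  pol <- cartesian_to_polar(mesh$vertices[, 1], mesh$vertices[, 2],
                            mesh$vertices[, 3], g)
  expect_true(all(pol$rho <= 1 + 1e-12))
  expect_gte(min(mesh$values), min(vals))
  expect_lte(max(mesh$values), max(vals))
  # constant input -> single-color mesh
  mono <- render_3d_surface(uv[, 1], uv[, 2], rep(20, 20), g,
                            n_rho = 6, n_theta = 12)
  expect_identical(length(unique(mono$colors)), 1L)
  # face indices reference existing vertices
  expect_true(all(mesh$faces >= 1 & mesh$faces <= nrow(mesh$vertices)))
})

test_that("PLY and OBJ exports are well-formed", {
  uv <- cbind(c(0, 0.3), c(0, 0.2))
  mesh <- render_3d_surface(uv[, 1], uv[, 2], c(10, 80), n_rho = 4, n_theta = 8)
  ply <- file.path(tempdir(), "mesh.ply")
  obj <- file.path(tempdir(), "mesh.obj")
  write_mesh_ply(mesh, ply)
  write_mesh_obj(mesh, obj)
  lines <- readLines(ply)
  expect_identical(lines[1], "ply")
  nv <- as.integer(sub("element vertex ", "", grep("element vertex", lines, value = TRUE)))
  nf <- as.integer(sub("element face ", "", grep("element face", lines, value = TRUE)))
  expect_identical(nv, nrow(mesh$vertices))
  expect_identical(nf, nrow(mesh$faces))
  body <- lines[(which(lines == "end_header") + 1):length(lines)]
  expect_identical(length(body), nv + nf)
  olines <- readLines(obj)
  expect_identical(sum(startsWith(olines, "v ")), nrow(mesh$vertices))
  expect_identical(sum(startsWith(olines, "f ")), nrow(mesh$faces))
  unlink(c(ply, obj))
})
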