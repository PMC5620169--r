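square_zone <- function(h = 0.5) {
  zone_polygon(rbind(c(-h, -h), c(h, -h), c(h, h), c(-h, h)))
}

star_zone <- function() {
  k <- 0:9
  r <- ifelse(k %% 2 == 0, 0.7, 0.3)
  zone_polygon(cbind(r * cos(k * pi / 5), r * sin(k * pi / 5)))
}

test_that("polygon validation rejects degenerate input", {
  expect_error(zone_polygon(rbind(c(0, 0), c(1, 0))), ">= 3")
  expect_error(zone_polygon(rbind(c(0, 0), c(2, 0), c(0, 2))), "unit disk")
  bowtie <- rbind(c(-0.5, -0.5), c(0.5, 0.5), c(0.5, -0.5), c(-0.5, 0.5))
  expect_error(zone_polygon(bowtie), "self-intersecting")
})

test_that("point-in-zone classifies center, exterior and boundary points", {
  z <- square_zone()
  expect_true(point_in_zone(0, 0, z))
  expect_false(point_in_zone(0.9, 0.3, z))
  # edge and vertex points count as inside
  expect_true(point_in_zone(0.5, 0, z))
  expect_true(point_in_zone(0.5, 0.5, z))
})

test_that("point-in-zone matches a ray-casting oracle on a star polygon", {
  z <- star_zone()
  set.seed(31)
  n <- 200
  r <- sqrt(runif(n)) * 0.95
  a <- runif(n, 0, 2 * pi)
  px <- r * cos(a); py <- r * sin(a)
  got <- point_in_zone(px, py, z)
  want <- oracle_point_in_polygon(px, py, z$vertices)
  expect_identical(got, want)
})

test_that("zone transposition is an exact identity across group maps", {
  loc <- generate_sampling_scheme()
  z <- zone_polygon(rbind(c(-0.1, 0.05), c(0.55, 0.05), c(0.55, 0.7), c(-0.1, 0.7)))
  per_group <- list(control = loc, ir5h = loc, ir24h = loc)
  cls <- transpose_zone(z, per_group)
  single <- transpose_zone(z, loc)
  expect_identical(cls, single)
  expect_gt(sum(cls$inside), 0)
  # mismatched location sets abort
  bad <- loc; bad$location_id[1] <- "other"
  expect_error(transpose_zone(z, list(loc, bad)), "mismatched location sets")
  shifted <- loc; shifted$rho[2] <- shifted$rho[2] + 0.01
  expect_error(transpose_zone(z, list(loc, shifted)), "coordinates")
  # a sliver polygon catching no sample classifies nothing inside
  sliver <- zone_polygon(rbind(c(0.01, 0.012), c(0.02, 0.012), c(0.02, 0.013)))
  expect_identical(sum(transpose_zone(sliver, loc)$inside), 0L)
})

test_that("zone summaries average fold changes per animal inside and outside", {
  expr <- data.frame(
    animal_id = "a1", group = "ir5h",
    sample_id = c("p1", "p2", "q1", "q2", "q3"),
    gene = "G",
    fold_change = c(2, 4, 1, 1, 1))
  cls <- data.frame(location_id = c("p1", "p2", "q1", "q2", "q3"),
                    inside = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  zs <- zone_summaries(expr, cls)
  expect_equal(zs$mean_inside, 3)
  expect_equal(zs$mean_outside, 1)
  expect_equal(c(zs$n_inside, zs$n_outside), c(2, 3))

  # all fold changes 1 -> both means 1
  expr$fold_change <- 1
  zs1 <- zone_summaries(expr, cls)
  expect_equal(c(zs1$mean_inside, zs1$mean_outside), c(1, 1))

  cls$inside <- FALSE
  expect_error(zone_summaries(expr, cls), "no sampling locations")
})

test_that("one-way ANOVA matches a sums-of-squares oracle and the t-test identity", {
  # equal group means -> F = 0, p = 1
  eq <- anova_groups(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_equal(eq$f, 0)
  expect_equal(eq$p, 1)

  # textbook toy: groups (1,2), (3,4), (5,6)
  toy <- anova_groups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b", "c"), each = 2))
  ref <- oracle_anova(c(1, 2, 3, 4, 5, 6), rep(c("a", "b", "c"), each = 2))
  expect_equal(toy$f, ref$f, tolerance = 1e-12)
  expect_equal(toy$p, ref$p, tolerance = 1e-12)

  # two groups: F equals the square of the pooled-variance t statistic
  set.seed(13)
  a <- rnorm(8); b <- rnorm(6, 0.5)
  two <- anova_groups(c(a, b), rep(c("a", "b"), c(8, 6)))
  t <- t.test(a, b, var.equal = TRUE)$statistic
  expect_equal(two$f, unname(t^2), tolerance = 1e-10)

  expect_error(anova_groups(1:3, c("a", "a", "b")), ">= 2 values")
})

test_that("Holm-Sidak adjustment reproduces the step-down closed form", {
  expect_equal(holm_sidak_adjust(c(0.01, 0.02, 0.04)),
               c(1 - 0.99^3, 1 - 0.98^2, 0.04), tolerance = 1e-12)
  expect_equal(round(holm_sidak_adjust(c(0.01, 0.02, 0.04)), 6),
               c(0.029701, 0.039600, 0.040000))
  expect_equal(holm_sidak_adjust(c(1, 1)), c(1, 1))
  expect_equal(holm_sidak_adjust(0.03), 0.03)
  # original order is preserved
  p <- c(0.04, 0.01, 0.02)
  expect_equal(holm_sidak_adjust(p)[2], 1 - 0.99^3)
  expect_error(holm_sidak_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("Holm-Sidak dominates Holm-Bonferroni and keeps p-value invariants", {
  set.seed(17)
  for (i in 1:300) {
    m <- sample(2:8, 1)
    p <- runif(m)
    hs <- holm_sidak_adjust(p)
    hb <- p.adjust(p, "holm")
    expect_true(all(hs <= hb + 1e-12))
    expect_true(all(hs >= p - 1e-12))
    expect_true(all(hs >= 0 & hs <= 1))
    o <- order(p)
    expect_true(all(diff(hs[o]) >= -1e-12))
  }
})

test_that("zone group comparison returns coherent per-contrast results", {
  st <- simulate_study(seed = 6)
  ex <- delta_delta_ct(collapse_replicates(st$ct))
  cls <- transpose_zone(ground_truth_zone_polygon(st$config), st$locations)
  zs <- zone_summaries(ex, cls)
  comp <- compare_zone_groups(zs)
  expect_identical(nrow(comp), 7L * 2L * 3L)
  expect_true(all(comp$p_adj >= comp$p_raw - 1e-12))
  expect_true(all(comp$f >= 0))
  expect_true(all(comp$anova_p >= 0 & comp$anova_p <= 1))
  # a strong configured 5h core effect is detected in the ischemic zone
  casp <- comp[comp$gene == "CASP3" & comp$zone == "ischemic" &
                 comp$contrast == "control vs ir5h", ]
  expect_lt(casp$p_adj, 0.001)
})

test_that("threshold helper proposes a zone around the hot region", {
  st <- simulate_study(seed = 12)
  ex <- delta_delta_ct(collapse_replicates(st$ct))
  hk <- ex[ex$gene == "CASP3" & ex$group == "ir5h", ]
  fc <- tapply(hk$fold_change, hk$sample_id, mean)
  loc <- st$locations[match(names(fc), st$locations$location_id), ]
  uv <- cbind(loc$rho * cospi(loc$theta_deg / 180),
              loc$rho * sinpi(loc$theta_deg / 180))
  grid <- idw_interpolate(uv[, 1], uv[, 2],
                          rescale_display(as.numeric(fc)), resolution = 81)
  z <- suggest_zone_by_threshold(grid)
  expect_s3_class(z, "zone_polygon")
  ctr <- colMeans(z$vertices)
  expect_lt(sqrt(ctr[1]^2 + (ctr[2] - 0.35)^2), 0.25)
})
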