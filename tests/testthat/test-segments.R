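toy_segment_data <- function() {
  # 6 locations in 2 segments, 1 animal per group
  loc <- data.frame(location_id = sprintf("L%d", 1:6),
                    segment = c(1, 1, 1, 10, 10, 10))
  expr <- rbind(
    data.frame(animal_id = "c1", group = "control",
               sample_id = loc$location_id, gene = "G",
               fold_change = c(1.0, 1.2, 0.8, 1.1, 0.9, 1.0)),
    data.frame(animal_id = "t1", group = "ir5h",
               sample_id = loc$location_id, gene = "G",
               fold_change = c(3.0, 3.4, 2.6, 1.0, 1.1, 0.9)))
  list(loc = loc, expr = expr)
}

test_that("segment summaries match hand computation and conserve counts", {
  d <- toy_segment_data()
  s <- segment_summaries(d$expr, d$loc)
  ctl1 <- s[s$group == "control" & s$segment == 1, ]
  expect_equal(ctl1$n, 3L)
  expect_equal(ctl1$mean, 1)
  expect_equal(ctl1$sd, sd(c(1.0, 1.2, 0.8)), tolerance = 1e-12)
  # empty segments reported with n = 0 and NA statistics
  expect_identical(nrow(s), 2L * 17L)
  empty <- s[s$segment == 5 & s$group == "control", ]
  expect_identical(empty$n, 0L)
  expect_true(is.na(empty$mean) && is.na(empty$sd))
  # conservation: counts sum to the number of locations per gene x group
  expect_equal(as.vector(tapply(s$n, s$group, sum)), c(6L, 6L))
})

test_that("uniform fold changes give mean 1 and SD 0 in occupied segments", {
  loc <- generate_sampling_scheme()
  expr <- data.frame(animal_id = "a", group = "control",
                     sample_id = loc$location_id, gene = "G", fold_change = 1)
  s <- segment_summaries(expr, loc)
  occ <- s[s$n > 0, ]
  expect_equal(sum(s$n), 52L)
  expect_true(all(occ$mean == 1))
  expect_true(all(occ$sd[occ$n >= 2] == 0))
})

test_that("default study yields 17 summaries per gene and group totalling 52", {
  st <- simulate_study(seed = 15)
  ex <- delta_delta_ct(collapse_replicates(st$ct))
  s <- segment_summaries(ex, st$locations)
  expect_identical(nrow(s), 7L * 3L * 17L)
  per <- tapply(s$n, paste(s$gene, s$group), sum)
  expect_true(all(per == 52 * table(st$animals$group)[
    sub(".* ", "", names(per))]))
})

test_that("2xSD relevance flags follow the pooled-SD rule strictly", {
  mk <- function(mean_a, sd_a, mean_b, sd_b, n = 3) {
    a <- data.frame(gene = "G", group = "control", segment = 1:17,
                    n = n, mean = 1, sd = 0.1)
    b <- data.frame(gene = "G", group = "ir5h", segment = 1:17,
                    n = n, mean = 1, sd = 0.1)
    a$mean[1] <- mean_a; a$sd[1] <- sd_a
    b$mean[1] <- mean_b; b$sd[1] <- sd_b
    relevance_flags(a, b)[1, ]
  }
  # zero difference is never relevant
  expect_false(mk(10, 3, 10, 5)$flagged)
  # forced by the formula: pooled SD 1, threshold 2, diff 5
  f <- mk(10, 1, 15, 1)
  expect_equal(f$threshold, 2)
  expect_true(f$flagged)
  # boundary: diff exactly 2 x pooled SD is NOT flagged (strict inequality)
  expect_false(mk(10, 1, 12, 1)$flagged)
  expect_true(mk(10, 1, 12.0001, 1)$flagged)
})

test_that("relevance flags are symmetric, scale-equivariant and NA-safe", {
  d <- toy_segment_data()
  s <- segment_summaries(d$expr, d$loc)
  a <- s[s$group == "control", ]; b <- s[s$group == "ir5h", ]
  fab <- relevance_flags(a, b); fba <- relevance_flags(b, a)
  expect_identical(fab$flagged, fba$flagged)
  expect_equal(fab$diff, fba$diff)
  expect_equal(fab$threshold, fba$threshold)
  # segment 1 differs strongly, segment 10 does not
  expect_true(fab$flagged[fab$segment == 1])
  expect_false(fab$flagged[fab$segment == 10])
  # undetermined (n < 2) segments are NA
  expect_true(all(is.na(fab$flagged[!fab$segment %in% c(1, 10)])))
  # scale equivariance: multiplying all fold changes by c > 0 changes nothing
  d2 <- d; d2$expr$fold_change <- d2$expr$fold_change * 3.7
  s2 <- segment_summaries(d2$expr, d2$loc)
  f2 <- relevance_flags(s2[s2$group == "control", ], s2[s2$group == "ir5h", ])
  expect_identical(f2$flagged, fab$flagged)
  expect_equal(f2$diff, fab$diff * 3.7)
  expect_equal(f2$threshold, fab$threshold * 3.7)
})

test_that("alternative SD-rule readings are available behind the switch", {
  d <- toy_segment_data()
  s <- segment_summaries(d$expr, d$loc)
  a <- s[s$group == "control", ]; b <- s[s$group == "ir5h", ]
  som <- relevance_flags(a, b, rule = "sd_of_means")
  # 2 x SD of the two means = sqrt(2) |diff| > |diff|: can never flag
  expect_true(all(!som$flagged, na.rm = TRUE))
  ssum <- relevance_flags(a, b, rule = "sum_sd")
  expect_equal(ssum$threshold[ssum$segment == 1],
               2 * (a$sd[a$segment == 1] + b$sd[b$segment == 1]))
  expect_error(relevance_flags(a, b[-1, ]), "mismatched")
})

test_that("segment polar display renders flags with red/grey/white fills", {
  d <- toy_segment_data()
  s <- segment_summaries(d$expr, d$loc)
  fl <- relevance_flags(s[s$group == "control", ], s[s$group == "ir5h", ])
  f <- file.path(tempdir(), "segpolar.png")
  fills <- render_segment_polar(fl, file = f)
  expect_true(file.exists(f) && file.info(f)$size > 0)
  expect_identical(unname(fills["1"]), "#D7191C")
  expect_identical(unname(fills["10"]), "white")
  expect_identical(unname(fills["5"]), "grey75")
  # no flags -> no red wedge; all flagged -> all red
  fl0 <- fl; fl0$flagged <- FALSE
  expect_false(any(render_segment_polar(fl0, file = f) == "#D7191C"))
  fl1 <- fl; fl1$flagged <- TRUE
  expect_true(all(render_segment_polar(fl1, file = f) == "#D7191C"))
  # summaries are filled through the color scale
  fills_mean <- render_segment_polar(s[s$group == "control", ], file = f)
  expect_identical(length(fills_mean), 17L)
  expect_error(render_segment_polar(fl[-1, ]), "one row per segment")
  unlink(f)
})
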