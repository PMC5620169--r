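#' Ischemic / remote zone polygon
#'
#' A zone delineated on the bulls-eye plane (typically around the visibly
#' ischemic territory on the 5h map) as an ordered, implicitly closed
#' polygon. The remote zone is the complement of the ischemic polygon
#' within the disk.
#'
#' @param vertices Two-column matrix (or list of `c(u, v)` pairs) of polygon
#'   vertices on the bulls-eye plane; at least 3, non-self-intersecting,
#'   inside the unit disk.
#' @param label Zone label, `"ischemic"` or `"remote"`.
#' @param source_group Group of the map the zone was drawn on.
#' @return An object of class `zone_polygon`.
#' @export
zone_polygon <- function(vertices, label = "ischemic", source_group = "ir5h") {
  if (is.list(vertices) && !is.data.frame(vertices))
    vertices <- do.call(rbind, vertices)
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3)
    stop("a zone polygon needs >= 3 (u, v) vertices")
  storage.mode(vertices) <- "double"
  if (any(!is.finite(vertices))) stop("non-finite polygon vertices")
  if (any(rowSums(vertices^2) > 1 + 1e-9))
    stop("polygon vertices must lie within the unit disk")
  if (polygon_self_intersects(vertices))
    stop("polygon is self-intersecting")
  label <- match.arg(label, c("ischemic", "remote"))
  structure(list(vertices = unname(vertices), label = label,
                 source_group = source_group),
            class = "zone_polygon")
}

# segment-intersection scan over non-adjacent edges
polygon_self_intersects <- function(V) {
  n <- nrow(V)
  E <- cbind(seq_len(n), c(2:n, 1))
  seg_int <- function(p1, p2, p3, p4) {
    d <- function(a, b, c) (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
    d1 <- d(p3, p4, p1); d2 <- d(p3, p4, p2)
    d3 <- d(p1, p2, p3); d4 <- d(p1, p2, p4)
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(n - 2)) for (j in (i + 2):n) {
    if (i == 1 && j == n) next  # adjacent through closure
    if (seg_int(V[E[i, 1], ], V[E[i, 2], ], V[E[j, 1], ], V[E[j, 2], ]))
      return(TRUE)
  }
  FALSE
}

#' Point-in-zone classification
#'
#' Even-odd (crossing-number) rule; points that fall exactly on a polygon
#' edge or vertex count as inside, so boundary samples have a deterministic
#' owner.
#'
#' @param u,v Coordinates of the query points on the bulls-eye plane.
#' @param zone A [zone_polygon()].
#' @param edge_tol Distance below which a point is treated as on an edge.
#' @return Logical vector: inside (or on the boundary of) the zone.
#' @export
point_in_zone <- function(u, v, zone, edge_tol = 1e-12) {
  stopifnot(inherits(zone, "zone_polygon"))
  V <- zone$vertices
  n <- nrow(V)
  xs <- V[, 1]; ys <- V[, 2]
  xe <- xs[c(2:n, 1)]; ye <- ys[c(2:n, 1)]
  vapply(seq_along(u), function(i) {
    px <- u[i]; py <- v[i]
    # on-edge check
    dx <- xe - xs; dy <- ye - ys
    len2 <- dx^2 + dy^2
    t <- pmin(1, pmax(0, ((px - xs) * dx + (py - ys) * dy) / ifelse(len2 == 0, 1, len2)))
    d2 <- (xs + t * dx - px)^2 + (ys + t * dy - py)^2
    if (any(d2 <= edge_tol^2)) return(TRUE)
    # crossing number for ray towards +u
    crosses <- ((ys > py) != (ye > py)) &
      (px < xs + (py - ys) * dx / dy)
    sum(crosses, na.rm = TRUE) %% 2 == 1
  }, logical(1))
}

#' Transpose a zone across group maps
#'
#' Applies a polygon drawn on one group's bulls-eye map verbatim to other
#' groups' maps. Because all groups share the same sampling locations and
#' coordinates, the classification is identical across maps; this is
#' verified and an error is raised on mismatched location sets.
#'
#' @param zone A [zone_polygon()].
#' @param locations A location data.frame (columns `location_id`, `rho`,
#'   `theta_deg`), or a named list of such data.frames (one per group map).
#' @return A data.frame `location_id`, `inside` (logical), `zone_label`.
#' @export
transpose_zone <- function(zone, locations) {
  stopifnot(inherits(zone, "zone_polygon"))
  if (is.data.frame(locations)) locations <- list(locations)
  ref <- locations[[1]]
  need <- c("location_id", "rho", "theta_deg")
  for (loc in locations) {
    if (!all(need %in% names(loc)))
      stop("location tables need columns: ", paste(need, collapse = ", "))
    if (!identical(sort(loc$location_id), sort(ref$location_id)))
      stop("mismatched location sets across group maps")
    m <- match(ref$location_id, loc$location_id)
    if (max(abs(loc$rho[m] - ref$rho), abs(loc$theta_deg[m] - ref$theta_deg)) > 1e-9)
      stop("mismatched location coordinates across group maps")
  }
  uv <- polar_to_disk(ref$rho, ref$theta_deg)
  data.frame(location_id = ref$location_id,
             inside = point_in_zone(uv[, 1], uv[, 2], zone),
             zone_label = zone$label, stringsAsFactors = FALSE)
}

#' Per-animal ischemic/remote zone summaries
#'
#' Averages fold changes (never display values) over the locations inside
#' and outside the zone, per animal and gene. The animal is the unit of
#' analysis for the downstream group comparison, avoiding pseudo-replication
#' of the many within-heart samples.
#'
#' @param expression An expression table from [delta_delta_ct()] with
#'   columns `animal_id`, `group`, `sample_id`, `gene`, `fold_change`.
#' @param classification A [transpose_zone()] result (or data.frame with
#'   `location_id` and `inside`).
#' @return A data.frame with one row per animal x gene: `mean_inside`,
#'   `mean_outside`, `n_inside`, `n_outside`.
#' @export
zone_summaries <- function(expression, classification) {
  need <- c("animal_id", "group", "sample_id", "gene", "fold_change")
  if (!all(need %in% names(expression)))
    stop("expression table needs columns: ", paste(need, collapse = ", "))
  if (!all(expression$sample_id %in% classification$location_id))
    stop("unclassified locations in expression table: ",
         paste(utils::head(setdiff(expression$sample_id,
                                   classification$location_id)), collapse = ", "))
  inside_ids <- classification$location_id[classification$inside]
  if (length(inside_ids) == 0)
    stop(sprintf("zone '%s' contains no sampling locations",
                 if ("zone_label" %in% names(classification))
                   classification$zone_label[1] else "ischemic"))
  expression$inside <- expression$sample_id %in% inside_ids
  agg <- stats::aggregate(fold_change ~ animal_id + group + gene + inside,
                          data = expression, FUN = mean)
  cnt <- stats::aggregate(fold_change ~ animal_id + group + gene + inside,
                          data = expression, FUN = length)
  key <- function(d) paste(d$animal_id, d$gene, sep = "\r")
  inside_part <- agg[agg$inside, ]
  outside_part <- agg[!agg$inside, ]
  out <- inside_part[, c("animal_id", "group", "gene")]
  out$mean_inside <- inside_part$fold_change
  mo <- match(key(inside_part), key(outside_part))
  out$mean_outside <- outside_part$fold_change[mo]
  ci <- cnt[cnt$inside, ]; co <- cnt[!cnt$inside, ]
  out$n_inside <- ci$fold_change[match(key(inside_part), key(ci))]
  out$n_outside <- co$fold_change[match(key(inside_part), key(co))]
  out <- out[order(out$gene, out$group, out$animal_id), ]
  rownames(out) <- NULL
  out
}

#' One-way fixed-effects ANOVA
#'
#' Classic between/within decomposition: `F = MS_between / MS_within` with
#' the p value from the F distribution. The fully degenerate case (zero
#' between- and within-group variance) is reported as `F = 0, p = 1`.
#'
#' @param values Numeric response.
#' @param groups Group labels (coerced to factor).
#' @return A list with `f`, `p`, `df_between`, `df_within`, `group_means`,
#'   `group_n`.
#' @export
anova_groups <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2) stop("need >= 2 groups")
  if (any(table(groups) < 2)) stop("need >= 2 values per group")
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  fit <- stats::lm(values ~ groups)
  av <- stats::anova(fit)
  f <- av[1, "F value"]; p <- av[1, "Pr(>F)"]
  if (!is.finite(f)) {  # zero residual variance
    if (av[1, "Sum Sq"] <= .Machine$double.eps * sum(values^2 + 1)) {
      f <- 0; p <- 1
    } else {
      f <- Inf; p <- 0
    }
  }
  list(f = f, p = p,
       df_between = av[1, "Df"], df_within = av[2, "Df"],
       group_means = gm, group_n = gn)
}

#' Holm-Sidak step-down adjustment
#'
#' Step-down Sidak procedure: with the raw p values sorted ascending,
#' `adj_(i) = 1 - (1 - p_(i))^(m - i + 1)`, enforced non-decreasing over the
#' step-down order, clipped to 1, and returned in the original order. It is
#' uniformly at least as powerful as Holm-Bonferroni.
#'
#' @param p Raw p values in \[0, 1\].
#' @return Adjusted p values, same order as the input.
#' @export
holm_sidak_adjust <- function(p) {
  p <- as.numeric(p)
  if (length(p) == 0) return(numeric(0))
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p values must lie in [0, 1]")
  m <- length(p)
  o <- order(p)
  # 1 - (1 - p)^k via expm1/log1p: keeps precision for very small p
  adj <- -expm1((m - seq_len(m) + 1) * log1p(-p[o]))
  adj <- pmin(1, cummax(adj))
  out <- numeric(m)
  out[o] <- adj
  out
}

#' Group comparison per gene and zone
#'
#' Runs the zone-level group analysis: one-way ANOVA across the study groups
#' on per-animal zone means, followed by all pairwise two-sample comparisons
#' (pooled-variance t tests) with Holm-Sidak adjustment.
#'
#' @param summaries A [zone_summaries()] result.
#' @param alpha Significance level recorded alongside the results.
#' @return A data.frame with one row per gene x zone x contrast, carrying
#'   the shared ANOVA `f`/`anova_p` and the contrast's raw and adjusted p.
#' @export
compare_zone_groups <- function(summaries, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  res <- list()
  for (gene in unique(summaries$gene)) {
    sg <- summaries[summaries$gene == gene, ]
    for (zone in c("ischemic", "remote")) {
      vals <- if (zone == "ischemic") sg$mean_inside else sg$mean_outside
      grp <- factor(sg$group)
      an <- anova_groups(vals, grp)
      lev <- levels(grp)
      pairs <- utils::combn(lev, 2)
      raw <- apply(pairs, 2, function(pr) {
        a <- vals[grp == pr[1]]; b <- vals[grp == pr[2]]
        pooled_t_p(a, b)
      })
      adj <- holm_sidak_adjust(raw)
      res[[length(res) + 1]] <- data.frame(
        gene = gene, zone = zone,
        contrast = paste(pairs[1, ], pairs[2, ], sep = " vs "),
        f = an$f, anova_p = an$p,
        p_raw = raw, p_adj = adj,
        significant = adj < alpha,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# two-sample pooled-variance t test p value
pooled_t_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) / (na + nb - 2)
  if (sp2 <= 0) return(if (mean(a) == mean(b)) 1 else 0)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * stats::pt(-abs(t), df = na + nb - 2)
}

#' Threshold-based zone suggestion
#'
#' Convenience helper that proposes an ischemic polygon as the largest
#' contour of an interpolated display map at `anchor_target + k` display
#' units. Intended as a starting point for manual delineation, never as the
#' default zone definition.
#'
#' @param grid A [idw_interpolate()] display-value grid.
#' @param k Display units above the anchor target (default 30).
#' @param anchor_target Display anchor (default 20).
#' @param source_group Group of the map the contour is taken from.
#' @return A [zone_polygon()], or `NULL` when no closed contour exists.
#' @export
suggest_zone_by_threshold <- function(grid, k = 30, anchor_target = 20,
                                      source_group = "ir5h") {
  stopifnot(inherits(grid, "polar_grid"))
  vals <- grid$values
  vals[is.na(vals)] <- min(vals, na.rm = TRUE)
  cl <- grDevices::contourLines(grid$u, grid$v, vals, levels = anchor_target + k)
  if (length(cl) == 0) return(NULL)
  closed <- Filter(function(s) {
    abs(s$x[1] - s$x[length(s$x)]) < 1e-9 && abs(s$y[1] - s$y[length(s$y)]) < 1e-9
  }, cl)
  if (length(closed) == 0) closed <- cl
  sizes <- vapply(closed, function(s) abs(polygon_area(s$x, s$y)), numeric(1))
  s <- closed[[which.max(sizes)]]
  n <- length(s$x)
  keep <- seq(1, n - 1)
  V <- cbind(s$x[keep], s$y[keep])
  r <- sqrt(rowSums(V^2))
  V[r > 1, ] <- V[r > 1, ] / r[r > 1]  # clip to disk
  zone_polygon(V, label = "ischemic", source_group = source_group)
}

polygon_area <- function(x, y) {
  n <- length(x)
  sum(x * y[c(2:n, 1)] - x[c(2:n, 1)] * y) / 2
}
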