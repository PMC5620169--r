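#' Per-segment expression summaries
#'
#' Mean and SD of fold changes per gene x group x AHA segment, pooling the
#' location values of all animals within a group. With 52 locations each
#' segment holds about three values per heart, which precludes formal
#' segment-level inference; the summaries feed the descriptive 2xSD
#' relevance criterion instead.
#'
#' @param expression Expression table with columns `group`, `sample_id`,
#'   `gene`, `fold_change` (and usually `animal_id`).
#' @param locations Location table with `location_id` and `segment`.
#' @return A data.frame `gene`, `group`, `segment` (1-17), `n`, `mean`,
#'   `sd`; empty segments are reported with `n = 0` and `NA` statistics,
#'   and `sd` is `NA` whenever `n < 2`.
#' @export
segment_summaries <- function(expression, locations) {
  need <- c("group", "sample_id", "gene", "fold_change")
  if (!all(need %in% names(expression)))
    stop("expression table needs columns: ", paste(need, collapse = ", "))
  if (!all(c("location_id", "segment") %in% names(locations)))
    stop("locations table needs columns location_id, segment")
  seg <- locations$segment[match(expression$sample_id, locations$location_id)]
  if (any(is.na(seg)))
    stop("expression rows with unknown location ids: ",
         paste(utils::head(unique(expression$sample_id[is.na(seg)])), collapse = ", "))
  expression$segment <- seg
  grid <- expand.grid(segment = 1:17,
                      group = unique(expression$group),
                      gene = unique(expression$gene),
                      stringsAsFactors = FALSE)
  key <- paste(expression$gene, expression$group, expression$segment, sep = "\r")
  gkey <- paste(grid$gene, grid$group, grid$segment, sep = "\r")
  n <- tapply(expression$fold_change, key, length)
  m <- tapply(expression$fold_change, key, mean)
  s <- tapply(expression$fold_change, key, stats::sd)
  idx <- match(gkey, names(n))
  out <- grid[, c("gene", "group", "segment")]
  out$n <- ifelse(is.na(idx), 0L, as.integer(n[idx]))
  out$mean <- as.numeric(m[idx])
  out$sd <- as.numeric(s[idx])
  out$sd[out$n < 2] <- NA_real_
  out <- out[order(out$gene, out$group, out$segment), ]
  rownames(out) <- NULL
  out
}

#' 2xSD segmental relevance flags
#'
#' Flags segments whose mean fold change differs between a baseline
#' (control) and a treatment group by more than twice the variability of
#' the two compared segments — a descriptive "biologically relevant"
#' criterion used in place of formal tests when only a handful of values
#' fall in each segment. Three readings of the variability term are
#' available:
#' \describe{
#'   \item{`pooled_sd` (default)}{two-sample pooled SD of the location
#'     values, `sqrt(((n_a-1) s_a^2 + (n_b-1) s_b^2) / (n_a+n_b-2))`.}
#'   \item{`sd_of_means`}{SD of the two segment means.}
#'   \item{`sum_sd`}{sum of the two segment SDs.}
#' }
#' Flagging is strict (`difference > 2 x SD`); segments where either group
#' has fewer than 2 values are undetermined (`NA`), rendered grey rather
#' than red.
#'
#' @param control_summaries,treatment_summaries [segment_summaries()] rows
#'   for the two groups being compared (matching gene/segment sets).
#' @param rule Variability rule, see above.
#' @return A data.frame `gene`, `comparison`, `segment`, `diff`,
#'   `threshold`, `flagged`.
#' @export
relevance_flags <- function(control_summaries, treatment_summaries,
                            rule = c("pooled_sd", "sd_of_means", "sum_sd")) {
  rule <- match.arg(rule)
  a <- control_summaries; b <- treatment_summaries
  ka <- paste(a$gene, a$segment, sep = "\r")
  kb <- paste(b$gene, b$segment, sep = "\r")
  if (!setequal(ka, kb) || anyDuplicated(ka) || anyDuplicated(kb))
    stop("mismatched gene x segment sets between the two summary tables")
  b <- b[match(ka, kb), ]
  diff <- abs(a$mean - b$mean)
  threshold <- switch(rule,
    pooled_sd = {
      dof <- a$n + b$n - 2
      2 * sqrt(pmax(0, ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / ifelse(dof > 0, dof, NA)))
    },
    sd_of_means = 2 * abs(a$mean - b$mean) / sqrt(2),
    sum_sd = 2 * (a$sd + b$sd))
  flagged <- diff > threshold
  undet <- a$n < 2 | b$n < 2
  flagged[undet] <- NA
  threshold[undet] <- NA_real_
  comparison <- paste(a$group, b$group, sep = " vs ")
  out <- data.frame(gene = a$gene, comparison = comparison,
                    segment = a$segment, diff = diff,
                    threshold = threshold, flagged = flagged,
                    stringsAsFactors = FALSE)
  out <- out[order(out$gene, out$segment), ]
  rownames(out) <- NULL
  out
}

#' Render the 17-segment polar display
#'
#' Schematic AHA bulls-eye with one filled wedge per segment. Given
#' relevance flags, flagged segments are drawn red, undetermined segments
#' grey and unflagged segments white; given summaries, wedges are filled by
#' the color scale applied to segment means.
#'
#' @param x A [relevance_flags()] result (one gene x comparison) or a
#'   [segment_summaries()] result (one gene x group).
#' @param colors Color scale used for summary means.
#' @param file Optional `.png`/`.svg` output path.
#' @param title Plot title.
#' @param width,height Device size.
#' @return Invisibly, the per-segment fill colors (named 1-17).
#' @export
render_segment_polar <- function(x, colors = display_color_scale(),
                                 file = NULL, title = "",
                                 width = 560, height = 560) {
  if (!all(1:17 %in% x$segment) ||
      anyDuplicated(x$segment[x$segment %in% 1:17]) > 0)
    stop("need exactly one row per segment 1-17 ",
         "(subset to one gene and one comparison/group first)")
  x <- x[match(1:17, x$segment), ]
  if ("flagged" %in% names(x)) {
    fill <- ifelse(is.na(x$flagged), "grey75",
                   ifelse(x$flagged, "#D7191C", "white"))
    legend_lab <- c("relevant (red)", "not relevant", "undetermined")
    legend_fill <- c("#D7191C", "white", "grey75")
  } else if ("mean" %in% names(x)) {
    fill <- scale_colors(colors, x$mean)
    legend_lab <- legend_fill <- NULL
  } else stop("x must carry a 'flagged' or 'mean' column")
  names(fill) <- as.character(1:17)

  dev_open <- open_device(file, width, height)
  if (dev_open) on.exit(grDevices::dev.off())
  op <- graphics::par(mar = c(1, 1, if (nzchar(title)) 2.5 else 1, 1))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.15, 1.15), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = title)
  sch <- aha17_scheme()
  wedge <- function(r0, r1, th0, th1, col) {
    tt <- seq(th0, th1, length.out = 40) * pi / 180
    graphics::polygon(c(r0 * cos(tt), r1 * cos(rev(tt))),
                      c(r0 * sin(tt), r1 * sin(rev(tt))),
                      col = col, border = "black")
  }
  br <- sch$ring_breaks
  for (rn in seq_along(sch$rings)) {
    ri <- sch$rings[[rn]]
    for (s in seq_len(ri$n_sectors)) {
      seg_id <- ri$first + s - 1L
      th0 <- ri$theta0 + (s - 1) * ri$sector_width
      wedge(br[rn], br[rn + 1], th0, th0 + ri$sector_width,
            fill[as.character(seg_id)])
      mid <- (th0 + ri$sector_width / 2) * pi / 180
      rm <- if (rn == 1) 0 else (br[rn] + br[rn + 1]) / 2
      graphics::text(rm * cos(mid), rm * sin(mid), seg_id, cex = 0.8)
    }
  }
  if (!is.null(legend_lab))
    graphics::legend("topright", legend = legend_lab, fill = legend_fill,
                     bty = "n", cex = 0.75)
  invisible(fill)
}
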