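# Independent oracles used across the test files. These deliberately take
# different computational routes than the package implementation.

# Relative quantification computed entirely in linear quantity space:
# quantities 2^-Ct, normalized by the geometric mean of the reference-gene
# quantities of the same sample, then divided by the calibrator quantity
# (gene-wise geometric mean over control samples, matching the package's
# arithmetic-mean-of-delta-Ct default).
oracle_fold_changes <- function(ct, targets, refs) {
  uid <- paste(ct$animal_id, ct$sample_id, sep = "/")
  q <- 2^(-ct$ct)
  norm <- sapply(unique(uid), function(u) {
    rq <- q[uid == u & ct$gene %in% refs]
    exp(mean(log(rq)))
  })
  tgt <- ct[ct$gene %in% targets, ]
  tq <- 2^(-tgt$ct) / norm[paste(tgt$animal_id, tgt$sample_id, sep = "/")]
  cal <- sapply(targets, function(g) {
    exp(mean(log(tq[tgt$gene == g & tgt$group == "control"])))
  })
  data.frame(animal_id = tgt$animal_id, sample_id = tgt$sample_id,
             gene = tgt$gene, fold_change = tq / cal[tgt$gene],
             stringsAsFactors = FALSE)
}

# Brute-force AHA segment lookup via an explicit boundary table scan.
oracle_segment <- function(rho, theta) {
  tab <- list(
    list(17, 0.00, 0.25, 0, 360),
    list(13, 0.25, 0.50, 45, 135), list(14, 0.25, 0.50, 135, 225),
    list(15, 0.25, 0.50, 225, 315), list(16, 0.25, 0.50, 315, 405),
    list(7, 0.50, 0.75, 60, 120), list(8, 0.50, 0.75, 120, 180),
    list(9, 0.50, 0.75, 180, 240), list(10, 0.50, 0.75, 240, 300),
    list(11, 0.50, 0.75, 300, 360), list(12, 0.50, 0.75, 360, 420),
    list(1, 0.75, 1.001, 60, 120), list(2, 0.75, 1.001, 120, 180),
    list(3, 0.75, 1.001, 180, 240), list(4, 0.75, 1.001, 240, 300),
    list(5, 0.75, 1.001, 300, 360), list(6, 0.75, 1.001, 360, 420))
  vapply(seq_along(rho), function(i) {
    th <- theta[i] %% 360
    for (row in tab) {
      in_rho <- rho[i] >= row[[2]] && rho[i] < row[[3]]
      in_th <- (th >= row[[4]] && th < row[[5]]) ||
        (th + 360 >= row[[4]] && th + 360 < row[[5]])
      if (in_rho && in_th) return(row[[1]])
    }
    NA_real_
  }, numeric(1))
}

# Ray-casting point-in-polygon oracle: casts a ray in an arbitrary fixed
# direction and counts proper edge crossings via orientation tests.
oracle_point_in_polygon <- function(px, py, V) {
  n <- nrow(V)
  dirx <- cos(0.5702); diry <- sin(0.5702)  # irrational direction, avoids vertex hits
  far <- 10
  cross2 <- function(ax, ay, bx, by) ax * by - ay * bx
  vapply(seq_along(px), function(i) {
    qx <- px[i] + far * dirx; qy <- py[i] + far * diry
    count <- 0
    for (e in seq_len(n)) {
      x1 <- V[e, 1]; y1 <- V[e, 2]
      j <- if (e == n) 1 else e + 1
      x2 <- V[j, 1]; y2 <- V[j, 2]
      d1 <- cross2(qx - px[i], qy - py[i], x1 - px[i], y1 - py[i])
      d2 <- cross2(qx - px[i], qy - py[i], x2 - px[i], y2 - py[i])
      d3 <- cross2(x2 - x1, y2 - y1, px[i] - x1, py[i] - y1)
      d4 <- cross2(x2 - x1, y2 - y1, qx - x1, qy - y1)
      if (d1 * d2 < 0 && d3 * d4 < 0) count <- count + 1
    }
    count %% 2 == 1
  }, logical(1))
}

# One-way ANOVA from explicit sums of squares.
oracle_anova <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups); n <- length(values)
  gm <- tapply(values, groups, mean)
  gn <- tapply(values, groups, length)
  ssb <- sum(gn * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  f <- (ssb / (k - 1)) / (ssw / (n - k))
  list(f = f, p = stats::pf(f, k - 1, n - k, lower.tail = FALSE))
}

# Closed-form least squares of y on x.
oracle_ols <- function(x, y) {
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  c(slope = b, intercept = mean(y) - b * mean(x))
}

# Small hand-made collapsed Ct table: 4 samples x (2 targets + 2 refs),
# one control and one treated animal, two samples each.
toy_ct_table <- function() {
  set.seed(42)
  samples <- c("s1", "s2", "s3", "s4")
  animals <- c("a1", "a1", "a2", "a2")
  groups <- c("control", "control", "ir5h", "ir5h")
  genes <- c("T1", "T2", "R1", "R2")
  grid <- expand.grid(i = 1:4, gene = genes, stringsAsFactors = FALSE)
  data.frame(sample_id = samples[grid$i], animal_id = animals[grid$i],
             group = groups[grid$i], gene = grid$gene,
             ct = round(stats::runif(nrow(grid), 18, 30), 2),
             stringsAsFactors = FALSE)
}

toy_panel <- function() qpcr_panel(targets = c("T1", "T2"),
                                   references = c("R1", "R2"))
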