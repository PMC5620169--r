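#' Synthetic study configuration
#'
#' Study conditions of the emulated porcine repetitive-ischemia/reperfusion
#' experiment: three groups (sham-operated control n = 8, ischemia 5h n = 6,
#' ischemia 24h n = 6), 52 quasi-uniform LV sampling locations, a panel of
#' 7 target + 3 reference genes, and a spatially localized ischemic-core
#' expression effect in the mid-LAD (apical-anterior) territory.
#'
#' @param group_sizes Named integer vector of animals per group.
#' @param n_locations Sampling locations per heart (default 52).
#' @param panel A [qpcr_panel()].
#' @param profiles Per-gene x group log2 fold-change amplitudes
#'   (see [default_profiles()]).
#' @param core_rho,core_theta_deg Bulls-eye position of the ischemic core
#'   center (default rho 0.35 at 90 degrees: apical-anterior).
#' @param core_sigma Spatial width of the core kernel in bulls-eye distance
#'   units (default 0.25).
#' @param baseline_ct Named baseline Ct per gene (cycles).
#' @param n_replicates Technical qPCR replicates per well (default 2).
#' @param ct_noise_sd Replicate-level Ct measurement noise SD in cycles
#'   (default 0.25).
#' @param animal_sd Animal-level random effect SD in cycles (default 0.15),
#'   additive in Ct and shared across all genes of an animal (it models
#'   loading/RNA-quality variation and cancels in delta-Ct).
#' @return An object of class `study_config`.
#' @export
study_config <- function(group_sizes = c(control = 8, ir5h = 6, ir24h = 6),
                         n_locations = 52,
                         panel = qpcr_panel(),
                         profiles = default_profiles(),
                         core_rho = 0.35, core_theta_deg = 90,
                         core_sigma = 0.25,
                         baseline_ct = c(CASP3 = 24, CLU = 22, ERCC4 = 26,
                                         GATA4 = 23, HK2 = 22, MEF2C = 25,
                                         HIF1A = 21, GAPDH = 18, HPRT1 = 24,
                                         PPIA = 20),
                         n_replicates = 2,
                         ct_noise_sd = 0.25,
                         animal_sd = 0.15) {
  problems <- character(0)
  if (length(group_sizes) < 1 || any(group_sizes < 1))
    problems <- c(problems, "group_sizes: all groups need >= 1 animal")
  if (!"control" %in% names(group_sizes))
    problems <- c(problems, "group_sizes: a 'control' group is required")
  if (n_locations < 1) problems <- c(problems, "n_locations: must be >= 1")
  if (!inherits(panel, "qpcr_panel")) problems <- c(problems, "panel: not a qpcr_panel")
  genes <- c(panel$targets, panel$references)
  if (!all(genes %in% names(baseline_ct)))
    problems <- c(problems, paste("baseline_ct: missing genes",
                                  paste(setdiff(genes, names(baseline_ct)), collapse = ", ")))
  if (!all(c("gene", "group", "core_log2fc", "remote_log2fc") %in% names(profiles)))
    problems <- c(problems, "profiles: needs gene, group, core_log2fc, remote_log2fc")
  if (any(!is.finite(profiles$core_log2fc)) || any(!is.finite(profiles$remote_log2fc)))
    problems <- c(problems, "profiles: amplitudes must be finite")
  if (!is.finite(core_sigma) || core_sigma <= 0)
    problems <- c(problems, "core_sigma: must be > 0")
  if (ct_noise_sd < 0) problems <- c(problems, "ct_noise_sd: must be >= 0")
  if (animal_sd < 0) problems <- c(problems, "animal_sd: must be >= 0")
  if (n_replicates < 1) problems <- c(problems, "n_replicates: must be >= 1")
  if (length(problems) > 0)
    stop("invalid study configuration:\n  ", paste(problems, collapse = "\n  "))
  structure(
    list(group_sizes = group_sizes, n_locations = as.integer(n_locations),
         panel = panel, profiles = profiles,
         core_rho = core_rho, core_theta_deg = core_theta_deg,
         core_sigma = core_sigma, baseline_ct = baseline_ct,
         n_replicates = as.integer(n_replicates),
         ct_noise_sd = ct_noise_sd, animal_sd = animal_sd),
    class = "study_config")
}

#' Default per-gene expression profiles
#'
#' Log2 fold-change amplitudes of the ischemic core and the remote
#' myocardium per gene and time point, encoding the qualitative
#' spatiotemporal patterns of the emulated study: a quick core-restricted
#' stress/apoptosis response at 5h (CASP3, HK2, HIF1A with partial remote
#' involvement), persistent core up-regulation of GATA4, CLU and ERCC4
#' through 24h, remote-zone down-regulation of HK2 at 5h deepening to
#' global down-regulation at 24h, and essentially unchanged MEF2C. The
#' control group is the baseline (all amplitudes 0).
#'
#' @return A data.frame `gene`, `group`, `core_log2fc`, `remote_log2fc`.
#' @export
default_profiles <- function() {
  amp <- rbind(
    #        gene     5h core  5h remote  24h core  24h remote
    c("HIF1A", 2.0, 1.0, 0.0, 1.0),
    c("CASP3", 2.0, 0.5, 0.0, 0.0),
    c("GATA4", 1.0, 0.0, 1.5, 0.0),
    c("MEF2C", 0.0, 0.0, 0.0, 0.0),
    c("HK2",   2.0, -1.0, -1.5, -1.5),
    c("CLU",   1.0, -0.5, 1.0, 0.5),
    c("ERCC4", 1.5, 0.0, 1.5, 0.0))
  genes <- amp[, 1]
  num <- apply(amp[, -1], 2, as.numeric)
  rbind(
    data.frame(gene = genes, group = "control",
               core_log2fc = 0, remote_log2fc = 0),
    data.frame(gene = genes, group = "ir5h",
               core_log2fc = num[, 1], remote_log2fc = num[, 2]),
    data.frame(gene = genes, group = "ir24h",
               core_log2fc = num[, 3], remote_log2fc = num[, 4]))
}

# Gaussian kernel weight of the core at bulls-eye distance d, and the
# plateau mixing weight: full core effect wherever the kernel weight is at
# least `threshold` (the zone-membership rule), Gaussian shoulders outside.
core_kernel <- function(d, sigma) exp(-d^2 / (2 * sigma^2))
core_mix_weight <- function(d, sigma, threshold = 0.5)
  pmin(1, core_kernel(d, sigma) / threshold)

#' Ground-truth ischemic zone polygon
#'
#' The circle (as a regular polygon) where the core kernel weight equals
#' the membership threshold: radius `sigma * sqrt(-2 * log(threshold))`
#' around the configured core center. Locations inside it are exactly the
#' generator's ground-truth ischemic set.
#'
#' @param config A [study_config()].
#' @param n_vertices Polygon resolution (default 72).
#' @param threshold Kernel-weight membership threshold (default 0.5).
#' @return A [zone_polygon()].
#' @export
ground_truth_zone_polygon <- function(config, n_vertices = 72, threshold = 0.5) {
  stopifnot(inherits(config, "study_config"))
  r <- config$core_sigma * sqrt(-2 * log(threshold))
  ctr <- polar_to_disk(config$core_rho, config$core_theta_deg)
  tt <- seq(0, 2 * pi, length.out = n_vertices + 1)[-(n_vertices + 1)]
  V <- cbind(ctr[1] + r * cos(tt), ctr[2] + r * sin(tt))
  rr <- sqrt(rowSums(V^2))
  V[rr > 1, ] <- V[rr > 1, ] / rr[rr > 1]
  zone_polygon(V, label = "ischemic", source_group = "ir5h")
}

#' Simulate a complete synthetic study
#'
#' Generates sampling locations, a ground-truth spatial log2 fold-change
#' field per gene and group, and a noisy replicate-level Ct table. The true
#' field is `core_log2fc * w + remote_log2fc * (1 - w)` with the plateau
#' weight `w = min(1, k / 0.5)`, `k = exp(-d^2 / (2 sigma^2))` and `d` the
#' Euclidean bulls-eye distance to the core center, so the full core
#' amplitude applies throughout the ground-truth ischemic zone (`k >= 0.5`)
#' and decays smoothly outside it. Target Cts are
#' `baseline - true_log2fc + animal_effect + noise` per replicate;
#' reference-gene Cts carry the animal effect and noise but no group
#' effect. Output is deterministic given `(config, seed)`.
#'
#' @param config A [study_config()].
#' @param seed Integer seed for all randomness.
#' @return A list of class `synthetic_study`: `locations`, `ct`
#'   (long replicate-level table), `truth` (gene x group x location true
#'   log2 fold change), `zone_membership` (`location_id`, `in_zone`),
#'   `animals`, and the resolved `config` and `seed`.
#' @export
simulate_study <- function(config = study_config(), seed = 1) {
  stopifnot(inherits(config, "study_config"))
  seed <- as.integer(seed)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv) else
    rm(".Random.seed", envir = .GlobalEnv))
  set.seed(seed)

  locations <- generate_sampling_scheme(config$n_locations)
  uv <- polar_to_disk(locations$rho, locations$theta_deg)
  ctr <- polar_to_disk(config$core_rho, config$core_theta_deg)
  d <- sqrt((uv[, 1] - ctr[1])^2 + (uv[, 2] - ctr[2])^2)
  w <- core_mix_weight(d, config$core_sigma)
  in_zone <- core_kernel(d, config$core_sigma) >= 0.5

  panel <- config$panel
  targets <- panel$targets
  refs <- panel$references
  groups <- names(config$group_sizes)
  animals <- data.frame(
    animal_id = unlist(lapply(groups, function(g)
      sprintf("%s_%02d", g, seq_len(config$group_sizes[[g]])))),
    group = rep(groups, times = config$group_sizes),
    stringsAsFactors = FALSE)

  # true log2 fold-change field: genes x groups x locations
  prof_key <- paste(config$profiles$gene, config$profiles$group, sep = "\r")
  truth <- expand.grid(location_id = locations$location_id,
                       gene = targets, group = groups,
                       stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  pm <- match(paste(truth$gene, truth$group, sep = "\r"), prof_key)
  if (any(is.na(pm)))
    stop("profiles table lacks amplitudes for some gene x group combinations")
  wloc <- w[match(truth$location_id, locations$location_id)]
  truth$true_log2fc <- config$profiles$core_log2fc[pm] * wloc +
    config$profiles$remote_log2fc[pm] * (1 - wloc)

  genes <- c(targets, refs)
  n_loc <- nrow(locations)
  n_ani <- nrow(animals)
  n_rep <- config$n_replicates
  grid <- expand.grid(replicate = seq_len(n_rep),
                      gene = genes,
                      location_id = locations$location_id,
                      animal_idx = seq_len(n_ani),
                      stringsAsFactors = FALSE, KEEP.OUT.ATTRS = FALSE)
  grid$animal_id <- animals$animal_id[grid$animal_idx]
  grid$group <- animals$group[grid$animal_idx]
  animal_eff <- stats::rnorm(n_ani, 0, config$animal_sd)
  tkey <- paste(grid$gene, grid$group, grid$location_id, sep = "\r")
  tmatch <- match(tkey, paste(truth$gene, truth$group, truth$location_id, sep = "\r"))
  lfc <- ifelse(is.na(tmatch), 0, truth$true_log2fc[tmatch])  # refs: no effect
  ct <- config$baseline_ct[grid$gene] - lfc + animal_eff[grid$animal_idx] +
    stats::rnorm(nrow(grid), 0, config$ct_noise_sd)
  ct_tab <- data.frame(sample_id = grid$location_id,
                       animal_id = grid$animal_id,
                       group = grid$group,
                       gene = grid$gene,
                       replicate = grid$replicate,
                       ct = unname(ct),
                       stringsAsFactors = FALSE)

  structure(
    list(locations = locations,
         ct = ct_tab,
         truth = truth,
         zone_membership = data.frame(location_id = locations$location_id,
                                      in_zone = in_zone),
         animals = animals,
         config = config, seed = seed),
    class = "synthetic_study")
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "Synthetic LV study: %d animals (%s), %d locations, %d genes, %d Ct records (seed %d)\n",
    nrow(x$animals),
    paste(sprintf("%s n=%d", names(x$config$group_sizes), x$config$group_sizes),
          collapse = ", "),
    nrow(x$locations),
    length(unique(x$ct$gene)), nrow(x$ct), x$seed))
  invisible(x)
}
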