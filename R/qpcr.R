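#' qPCR panel configuration
#'
#' Defines the target and reference gene panel of a relative-quantification
#' run. The default panel is seven targets of interest in porcine
#' ischemia/reperfusion (stress response, apoptosis, cardiac transcription
#' factors, glucose metabolism, DNA repair) normalized against the three
#' reference genes GAPDH, HPRT1 and PPIA.
#'
#' @param targets Character vector of target gene symbols.
#' @param references Character vector of reference (housekeeping) gene
#'   symbols; at least one, disjoint from `targets`.
#' @param calibrator Either `"control_mean"` (gene-wise mean delta-Ct over
#'   all control-group samples) or the id of a named calibrator sample
#'   (e.g. a basal-posterior reference location).
#' @param sd_flag_cycles Replicate-SD QC threshold in cycles.
#' @return An object of class `qpcr_panel`.
#' @export
qpcr_panel <- function(targets = c("CASP3", "CLU", "ERCC4", "GATA4",
                                   "HK2", "MEF2C", "HIF1A"),
                       references = c("GAPDH", "HPRT1", "PPIA"),
                       calibrator = "control_mean",
                       sd_flag_cycles = 0.5) {
  targets <- as.character(targets)
  references <- as.character(references)
  if (length(references) < 1) stop("at least one reference gene is required")
  if (length(intersect(targets, references)) > 0)
    stop("targets and references must be disjoint")
  if (anyDuplicated(c(targets, references)))
    stop("duplicated gene symbols in panel")
  stopifnot(is.character(calibrator), length(calibrator) == 1,
            is.numeric(sd_flag_cycles), sd_flag_cycles >= 0)
  structure(list(targets = targets, references = references,
                 calibrator = calibrator, sd_flag_cycles = sd_flag_cycles),
            class = "qpcr_panel")
}

#' Packaged primer metadata
#'
#' Primer sequences and amplicon lengths (bp) for the default panel, as used
#' on a SYBR-green assay. Primer metadata is recorded as missing (`NA`)
#' where no sequence is available for a panel gene.
#'
#' @return A data.frame with columns `gene`, `role`, `forward_primer`,
#'   `reverse_primer`, `amplicon_length_bp`.
#' @export
primer_panel <- function() {
  path <- system.file("extdata", "primer_panel.csv", package = "cardimap",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE,
                  colClasses = c(amplicon_length_bp = "integer"))
}

#' Collapse technical qPCR replicates
#'
#' Averages replicate Ct values per sample x gene (and animal, if present)
#' and flags wells whose replicate SD exceeds a QC threshold. A single
#' replicate has no defined SD; it is recorded as 0 and never flagged.
#'
#' @param ct A data.frame of raw Ct records with at least columns
#'   `sample_id`, `gene`, `ct`; columns `animal_id` and `group` are carried
#'   through when present.
#' @param sd_flag_cycles Flag threshold on the replicate SD, in cycles.
#' @return A data.frame with one row per sample x gene (x animal) and
#'   columns `ct` (mean), `ct_sd`, `n_replicates`, `qc_flag`.
#' @export
collapse_replicates <- function(ct, sd_flag_cycles = 0.5) {
  if (!is.data.frame(ct) || nrow(ct) == 0)
    stop("ct must be a non-empty data.frame of Ct records")
  need <- c("sample_id", "gene", "ct")
  if (!all(need %in% names(ct)))
    stop("ct table must contain columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(ct$ct))) stop("non-finite Ct values")
  keys <- c(intersect(c("animal_id", "group"), names(ct)), "sample_id", "gene")
  key <- do.call(paste, c(ct[keys], sep = "\r"))
  first <- !duplicated(key)
  n <- as.vector(rowsum(rep(1, nrow(ct)), key))
  s1 <- as.vector(rowsum(ct$ct, key))
  s2 <- as.vector(rowsum(ct$ct^2, key))
  ord <- sort(unique(key))  # rowsum output order
  m <- s1 / n
  ss <- pmax(0, s2 - s1^2 / n)
  sdv <- ifelse(n >= 2, sqrt(ss / (n - 1)), 0)
  out <- ct[first, keys, drop = FALSE]
  idx <- match(key[first], ord)
  out$ct <- m[idx]
  out$ct_sd <- sdv[idx]
  out$n_replicates <- as.integer(n[idx])
  out$qc_flag <- out$ct_sd > sd_flag_cycles
  rownames(out) <- NULL
  out
}

#' Fit a qPCR standard (calibration) curve
#'
#' Ordinary least squares of Ct on log10 relative quantity over a dilution
#' series (typically five 1:8 dilutions of one sample). The amplification
#' efficiency is `E = 10^(-1/slope)`; an ideal assay doubles per cycle
#' (`E = 2`, slope -3.3219 cycles per decade).
#'
#' @param quantity Relative input quantities (first dilution = 1).
#' @param ct Mean Ct per dilution point.
#' @return An object of class `calibration_curve` with `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `valid` (slope < 0) and `plausible`
#'   (efficiency in (1, 2.5\]).
#' @export
fit_calibration_curve <- function(quantity, ct) {
  quantity <- as.numeric(quantity)
  ct <- as.numeric(ct)
  if (length(quantity) != length(ct)) stop("quantity and ct lengths differ")
  if (length(unique(quantity)) < 3)
    stop("calibration requires >= 3 distinct quantities")
  if (any(quantity <= 0)) stop("quantities must be positive")
  lq <- log10(quantity)
  if (stats::sd(lq) == 0) stop("zero variance in quantity")
  fit <- stats::lm(ct ~ lq)
  slope <- unname(stats::coef(fit)[2])
  # slopes indistinguishable from 0 mark a failed amplification series
  neg <- is.finite(slope) && slope < -sqrt(.Machine$double.eps)
  eff <- if (neg) 10^(-1 / slope) else NA_real_
  tss <- sum((ct - mean(ct))^2)
  r2 <- if (tss > 0) 1 - sum(stats::residuals(fit)^2) / tss else NA_real_
  structure(
    list(quantity = quantity, ct = ct,
         slope = slope, intercept = unname(stats::coef(fit)[1]),
         efficiency = eff,
         r_squared = r2,
         valid = neg,
         plausible = is.finite(eff) && eff > 1 && eff <= 2.5),
    class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf("Calibration curve: slope %.4f cycles/log10, E = %.4f, R^2 = %.4f%s\n",
              x$slope, x$efficiency, x$r_squared,
              if (!x$valid) " [INVALID: non-negative slope]" else ""))
  invisible(x)
}

#' Relative expression by the delta-delta-Ct method
#'
#' Computes per sample x gene fold changes from collapsed Ct values.
#' `delta_ct` is the target Ct minus the arithmetic mean of the reference
#' gene Cts of the same sample — identical to normalizing by the geometric
#' mean of reference quantities in linear space. `delta_delta_ct` subtracts
#' the calibrator's gene-wise delta-Ct, and
#' `fold_change = efficiency^(-delta_delta_ct)`.
#'
#' @param ct Collapsed Ct table (see [collapse_replicates()]) with columns
#'   `sample_id`, `gene`, `ct` and, for the default calibrator, `group`;
#'   `animal_id` is carried through when present. A sample is identified by
#'   `(animal_id, sample_id)` when `animal_id` is present.
#' @param panel A [qpcr_panel()].
#' @param calibrator Overrides the panel calibrator: `"control_mean"` or a
#'   sample id.
#' @param efficiency Amplification efficiency used in the fold-change
#'   exponentiation; default exactly 2 (classic delta-delta-Ct).
#' @param curve Optional [fit_calibration_curve()] result; when supplied its
#'   fitted efficiency replaces `efficiency` for the whole run.
#' @return A data.frame with one row per sample x target gene and columns
#'   `delta_ct`, `delta_delta_ct`, `fold_change`.
#' @export
delta_delta_ct <- function(ct, panel = qpcr_panel(), calibrator = NULL,
                           efficiency = 2, curve = NULL) {
  stopifnot(inherits(panel, "qpcr_panel"))
  need <- c("sample_id", "gene", "ct")
  if (!all(need %in% names(ct)))
    stop("ct table must contain columns: ", paste(need, collapse = ", "))
  if (!is.null(curve)) {
    stopifnot(inherits(curve, "calibration_curve"))
    if (!curve$valid) stop("calibration curve is invalid (non-negative slope)")
    efficiency <- curve$efficiency
  }
  if (!is.numeric(efficiency) || !is.finite(efficiency) || efficiency <= 0)
    stop("efficiency must be a positive number")
  calibrator <- calibrator %||% panel$calibrator

  has_animal <- "animal_id" %in% names(ct)
  uid <- if (has_animal) paste(ct$animal_id, ct$sample_id, sep = "\r") else ct$sample_id

  refs <- panel$references
  is_ref <- ct$gene %in% refs
  # every sample must have every reference gene
  ref_counts <- rowsum(outer(ct$gene, refs, "==") * 1, uid)
  missing <- rownames(ref_counts)[apply(ref_counts, 1, function(r) any(r < 1))]
  if (length(missing) > 0)
    stop("missing reference gene Ct for sample(s): ",
         paste(gsub("\r", "/", utils::head(missing, 10)), collapse = ", "))

  ref_mean_by_uid <- rowsum(ct$ct[is_ref], uid[is_ref]) /
    as.vector(rowsum(rep(1, sum(is_ref)), uid[is_ref]))
  ref_mean <- ref_mean_by_uid[match(uid, rownames(ref_mean_by_uid)), 1]

  tgt <- ct[!is_ref & ct$gene %in% panel$targets, , drop = FALSE]
  if (nrow(tgt) == 0) stop("no target-gene Ct records found for the panel")
  tgt_uid <- if (has_animal) paste(tgt$animal_id, tgt$sample_id, sep = "\r") else tgt$sample_id
  tgt$delta_ct <- tgt$ct - ref_mean[match(tgt_uid, uid)]

  if (identical(calibrator, "control_mean")) {
    if (!"group" %in% names(tgt))
      stop("calibrator 'control_mean' requires a 'group' column")
    ctrl <- tgt$group == "control"
    if (!any(ctrl)) stop("no control-group samples to form the calibrator")
    cal_dct <- tapply(tgt$delta_ct[ctrl], tgt$gene[ctrl], mean)
  } else {
    sel <- tgt$sample_id == calibrator
    if (!any(sel)) stop("calibrator sample not found: ", calibrator)
    cal_dct <- tapply(tgt$delta_ct[sel], tgt$gene[sel], mean)
  }
  if (any(!tgt$gene %in% names(cal_dct)))
    stop("calibrator has no delta-Ct for gene(s): ",
         paste(setdiff(unique(tgt$gene), names(cal_dct)), collapse = ", "))
  tgt$delta_delta_ct <- tgt$delta_ct - as.numeric(cal_dct[tgt$gene])
  tgt$fold_change <- efficiency^(-tgt$delta_delta_ct)
  keep <- c(intersect(c("animal_id", "group"), names(tgt)),
            "sample_id", "gene", "delta_ct", "delta_delta_ct", "fold_change")
  out <- tgt[, keep, drop = FALSE]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
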