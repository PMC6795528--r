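# The correlation-based clonality statistic, its decision rule, the
# deterministic conclusive/inconclusive quality gate, and the per-pair call.

#' Default decision cut-off for the clonality correlation
#'
#' The published operating point of the segmented-profile Pearson
#' correlation: pairs with r above the cut-off are called clonal, below it
#' non-clonal. \code{\link{calibrate_cutoff}} regenerates a pool-specific
#' value.
#' @export
DEFAULT_CUTOFF <- 0.54

#' Pearson correlation between two binned segment-value vectors
#'
#' The clonality statistic: the Pearson product-moment correlation of the
#' two tumors' segmented log2 ratios, computed over jointly non-missing bins
#' of a shared \code{\link{bin_grid}}.
#'
#' @param bins_a,bins_b Numeric vectors of equal length (per-bin segment
#'   values, \code{NA} = bin not covered).
#' @param min_bins Minimum number of jointly non-missing bins (default 30);
#'   fewer is an error ("insufficient overlap").
#' @return The correlation, or \code{NA} when either vector has zero
#'   variance over the joint bins (an undefined correlation, which
#'   propagates to an inconclusive call).
#' @export
pearson_clonality <- function(bins_a, bins_b, min_bins = 30) {
  if (length(bins_a) != length(bins_b))
    stop("bin vectors must share one grid (equal length)")
  ok <- is.finite(bins_a) & is.finite(bins_b)
  n <- sum(ok)
  if (n < min_bins)
    stop(sprintf("insufficient overlap: %d joint bins < %d", n, min_bins))
  a <- bins_a[ok]; b <- bins_b[ok]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  stats::cor(a, b)
}

#' Classify a clonality correlation against the cut-off
#'
#' r above the cut-off is clonal, below it non-clonal. Exact equality is
#' called clonal: the published rule leaves the tie unassigned, and a
#' deterministic tie-break is required.
#'
#' @param r Correlation in [-1, 1].
#' @param cutoff Decision threshold (default \code{DEFAULT_CUTOFF} = 0.54).
#' @return \code{"clonal"} or \code{"non-clonal"}.
#' @export
classify_correlation <- function(r, cutoff = DEFAULT_CUTOFF) {
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r < -1 || r > 1)
    stop("r must be a single number in [-1, 1]")
  if (r >= cutoff) "clonal" else "non-clonal"
}

#' Quality metrics of a segmented profile
#'
#' \code{deflection} is the probe-count-weighted mean of |segment mean| over
#' the included genome: how far the profile departs from the flat normal
#' line. \code{signal_to_noise} = deflection / max(noise, 1e-12).
#'
#' @param seg A \code{segmented_profile}.
#' @return List with \code{noise}, \code{mad}, \code{deflection},
#'   \code{signal_to_noise}.
#' @export
quality_metrics <- function(seg) {
  stopifnot(inherits(seg, "segmented_profile"))
  w <- seg$segments$num_probes
  deflection <- if (sum(w) > 0)
    sum(w * abs(seg$segments$mean)) / sum(w) else 0
  list(noise = seg$noise, mad = seg$mad, deflection = deflection,
       signal_to_noise = deflection / max(seg$noise, 1e-12))
}

#' Conclusive/inconclusive quality gate
#'
#' Deterministic replacement for expert visual review: a profile is
#' inconclusive when its deflection from the normal is low relative to its
#' noise (\code{signal_to_noise < min_snr}) or the noise itself is excessive
#' (\code{noise > max_noise}).
#'
#' @param seg A \code{segmented_profile}.
#' @param min_snr Minimum signal-to-noise (default 2).
#' @param max_noise Maximum per-probe noise sd (default 0.5).
#' @return List with \code{status} ("conclusive"/"inconclusive") and
#'   \code{metrics} (see \code{\link{quality_metrics}}).
#' @export
quality_gate <- function(seg, min_snr = 2, max_noise = 0.5) {
  m <- quality_metrics(seg)
  status <- if (m$signal_to_noise < min_snr || m$noise > max_noise)
    "inconclusive" else "conclusive"
  list(status = status, metrics = m)
}

#' Call clonality for one tumor pair
#'
#' The per-pair pipeline step: gate both profiles, correlate their binned
#' segment values, and classify. If either tumor fails the quality gate or
#' the correlation is undefined the call is inconclusive; otherwise the call
#' is determined solely by the correlation versus the cut-off.
#'
#' @param seg_a,seg_b \code{segmented_profile}s of the two tumors.
#' @param grid A \code{bin_grid} on the shared genome model.
#' @param cutoff Decision threshold.
#' @param min_snr,max_noise Gate parameters (see \code{\link{quality_gate}}).
#' @param min_bins Minimum joint bins for the correlation.
#' @param pair_id Pair identifier.
#' @return An object of class \code{clonality_result}: a list with
#'   \code{pair_id}, \code{sample_a}, \code{sample_b}, \code{pearson_r},
#'   \code{cutoff}, \code{call}, \code{quality_a}, \code{quality_b},
#'   \code{n_bins}, \code{external_lr} (slot for a third-party likelihood
#'   ratio, negative = non-clonal by convention; never computed here).
#' @export
call_pair <- function(seg_a, seg_b, grid, cutoff = DEFAULT_CUTOFF,
                      min_snr = 2, max_noise = 0.5, min_bins = 30,
                      pair_id = paste(seg_a$sample_id, seg_b$sample_id,
                                      sep = "_vs_")) {
  gate_a <- quality_gate(seg_a, min_snr, max_noise)
  gate_b <- quality_gate(seg_b, min_snr, max_noise)
  ba <- project_to_bins(seg_a, grid)
  bb <- project_to_bins(seg_b, grid)
  r <- pearson_clonality(ba, bb, min_bins = min_bins)
  n_bins <- sum(is.finite(ba) & is.finite(bb))
  call <- if (gate_a$status == "inconclusive" ||
              gate_b$status == "inconclusive" || is.na(r)) {
    "inconclusive"
  } else {
    classify_correlation(r, cutoff)
  }
  structure(list(pair_id = pair_id,
                 sample_a = seg_a$sample_id, sample_b = seg_b$sample_id,
                 pearson_r = r, cutoff = cutoff, call = call,
                 quality_a = gate_a$metrics, quality_b = gate_b$metrics,
                 n_bins = n_bins, external_lr = NA_real_),
            class = "clonality_result")
}

#' @export
print.clonality_result <- function(x, ...) {
  cat(sprintf("<clonality_result> %s: r=%s, cutoff=%.3f -> %s (%d bins)\n",
              x$pair_id,
              ifelse(is.na(x$pearson_r), "NA", sprintf("%.3f", x$pearson_r)),
              x$cutoff, x$call, x$n_bins))
  invisible(x)
}

#' Collect clonality results into a data frame
#'
#' @param results List of \code{clonality_result} objects.
#' @return Data frame, one row per pair, with the standard result columns.
#' @export
results_table <- function(results) {
  do.call(rbind, lapply(results, function(x) {
    data.frame(pair_id = x$pair_id, sample_a = x$sample_a,
               sample_b = x$sample_b, pearson_r = x$pearson_r,
               cutoff = x$cutoff, call = x$call,
               snr_a = x$quality_a$signal_to_noise,
               snr_b = x$quality_b$signal_to_noise,
               noise_a = x$quality_a$noise, noise_b = x$quality_b$noise,
               mad_a = x$quality_a$mad, mad_b = x$quality_b$mad,
               n_bins = x$n_bins, stringsAsFactors = FALSE)
  }))
}

#' Write per-pair clonality results as TSV
#'
#' @param results List of \code{clonality_result}s or the data frame from
#'   \code{\link{results_table}}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_results_tsv <- function(results, path) {
  df <- if (is.data.frame(results)) results else results_table(results)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
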