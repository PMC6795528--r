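# Probe-level and segmented copy-number profile containers with
# robust noise / spread metrics.

PLATFORMS <- c("44k", "105k", "180k", "custom")

#' Construct a probe-level copy number profile
#'
#' One tumor's probe-level log2 tumor/normal ratios on genomic coordinates.
#' Probes are sorted by (chromosome, start); intervals are 0-based half-open.
#' Probes with missing log2 ratios are dropped with a message (mirroring what
#' every reader logs).
#'
#' @param sample_id Sample identifier.
#' @param probes Data frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{log2ratio}.
#' @param platform One of \code{"44k"}, \code{"105k"}, \code{"180k"},
#'   \code{"custom"}.
#' @param genome A \code{genome_model}; chromosome order is taken from it.
#' @return An object of class \code{probe_profile}.
#' @export
probe_profile <- function(sample_id, probes, platform = "custom",
                          genome = default_genome()) {
  platform <- match.arg(platform, PLATFORMS)
  stopifnot(is.data.frame(probes))
  need <- c("chrom", "start", "end", "log2ratio")
  if (!all(need %in% names(probes)))
    stop("probes must have columns: ", paste(need, collapse = ", "))
  probes <- probes[, need]
  probes$chrom <- as.character(probes$chrom)
  n0 <- nrow(probes)
  keep <- is.finite(probes$log2ratio)
  if (any(!keep)) {
    message(sprintf("%s: dropped %d of %d probes with missing log2ratio",
                    sample_id, sum(!keep), n0))
    probes <- probes[keep, , drop = FALSE]
  }
  if (nrow(probes) == 0) stop("empty profile")
  unknown <- setdiff(unique(probes$chrom), genome$chrom)
  if (length(unknown) > 0) {
    message(sprintf("%s: dropped %d probes on chromosomes outside the genome model (%s)",
                    sample_id, sum(probes$chrom %in% unknown),
                    paste(unknown, collapse = ",")))
    probes <- probes[!probes$chrom %in% unknown, , drop = FALSE]
    if (nrow(probes) == 0) stop("empty profile")
  }
  if (any(probes$end <= probes$start)) stop("probe intervals must satisfy end > start")
  ord <- order(match(probes$chrom, genome$chrom), probes$start)
  probes <- probes[ord, , drop = FALSE]
  rownames(probes) <- NULL
  structure(list(sample_id = sample_id, platform = platform,
                 probes = probes, genome = genome),
            class = "probe_profile")
}

#' @export
print.probe_profile <- function(x, ...) {
  cat(sprintf("<probe_profile> %s [%s]: %d probes on %d chromosomes\n",
              x$sample_id, x$platform, nrow(x$probes),
              length(unique(x$probes$chrom))))
  invisible(x)
}

#' Median absolute deviation of probe log2 ratios
#'
#' The unscaled MAD, \code{median(|x - median(x)|)}, used throughout as the
#' profile-level spread annotation (the "MAD" printed next to CNA profile
#' plots). Note this is deliberately not multiplied by the 1.4826 Gaussian
#' consistency factor.
#'
#' @param profile A \code{probe_profile}.
#' @return Non-negative numeric scalar.
#' @export
compute_mad <- function(profile) {
  stopifnot(inherits(profile, "probe_profile"))
  x <- profile$probes$log2ratio
  if (length(x) == 0) stop("empty profile")
  stats::median(abs(x - stats::median(x)))
}

#' Robust per-probe noise estimate
#'
#' Estimates the per-probe standard deviation from first differences of
#' log2 ratios within chromosomes:
#' \code{1.4826 * median(|diff(x)|) / sqrt(2)}. Because a copy number profile
#' is piecewise constant, successive-probe differences are pure noise except
#' at the few breakpoints, so the median is insensitive to the true segment
#' structure.
#'
#' @param profile A \code{probe_profile}.
#' @return Non-negative numeric scalar (log2-ratio units).
#' @export
estimate_noise <- function(profile) {
  stopifnot(inherits(profile, "probe_profile"))
  d <- unlist(lapply(split(profile$probes$log2ratio, profile$probes$chrom),
                     diff), use.names = FALSE)
  if (length(d) == 0)
    stop("need at least 2 probes on at least one chromosome")
  1.4826 * stats::median(abs(d)) / sqrt(2)
}

#' Construct a segmented copy number profile
#'
#' Piecewise-constant representation of a probe profile: per-chromosome,
#' non-overlapping, contiguous segments each carrying the mean log2 ratio of
#' its probes. Usually produced by \code{\link{segment_profile}}.
#'
#' @param sample_id Sample identifier.
#' @param segments Data frame with columns \code{chrom}, \code{start},
#'   \code{end}, \code{num_probes}, \code{mean}.
#' @param noise Per-probe noise sd estimate (see \code{\link{estimate_noise}}).
#' @param mad Unscaled MAD of the probe log2 ratios.
#' @param genome A \code{genome_model}.
#' @return An object of class \code{segmented_profile}.
#' @export
segmented_profile <- function(sample_id, segments, noise, mad,
                              genome = default_genome()) {
  need <- c("chrom", "start", "end", "num_probes", "mean")
  stopifnot(is.data.frame(segments), all(need %in% names(segments)))
  segments <- segments[, need]
  segments$chrom <- as.character(segments$chrom)
  if (nrow(segments) > 0 && any(segments$end <= segments$start))
    stop("segment intervals must satisfy end > start")
  if (!is.finite(noise) || noise < 0) stop("noise must be >= 0")
  if (!is.finite(mad) || mad < 0) stop("mad must be >= 0")
  ord <- order(match(segments$chrom, genome$chrom), segments$start)
  segments <- segments[ord, , drop = FALSE]
  rownames(segments) <- NULL
  structure(list(sample_id = sample_id, segments = segments,
                 noise = noise, mad = mad, genome = genome),
            class = "segmented_profile")
}

#' @export
print.segmented_profile <- function(x, ...) {
  cat(sprintf("<segmented_profile> %s: %d segments, noise=%.4f, MAD=%.4f\n",
              x$sample_id, nrow(x$segments), x$noise, x$mad))
  invisible(x)
}

#' Plot a segmented profile
#'
#' Whole-genome scatter of probe log2 ratios with segment means overlaid,
#' in the conventional per-pair CNA figure style.
#'
#' @param x A \code{segmented_profile}.
#' @param probe_profile Optional matching \code{probe_profile} whose probes
#'   are drawn under the segment means.
#' @param ... Passed to \code{plot}.
#' @export
plot.segmented_profile <- function(x, probe_profile = NULL, ...) {
  gm <- x$genome
  offset <- c(0, cumsum(gm$length))[seq_len(nrow(gm))]
  names(offset) <- gm$chrom
  if (!is.null(probe_profile)) {
    px <- offset[probe_profile$probes$chrom] +
      (probe_profile$probes$start + probe_profile$probes$end) / 2
    graphics::plot(px, probe_profile$probes$log2ratio, pch = ".",
                   col = "grey50", xlab = "chromosomal position",
                   ylab = "log2 tumor/normal ratio",
                   main = sprintf("%s (MAD = %.2f)", x$sample_id, x$mad), ...)
  } else {
    graphics::plot(NA, xlim = c(0, sum(gm$length)), ylim = c(-1.5, 1.5),
                   xlab = "chromosomal position",
                   ylab = "log2 tumor/normal ratio",
                   main = sprintf("%s (MAD = %.2f)", x$sample_id, x$mad), ...)
  }
  graphics::abline(v = cumsum(gm$length), col = "grey80")
  graphics::segments(offset[x$segments$chrom] + x$segments$start,
                     x$segments$mean,
                     offset[x$segments$chrom] + x$segments$end,
                     x$segments$mean, col = "red", lwd = 2)
  invisible(x)
}
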