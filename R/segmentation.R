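# Recursive binary segmentation of probe log2 ratios and projection of
# segment means onto a fixed bin grid.

# Best split of x[lo..hi] by a two-sample z statistic against a known noise
# sd. Returns NULL or the split index (last probe of the left part).
.best_split <- function(x, lo, hi, sigma, min_probes, alpha) {
  n <- hi - lo + 1
  if (n < 2 * min_probes) return(NULL)
  xs <- x[lo:hi]
  cs <- cumsum(xs)
  tot <- cs[n]
  k <- min_probes:(n - min_probes)        # size of the left part
  mean_l <- cs[k] / k
  mean_r <- (tot - cs[k]) / (n - k)
  z <- (mean_l - mean_r) / (sigma * sqrt(1 / k + 1 / (n - k)))
  best <- which.max(abs(z))
  # Bonferroni over the candidate split positions keeps flat stretches from
  # fragmenting: the max |z| under the null grows like sqrt(2 log n).
  p <- 2 * stats::pnorm(-abs(z[best])) * length(k)
  if (p >= alpha) return(NULL)
  lo + k[best] - 1
}

.segment_chromosome <- function(x, sigma, min_probes, alpha) {
  n <- length(x)
  # breakpoints stored as index of the last probe of each segment
  recurse <- function(lo, hi) {
    s <- .best_split(x, lo, hi, sigma, min_probes, alpha)
    if (is.null(s)) return(hi)
    c(recurse(lo, s), recurse(s + 1, hi))
  }
  ends <- recurse(1, n)
  starts <- c(1, utils::head(ends, -1) + 1)
  means <- vapply(seq_along(starts),
                  function(i) mean(x[starts[i]:ends[i]]), numeric(1))
  data.frame(first = starts, last = ends, mean = means)
}

#' Segment a probe profile into regions of constant copy number
#'
#' Per-chromosome recursive binary segmentation: each candidate breakpoint is
#' the position maximizing a two-sample z statistic (left mean vs right mean,
#' scaled by the robust noise estimate), accepted when its
#' Bonferroni-corrected two-sided p-value is below \code{alpha}. A
#' deterministic, desk-scale stand-in for circular binary segmentation.
#' Segment means are the plain means of their probes' log2 ratios; segments
#' tile the probed territory exactly.
#'
#' @param profile A \code{probe_profile}.
#' @param min_probes Minimum probes on each side of an accepted breakpoint
#'   (default 5). Chromosomes with fewer probes than \code{2 * min_probes}
#'   become a single segment.
#' @param alpha Significance level for accepting a breakpoint (default 0.01).
#' @return A \code{segmented_profile} with \code{noise} and \code{mad}
#'   populated from the input probes.
#' @export
segment_profile <- function(profile, min_probes = 5, alpha = 0.01) {
  stopifnot(inherits(profile, "probe_profile"))
  if (!is.numeric(min_probes) || min_probes < 1)
    stop("min_probes must be >= 1")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0, 1)")
  noise <- estimate_noise(profile)
  mad <- compute_mad(profile)
  sigma <- max(noise, 1e-10)  # noiseless profiles: any real step is accepted
  pr <- profile$probes
  chroms <- intersect(profile$genome$chrom, unique(pr$chrom))
  segs <- lapply(chroms, function(ch) {
    sub <- pr[pr$chrom == ch, , drop = FALSE]
    parts <- .segment_chromosome(sub$log2ratio, sigma, min_probes, alpha)
    data.frame(chrom = ch,
               start = sub$start[parts$first],
               end = sub$end[parts$last],
               num_probes = parts$last - parts$first + 1L,
               mean = parts$mean,
               stringsAsFactors = FALSE)
  })
  segmented_profile(profile$sample_id, do.call(rbind, segs),
                    noise = noise, mad = mad, genome = profile$genome)
}

#' Project segment means onto a fixed bin grid
#'
#' Each bin receives the overlap-length-weighted mean of the segment means
#' covering it; bins covered by no segment are \code{NA}. This puts profiles
#' from arrays of different probe density on one comparable vector.
#'
#' @param seg A \code{segmented_profile}.
#' @param grid A \code{bin_grid} built on the same \code{genome_model}.
#' @return Numeric vector of length \code{nrow(grid)} with \code{NA} for
#'   uncovered bins.
#' @export
project_to_bins <- function(seg, grid) {
  stopifnot(inherits(seg, "segmented_profile"), inherits(grid, "bin_grid"))
  if (!same_genome(seg$genome, attr(grid, "genome")))
    stop("segmented profile and bin grid use different genome models")
  bin_size <- attr(grid, "bin_size")
  acc <- numeric(nrow(grid))
  wt <- numeric(nrow(grid))
  # row index of the first bin of each chromosome in the grid
  first_bin <- match(attr(grid, "genome")$chrom, grid$chrom)
  names(first_bin) <- attr(grid, "genome")$chrom
  sg <- seg$segments
  for (i in seq_len(nrow(sg))) {
    ch <- sg$chrom[i]
    s <- sg$start[i]; e <- sg$end[i]
    i0 <- floor(s / bin_size); i1 <- floor((e - 1) / bin_size)
    rows <- first_bin[[ch]] + (i0:i1)
    ov <- pmin(e, (i0:i1 + 1) * bin_size) - pmax(s, (i0:i1) * bin_size)
    acc[rows] <- acc[rows] + ov * sg$mean[i]
    wt[rows] <- wt[rows] + ov
  }
  out <- ifelse(wt > 0, acc / wt, NA_real_)
  out
}
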