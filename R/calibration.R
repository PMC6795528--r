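# Cut-off calibration: non-clonal reference pairs, the specificity
# quantile, and the 2/3-subsample cross-validation whose 10,000 cut-offs
# are summarized by the mode of a fitted normal.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG stream afterwards.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Sample non-clonal reference pairs from a profile pool
#'
#' Builds the known non-clonal reference set used for cut-off calibration:
#' unordered pairs of profiles from two distinct patients are, by
#' construction, non-clonal. Pairs are sampled uniformly without
#' replacement from all cross-patient pairs, and each pair's clonality
#' correlation is computed.
#'
#' @param profiles List of \code{segmented_profile}s.
#' @param patient_ids Character vector, parallel to \code{profiles}; the
#'   two members of a pair must come from distinct patients.
#' @param n_pairs Number of pairs to draw.
#' @param grid A \code{bin_grid} for the correlation.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param provenance \code{"synthetic"} or \code{"external"}.
#' @param min_bins Passed to \code{\link{pearson_clonality}}.
#' @return An object of class \code{reference_pair_pool}: a list with
#'   \code{pairs} (data frame \code{id_a}, \code{id_b}, \code{pearson_r}),
#'   \code{provenance} and \code{seed}.
#' @export
sample_reference_pairs <- function(profiles, patient_ids, n_pairs, grid,
                                   seed, provenance = "synthetic",
                                   min_bins = 30) {
  stopifnot(length(profiles) == length(patient_ids))
  if (length(unique(patient_ids)) < 2)
    stop("need profiles from at least 2 distinct patients")
  idx <- utils::combn(length(profiles), 2)
  cross <- patient_ids[idx[1, ]] != patient_ids[idx[2, ]]
  idx <- idx[, cross, drop = FALSE]
  if (n_pairs > ncol(idx))
    stop(sprintf("n_pairs (%d) exceeds the %d distinct cross-patient pairs",
                 n_pairs, ncol(idx)))
  take <- with_seed(seed, sample.int(ncol(idx), n_pairs))
  idx <- idx[, take, drop = FALSE]
  # bin each profile once; correlations then reuse the cached vectors
  binned <- lapply(profiles, project_to_bins, grid = grid)
  r <- vapply(seq_len(ncol(idx)), function(j) {
    pearson_clonality(binned[[idx[1, j]]], binned[[idx[2, j]]],
                      min_bins = min_bins)
  }, numeric(1))
  ids <- vapply(profiles, function(p) p$sample_id, character(1))
  structure(list(pairs = data.frame(id_a = ids[idx[1, ]],
                                    id_b = ids[idx[2, ]],
                                    pearson_r = r,
                                    stringsAsFactors = FALSE),
                 provenance = match.arg(provenance,
                                        c("synthetic", "external")),
                 seed = seed),
            class = "reference_pair_pool")
}

#' @export
print.reference_pair_pool <- function(x, ...) {
  cat(sprintf("<reference_pair_pool> %d %s non-clonal pairs (seed %s)\n",
              nrow(x$pairs), x$provenance, format(x$seed)))
  invisible(x)
}

#' Specificity quantile of a non-clonal correlation set
#'
#' The threshold below which the requested fraction of known non-clonal
#' pairs is classified non-clonal: the empirical quantile (R default
#' linear-interpolation convention, type 7) of the correlations.
#'
#' @param correlations Numeric vector of pairwise correlations (>= 10).
#' @param specificity Target specificity in (0, 1), default 0.95.
#' @return The cut-off value.
#' @export
specificity_cutoff <- function(correlations, specificity = 0.95) {
  correlations <- correlations[is.finite(correlations)]
  if (length(correlations) < 10)
    stop("need at least 10 finite correlation values")
  if (!is.numeric(specificity) || specificity <= 0 || specificity >= 1)
    stop("specificity must be in (0, 1)")
  unname(stats::quantile(correlations, specificity, type = 7))
}

#' Cross-validated cut-off calibration
#'
#' Repeats, \code{iterations} times: draw \code{floor(subsample * N)} pairs
#' without replacement from the reference pool and record the
#' \code{specificity} quantile of their correlations. The per-iteration
#' cut-offs are summarized by a fitted normal, and the final cut-off is the
#' mode of that normal (= its mean; a kernel-density mode is available for
#' visibly non-normal pools). A warning is emitted when the calibrated value
#' departs from the shipped default 0.54 by more than 0.05, since a
#' pool-specific cut-off is expected to differ from the published one.
#'
#' @param pool A \code{reference_pair_pool}.
#' @param iterations Number of cross-validation iterations (default 10000).
#' @param subsample Fraction of pairs per iteration (default 2/3).
#' @param specificity Target specificity (default 0.95).
#' @param seed Integer seed; the whole procedure is reproducible.
#' @param mode_method \code{"normal"} (mean of the ML normal fit) or
#'   \code{"kde"} (mode of a kernel density estimate).
#' @return An object of class \code{calibration_result}: list with
#'   \code{cutoff}, \code{iteration_cutoffs}, \code{normal_mean},
#'   \code{normal_sd}, \code{iterations}, \code{subsample},
#'   \code{specificity}, \code{seed}, \code{mode_method}.
#' @export
calibrate_cutoff <- function(pool, iterations = 10000, subsample = 2 / 3,
                             specificity = 0.95, seed = 1,
                             mode_method = c("normal", "kde")) {
  stopifnot(inherits(pool, "reference_pair_pool"))
  mode_method <- match.arg(mode_method)
  r <- pool$pairs$pearson_r
  r <- r[is.finite(r)]
  n <- length(r)
  m <- floor(subsample * n)
  if (m < 10)
    stop("subsample of the pool has fewer than 10 pairs")
  cuts <- with_seed(seed, vapply(seq_len(iterations), function(i) {
    specificity_cutoff(r[sample.int(n, m)], specificity)
  }, numeric(1)))
  mu <- mean(cuts)
  sdv <- stats::sd(cuts)
  final <- if (mode_method == "normal" || sdv == 0) {
    mu  # the mode of a normal distribution equals its mean
  } else {
    d <- stats::density(cuts)
    d$x[which.max(d$y)]
  }
  if (abs(final - DEFAULT_CUTOFF) > 0.05)
    warning(sprintf(paste0("calibrated cut-off %.3f differs from the ",
                           "shipped default %.2f by more than 0.05"),
                    final, DEFAULT_CUTOFF))
  structure(list(cutoff = final, iteration_cutoffs = cuts,
                 normal_mean = mu, normal_sd = if (is.na(sdv)) 0 else sdv,
                 iterations = iterations, subsample = subsample,
                 specificity = specificity, seed = seed,
                 mode_method = mode_method),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat(sprintf(paste0("<calibration_result> cutoff=%.4f ",
                     "(normal mean %.4f, sd %.4f; %d iterations, ",
                     "subsample %.3f, specificity %.2f)\n"),
              x$cutoff, x$normal_mean, x$normal_sd, x$iterations,
              x$subsample, x$specificity))
  invisible(x)
}

#' Write a calibration result to disk
#'
#' Writes the scalar summary as JSON and the per-iteration cut-off vector as
#' a one-column TSV next to it.
#'
#' @param calib A \code{calibration_result}.
#' @param json_path Output JSON path; the iteration vector goes to the same
#'   path with extension \code{.iterations.tsv}.
#' @return \code{json_path}, invisibly.
#' @export
write_calibration <- function(calib, json_path) {
  stopifnot(inherits(calib, "calibration_result"))
  out <- calib[c("cutoff", "normal_mean", "normal_sd", "iterations",
                 "subsample", "specificity", "seed", "mode_method")]
  jsonlite::write_json(out, json_path, auto_unbox = TRUE, digits = NA)
  tsv <- paste0(tools::file_path_sans_ext(json_path), ".iterations.tsv")
  utils::write.table(data.frame(cutoff = calib$iteration_cutoffs), tsv,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(json_path)
}
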