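# Synthetic paired tumor CNA profiles: shared/private aberrations, tumor
# purity attenuation, probe-level Gaussian noise, and cohort metadata with
# realistic clinicopathological category mixes.

# probe spacing (bp) emulating array resolution by genome-wide probe count
.PLATFORM_SPACING <- c("44k" = 65000, "105k" = 27500, "180k" = 16000)

#' Simulation configuration
#'
#' The stated world of the synthetic cohort. Defaults emulate
#' macrodissected FFPE lung carcinoma arrays: a heavy aberration load
#' (Poisson-distributed event count, log-uniform event lengths spanning
#' focal to arm scale), integer copy number states diluted by tumor purity,
#' and i.i.d. Gaussian probe noise at 180k-array spacing.
#'
#' @param platform \code{"44k"}, \code{"105k"}, \code{"180k"} (uniform
#'   probe grids at the matching genome-wide spacing) or \code{"custom"}
#'   with \code{probe_spacing} given.
#' @param probe_spacing Probe spacing in bp for \code{platform = "custom"}.
#' @param genome A \code{genome_model}.
#' @param aberration_rate Poisson mean number of aberration events per
#'   tumor (default 40).
#' @param length_range Log-uniform aberration length bounds in bp
#'   (default 10-150 Mb).
#' @param cn_states Integer copy number states of events and
#'   \code{cn_probs} their probabilities (default loss CN1 0.40, gain CN3
#'   0.45, amplification CN4 0.15; normal is CN2).
#' @param cn_probs See \code{cn_states}.
#' @param shared_fraction Fraction of the ancestor aberration set copied
#'   into both tumors of a clonal pair (default 0.85).
#' @param private_rate Poisson mean number of private aberrations per
#'   tumor of a clonal pair (default 6).
#' @param purity_range Tumor purity bounds, uniform draw (default
#'   0.5-0.9).
#' @param noise_range Probe noise sd bounds, uniform draw (default
#'   0.04-0.12 log2 units).
#' @param poor_noise Probe noise sd of intentionally poor-quality tumors
#'   (default 0.3); poor tumors additionally carry zero aberrations, the
#'   observable signature of degraded input DNA.
#' @param mixture Cohort mixture of pair classes, named fractions summing
#'   to 1: \code{clonal}, \code{non-clonal}, \code{poor} (default
#'   0.55/0.25/0.20, echoing a clinical cohort's clonal /
#'   non-clonal / inconclusive split).
#' @param meta Metadata category mixes (organ-site split of pairs,
#'   synchronous fraction, interval class fractions, histology mix and
#'   match probability, nodal/systemic/mutation rates); see defaults in
#'   the source.
#' @return An object of class \code{simulation_config}.
#' @export
simulation_config <- function(platform = "180k", probe_spacing = NULL,
                              genome = default_genome(),
                              aberration_rate = 40,
                              length_range = c(10e6, 150e6),
                              cn_states = c(1, 3, 4),
                              cn_probs = c(0.40, 0.45, 0.15),
                              shared_fraction = 0.85,
                              private_rate = 6,
                              purity_range = c(0.5, 0.9),
                              noise_range = c(0.04, 0.12),
                              poor_noise = 0.3,
                              mixture = c(clonal = 0.55,
                                          `non-clonal` = 0.25,
                                          poor = 0.20),
                              meta = list()) {
  platform <- match.arg(platform, PLATFORMS)
  if (platform == "custom") {
    if (is.null(probe_spacing) || probe_spacing <= 0)
      stop("platform 'custom' requires a positive probe_spacing")
  } else {
    probe_spacing <- unname(.PLATFORM_SPACING[platform])
  }
  problems <- character(0)
  if (aberration_rate < 0) problems <- c(problems, "aberration_rate < 0")
  if (length(length_range) != 2 || length_range[1] <= 0 ||
      length_range[2] < length_range[1])
    problems <- c(problems, "invalid length_range")
  if (length(cn_states) != length(cn_probs) || any(cn_probs < 0) ||
      abs(sum(cn_probs) - 1) > 1e-8)
    problems <- c(problems, "cn_probs must match cn_states and sum to 1")
  if (any(cn_states < 0)) problems <- c(problems, "cn_states must be >= 0")
  if (shared_fraction < 0 || shared_fraction > 1)
    problems <- c(problems, "shared_fraction outside [0, 1]")
  if (private_rate < 0) problems <- c(problems, "private_rate < 0")
  if (length(purity_range) != 2 || purity_range[1] <= 0 ||
      purity_range[2] > 1 || purity_range[2] < purity_range[1])
    problems <- c(problems, "purity_range must be within (0, 1]")
  if (length(noise_range) != 2 || noise_range[1] < 0 ||
      noise_range[2] < noise_range[1])
    problems <- c(problems, "invalid noise_range")
  if (!all(c("clonal", "non-clonal", "poor") %in% names(mixture)) ||
      any(mixture < 0) || abs(sum(mixture) - 1) > 1e-8)
    problems <- c(problems,
                  "mixture must name clonal/non-clonal/poor and sum to 1")
  if (length(problems) > 0)
    stop("invalid simulation config: ", paste(problems, collapse = "; "))
  meta_defaults <- list(
    # organ-site split of pairs: both lung / lung vs head&neck / lung vs other
    site_mix = c(lung_lung = 0.29, lung_hn = 0.23, lung_other = 0.47,
                 other = 0.01),
    synchronous_fraction = 0.25,
    # metachronous interval classes: <2y, 2-4y, >=4y (months drawn within)
    interval_mix = c(short = 0.48, mid = 0.31, long = 0.21),
    interval_max = 252,
    histology_mix = c(adenocarcinoma = 0.37, squamous = 0.45,
                      adenosquamous = 0.01, `undifferentiated-NSCLC` = 0.05,
                      `small-cell` = 0.02, carcinoid = 0.04, other = 0.06),
    histology_match_prob = 0.94,
    n2_n3_prob = 0.2, systemic_mets_prob = 0.15,
    mutation_tested_prob = 0.08, mutation_match_prob = 0.73,
    cis_prob = 0.02, followup_mets_prob = 0.57
  )
  meta <- utils::modifyList(meta_defaults, meta)
  structure(list(platform = platform, probe_spacing = probe_spacing,
                 genome = genome, aberration_rate = aberration_rate,
                 length_range = length_range, cn_states = cn_states,
                 cn_probs = cn_probs, shared_fraction = shared_fraction,
                 private_rate = private_rate, purity_range = purity_range,
                 noise_range = noise_range, poor_noise = poor_noise,
                 mixture = mixture, meta = meta),
            class = "simulation_config")
}

#' Observed log2 ratio of a copy number state under tumor purity dilution
#'
#' A tumor fraction \code{purity} of cells at copy number \code{cn} mixed
#' with diploid normal cells yields an observed ratio
#' \code{log2(purity * cn / 2 + (1 - purity))}.
#'
#' @param cn True copy number (>= 0).
#' @param purity Fraction of neoplastic cells in (0, 1].
#' @return Observed log2 tumor/normal ratio.
#' @export
apply_purity <- function(cn, purity) {
  if (any(purity <= 0) || any(purity > 1))
    stop("purity must be in (0, 1]")
  if (any(cn < 0)) stop("copy number must be >= 0")
  log2(purity * cn / 2 + (1 - purity))
}

# Draw one aberration event set: data frame chrom/start/end/cn.
.draw_events <- function(config, n_events) {
  gm <- config$genome
  if (n_events == 0)
    return(data.frame(chrom = character(0), start = numeric(0),
                      end = numeric(0), cn = numeric(0),
                      stringsAsFactors = FALSE))
  chrom_idx <- sample.int(nrow(gm), n_events, replace = TRUE,
                          prob = gm$length)
  len <- exp(stats::runif(n_events, log(config$length_range[1]),
                          log(config$length_range[2])))
  chrlen <- gm$length[chrom_idx]
  start <- floor(stats::runif(n_events, 0, pmax(chrlen - len, 1)))
  end <- pmin(start + floor(len), chrlen)
  cn <- sample(config$cn_states, n_events, replace = TRUE,
               prob = config$cn_probs)
  data.frame(chrom = gm$chrom[chrom_idx], start = start, end = end,
             cn = cn, stringsAsFactors = FALSE)
}

# Render events into a probe-level profile plus its ground-truth segment
# table. Later events overwrite earlier ones on overlapping territory.
.render_profile <- function(config, sample_id, events, purity, noise_sd) {
  gm <- config$genome
  sp <- config$probe_spacing
  probes_list <- vector("list", nrow(gm))
  truth_list <- vector("list", nrow(gm))
  for (i in seq_len(nrow(gm))) {
    ch <- gm$chrom[i]
    starts <- seq(0, gm$length[i] - 1, by = sp)
    cn <- rep(2, length(starts))
    ev <- events[events$chrom == ch, , drop = FALSE]
    for (j in seq_len(nrow(ev)))
      cn[starts >= ev$start[j] & starts < ev$end[j]] <- ev$cn[j]
    expected <- apply_purity(cn, purity)
    probes_list[[i]] <- data.frame(
      chrom = ch, start = starts, end = pmin(starts + sp, gm$length[i]),
      log2ratio = expected + stats::rnorm(length(starts), 0, noise_sd),
      stringsAsFactors = FALSE)
    # run-length encode the probe-level truth
    r <- rle(cn)
    last <- cumsum(r$lengths)
    first <- c(1, utils::head(last, -1) + 1)
    truth_list[[i]] <- data.frame(
      chrom = ch, start = starts[first],
      end = pmin(starts[last] + sp, gm$length[i]),
      cn = r$values,
      log2_expected = apply_purity(r$values, purity),
      stringsAsFactors = FALSE)
  }
  list(profile = probe_profile(sample_id, do.call(rbind, probes_list),
                               platform = config$platform, genome = gm),
       truth = do.call(rbind, truth_list),
       purity = purity, noise_sd = noise_sd)
}

# Draw purity and noise for one tumor of the given quality.
.draw_quality <- function(config, quality) {
  if (quality == "poor") {
    list(purity = stats::runif(1, config$purity_range[1],
                               config$purity_range[2]),
         noise = config$poor_noise, n_events = 0L)
  } else {
    list(purity = stats::runif(1, config$purity_range[1],
                               config$purity_range[2]),
         noise = stats::runif(1, config$noise_range[1],
                              config$noise_range[2]),
         n_events = stats::rpois(1, config$aberration_rate))
  }
}

#' Simulate one tumor pair
#'
#' Clonal pairs share a configured fraction of one ancestor aberration set
#' and add independent private aberrations per tumor; non-clonal pairs draw
#' two fully independent aberration sets and share no breakpoints by
#' construction. Profiles are rendered at the configured platform spacing
#' with purity attenuation and i.i.d. Gaussian probe noise. Poor-quality
#' tumors carry zero aberrations and maximal noise, the observable
#' signature of degraded DNA.
#'
#' @param config A \code{simulation_config}.
#' @param truth \code{"clonal"} or \code{"non-clonal"}.
#' @param seed Integer seed; the pair is fully reproducible.
#' @param quality \code{"good"} or \code{"poor"}.
#' @param pair_id Pair identifier stem for the two sample ids.
#' @return An object of class \code{simulated_pair}: list with
#'   \code{truth}, \code{quality}, \code{profile_a}, \code{profile_b}
#'   (\code{probe_profile}s), \code{truth_a}, \code{truth_b} (ground-truth
#'   segment tables), \code{purity_a}, \code{purity_b}, \code{noise_a},
#'   \code{noise_b}, \code{metadata} (a \code{pair_metadata}).
#' @export
simulate_profile_pair <- function(config, truth = c("clonal", "non-clonal"),
                                  seed = 1, quality = c("good", "poor"),
                                  pair_id = "pair") {
  stopifnot(inherits(config, "simulation_config"))
  truth <- match.arg(truth)
  quality <- match.arg(quality)
  with_seed(seed, {
    qa <- .draw_quality(config, quality)
    qb <- .draw_quality(config, quality)
    if (truth == "clonal") {
      n_anc <- stats::rpois(1, config$aberration_rate)
      ancestor <- .draw_events(config, n_anc)
      n_shared <- round(config$shared_fraction * n_anc)
      shared <- ancestor[seq_len(n_shared), , drop = FALSE]
      ev_a <- rbind(shared, .draw_events(
        config, if (quality == "poor") 0L else stats::rpois(1, config$private_rate)))
      ev_b <- rbind(shared, .draw_events(
        config, if (quality == "poor") 0L else stats::rpois(1, config$private_rate)))
      if (quality == "poor") { ev_a <- ev_a[0, ]; ev_b <- ev_b[0, ] }
    } else {
      ev_a <- .draw_events(config, qa$n_events)
      ev_b <- .draw_events(config, qb$n_events)
    }
    a <- .render_profile(config, paste0(pair_id, "_A"), ev_a,
                         qa$purity, qa$noise)
    b <- .render_profile(config, paste0(pair_id, "_B"), ev_b,
                         qb$purity, qb$noise)
    md <- .draw_metadata(config, pair_id)
    structure(list(truth = truth, quality = quality,
                   profile_a = a$profile, profile_b = b$profile,
                   truth_a = a$truth, truth_b = b$truth,
                   purity_a = a$purity, purity_b = b$purity,
                   noise_a = a$noise_sd, noise_b = b$noise_sd,
                   metadata = md),
              class = "simulated_pair")
  })
}

# Draw clinical metadata for one pair from the configured category mixes.
.draw_metadata <- function(config, pair_id) {
  m <- config$meta
  site <- sample(names(m$site_mix), 1, prob = m$site_mix)
  organ_a <- if (site == "other") "other-specified" else "lung"
  organ_b <- switch(site, lung_lung = "lung", lung_hn = "head&neck",
                    lung_other = "other-specified", other = "other-specified")
  lobe_a <- if (organ_a == "lung") sample(LUNG_LOBES, 1) else NA_character_
  lobe_b <- if (organ_b == "lung") sample(LUNG_LOBES, 1) else NA_character_
  synchronous <- stats::runif(1) < m$synchronous_fraction
  interval <- if (synchronous) 0L else {
    cls <- sample(names(m$interval_mix), 1, prob = m$interval_mix)
    switch(cls,
           short = sample(1:23, 1),
           mid = sample(24:47, 1),
           long = sample(48:m$interval_max, 1))
  }
  match_hist <- stats::runif(1) < m$histology_match_prob
  h <- names(m$histology_mix)
  hist_a <- sample(h, 1, prob = m$histology_mix)
  hist_b <- if (match_hist) hist_a else
    sample(setdiff(h, hist_a), 1,
           prob = m$histology_mix[setdiff(h, hist_a)])
  tested <- stats::runif(1) < m$mutation_tested_prob
  mutation <- if (!tested) "missing" else
    if (stats::runif(1) < m$mutation_match_prob) "match" else "no-match"
  pair_metadata(
    pair_id,
    tumor_record(paste0(pair_id, "_A"), organ_a, lobe = lobe_a,
                 histology = hist_a,
                 cis_origin = stats::runif(1) < m$cis_prob),
    tumor_record(paste0(pair_id, "_B"), organ_b, lobe = lobe_b,
                 histology = hist_b,
                 cis_origin = stats::runif(1) < m$cis_prob),
    interval_months = interval,
    n2_n3 = stats::runif(1) < m$n2_n3_prob,
    systemic_mets = stats::runif(1) < m$systemic_mets_prob,
    mutation_comparison = mutation,
    followup_mets = stats::runif(1) < m$followup_mets_prob)
}

#' Simulate a cohort of tumor pairs
#'
#' Pair classes (clonal / non-clonal / poor-quality) are drawn from the
#' configured mixture; each pair gets profiles and clinical metadata.
#' Optionally writes per-tumor probe TSVs, ground-truth SEG files, the
#' metadata TSV consumed by the rule engines, and a \code{truth.json}
#' manifest into \code{dir}.
#'
#' @param config A \code{simulation_config}.
#' @param n_pairs Number of pairs (>= 1).
#' @param seed Integer seed.
#' @param dir Optional output directory.
#' @return An object of class \code{simulated_cohort}: list with
#'   \code{pairs} (list of \code{simulated_pair}), \code{truth_labels},
#'   \code{qualities}, \code{metadata} (data frame via
#'   \code{\link{metadata_table}}), \code{config}, \code{seed}.
#' @export
simulate_cohort <- function(config, n_pairs, seed = 1, dir = NULL) {
  stopifnot(inherits(config, "simulation_config"), n_pairs >= 1)
  classes <- with_seed(seed, sample(names(config$mixture), n_pairs,
                                    replace = TRUE, prob = config$mixture))
  truth <- ifelse(classes == "non-clonal", "non-clonal", "clonal")
  quality <- ifelse(classes == "poor", "poor", "good")
  # each pair gets its own seed derived from the cohort seed (kept < 2^31)
  pair_seeds <- (as.numeric(seed) * 10007 + 13 * seq_len(n_pairs)) %%
    .Machine$integer.max
  pairs <- lapply(seq_len(n_pairs), function(i) {
    simulate_profile_pair(config, truth = truth[i], seed = pair_seeds[i],
                          quality = quality[i],
                          pair_id = sprintf("pair%03d", i))
  })
  md <- metadata_table(lapply(pairs, function(p) p$metadata))
  cohort <- structure(list(pairs = pairs, truth_labels = truth,
                           qualities = quality, metadata = md,
                           config = config, seed = seed),
                      class = "simulated_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' Flatten pair metadata into the cohort metadata table
#'
#' @param metadata_list List of \code{pair_metadata} objects.
#' @return Data frame, one row per pair, with the documented column
#'   dictionary (\code{pair_id}, organs, lobes, raw histologies, IHC,
#'   interval, nodal/systemic flags, mutation comparison, follow-up).
#' @export
metadata_table <- function(metadata_list) {
  do.call(rbind, lapply(metadata_list, function(p) {
    data.frame(pair_id = p$pair_id,
               organ_a = p$tumor_a$organ, organ_b = p$tumor_b$organ,
               lobe_a = p$tumor_a$lobe, lobe_b = p$tumor_b$lobe,
               histology_a = p$tumor_a$histology,
               histology_b = p$tumor_b$histology,
               ttf1_a = p$tumor_a$ttf1, mucin_a = p$tumor_a$mucin,
               p63_a = p$tumor_a$p63,
               ttf1_b = p$tumor_b$ttf1, mucin_b = p$tumor_b$mucin,
               p63_b = p$tumor_b$p63,
               cis_a = isTRUE(p$tumor_a$cis_origin),
               cis_b = isTRUE(p$tumor_b$cis_origin),
               interval_months = p$interval_months,
               n2_n3 = p$n2_n3, systemic_mets = p$systemic_mets,
               mutation_comparison = p$mutation_comparison,
               followup_mets = p$followup_mets,
               stringsAsFactors = FALSE)
  }))
}

#' Rebuild pair_metadata objects from a metadata table
#'
#' Inverse of \code{\link{metadata_table}}; used when metadata arrive as
#' TSV.
#'
#' @param df Data frame in the \code{\link{metadata_table}} layout.
#' @return List of \code{pair_metadata} objects.
#' @export
metadata_from_table <- function(df) {
  lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    pair_metadata(
      r$pair_id,
      tumor_record(paste0(r$pair_id, "_A"), r$organ_a, lobe = r$lobe_a,
                   histology = r$histology_a, ttf1 = r$ttf1_a,
                   mucin = r$mucin_a, p63 = r$p63_a, cis_origin = r$cis_a),
      tumor_record(paste0(r$pair_id, "_B"), r$organ_b, lobe = r$lobe_b,
                   histology = r$histology_b, ttf1 = r$ttf1_b,
                   mucin = r$mucin_b, p63 = r$p63_b, cis_origin = r$cis_b),
      interval_months = r$interval_months, n2_n3 = r$n2_n3,
      systemic_mets = r$systemic_mets,
      mutation_comparison = r$mutation_comparison,
      followup_mets = r$followup_mets)
  })
}

#' Write a simulated cohort to disk
#'
#' Emits per-tumor probe TSVs, ground-truth SEG files, the
#' \code{pairs_metadata.tsv} consumed by the rule engines, and
#' \code{truth.json}.
#'
#' @param cohort A \code{simulated_cohort}.
#' @param dir Output directory (created if needed).
#' @return \code{dir}, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (p in cohort$pairs) {
    write_probe_tsv(p$profile_a,
                    file.path(dir, paste0(p$profile_a$sample_id, ".tsv")))
    write_probe_tsv(p$profile_b,
                    file.path(dir, paste0(p$profile_b$sample_id, ".tsv")))
    truth_seg <- rbind(
      data.frame(ID = p$profile_a$sample_id, chrom = p$truth_a$chrom,
                 `loc.start` = p$truth_a$start + 1,
                 `loc.end` = p$truth_a$end, `num.mark` = NA_integer_,
                 `seg.mean` = p$truth_a$log2_expected,
                 check.names = FALSE),
      data.frame(ID = p$profile_b$sample_id, chrom = p$truth_b$chrom,
                 `loc.start` = p$truth_b$start + 1,
                 `loc.end` = p$truth_b$end, `num.mark` = NA_integer_,
                 `seg.mean` = p$truth_b$log2_expected,
                 check.names = FALSE))
    utils::write.table(truth_seg,
                       file.path(dir, paste0(p$metadata$pair_id,
                                             "_truth.seg")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  utils::write.table(cohort$metadata, file.path(dir, "pairs_metadata.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = cohort$seed,
         pairs = data.frame(
           pair_id = vapply(cohort$pairs,
                            function(p) p$metadata$pair_id, character(1)),
           truth = cohort$truth_labels, quality = cohort$qualities)),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Simulate a pool of single-tumor reference profiles
#'
#' One good-quality tumor per synthetic patient, used to build the
#' non-clonal reference pairs for cut-off calibration (any two profiles
#' from distinct patients are non-clonal by construction).
#'
#' @param config A \code{simulation_config}.
#' @param n_profiles Number of patients/profiles.
#' @param seed Integer seed.
#' @return List with \code{profiles} (list of \code{probe_profile}) and
#'   \code{patient_ids}.
#' @export
simulate_reference_pool <- function(config, n_profiles, seed = 1) {
  stopifnot(inherits(config, "simulation_config"), n_profiles >= 2)
  seeds <- (as.numeric(seed) * 20011 + 17 * seq_len(n_profiles)) %%
    .Machine$integer.max
  profiles <- lapply(seq_len(n_profiles), function(i) {
    with_seed(seeds[i], {
      q <- .draw_quality(config, "good")
      .render_profile(config, sprintf("ref%03d", i),
                      .draw_events(config, q$n_events),
                      q$purity, q$noise)$profile
    })
  })
  list(profiles = profiles,
       patient_ids = sprintf("patient%03d", seq_len(n_profiles)))
}
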