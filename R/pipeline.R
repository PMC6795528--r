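# End-to-end orchestration: simulate or ingest profiles, segment, call
# clonality, classify clinical rules, and write the concordance report plus
# a reproducibility manifest.

#' Default pipeline configuration
#'
#' Every tunable threshold of the pipeline in one (JSON-serializable) list:
#' the decision cut-off, quality-gate limits, bin size, segmentation
#' parameters, calibration settings and the simulation configuration. Saved
#' verbatim into the run manifest.
#'
#' @param ... Named overrides of the defaults.
#' @return Named list of configuration values.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    cutoff = DEFAULT_CUTOFF,
    min_snr = 2, max_noise = 0.5,
    bin_size = 1e5, min_bins = 30,
    min_probes = 5, alpha = 0.01,
    include_sex = FALSE,
    calibration = list(iterations = 10000, subsample = 2 / 3,
                       specificity = 0.95),
    simulation = list(platform = "180k")
  )
  utils::modifyList(cfg, list(...))
}

#' Read / write a pipeline configuration
#'
#' @param path JSON file path.
#' @return For \code{read_config}, the configuration list merged over the
#'   defaults.
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, cfg)
}

#' @rdname read_config
#' @param config Configuration list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

.sim_config_from_pipeline <- function(config, genome) {
  args <- config$simulation
  args$genome <- genome
  do.call(simulation_config, args)
}

#' Run the full clonality analysis
#'
#' Orchestrates: simulate (or ingest) paired probe profiles, segment each
#' tumor, call per-pair clonality (gate + correlation + cut-off), classify
#' the clinical metadata with the Martini-Melamed and ACCP-2013 engines,
#' assemble the concordance report, and write everything plus a manifest
#' under \code{output_dir}.
#'
#' When \code{input_dir} is given it must contain per-tumor probe TSVs
#' named \code{<pair_id>_A.tsv} / \code{<pair_id>_B.tsv} and a
#' \code{pairs_metadata.tsv} in the \code{\link{metadata_table}} layout;
#' when \code{simulate = TRUE} a cohort of \code{n_pairs} is generated
#' instead.
#'
#' @param config Configuration from \code{\link{pipeline_config}}.
#' @param input_dir Directory of probe TSVs and metadata, or \code{NULL}.
#' @param simulate Generate a synthetic cohort instead of reading inputs.
#' @param n_pairs Number of simulated pairs.
#' @param seed Seed for the simulated cohort.
#' @param output_dir Output directory (created if needed).
#' @return The run manifest (list), invisibly; files are written under
#'   \code{output_dir}: \code{clonality_results.tsv},
#'   \code{classified_pairs.tsv}, \code{report.json},
#'   \code{manifest.json}.
#' @export
run_clonality_analysis <- function(config = pipeline_config(),
                                   input_dir = NULL, simulate = FALSE,
                                   n_pairs = 20, seed = 1,
                                   output_dir = tempfile("cna_run_")) {
  t0 <- Sys.time()
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  genome <- default_genome(include_sex = isTRUE(config$include_sex))
  grid <- bin_grid(genome, config$bin_size)
  timings <- list()
  stage <- function(name, expr) {
    s <- Sys.time()
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- as.numeric(difftime(Sys.time(), s, units = "secs"))
    out
  }

  inputs <- list()
  if (simulate) {
    cohort <- stage("simulate", {
      sim_cfg <- .sim_config_from_pipeline(config, genome)
      simulate_cohort(sim_cfg, n_pairs, seed = seed)
    })
    pair_ids <- vapply(cohort$pairs, function(p) p$metadata$pair_id,
                       character(1))
    profile_pairs <- lapply(cohort$pairs,
                            function(p) list(a = p$profile_a,
                                             b = p$profile_b))
    metadata <- lapply(cohort$pairs, function(p) p$metadata)
  } else {
    if (is.null(input_dir)) stop("either input_dir or simulate is required")
    md_path <- file.path(input_dir, "pairs_metadata.tsv")
    if (!file.exists(md_path))
      stop("input error: missing ", md_path)
    md_df <- stage("read_metadata",
                   utils::read.table(md_path, header = TRUE, sep = "\t",
                                     stringsAsFactors = FALSE))
    metadata <- metadata_from_table(md_df)
    pair_ids <- md_df$pair_id
    profile_pairs <- stage("read_profiles", lapply(pair_ids, function(pid) {
      fa <- file.path(input_dir, paste0(pid, "_A.tsv"))
      fb <- file.path(input_dir, paste0(pid, "_B.tsv"))
      for (f in c(fa, fb)) {
        if (!file.exists(f)) stop("input error: missing ", f)
        inputs[[f]] <<- unname(tools::md5sum(f))
      }
      list(a = read_probe_tsv(fa, genome = genome),
           b = read_probe_tsv(fb, genome = genome))
    }))
  }

  results <- stage("call_clonality", lapply(seq_along(profile_pairs),
    function(i) {
      pp <- profile_pairs[[i]]
      tryCatch({
        sa <- segment_profile(pp$a, config$min_probes, config$alpha)
        sb <- segment_profile(pp$b, config$min_probes, config$alpha)
        call_pair(sa, sb, grid, cutoff = config$cutoff,
                  min_snr = config$min_snr, max_noise = config$max_noise,
                  min_bins = config$min_bins, pair_id = pair_ids[i])
      }, error = function(e)
        stop(sprintf("pair %s: %s", pair_ids[i], conditionMessage(e)),
             call. = FALSE))
    }))
  res_df <- results_table(results)
  write_results_tsv(res_df, file.path(output_dir, "clonality_results.tsv"))

  classified <- stage("classify_rules", classify_pairs(metadata))
  classified$cna_call <- res_df$call[match(classified$pair_id,
                                           res_df$pair_id)]
  classified$pearson_r <- res_df$pearson_r[match(classified$pair_id,
                                                 res_df$pair_id)]
  utils::write.table(classified,
                     file.path(output_dir, "classified_pairs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  report <- stage("report", {
    summ <- cohort_summary(classified)
    list(n_pairs = summ$n,
         cna_calls = summ$marginals$cna_call,
         concordance = lapply(summ$comparisons, function(cmp) {
           if (is.null(cmp$rate)) return(NULL)
           out <- list(percent = cmp$rate$percent,
                       concordant = cmp$rate$concordant,
                       retained = cmp$rate$retained)
           if (!is.null(cmp$mcnemar)) {
             out$mcnemar_p <- cmp$mcnemar$p_value
             out$mcnemar_statistic <- cmp$mcnemar$statistic
           }
           out
         }))
  })
  jsonlite::write_json(report, file.path(output_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  manifest <- list(
    package_version = as.character(utils::packageVersion("cnaclonality")),
    config = config, seed = seed, simulate = simulate,
    inputs = inputs,
    outputs = c("clonality_results.tsv", "classified_pairs.tsv",
                "report.json", "manifest.json"),
    timings = timings,
    started = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    finished = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
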