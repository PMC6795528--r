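# Readers and writers for probe TSV (BED-like, 0-based half-open) and
# SEG (IGV dialect, 1-based closed). All readers log record counts and
# dropped probes via message().

#' Read a probe-level profile from TSV
#'
#' Expects a tab-separated file with a header line and columns
#' \code{chrom}, \code{start}, \code{end}, \code{log2ratio}; coordinates are
#' BED-like 0-based half-open. Rows with non-finite log2 ratios are dropped
#' and logged.
#'
#' @param path File path.
#' @param sample_id Sample id; defaults to the file name without extension.
#' @param platform Array platform label.
#' @param genome A \code{genome_model}.
#' @return A \code{probe_profile}.
#' @export
read_probe_tsv <- function(path, sample_id = NULL, platform = "custom",
                           genome = default_genome()) {
  if (is.null(sample_id))
    sample_id <- tools::file_path_sans_ext(basename(path))
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "log2ratio")
  if (!all(need %in% names(df)))
    stop(sprintf("malformed probe TSV '%s': expected columns %s",
                 path, paste(need, collapse = ", ")))
  message(sprintf("read %d probe records from %s", nrow(df), path))
  probe_profile(sample_id, df, platform = platform, genome = genome)
}

#' Write a probe-level profile to TSV
#'
#' @param profile A \code{probe_profile}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_probe_tsv <- function(profile, path) {
  stopifnot(inherits(profile, "probe_profile"))
  utils::write.table(profile$probes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read segmented profiles from a SEG file
#'
#' IGV-dialect SEG: columns \code{ID}, \code{chrom}, \code{loc.start},
#' \code{loc.end}, \code{num.mark}, \code{seg.mean}; 1-based closed
#' coordinates, converted to the internal 0-based half-open convention at
#' this boundary. A file may hold several samples.
#'
#' @param path File path.
#' @param genome A \code{genome_model}.
#' @return A named list of \code{segmented_profile} objects (noise and MAD
#'   are not recoverable from SEG and are set to 0).
#' @export
read_seg <- function(path, genome = default_genome()) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("ID", "chrom", "loc.start", "loc.end", "num.mark", "seg.mean")
  if (!all(need %in% names(df)))
    stop(sprintf("malformed SEG '%s': expected columns %s",
                 path, paste(need, collapse = ", ")))
  message(sprintf("read %d segment records (%d samples) from %s",
                  nrow(df), length(unique(df$ID)), path))
  lapply(split(df, df$ID), function(sub) {
    segmented_profile(sub$ID[1],
                      data.frame(chrom = as.character(sub$chrom),
                                 start = sub$loc.start - 1,
                                 end = sub$loc.end,
                                 num_probes = sub$num.mark,
                                 mean = sub$seg.mean,
                                 stringsAsFactors = FALSE),
                      noise = 0, mad = 0, genome = genome)
  })
}

#' Write segmented profiles to a SEG file
#'
#' @param segs A \code{segmented_profile} or list of them.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_seg <- function(segs, path) {
  if (inherits(segs, "segmented_profile")) segs <- list(segs)
  rows <- lapply(segs, function(s) {
    data.frame(ID = s$sample_id, chrom = s$segments$chrom,
               `loc.start` = s$segments$start + 1,
               `loc.end` = s$segments$end,
               `num.mark` = s$segments$num_probes,
               `seg.mean` = s$segments$mean,
               check.names = FALSE, stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
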