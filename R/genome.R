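# Genome model and fixed-width binning grid.

# hg19 chromosome lengths in bp (GRCh37 primary assembly).
.HG19_LENGTHS <- c(
  "1" = 249250621, "2" = 243199373, "3" = 198022430, "4" = 191154276,
  "5" = 180915260, "6" = 171115067, "7" = 159138663, "8" = 146364022,
  "9" = 141213431, "10" = 135534747, "11" = 135006516, "12" = 133851895,
  "13" = 115169878, "14" = 107349540, "15" = 102531392, "16" = 90354753,
  "17" = 81195210, "18" = 78077248, "19" = 59128983, "20" = 63025520,
  "21" = 48129895, "22" = 51304566, "X" = 155270560, "Y" = 59373566
)

#' Construct a genome model
#'
#' A genome model fixes the chromosome names, their order, and their lengths
#' for every downstream coordinate computation. All coordinates in this
#' package are 0-based, half-open \code{[start, end)}.
#'
#' @param chromosomes Character vector of chromosome names, in the order they
#'   are to be laid out.
#' @param lengths Numeric vector of chromosome lengths in bp, parallel to
#'   \code{chromosomes}.
#' @return An object of class \code{genome_model}: a data frame with columns
#'   \code{chrom} and \code{length}.
#' @examples
#' gm <- genome_model(c("1", "2"), c(5e7, 4e7))
#' @export
genome_model <- function(chromosomes, lengths) {
  chromosomes <- as.character(chromosomes)
  if (length(chromosomes) != length(lengths))
    stop("chromosomes and lengths must have equal length")
  if (anyDuplicated(chromosomes))
    stop("chromosome names must be unique")
  lengths <- as.numeric(lengths)
  if (any(!is.finite(lengths)) || any(lengths <= 0))
    stop("chromosome lengths must be positive and finite")
  gm <- data.frame(chrom = chromosomes, length = lengths,
                   stringsAsFactors = FALSE)
  class(gm) <- c("genome_model", "data.frame")
  gm
}

#' Default human genome model (hg19-like)
#'
#' @param include_sex Include chromosomes X and Y? Defaults to \code{FALSE}:
#'   reference-normalization artifacts dominate the sex chromosomes and the
#'   clonality comparison is restricted to autosomes 1-22 by default.
#' @return A \code{genome_model} with autosomes 1..22 (plus X, Y on request).
#' @export
default_genome <- function(include_sex = FALSE) {
  keep <- if (include_sex) names(.HG19_LENGTHS) else as.character(1:22)
  genome_model(keep, .HG19_LENGTHS[keep])
}

#' Tile a genome with fixed-width bins
#'
#' Produces the common comparison grid on which two segmented profiles
#' (possibly from arrays of different probe density) are compared. Bins are
#' half-open, non-overlapping and tile each chromosome in order; the last bin
#' of a chromosome is truncated at the chromosome end.
#'
#' @param genome A \code{genome_model}.
#' @param bin_size Bin width in bp (default 100 kb, comparable to the probe
#'   spacing of a 180k array).
#' @return An object of class \code{bin_grid}: a data frame with columns
#'   \code{chrom}, \code{start}, \code{end}; attributes \code{genome} and
#'   \code{bin_size}.
#' @export
bin_grid <- function(genome, bin_size = 1e5) {
  stopifnot(inherits(genome, "genome_model"))
  if (!is.numeric(bin_size) || length(bin_size) != 1 || bin_size <= 0)
    stop("bin_size must be a positive number")
  pieces <- lapply(seq_len(nrow(genome)), function(i) {
    len <- genome$length[i]
    starts <- seq(0, len - 1, by = bin_size)
    data.frame(chrom = genome$chrom[i], start = starts,
               end = pmin(starts + bin_size, len),
               stringsAsFactors = FALSE)
  })
  grid <- do.call(rbind, pieces)
  rownames(grid) <- NULL
  attr(grid, "genome") <- genome
  attr(grid, "bin_size") <- bin_size
  class(grid) <- c("bin_grid", "data.frame")
  grid
}

# TRUE when two genome models describe the same coordinate system.
same_genome <- function(a, b) {
  identical(a$chrom, b$chrom) && isTRUE(all.equal(a$length, b$length))
}
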