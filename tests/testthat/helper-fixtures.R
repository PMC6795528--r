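# Shared fixtures and independent oracles for the test suite.

# A small two-chromosome genome keeps unit tests fast while exercising the
# per-chromosome logic.
tiny_genome <- function() genome_model(c("1", "2"), c(5e7, 4e7))

# Build a probe_profile from one or more per-chromosome log2ratio vectors,
# with uniform probe spacing.
make_profile <- function(values, genome = tiny_genome(), spacing = 5e4,
                         sample_id = "s1") {
  if (!is.list(values)) values <- list(`1` = values)
  probes <- do.call(rbind, lapply(names(values), function(ch) {
    n <- length(values[[ch]])
    start <- (seq_len(n) - 1) * spacing
    data.frame(chrom = rep(ch, n), start = start, end = start + spacing,
               log2ratio = values[[ch]])
  }))
  probe_profile(sample_id, probes, genome = genome)
}

# Desk-scale simulation config on the tiny genome.
tiny_config <- function(...) {
  simulation_config(platform = "custom", probe_spacing = 5e4,
                    genome = tiny_genome(), ...)
}

# Textbook Pearson correlation: the independent oracle for
# pearson_clonality.
pearson_oracle <- function(x, y) {
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  num / den
}

# Rank-based AUC (probability a clonal pair outranks a non-clonal pair).
auc_rank <- function(scores, labels) {
  pos <- scores[labels]
  neg <- scores[!labels]
  r <- rank(c(pos, neg))
  (sum(r[seq_along(pos)]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))
}

# Sample skewness g1.
skewness_g1 <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^(3 / 2)
}

# Metadata fixtures for the rule engines.
lung_pair <- function(pair_id = "p", lobe_a = "RUL", lobe_b = "RUL",
                      hist_a = "adenocarcinoma", hist_b = "adenocarcinoma",
                      interval = 0, n2_n3 = FALSE, systemic = FALSE,
                      cis_a = FALSE, cis_b = FALSE, ...) {
  pair_metadata(pair_id,
                tumor_record("a", "lung", lobe = lobe_a,
                             histology = hist_a, cis_origin = cis_a),
                tumor_record("b", "lung", lobe = lobe_b,
                             histology = hist_b, cis_origin = cis_b),
                interval_months = interval, n2_n3 = n2_n3,
                systemic_mets = systemic, ...)
}
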