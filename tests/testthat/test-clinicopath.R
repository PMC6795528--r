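# clinicopath_rules: histology harmonization, matching, and the
# Martini-Melamed / ACCP-2013 rule engines.

test_that("harmonize_histology maps IHC on undifferentiated NSCLC", {
  rec <- function(...) tumor_record("t", "lung", histology = "NSCLC-NOS", ...)
  expect_equal(harmonize_histology(rec(ttf1 = "neg", mucin = "neg",
                                       p63 = "pos")), "squamous")
  expect_equal(harmonize_histology(rec(ttf1 = "pos", p63 = "neg")),
               "adenocarcinoma")
  expect_equal(harmonize_histology(rec(mucin = "pos", p63 = "neg")),
               "adenocarcinoma")
  expect_equal(harmonize_histology(rec(ttf1 = "neg", mucin = "neg",
                                       p63 = "neg")),
               "undifferentiated-NSCLC")
  # double positive (possible adenosquamous) and missing IHC both stay NOS
  expect_equal(harmonize_histology(rec(ttf1 = "pos", p63 = "pos")),
               "undifferentiated-NSCLC")
  expect_equal(harmonize_histology(rec()), "undifferentiated-NSCLC")
  # plain categories pass through, synonyms normalize
  expect_equal(harmonize_histology(tumor_record("t", "lung",
                                                histology = "SqCC")),
               "squamous")
  expect_equal(harmonize_histology(tumor_record("t", "lung",
                                                histology = "ADC")),
               "adenocarcinoma")
  expect_error(harmonize_histology(tumor_record("t", "lung")),
               "no histology")
  expect_error(harmonize_histology(tumor_record("t", "lung",
                                                histology = "gibberish")),
               "unrecognized")
})

test_that("histology_match is equality on categories (incl. IHC-favored)", {
  expect_true(histology_match("adenocarcinoma", "adenocarcinoma"))
  expect_false(histology_match("adenocarcinoma", "squamous"))
  # a squamous-via-IHC sample matches a squamous sample
  via_ihc <- harmonize_histology(tumor_record("t", "lung",
                                              histology = "NSCLC-NOS",
                                              ttf1 = "neg", mucin = "neg",
                                              p63 = "pos"))
  expect_true(histology_match(via_ihc, "squamous"))
})

test_that("classify_mm follows the reconstructed Martini-Melamed table", {
  # one tumor outside the lungs -> not applicable
  hn <- pair_metadata("p", tumor_record("a", "lung", lobe = "RUL",
                                        histology = "squamous"),
                      tumor_record("b", "head&neck",
                                   histology = "squamous"),
                      interval_months = 0)
  expect_equal(classify_mm(hn, "squamous", "squamous"), "not-applicable")
  # different histology -> MPLC
  expect_equal(classify_mm(lung_pair(hist_b = "squamous"),
                           "adenocarcinoma", "squamous"), "MPLC")
  # same histology, synchronous, same lobe, no CIS -> metastatic
  expect_equal(classify_mm(lung_pair(), "adenocarcinoma",
                           "adenocarcinoma"), "metastatic")
  # metachronous >= 24 months -> MPLC
  expect_equal(classify_mm(lung_pair(interval = 30), "adenocarcinoma",
                           "adenocarcinoma"), "MPLC")
  # CIS origin -> MPLC
  expect_equal(classify_mm(lung_pair(cis_a = TRUE), "adenocarcinoma",
                           "adenocarcinoma"), "MPLC")
  # different lobe, node-negative, no systemic mets -> MPLC
  expect_equal(classify_mm(lung_pair(lobe_b = "LLL"), "adenocarcinoma",
                           "adenocarcinoma"), "MPLC")
  # ... but nodal involvement keeps it metastatic
  expect_equal(classify_mm(lung_pair(lobe_b = "LLL", n2_n3 = TRUE),
                           "adenocarcinoma", "adenocarcinoma"),
               "metastatic")
  # missing lobe on a lung-lung pair errors, naming the field
  broken <- lung_pair()
  broken$tumor_a$lobe <- NA_character_
  expect_error(classify_mm(broken, "adenocarcinoma", "adenocarcinoma"),
               "tumor_a\\$lobe")
})

test_that("classify_accp2013 honors the documented precedence", {
  adc <- "adenocarcinoma"
  cls <- function(...) as.character(classify_accp2013(...))
  # same histology, same lobe, synchronous, N0, no mets -> T3
  expect_equal(cls(lung_pair(), adc, adc), "T3")
  # different ipsilateral lobes -> T4
  expect_equal(cls(lung_pair(lobe_a = "RUL", lobe_b = "RLL"), adc, adc),
               "T4")
  # different lobes with N2 involvement -> metastatic
  expect_equal(cls(lung_pair(lobe_a = "RUL", lobe_b = "LLL",
                             n2_n3 = TRUE), adc, adc), "metastatic")
  # different histology -> MPLC (never T3/T4)
  expect_equal(cls(lung_pair(hist_b = "squamous"), adc, "squamous"),
               "MPLC")
  # systemic metastases dominate for same-histology pairs
  expect_equal(cls(lung_pair(systemic = TRUE), adc, adc), "metastatic")
  # >= 4 years with no systemic mets -> MPLC even in the same lobe
  expect_equal(cls(lung_pair(interval = 60), adc, adc), "MPLC")
  # contralateral, node-negative, no mets -> MPLC
  expect_equal(cls(lung_pair(lobe_a = "RUL", lobe_b = "LUL"), adc, adc),
               "MPLC")
  # separate CIS foci -> MPLC
  expect_equal(cls(lung_pair(cis_b = TRUE), adc, adc), "MPLC")
  # extrapulmonary partner -> not applicable
  hn <- pair_metadata("p", tumor_record("a", "lung", lobe = "RUL",
                                        histology = "squamous"),
                      tumor_record("b", "head&neck",
                                   histology = "squamous"),
                      interval_months = 0)
  expect_equal(cls(hn, "squamous", "squamous"), "not-applicable")
  # the deciding rule is reported and the precedence is visible
  out <- classify_accp2013(lung_pair(), adc, adc)
  expect_equal(attr(out, "rule"), "same-lobe -> T3")
  expect_equal(accp_rule_order()[1], "different-histology-or-CIS -> MPLC")
})

test_that("both classifiers are total and agree on applicability", {
  set.seed(41)
  hist_opts <- c("adenocarcinoma", "squamous", "small-cell")
  for (i in 1:300) {
    organs <- sample(c("lung", "head&neck", "other"), 2, replace = TRUE,
                     prob = c(0.7, 0.15, 0.15))
    mk <- function(organ, id) tumor_record(
      id, organ,
      lobe = if (organ == "lung") sample(LUNG_LOBES, 1) else NA_character_,
      histology = sample(hist_opts, 1),
      cis_origin = runif(1) < 0.1)
    pm <- pair_metadata("p", mk(organs[1], "a"), mk(organs[2], "b"),
                        interval_months = sample(0:120, 1),
                        n2_n3 = runif(1) < 0.3,
                        systemic_mets = runif(1) < 0.3)
    ha <- harmonize_histology(pm$tumor_a)
    hb <- harmonize_histology(pm$tumor_b)
    mm <- classify_mm(pm, ha, hb)
    accp <- as.character(classify_accp2013(pm, ha, hb))
    expect_true(mm %in% c("MPLC", "metastatic", "not-applicable"))
    expect_true(accp %in% c("MPLC", "T3", "T4", "metastatic",
                            "not-applicable"))
    # not-applicable on exactly the same pairs
    expect_equal(mm == "not-applicable", accp == "not-applicable")
    # never T3/T4 for different-histology pairs
    if (ha != hb) expect_false(accp %in% c("T3", "T4"))
  }
})

test_that("classify_pairs appends the classification columns", {
  pairs <- list(lung_pair("p1"),
                lung_pair("p2", hist_b = "squamous", lobe_b = "LLL"))
  df <- classify_pairs(pairs)
  expect_equal(df$pair_id, c("p1", "p2"))
  expect_equal(df$histology_match, c("match", "no-match"))
  expect_equal(df$mm_class, c("metastatic", "MPLC"))
  expect_equal(df$accp_class, c("T3", "MPLC"))
})
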