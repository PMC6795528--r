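# Histology harmonization and the Martini-Melamed / ACCP-2013 rule engines
# that classify intrapulmonary tumor pairs as multiple primary lung cancer
# (MPLC) versus metastatic disease from clinical metadata.

HISTOLOGY_CATEGORIES <- c("adenocarcinoma", "squamous", "adenosquamous",
                          "undifferentiated-NSCLC", "small-cell",
                          "carcinoid", "LCNEC", "other")

LUNG_LOBES <- c("RUL", "RML", "RLL", "LUL", "LLL")

# raw-histology synonyms -> canonical category ("NOS" routes through IHC)
.HISTOLOGY_SYNONYMS <- c(
  "adenocarcinoma" = "adenocarcinoma", "adc" = "adenocarcinoma",
  "squamous" = "squamous", "squamous cell carcinoma" = "squamous",
  "sqcc" = "squamous",
  "adenosquamous" = "adenosquamous",
  "adenosquamous carcinoma" = "adenosquamous",
  "small-cell" = "small-cell", "small cell carcinoma" = "small-cell",
  "sclc" = "small-cell",
  "carcinoid" = "carcinoid", "pulmonary carcinoid tumor" = "carcinoid",
  "lcnec" = "LCNEC", "large cell neuroendocrine carcinoma" = "LCNEC",
  "other" = "other",
  "undifferentiated-nsclc" = "NOS", "undifferentiated nsclc" = "NOS",
  "undifferentiated non-small cell carcinoma" = "NOS",
  "nsclc-nos" = "NOS", "nsclc nos" = "NOS", "nos" = "NOS"
)

#' Construct a per-tumor clinical record
#'
#' @param tumor_id Tumor identifier.
#' @param organ Organ site: \code{"lung"}, \code{"head&neck"}, or any other
#'   specified site label.
#' @param lobe Lung lobe (\code{"RUL"}, \code{"RML"}, \code{"RLL"},
#'   \code{"LUL"}, \code{"LLL"}); only allowed when \code{organ} is lung.
#' @param histology Raw histology text (e.g. \code{"adenocarcinoma"},
#'   \code{"SqCC"}, \code{"NSCLC-NOS"}).
#' @param ttf1,mucin,p63 IHC marker states, each \code{"pos"}, \code{"neg"}
#'   or \code{"unknown"}; consulted only for undifferentiated NSCLC.
#' @param cis_origin Does the tumor arise from carcinoma in situ? Optional.
#' @return An object of class \code{tumor_record}.
#' @export
tumor_record <- function(tumor_id, organ, lobe = NA_character_,
                         histology = NA_character_, ttf1 = "unknown",
                         mucin = "unknown", p63 = "unknown",
                         cis_origin = NA) {
  organ <- as.character(organ)
  if (!is.na(lobe)) {
    if (organ != "lung")
      stop("lobe may only be given for lung tumors")
    lobe <- match.arg(lobe, LUNG_LOBES)
  }
  chk <- function(x) match.arg(x, c("pos", "neg", "unknown"))
  structure(list(tumor_id = tumor_id, organ = organ, lobe = lobe,
                 histology = histology, ttf1 = chk(ttf1),
                 mucin = chk(mucin), p63 = chk(p63),
                 cis_origin = cis_origin),
            class = "tumor_record")
}

#' Construct per-pair clinical metadata
#'
#' @param pair_id Pair identifier.
#' @param tumor_a,tumor_b \code{tumor_record}s of the two tumors.
#' @param interval_months Whole months between the diagnoses (0 =
#'   synchronous).
#' @param n2_n3 Signs of N2 or N3 lymph node involvement?
#' @param systemic_mets Systemic (multiple) metastases present?
#' @param mutation_comparison \code{"match"}, \code{"no-match"} or
#'   \code{"missing"} (not assayed on both tumors).
#' @param followup_mets Metastatic disease during follow-up (optional).
#' @return An object of class \code{pair_metadata}.
#' @export
pair_metadata <- function(pair_id, tumor_a, tumor_b, interval_months,
                          n2_n3 = FALSE, systemic_mets = FALSE,
                          mutation_comparison = "missing",
                          followup_mets = NA) {
  stopifnot(inherits(tumor_a, "tumor_record"),
            inherits(tumor_b, "tumor_record"))
  if (!is.numeric(interval_months) || interval_months < 0)
    stop("interval_months must be a non-negative whole number of months")
  structure(list(pair_id = pair_id, tumor_a = tumor_a, tumor_b = tumor_b,
                 interval_months = as.integer(interval_months),
                 n2_n3 = isTRUE(n2_n3),
                 systemic_mets = isTRUE(systemic_mets),
                 mutation_comparison = match.arg(mutation_comparison,
                                                 c("match", "no-match",
                                                   "missing")),
                 followup_mets = followup_mets),
            class = "pair_metadata")
}

#' Harmonize raw histology into a major category
#'
#' Maps raw histology text to one of the major WHO-style categories. For
#' undifferentiated NSCLC the IHC panel decides:
#' TTF-1-or-mucin positive with p63 negative favors adenocarcinoma;
#' TTF-1 and mucin negative with p63 positive favors squamous; all three
#' negative stays undifferentiated NSCLC (NOS); TTF-1/mucin and p63 both
#' positive (possible adenosquamous) and missing IHC also stay
#' undifferentiated.
#'
#' @param record A \code{tumor_record}.
#' @return One of \code{HISTOLOGY_CATEGORIES}.
#' @export
harmonize_histology <- function(record) {
  stopifnot(inherits(record, "tumor_record"))
  raw <- record$histology
  if (is.na(raw) || !nzchar(raw)) stop("no histology information available")
  key <- tolower(trimws(raw))
  cat <- .HISTOLOGY_SYNONYMS[key]
  if (is.na(cat))
    stop(sprintf("unrecognized histology '%s'", raw))
  cat <- unname(cat)
  if (cat != "NOS") return(cat)
  ttf1 <- record$ttf1; mucin <- record$mucin; p63 <- record$p63
  if ((ttf1 == "pos" || mucin == "pos") && p63 == "neg")
    return("adenocarcinoma")
  if (ttf1 == "neg" && mucin == "neg" && p63 == "pos")
    return("squamous")
  # all negative, double positive, or incomplete IHC
  "undifferentiated-NSCLC"
}

#' Do two histology categories match?
#'
#' @param a,b Harmonized histology categories.
#' @return \code{TRUE} iff the categories are equal.
#' @export
histology_match <- function(a, b) {
  a <- match.arg(a, HISTOLOGY_CATEGORIES)
  b <- match.arg(b, HISTOLOGY_CATEGORIES)
  identical(a, b)
}

.lobe_side <- function(lobe) substr(lobe, 1, 1)  # "R" or "L"

# both tumors intrapulmonary?
.both_lung <- function(pair) {
  pair$tumor_a$organ == "lung" && pair$tumor_b$organ == "lung"
}

.require_fields <- function(pair, classifier) {
  missing <- character(0)
  for (side in c("tumor_a", "tumor_b")) {
    if (is.na(pair[[side]]$lobe))
      missing <- c(missing, paste0(side, "$lobe"))
  }
  if (length(missing) > 0)
    stop(sprintf("%s: missing required fields for %s: %s",
                 pair$pair_id, classifier, paste(missing, collapse = ", ")))
}

#' Martini-Melamed classification of an intrapulmonary tumor pair
#'
#' Reconstructed Martini-Melamed (1975) rule table. Not applicable when
#' either tumor lies outside the lungs. MPLC when the histologies differ,
#' or when they match and the pair is metachronous with an interval of at
#' least 24 months, or either tumor originates from carcinoma in situ, or
#' the tumors sit in different lobes/lungs with no N2/N3 carcinoma in the
#' common lymphatics and no systemic metastases. Everything else is
#' intrapulmonary metastatic disease.
#'
#' @param pair A \code{pair_metadata}.
#' @param hist_a,hist_b Harmonized histology categories of the two tumors.
#' @return \code{"MPLC"}, \code{"metastatic"} or \code{"not-applicable"}.
#' @export
classify_mm <- function(pair, hist_a, hist_b) {
  stopifnot(inherits(pair, "pair_metadata"))
  if (!.both_lung(pair)) return("not-applicable")
  .require_fields(pair, "Martini-Melamed")
  if (!histology_match(hist_a, hist_b)) return("MPLC")
  cis <- isTRUE(pair$tumor_a$cis_origin) || isTRUE(pair$tumor_b$cis_origin)
  diff_lobe <- pair$tumor_a$lobe != pair$tumor_b$lobe
  if (pair$interval_months >= 24) return("MPLC")
  if (cis) return("MPLC")
  if (diff_lobe && !pair$n2_n3 && !pair$systemic_mets) return("MPLC")
  "metastatic"
}

# ACCP-2013 rules in evaluation order. The published MPLC / metastasis /
# T3 / T4 definitions overlap; this fixed precedence resolves the overlaps
# so that anatomic T3/T4 configurations are recognized before the
# short-interval metastasis rule, and the different-lobe MPLC rule is
# reserved for contralateral pairs (ipsilateral different-lobe pairs are T4
# by definition). The order is data, visible to callers via
# `accp_rule_order()`.
.ACCP_RULES <- list(
  list(name = "different-histology-or-CIS -> MPLC",
       test = function(p, same_hist, cis, diff_lobe, ipsi) !same_hist || cis,
       class = "MPLC"),
  list(name = "systemic-metastases -> metastatic",
       test = function(p, same_hist, cis, diff_lobe, ipsi) p$systemic_mets,
       class = "metastatic"),
  list(name = "different-lobes+N2/N3 -> metastatic",
       test = function(p, same_hist, cis, diff_lobe, ipsi)
         diff_lobe && p$n2_n3,
       class = "metastatic"),
  list(name = "interval>=4y -> MPLC",
       test = function(p, same_hist, cis, diff_lobe, ipsi)
         p$interval_months >= 48,
       class = "MPLC"),
  list(name = "same-lobe -> T3",
       test = function(p, same_hist, cis, diff_lobe, ipsi) !diff_lobe,
       class = "T3"),
  list(name = "different-ipsilateral-lobes -> T4",
       test = function(p, same_hist, cis, diff_lobe, ipsi) ipsi,
       class = "T4"),
  list(name = "contralateral-no-N2/N3-no-mets -> MPLC",
       test = function(p, same_hist, cis, diff_lobe, ipsi)
         !ipsi && !p$n2_n3 && !p$systemic_mets,
       class = "MPLC"),
  list(name = "interval<2y -> metastatic",
       test = function(p, same_hist, cis, diff_lobe, ipsi)
         p$interval_months < 24,
       class = "metastatic"),
  list(name = "fallback -> metastatic",
       test = function(p, same_hist, cis, diff_lobe, ipsi) TRUE,
       class = "metastatic")
)

#' ACCP-2013 rule precedence
#'
#' @return Character vector naming the rules of
#'   \code{\link{classify_accp2013}} in the order they are evaluated.
#' @export
accp_rule_order <- function() {
  vapply(.ACCP_RULES, function(r) r$name, character(1))
}

#' ACCP-2013 classification of an intrapulmonary tumor pair
#'
#' Implements the ACCP-2013 definitions: MPLC for different histology,
#' separate carcinoma-in-situ foci, same histology in a different lobe with
#' no N2/N3 involvement and no systemic metastases, or same histology with
#' at least a 4-year interval and no systemic metastases; pulmonary
#' metastasis for systemic metastases, different lobes with N2/N3
#' involvement, or an interval under two years; T3 for same-lobe
#' same-histology pairs; T4 for same-histology pairs in different
#' ipsilateral lobes. Overlaps between these definitions are resolved by a
#' fixed precedence (\code{\link{accp_rule_order}}); the first matching
#' rule wins and its name is attached as attribute \code{"rule"}.
#'
#' @param pair A \code{pair_metadata}.
#' @param hist_a,hist_b Harmonized histology categories.
#' @return \code{"MPLC"}, \code{"T3"}, \code{"T4"}, \code{"metastatic"} or
#'   \code{"not-applicable"}, with the deciding rule name as attribute.
#' @export
classify_accp2013 <- function(pair, hist_a, hist_b) {
  stopifnot(inherits(pair, "pair_metadata"))
  if (!.both_lung(pair)) return("not-applicable")
  .require_fields(pair, "ACCP-2013")
  same_hist <- histology_match(hist_a, hist_b)
  cis <- isTRUE(pair$tumor_a$cis_origin) || isTRUE(pair$tumor_b$cis_origin)
  diff_lobe <- pair$tumor_a$lobe != pair$tumor_b$lobe
  ipsi <- diff_lobe &&
    .lobe_side(pair$tumor_a$lobe) == .lobe_side(pair$tumor_b$lobe)
  for (rule in .ACCP_RULES) {
    if (rule$test(pair, same_hist, cis, diff_lobe, ipsi))
      return(structure(rule$class, rule = rule$name))
  }
  stop("unreachable: ACCP rule table is not total")  # nocov
}

#' Classify a cohort's pair metadata with both rule engines
#'
#' Convenience wrapper: harmonizes histology, evaluates histology matching,
#' Martini-Melamed and ACCP-2013 for every pair.
#'
#' @param pairs List of \code{pair_metadata} objects.
#' @return Data frame with columns \code{pair_id}, \code{hist_a},
#'   \code{hist_b}, \code{histology_match}, \code{mm_class},
#'   \code{accp_class}, \code{interval_months}, \code{mutation_comparison},
#'   \code{followup_mets}.
#' @export
classify_pairs <- function(pairs) {
  do.call(rbind, lapply(pairs, function(p) {
    ha <- harmonize_histology(p$tumor_a)
    hb <- harmonize_histology(p$tumor_b)
    data.frame(pair_id = p$pair_id, hist_a = ha, hist_b = hb,
               histology_match = ifelse(histology_match(ha, hb),
                                        "match", "no-match"),
               mm_class = classify_mm(p, ha, hb),
               accp_class = as.character(classify_accp2013(p, ha, hb)),
               interval_months = p$interval_months,
               mutation_comparison = p$mutation_comparison,
               followup_mets = p$followup_mets,
               stringsAsFactors = FALSE)
  }))
}
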