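# Cross-tabulation of per-pair classifications, concordance rates, and the
# McNemar test on the discordant cells.

#' Cross-tabulate two per-pair classifications
#'
#' @param labels_a,labels_b Equal-length aligned label vectors (method A in
#'   rows, method B in columns).
#' @param levels_a,levels_b Optional explicit label orderings; defaults to
#'   order of first appearance.
#' @return An object of class \code{concordance_table}: a list with
#'   \code{counts} (integer matrix), and \code{n} (total pairs).
#' @export
crosstab <- function(labels_a, labels_b, levels_a = NULL, levels_b = NULL) {
  if (length(labels_a) != length(labels_b))
    stop("label vectors must have equal length")
  if (is.null(levels_a)) levels_a <- unique(as.character(labels_a))
  if (is.null(levels_b)) levels_b <- unique(as.character(labels_b))
  counts <- table(factor(labels_a, levels = levels_a),
                  factor(labels_b, levels = levels_b))
  counts <- matrix(as.integer(counts), nrow = length(levels_a),
                   ncol = length(levels_b),
                   dimnames = list(levels_a, levels_b))
  structure(list(counts = counts, n = length(labels_a)),
            class = "concordance_table")
}

#' Build a concordance table directly from cell counts
#'
#' Convenience constructor for reproducing printed summary tables.
#'
#' @param counts Matrix of non-negative integers with row and column names.
#' @return A \code{concordance_table}.
#' @export
concordance_table <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry row and column names")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "integer"
  structure(list(counts = counts, n = sum(counts)),
            class = "concordance_table")
}

#' @export
print.concordance_table <- function(x, ...) {
  cat(sprintf("<concordance_table> n = %d\n", x$n))
  print(x$counts)
  invisible(x)
}

#' Concordance rate of a cross-tabulation
#'
#' Fraction of retained pairs falling in cells declared concordant. The
#' concordant cell set is explicit data (e.g. histology match vs CNA clonal
#' and histology no-match vs CNA non-clonal); columns/rows such as
#' "inconclusive" are typically excluded so the rate refers to conclusive
#' results only. The percentage is rounded to the nearest whole percent for
#' reporting; the exact fraction is retained.
#'
#' @param tab A \code{concordance_table}.
#' @param concordant Two-column matrix (or list of length-2 character
#'   vectors) of (row label, column label) pairs counted as concordant.
#' @param exclude Character vector of row or column labels dropped before
#'   computing the rate (default none).
#' @return List with \code{concordant} (count), \code{retained} (count),
#'   \code{fraction}, and \code{percent} (rounded integer).
#' @export
concordance_rate <- function(tab, concordant, exclude = character(0)) {
  stopifnot(inherits(tab, "concordance_table"))
  if (is.list(concordant))
    concordant <- do.call(rbind, concordant)
  concordant <- matrix(as.character(concordant), ncol = 2)
  bad <- !(concordant[, 1] %in% rownames(tab$counts)) |
    !(concordant[, 2] %in% colnames(tab$counts))
  if (any(bad))
    stop("concordance mapping references labels absent from the table")
  keep_r <- setdiff(rownames(tab$counts), exclude)
  keep_c <- setdiff(colnames(tab$counts), exclude)
  sub <- tab$counts[keep_r, keep_c, drop = FALSE]
  retained <- sum(sub)
  if (retained == 0) stop("no pairs retained after exclusion")
  conc <- concordant[concordant[, 1] %in% keep_r &
                       concordant[, 2] %in% keep_c, , drop = FALSE]
  n_conc <- sum(sub[conc])
  list(concordant = n_conc, retained = retained,
       fraction = n_conc / retained,
       percent = as.integer(round(100 * n_conc / retained)))
}

#' McNemar test from the discordant cell counts
#'
#' Paired test of marginal homogeneity of a 2x2 table, driven entirely by
#' the two discordant cell counts b and c. The default is the
#' continuity-corrected chi-square: statistic \code{(|b-c|-1)^2/(b+c)} on 1
#' df, with the statistic forced to 0 (p = 1) when \code{|b-c| <= 1}. The
#' exact alternative doubles the smaller binomial(b+c, 1/2) tail, capped at
#' 1.
#'
#' @param b,c The two discordant cell counts.
#' @param method \code{"chi2cc"} (default) or \code{"exact"}.
#' @return An object of class \code{mcnemar_result}: list with \code{b},
#'   \code{c}, \code{statistic}, \code{p_value}, \code{method}.
#' @export
mcnemar_test <- function(b, c, method = c("chi2cc", "exact")) {
  method <- match.arg(method)
  if (b < 0 || c < 0 || b != round(b) || c != round(c))
    stop("b and c must be non-negative integers")
  if (b + c == 0) {
    warning("no discordant pairs; p-value is 1 by convention")
    return(structure(list(b = b, c = c, statistic = 0, p_value = 1,
                          method = method), class = "mcnemar_result"))
  }
  if (method == "chi2cc") {
    if (abs(b - c) <= 1) {
      stat <- 0; p <- 1
    } else {
      stat <- (abs(b - c) - 1)^2 / (b + c)
      p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)
    }
  } else {
    stat <- NA_real_
    p <- min(1, 2 * stats::pbinom(min(b, c), b + c, 0.5))
  }
  structure(list(b = b, c = c, statistic = stat, p_value = p,
                 method = method), class = "mcnemar_result")
}

#' @export
print.mcnemar_result <- function(x, ...) {
  cat(sprintf("<mcnemar_result> b=%d c=%d %s: statistic=%s, p=%.4g\n",
              x$b, x$c, x$method,
              ifelse(is.na(x$statistic), "NA", sprintf("%.3f", x$statistic)),
              x$p_value))
  invisible(x)
}

# Concordance mappings used throughout: a clonal CNA result corresponds to
# matching histology, matching mutations, MM intrapulmonary metastasis,
# and ACCP "related" (metastatic, T3 or T4) respectively.
.CNA_CONCORDANCE <- list(
  histology = list(concordant = rbind(c("match", "clonal"),
                                      c("no-match", "non-clonal")),
                   positive = "match"),
  mutation = list(concordant = rbind(c("match", "clonal"),
                                     c("no-match", "non-clonal")),
                  positive = "match"),
  mm = list(concordant = rbind(c("metastatic", "clonal"),
                               c("MPLC", "non-clonal")),
            positive = "metastatic"),
  accp = list(concordant = rbind(c("related", "clonal"),
                                 c("MPLC", "non-clonal")),
              positive = "related")
)

# Collapse ACCP classes to related (metastatic/T3/T4) vs MPLC.
.accp_related <- function(x) {
  ifelse(x %in% c("metastatic", "T3", "T4"), "related",
         ifelse(x == "MPLC", "MPLC", x))
}

# 2x2 discordant cells for a method-vs-CNA comparison, after dropping
# inconclusive CNA results and not-applicable method results.
.discordant_cells <- function(method_labels, cna_calls, positive) {
  keep <- cna_calls %in% c("clonal", "non-clonal") &
    !method_labels %in% c("not-applicable", "missing")
  m <- method_labels[keep]; k <- cna_calls[keep]
  list(b = sum(m == positive & k == "non-clonal"),
       c = sum(m != positive & k == "clonal"))
}

#' Cohort-level summary report
#'
#' From complete per-pair records, emits the marginal counts/percentages by
#' every classification axis, the method-vs-CNA concordance tables with
#' concordance rates and McNemar tests (inconclusive CNA results and
#' not-applicable/missing method results excluded), and, when follow-up is
#' recorded, the follow-up cross-tables.
#'
#' @param records Data frame with one row per pair and columns
#'   \code{cna_call} (clonal/non-clonal/inconclusive),
#'   \code{histology_match} (match/no-match), \code{mm_class},
#'   \code{accp_class}, \code{mutation_comparison}
#'   (match/no-match/missing), and optionally \code{followup_mets}
#'   (logical).
#' @param mcnemar_method Passed to \code{\link{mcnemar_test}}.
#' @return An object of class \code{cohort_summary}: list with
#'   \code{marginals}, \code{comparisons} (per method: table, rate,
#'   mcnemar), and \code{followup} (or NULL).
#' @export
cohort_summary <- function(records, mcnemar_method = "chi2cc") {
  need <- c("cna_call", "histology_match", "mm_class", "accp_class",
            "mutation_comparison")
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  n <- nrow(records)
  marg <- lapply(records[need], function(x) {
    tb <- table(x)
    data.frame(category = names(tb), count = as.integer(tb),
               percent = as.integer(round(100 * as.integer(tb) / n)),
               stringsAsFactors = FALSE)
  })
  cna_levels <- c("clonal", "non-clonal", "inconclusive")
  methods <- list(
    histology = records$histology_match,
    mm = records$mm_class,
    accp = .accp_related(records$accp_class),
    mutation = records$mutation_comparison
  )
  comparisons <- lapply(names(methods), function(nm) {
    lab <- methods[[nm]]
    spec <- .CNA_CONCORDANCE[[nm]]
    tab <- crosstab(lab, records$cna_call,
                    levels_a = unique(c(spec$concordant[, 1],
                                        unique(lab))),
                    levels_b = cna_levels)
    drop <- c("inconclusive", "not-applicable", "missing")
    rate <- tryCatch(
      concordance_rate(tab, spec$concordant, exclude = drop),
      error = function(e) NULL)
    dc <- .discordant_cells(lab, records$cna_call, spec$positive)
    mc <- if (dc$b + dc$c > 0)
      mcnemar_test(dc$b, dc$c, mcnemar_method) else NULL
    list(method = nm, table = tab, rate = rate, mcnemar = mc)
  })
  names(comparisons) <- names(methods)
  followup <- NULL
  if ("followup_mets" %in% names(records) &&
      any(!is.na(records$followup_mets))) {
    fu <- ifelse(records$followup_mets, "yes", "no")
    keep <- !is.na(records$followup_mets)
    followup <- lapply(names(methods), function(nm) {
      lab <- methods[[nm]][keep]
      ok <- !lab %in% c("not-applicable", "missing", "inconclusive")
      crosstab(lab[ok], fu[keep][ok], levels_b = c("yes", "no"))
    })
    names(followup) <- names(methods)
    ok <- records$cna_call[keep] %in% c("clonal", "non-clonal")
    followup$cna <- crosstab(records$cna_call[keep][ok], fu[keep][ok],
                             levels_a = c("clonal", "non-clonal"),
                             levels_b = c("yes", "no"))
  }
  structure(list(n = n, marginals = marg, comparisons = comparisons,
                 followup = followup),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("<cohort_summary> %d pairs\n", x$n))
  cat("CNA calls:\n")
  print(x$marginals$cna_call)
  for (nm in names(x$comparisons)) {
    cmp <- x$comparisons[[nm]]
    if (!is.null(cmp$rate))
      cat(sprintf("%s vs CNA: %d%% concordant (%d/%d)%s\n", nm,
                  cmp$rate$percent, cmp$rate$concordant, cmp$rate$retained,
                  if (!is.null(cmp$mcnemar))
                    sprintf(", McNemar p = %.3g", cmp$mcnemar$p_value)
                  else ""))
  }
  invisible(x)
}

#' Per-group positive fraction of a two-column cross-table
#'
#' Helper for follow-up style tables: for each row (group) of a
#' \code{concordance_table}, the fraction falling in the given column.
#'
#' @param tab A \code{concordance_table}.
#' @param column Column label (e.g. \code{"yes"}).
#' @return Data frame with \code{group}, \code{count}, \code{total},
#'   \code{percent} (rounded integer).
#' @export
group_fraction <- function(tab, column) {
  stopifnot(inherits(tab, "concordance_table"))
  if (!column %in% colnames(tab$counts)) stop("no such column: ", column)
  tot <- rowSums(tab$counts)
  cnt <- tab$counts[, column]
  data.frame(group = rownames(tab$counts), count = as.integer(cnt),
             total = as.integer(tot),
             percent = as.integer(round(100 * cnt / pmax(tot, 1))),
             stringsAsFactors = FALSE)
}
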