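#' Aggregate CDR3-level scores into one complementarity score per case
#'
#' A case's repertoire yields one pair score per recovered CDR3; the
#' per-case complementarity score (CS) is their maximum by default - a
#' single strongly complementary clone is the salient event - or their
#' mean for sensitivity analysis.
#'
#' @param scores Numeric vector of pair scores for one case against one
#'   antigen or fragment; must be nonempty (cases with no recovered CDR3s
#'   are excluded upstream, mirroring the restriction of the analysis to
#'   cases with receptor recombination-read recoveries).
#' @param method `"max"` (default) or `"mean"`.
#' @param case_id,antigen_label Identifiers recorded in the output row.
#' @return One-row data frame with columns `case_id`, `antigen_label`,
#'   `cs`, `n_cdr3`.
#' @examples
#' aggregate_sample_score(c(1, 5, -2), "max")$cs    # 5
#' aggregate_sample_score(c(1, 5, -2), "mean")$cs   # 1.333...
#' @export
aggregate_sample_score <- function(scores, method = c("max", "mean"),
                                   case_id = NA_character_,
                                   antigen_label = NA_character_) {
  method <- match.arg(method)
  if (length(scores) == 0L)
    stop("no CDR3 scores to aggregate for case '", case_id,
         "'; cases without recovered CDR3s must be excluded upstream",
         call. = FALSE)
  if (any(!is.finite(scores)))
    stop("non-finite pair score for case '", case_id, "'", call. = FALSE)
  cs <- if (method == "max") max(scores) else mean(scores)
  data.frame(case_id = case_id, antigen_label = antigen_label,
             cs = cs, n_cdr3 = length(scores), stringsAsFactors = FALSE)
}

#' Per-case complementarity scores for a whole cohort
#'
#' Scores every CDR3 in a cohort table against one antigen fragment and
#' aggregates to one CS per case. TRA and TRB chains are pooled into a
#' single repertoire per case unless a `chain` filter is given.
#'
#' @param cdr3_table Data frame with columns `case_id`, `chain`, `cdr3_aa`
#'   (see [read_cdr3_table()]).
#' @param fragment One-row data frame in the [fragment_protein()] layout,
#'   or a single peptide string.
#' @param chain Optional filter, `"TRA"` or `"TRB"`; `NULL` pools both.
#' @inheritParams pair_score
#' @inheritParams aggregate_sample_score
#' @return Data frame of score records, one row per case: `case_id`,
#'   `antigen_label`, `cs`, `n_cdr3`, ordered by `case_id`.
#' @export
score_cohort <- function(cdr3_table, fragment, method = c("max", "mean"),
                         chain = NULL, weights = score_weights(),
                         table = charge_table(), normalize = FALSE) {
  method <- match.arg(method)
  stopifnot(is.data.frame(cdr3_table),
            all(c("case_id", "chain", "cdr3_aa") %in% names(cdr3_table)))
  if (is.data.frame(fragment)) {
    stopifnot(nrow(fragment) == 1L, "sequence" %in% names(fragment))
    label <- if (fragment$fragment_index[1] > 0)
      paste0(fragment$antigen_name[1], ":", fragment$fragment_index[1])
    else fragment$antigen_name[1]
    fseq <- fragment$sequence[1]
  } else {
    fseq <- as.character(fragment)
    label <- fseq
  }
  if (!is.null(chain)) {
    chain <- match.arg(chain, c("TRA", "TRB"))
    cdr3_table <- cdr3_table[cdr3_table$chain == chain, , drop = FALSE]
  }
  if (nrow(cdr3_table) == 0L)
    stop("no CDR3s to score", if (!is.null(chain))
      paste0(" for chain ", chain), call. = FALSE)
  ids <- unique(cdr3_table$case_id)
  recs <- lapply(ids, function(id) {
    seqs <- cdr3_table$cdr3_aa[cdr3_table$case_id == id]
    ps <- vapply(seqs, pair_score, numeric(1),
                 fragment = fseq, weights = weights, table = table,
                 normalize = normalize, USE.NAMES = FALSE)
    aggregate_sample_score(ps, method, case_id = id, antigen_label = label)
  })
  out <- do.call(rbind, recs)
  out[order(out$case_id), , drop = FALSE]
}

#' Median split of a scored cohort
#'
#' Stratifies cases into upper and lower 50th-percentile complementarity
#' score groups. The threshold is the median CS; cases strictly above it
#' form the upper group and all others the lower, so with an odd cohort
#' size or ties at the median the lower group is at least as large.
#'
#' @param records Data frame of score records with columns `case_id` and
#'   `cs` (see [score_cohort()]); at least 4 rows, one per case.
#' @return List with class `"cs_stratification"`: `upper` and `lower`
#'   (character vectors of case ids) and `threshold` (the median CS).
#' @examples
#' recs <- data.frame(case_id = letters[1:4], cs = c(1, 2, 3, 4))
#' stratify_median(recs)
#' @export
stratify_median <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("case_id", "cs") %in% names(records)))
  if (anyDuplicated(records$case_id))
    stop("duplicate case_id in score records", call. = FALSE)
  if (nrow(records) < 4L)
    stop("median stratification needs at least 4 cases; got ",
         nrow(records), call. = FALSE)
  if (any(!is.finite(records$cs)))
    stop("non-finite complementarity score", call. = FALSE)
  thr <- stats::median(records$cs)
  up <- records$cs > thr
  if (!any(up))
    stop("degenerate split: all complementarity scores are at or below ",
         "the median (are all scores identical?)", call. = FALSE)
  structure(list(upper = records$case_id[up],
                 lower = records$case_id[!up],
                 threshold = thr),
            class = "cs_stratification")
}

#' @export
print.cs_stratification <- function(x, ...) {
  cat("Median-split cohort stratification\n")
  cat("  threshold (median CS):", format(x$threshold), "\n")
  cat("  upper group:", length(x$upper), "cases\n")
  cat("  lower group:", length(x$lower), "cases\n")
  invisible(x)
}

#' Stratification as a two-column table
#'
#' @param strat A `"cs_stratification"` from [stratify_median()].
#' @return Data frame `case_id`, `group` (`"upper"`/`"lower"`), ordered by
#'   `case_id`.
#' @export
stratification_table <- function(strat) {
  stopifnot(inherits(strat, "cs_stratification"))
  out <- data.frame(
    case_id = c(strat$upper, strat$lower),
    group = rep(c("upper", "lower"),
                c(length(strat$upper), length(strat$lower))),
    stringsAsFactors = FALSE
  )
  out[order(out$case_id), , drop = FALSE]
}
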