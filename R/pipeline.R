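#' Survival analysis of a scored cohort
#'
#' The headline survival analysis: score every case's CDR3 repertoire
#' against one antigen (or antigen fragment), aggregate to one
#' complementarity score per case, split the cohort at the median score,
#' estimate a Kaplan-Meier curve per group, and compare the groups with
#' the logrank test.
#'
#' @param cdr3_table CDR3 table (`case_id`, `chain`, `cdr3_aa`), in
#'   memory or a TSV path.
#' @param antigen One-row fragment table (see [fragment_protein()],
#'   [whole_protein()]), a peptide string, or a FASTA path whose first
#'   record is used whole.
#' @param survival_table Survival table (`case_id`, `time_months`,
#'   `event`), in memory or a CSV path.
#' @param config A [run_config()].
#' @param outdir Optional directory; when given, all intermediates
#'   (score records, stratification, both KM curves, logrank summary and
#'   a run manifest) are written there.
#' @return List: `scores`, `stratification`, `km` (named list of the two
#'   curves), `logrank`.
#' @export
run_survival_analysis <- function(cdr3_table, antigen, survival_table,
                                  config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  inputs <- list()
  if (is.character(cdr3_table) && length(cdr3_table) == 1L) {
    inputs$cdr3_table <- cdr3_table
    cdr3_table <- read_cdr3_table(cdr3_table)
  } else validate_cdr3_table(cdr3_table)
  antigen <- resolve_antigen(antigen, inputs)
  if (is.character(survival_table) && length(survival_table) == 1L) {
    inputs$survival_table <- survival_table
    survival_table <- read_survival_table(survival_table)
  }
  shared <- intersect(unique(cdr3_table$case_id), survival_table$case_id)
  if (length(shared) < 4L)
    stop("[join] only ", length(shared), " case(s) shared between the ",
         "CDR3 table and the survival table; need at least 4",
         call. = FALSE)
  cfg_log(config, "info", "scoring ", length(shared), " cases against ",
          antigen$antigen_name[1])
  scores <- tryCatch(
    score_cohort(cdr3_table[cdr3_table$case_id %in% shared, ], antigen,
                 method = config$aggregation, chain = config$chain,
                 weights = config$weights, table = config$table,
                 normalize = config$normalize),
    error = function(e) stop("[scoring] ", conditionMessage(e),
                             call. = FALSE))
  strat <- tryCatch(stratify_median(scores),
                    error = function(e) stop("[stratification] ",
                                             conditionMessage(e),
                                             call. = FALSE))
  surv <- survival_table[match(scores$case_id, survival_table$case_id), ]
  grp <- ifelse(surv$case_id %in% strat$upper, "upper", "lower")
  km <- lapply(c(upper = "upper", lower = "lower"), function(g)
    km_estimate(surv$time_months[grp == g], surv$event[grp == g]))
  lr <- tryCatch(logrank_test(surv$time_months, surv$event, grp),
                 error = function(e) stop("[logrank] ",
                                          conditionMessage(e),
                                          call. = FALSE))
  cfg_log(config, "info", "logrank chi-square ",
          format(lr$chi_square, digits = 4), ", p ",
          format(lr$p_value, digits = 4))
  res <- list(scores = scores, stratification = strat, km = km,
              logrank = lr)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_score_records(scores, file.path(outdir, "score_records.csv"))
    write_stratification(strat, file.path(outdir, "stratification.csv"))
    write_km_curve(km$upper, file.path(outdir, "km_upper.csv"))
    write_km_curve(km$lower, file.path(outdir, "km_lower.csv"))
    utils::write.csv(
      data.frame(chi_square = lr$chi_square, p_value = lr$p_value,
                 n_upper = unname(lr$n[names(lr$n) == "upper"]),
                 n_lower = unname(lr$n[names(lr$n) == "lower"])),
      file.path(outdir, "logrank.csv"), row.names = FALSE, quote = FALSE)
    write_manifest(file.path(outdir, "manifest.json"), inputs, config,
                   config$seed)
  }
  res
}

#' Correlation analysis of a scored cohort
#'
#' Scores the cohort against one antigen fragment and screens a gene
#' panel for Pearson correlation of expression with the per-case
#' complementarity score, producing the ranked table and per-gene
#' scatter data.
#'
#' @inheritParams run_survival_analysis
#' @param expression Expression matrix (cases x genes; rownames case
#'   ids), a `case_id`-keyed data frame, or a CSV path.
#' @param panel Gene symbols to screen; `NULL` screens all genes.
#' @return List: `scores`, `correlations` (ranked table), `scatter`
#'   (long-format per-gene scatter data).
#' @export
run_correlation_analysis <- function(cdr3_table, antigen, expression,
                                     panel = NULL, config = run_config(),
                                     outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  inputs <- list()
  if (is.character(cdr3_table) && length(cdr3_table) == 1L) {
    inputs$cdr3_table <- cdr3_table
    cdr3_table <- read_cdr3_table(cdr3_table)
  } else validate_cdr3_table(cdr3_table)
  antigen <- resolve_antigen(antigen, inputs)
  if (is.character(expression) && length(expression) == 1L) {
    inputs$expression <- expression
    expression <- read_expression_matrix(expression)
  } else expression <- as_expression_matrix(expression)
  scores <- tryCatch(
    score_cohort(cdr3_table, antigen, method = config$aggregation,
                 chain = config$chain, weights = config$weights,
                 table = config$table, normalize = config$normalize),
    error = function(e) stop("[scoring] ", conditionMessage(e),
                             call. = FALSE))
  cors <- correlation_screen(scores, expression, panel = panel,
                             log2_transform = config$log2_expression)
  sc <- scatter_data(scores, expression,
                     genes = if (is.null(panel)) NULL else cors$gene)
  res <- list(scores = scores, correlations = cors, scatter = sc)
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_score_records(scores, file.path(outdir, "score_records.csv"))
    write_correlation_table(cors, file.path(outdir, "correlations.csv"))
    utils::write.csv(sc, file.path(outdir, "scatter_data.csv"),
                     row.names = FALSE, quote = FALSE)
    write_manifest(file.path(outdir, "manifest.json"), inputs, config,
                   config$seed)
  }
  res
}

#' End-to-end synthetic pipeline
#'
#' Runs the whole analysis from a single seeded [cohort_spec()] with no
#' external input: simulate repertoires, score them against an antigen
#' fragment, split at the median score, simulate group-dependent
#' survival and score-coupled expression, then run the survival and
#' correlation analyses. Two runs from the same spec produce
#' byte-identical result tables.
#'
#' @param spec A [cohort_spec()].
#' @param antigen Antigen fragment to score against; defaults to the
#'   benchmark 60-mer of [spag9_fragment6()].
#' @param config A [run_config()].
#' @param outdir Optional output directory for all result tables.
#' @return List: `cdr3_table`, `survival` and `correlation` (the two
#'   stage results), `expression`, `survival_table`.
#' @export
run_pipeline <- function(spec, antigen = spag9_fragment6(),
                         config = run_config(), outdir = NULL) {
  stopifnot(inherits(spec, "cohort_spec"), inherits(config, "run_config"))
  antigen <- resolve_antigen(antigen, list())
  cfg_log(config, "info", "simulating ", spec$n_samples,
          "-case cohort (seed ", spec$seed, ")")
  cdr3 <- simulate_repertoires(spec)
  scores <- score_cohort(cdr3, antigen, method = config$aggregation,
                         chain = config$chain, weights = config$weights,
                         table = config$table, normalize = config$normalize)
  surv_tab <- simulate_survival(scores, spec)
  expr <- simulate_expression(scores, spec)
  surv_res <- run_survival_analysis(
    cdr3, antigen, surv_tab, config,
    outdir = if (is.null(outdir)) NULL else file.path(outdir, "survival"))
  cor_res <- run_correlation_analysis(
    cdr3, antigen, expr, panel = spec$gene_specs$gene, config,
    outdir = if (is.null(outdir)) NULL else file.path(outdir, "correlation"))
  if (!is.null(outdir)) {
    dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
    write_cdr3_table(cdr3, file.path(outdir, "cdr3_table.tsv"))
    write_survival_table(surv_tab, file.path(outdir, "survival_table.csv"))
    write_expression_matrix(expr, file.path(outdir, "expression.csv"))
  }
  list(cdr3_table = cdr3, survival = surv_res, correlation = cor_res,
       expression = expr, survival_table = surv_tab)
}

# Accept an antigen given as a fragment-table row, a raw peptide string,
# or a FASTA path (first record, scored whole). Returns a one-row
# fragment table; records the path in `inputs` by reference semantics at
# the caller (the caller passes and ignores, so just return).
resolve_antigen <- function(antigen, inputs) {
  if (is.data.frame(antigen)) {
    stopifnot(nrow(antigen) == 1L,
              all(c("antigen_name", "fragment_index", "sequence")
                  %in% names(antigen)))
    return(antigen)
  }
  if (is.character(antigen) && length(antigen) == 1L) {
    if (file.exists(antigen)) {
      fa <- read_antigen_fasta(antigen)
      return(whole_protein(fa$sequence[1], fa$name[1]))
    }
    return(whole_protein(antigen, "antigen"))
  }
  stop("antigen must be a one-row fragment table, a peptide string, or ",
       "a FASTA path", call. = FALSE)
}
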