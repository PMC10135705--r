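#' Pearson correlation with a t-based two-sided p-value
#'
#' Sample Pearson coefficient between two numeric vectors, with the
#' two-sided p-value from `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2`
#' degrees of freedom (delegated to [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, each with
#'   nonzero variance.
#' @return List with `r`, `p` and `n`.
#' @examples
#' pearson_cor(1:5, c(2, 1, 4, 3, 6))
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y))
    stop("'x' and 'y' lengths differ", call. = FALSE)
  if (length(x) < 3L)
    stop("Pearson correlation needs at least 3 paired values; got ",
         length(x), call. = FALSE)
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("non-finite values in correlation input", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance: correlation undefined", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlation screen of gene expression against complementarity scores
#'
#' For each gene in a panel, the Pearson correlation of its expression
#' values with the per-case complementarity score, over the cases shared
#' between the score records and the expression matrix. This is the
#' analysis behind ranked tables of immune-marker or apoptosis-effector
#' genes versus CDR3-antigen complementarity.
#'
#' @param scores Data frame of score records with columns `case_id`, `cs`
#'   (see [score_cohort()]).
#' @param expr Numeric matrix, cases in rows (rownames are case ids),
#'   genes in columns; values nonnegative normalized expression.
#' @param panel Character vector of gene symbols to screen; `NULL` screens
#'   every column of `expr`. Panel genes absent from `expr`, and genes
#'   with constant expression over the shared cases, are skipped with a
#'   warning and listed in the `"warnings"` attribute of the result.
#' @param log2_transform If `TRUE`, apply `log2(x + 1)` to expression
#'   before correlating; default correlates the linear values.
#' @return Data frame with columns `gene`, `r`, `p`, `p_adj`
#'   (Benjamini-Hochberg across the screened panel), `n`, sorted by
#'   ascending `p` (ties broken by descending `|r|`, then gene symbol).
#'   Rows are never filtered by significance.
#' @export
correlation_screen <- function(scores, expr, panel = NULL,
                               log2_transform = FALSE) {
  stopifnot(is.data.frame(scores),
            all(c("case_id", "cs") %in% names(scores)))
  expr <- as_expression_matrix(expr)
  if (is.null(panel)) panel <- colnames(expr)
  if (length(panel) == 0L)
    stop("empty gene panel", call. = FALSE)
  warn <- character(0)
  missing <- setdiff(panel, colnames(expr))
  if (length(missing) == length(panel))
    stop("none of the panel genes are present in the expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (length(missing)) {
    warn <- c(warn, paste0("gene '", missing,
                           "' absent from expression matrix; skipped"))
  }
  panel <- setdiff(panel, missing)
  ids <- intersect(scores$case_id, rownames(expr))
  if (length(ids) < 3L)
    stop("only ", length(ids), " case(s) shared between scores and ",
         "expression matrix; need at least 3", call. = FALSE)
  cs <- scores$cs[match(ids, scores$case_id)]
  rows <- list()
  for (g in panel) {
    v <- expr[ids, g]
    if (log2_transform) v <- log2(v + 1)
    if (stats::sd(v) == 0) {
      warn <- c(warn, paste0("gene '", g,
                             "' has constant expression over the ",
                             length(ids), " shared cases; skipped"))
      next
    }
    pc <- pearson_cor(cs, v)
    rows[[g]] <- data.frame(gene = g, r = pc$r, p = pc$p, n = pc$n,
                            stringsAsFactors = FALSE)
  }
  if (length(warn)) warning(paste(warn, collapse = "\n"), call. = FALSE)
  if (length(rows) == 0L)
    stop("no panel gene could be correlated (all constant or missing)",
         call. = FALSE)
  out <- do.call(rbind, rows)
  out$p_adj <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, -abs(out$r), out$gene), , drop = FALSE]
  rownames(out) <- NULL
  out[, c("gene", "r", "p", "p_adj", "n")]
}

# Coerce expression input (matrix or case_id-keyed data frame) to a
# numeric matrix with case-id rownames, enforcing the container's
# invariants: unique ids and symbols, finite nonnegative values.
as_expression_matrix <- function(expr) {
  if (is.data.frame(expr)) {
    if ("case_id" %in% names(expr)) {
      ids <- as.character(expr$case_id)
      expr <- as.matrix(expr[, setdiff(names(expr), "case_id"),
                             drop = FALSE])
      rownames(expr) <- ids
    } else {
      expr <- as.matrix(expr)
    }
  }
  if (!is.matrix(expr) || !is.numeric(expr))
    stop("expression input must be a numeric matrix or a data frame ",
         "with a 'case_id' column", call. = FALSE)
  if (is.null(rownames(expr)))
    stop("expression matrix must have case ids as rownames", call. = FALSE)
  if (anyDuplicated(rownames(expr)))
    stop("duplicate case ids in expression matrix", call. = FALSE)
  if (anyDuplicated(colnames(expr)))
    stop("duplicate gene symbols in expression matrix", call. = FALSE)
  if (any(!is.finite(expr)) || any(expr < 0))
    stop("expression values must be finite and nonnegative", call. = FALSE)
  expr
}

#' Per-gene scatter data for plotting expression against scores
#'
#' @inheritParams correlation_screen
#' @param genes Genes to export; default all shared panel genes.
#' @return Data frame `case_id`, `cs`, `gene`, `expression` (long format),
#'   restricted to cases shared between the two inputs.
#' @export
scatter_data <- function(scores, expr, genes = NULL) {
  expr <- as_expression_matrix(expr)
  if (is.null(genes)) genes <- colnames(expr)
  genes <- intersect(genes, colnames(expr))
  ids <- intersect(scores$case_id, rownames(expr))
  cs <- scores$cs[match(ids, scores$case_id)]
  do.call(rbind, lapply(genes, function(g) {
    data.frame(case_id = ids, cs = cs, gene = g,
               expression = unname(expr[ids, g]),
               stringsAsFactors = FALSE)
  }))
}
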