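#' Read antigen sequences from FASTA
#'
#' @param path FASTA file of protein sequences. The antigen name is the
#'   first whitespace-delimited token of each description line; sequences
#'   are upper-cased and wrapped lines joined.
#' @return Data frame `name`, `sequence`.
#' @export
read_antigen_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  set <- Biostrings::readAAStringSet(path)
  if (length(set) == 0L)
    stop("no FASTA records in ", path, call. = FALSE)
  seqs <- toupper(as.character(set))
  if (any(!nzchar(seqs)))
    stop("empty sequence record in ", path, call. = FALSE)
  nm <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  if (any(is.na(nm) | !nzchar(nm)))
    stop("record with empty description line in ", path, call. = FALSE)
  data.frame(name = nm, sequence = unname(seqs), stringsAsFactors = FALSE)
}

#' Read sequencing reads from FASTA or FASTQ
#'
#' @param path Reads file; format inferred from the extension (`.fastq` /
#'   `.fq` read as FASTQ, quality ignored; anything else as FASTA).
#' @return Data frame `read_id`, `sequence` (upper-cased nucleotides).
#' @export
read_reads <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  fmt <- if (grepl("\\.(fastq|fq)(\\.gz)?$", path, ignore.case = TRUE))
    "fastq" else "fasta"
  set <- Biostrings::readDNAStringSet(path, format = fmt)
  if (length(set) == 0L)
    stop("no records in ", path, call. = FALSE)
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1)
  data.frame(read_id = ids, sequence = toupper(as.character(unname(set))),
             stringsAsFactors = FALSE)
}

#' Write antigen fragments as FASTA
#'
#' Headers follow `>antigen|fragment_<i>|<start>-<end>` with 1-based
#' inclusive coordinates for human readability (the fragment table itself
#' keeps 0-based half-open intervals).
#'
#' @param fragments Fragment table from [fragment_protein()].
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_fragments_fasta <- function(fragments, path) {
  stopifnot(all(c("antigen_name", "fragment_index", "start", "end",
                  "sequence") %in% names(fragments)))
  hdr <- sprintf("%s|fragment_%d|%d-%d", fragments$antigen_name,
                 fragments$fragment_index, fragments$start + 1L,
                 fragments$end)
  set <- Biostrings::AAStringSet(fragments$sequence)
  names(set) <- hdr
  Biostrings::writeXStringSet(set, path, width = 60L)
  invisible(path)
}

#' Read a fragment FASTA back into the fragment-table layout
#'
#' @param path FASTA written by [write_fragments_fasta()].
#' @return Fragment table (`antigen_name`, `fragment_index`, `start`,
#'   `end`, `sequence`).
#' @export
read_fragments_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  parts <- strsplit(names(set), "|", fixed = TRUE)
  bad <- which(lengths(parts) != 3L)
  if (length(bad))
    stop("malformed fragment header at record ", bad[1], " in ", path,
         call. = FALSE)
  idx <- as.integer(sub("^fragment_", "", vapply(parts, `[`, "", 2)))
  coords <- strsplit(vapply(parts, `[`, "", 3), "-", fixed = TRUE)
  start1 <- as.integer(vapply(coords, `[`, "", 1))
  end1 <- as.integer(vapply(coords, `[`, "", 2))
  data.frame(antigen_name = vapply(parts, `[`, "", 1),
             fragment_index = idx,
             start = start1 - 1L,
             end = end1,
             sequence = as.character(unname(set)),
             stringsAsFactors = FALSE)
}

#' Read a CDR3 table
#'
#' Tab-separated with header `case_id`, `chain`, `cdr3_aa`. Chains must
#' be TRA or TRB; sequences must use the standard amino-acid alphabet and
#' be at least 5 residues (shorter candidates are not CDR3s).
#'
#' @param path TSV file.
#' @return Data frame `case_id`, `chain`, `cdr3_aa`.
#' @export
read_cdr3_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  need <- c("case_id", "chain", "cdr3_aa")
  if (!all(need %in% names(df)))
    stop("CDR3 table must have columns ", paste(need, collapse = ", "),
         "; found ", paste(names(df), collapse = ", "), call. = FALSE)
  df$case_id <- trimws(df$case_id)
  validate_cdr3_table(df[, need])
}

# Shared validation for in-memory and file-sourced CDR3 tables.
validate_cdr3_table <- function(df) {
  bad_chain <- which(!df$chain %in% c("TRA", "TRB"))
  if (length(bad_chain))
    stop("row ", bad_chain[1], ": chain must be TRA or TRB (got '",
         df$chain[bad_chain[1]], "')", call. = FALSE)
  short <- which(nchar(df$cdr3_aa) < 5L)
  if (length(short))
    stop("row ", short[1], ": CDR3 '", df$cdr3_aa[short[1]],
         "' shorter than 5 residues is rejected as non-CDR3",
         call. = FALSE)
  for (i in seq_len(nrow(df)))
    seq_charges(df$cdr3_aa[i], context = paste0("CDR3 table row ", i))
  df
}

#' @rdname read_cdr3_table
#' @param df CDR3 table to write.
#' @export
write_cdr3_table <- function(df, path) {
  utils::write.table(df[, c("case_id", "chain", "cdr3_aa")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write score-record tables
#'
#' CSV dialect `case_id,antigen_label,cs,n_cdr3`.
#'
#' @param path CSV file.
#' @return Data frame of score records.
#' @export
read_score_records <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "antigen_label", "cs", "n_cdr3")
  if (!all(need %in% names(df)))
    stop("score-record CSV must have columns ",
         paste(need, collapse = ", "), call. = FALSE)
  df$case_id <- trimws(as.character(df$case_id))
  if (any(!is.finite(df$cs)))
    stop("non-finite complementarity score in ", path, call. = FALSE)
  if (any(df$n_cdr3 < 1))
    stop("score record with n_cdr3 < 1 in ", path, call. = FALSE)
  df[, need]
}

#' @rdname read_score_records
#' @param records Score records to write.
#' @export
write_score_records <- function(records, path) {
  utils::write.csv(records[, c("case_id", "antigen_label", "cs", "n_cdr3")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write survival tables
#'
#' CSV dialect `case_id,time_months,event` with `event` 1 = observed,
#' 0 = censored.
#'
#' @param path CSV file.
#' @return Data frame `case_id`, `time_months`, `event`.
#' @export
read_survival_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("case_id", "time_months", "event")
  if (!all(need %in% names(df)))
    stop("survival CSV must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  df$case_id <- trimws(as.character(df$case_id))
  if (any(!is.finite(df$time_months)) || any(df$time_months < 0))
    stop("follow-up times must be finite and nonnegative in ", path,
         call. = FALSE)
  if (!all(df$event %in% c(0, 1)))
    stop("event indicator must be 0 or 1 in ", path, call. = FALSE)
  df[, need]
}

#' @rdname read_survival_table
#' @param df Survival table to write.
#' @export
write_survival_table <- function(df, path) {
  utils::write.csv(df[, c("case_id", "time_months", "event")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write expression matrices
#'
#' CSV dialect: first column `case_id`, remaining columns gene symbols,
#' values nonnegative normalized expression.
#'
#' @param path CSV file.
#' @return Numeric matrix, cases x genes, rownames case ids.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (names(df)[1] != "case_id")
    stop("expression CSV must have 'case_id' as its first column",
         call. = FALSE)
  df$case_id <- trimws(as.character(df$case_id))
  as_expression_matrix(df)
}

#' @rdname read_expression_matrix
#' @param expr Expression matrix to write (rownames are case ids).
#' @export
write_expression_matrix <- function(expr, path) {
  expr <- as_expression_matrix(expr)
  df <- data.frame(case_id = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write cohort stratifications
#'
#' CSV dialect `case_id,group` with group `upper`/`lower`.
#'
#' @param path CSV file.
#' @param strat A `"cs_stratification"` (the threshold is written as a
#'   comment-free extra column, `threshold`, repeated on every row, so
#'   the file round-trips).
#' @return For the reader, a `"cs_stratification"` object.
#' @export
read_stratification <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("case_id", "group", "threshold") %in% names(df)))
  structure(list(upper = df$case_id[df$group == "upper"],
                 lower = df$case_id[df$group == "lower"],
                 threshold = df$threshold[1]),
            class = "cs_stratification")
}

#' @rdname read_stratification
#' @export
write_stratification <- function(strat, path) {
  df <- stratification_table(strat)
  df$threshold <- strat$threshold
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write Kaplan-Meier curves
#'
#' CSV dialect `time,survival,at_risk,events` (one file per group).
#'
#' @param path CSV file.
#' @param curve A `"km_curve"` from [km_estimate()].
#' @return For the reader, a `"km_curve"` data frame.
#' @export
read_km_curve <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("time", "survival", "at_risk", "events") %in% names(df)))
  out <- data.frame(time = df$time, n_risk = df$at_risk,
                    n_event = df$events,
                    n_censor = if ("censored" %in% names(df)) df$censored
                    else NA_integer_,
                    survival = df$survival)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' @rdname read_km_curve
#' @export
write_km_curve <- function(curve, path) {
  stopifnot(inherits(curve, "km_curve"))
  utils::write.csv(
    data.frame(time = curve$time, survival = curve$survival,
               at_risk = curve$n_risk, events = curve$n_event,
               censored = curve$n_censor),
    path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write correlation tables
#'
#' CSV dialect `gene,r,p,p_adj,n` as produced by [correlation_screen()].
#'
#' @param path CSV file.
#' @param tab Correlation table to write.
#' @return For the reader, the correlation data frame.
#' @export
read_correlation_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("gene", "r", "p", "p_adj", "n") %in% names(df)))
  df
}

#' @rdname read_correlation_table
#' @export
write_correlation_table <- function(tab, path) {
  utils::write.csv(tab[, c("gene", "r", "p", "p_adj", "n")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' The 60-residue benchmark antigen fragment
#'
#' A charged 60-mer segment of the cancer-testis antigen SPAG9 used
#' throughout examples and as the default antigen of the synthetic
#' end-to-end pipeline.
#'
#' @return One-row fragment table (`antigen_name = "SPAG9"`,
#'   `fragment_index = 6`).
#' @export
spag9_fragment6 <- function() {
  data.frame(
    antigen_name = "SPAG9",
    fragment_index = 6L,
    start = 300L,
    end = 360L,
    sequence = paste0("KHIEVQVAQETRNVSTGSAENEEKSEVQAIIESTPELDMDKDLSGYKGSS",
                      "TPTKGIENKA"),
    stringsAsFactors = FALSE
  )
}
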