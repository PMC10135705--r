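#' Electrostatic complementarity at a fixed alignment register
#'
#' Scores one alignment register of a CDR3 peptide against an antigen
#' peptide. At CDR3 position `i`, aligned with antigen position
#' `offset + i`, opposite charges add to the score and like charges
#' subtract: each term is `-q_cdr3 * q_antigen`, weighted `w_direct` for
#' the directly opposed residue and `w_adjacent` for each of its two
#' immediate neighbours on the antigen. Antigen positions outside the
#' fragment contribute nothing.
#'
#' @param cdr3 CDR3 amino-acid sequence (string, standard alphabet,
#'   length >= 5).
#' @param fragment Antigen peptide sequence, at least as long as `cdr3`.
#' @param offset 0-based offset of the CDR3 start along the fragment;
#'   must satisfy `0 <= offset <= nchar(fragment) - nchar(cdr3)`.
#' @param weights A [score_weights()].
#' @param table A [charge_table()].
#' @return Numeric score for this register.
#' @examples
#' alignment_score("KKKKK", "EEEEE", 0)   # fully complementary: positive
#' alignment_score("GGGGG", "EEEEE", 0)   # neutral slider: 0
#' @seealso [pair_score()] for the maximum over all registers.
#' @export
alignment_score <- function(cdr3, fragment, offset,
                            weights = score_weights(),
                            table = charge_table()) {
  qc <- seq_charges(cdr3, table, context = "cdr3")
  qa <- seq_charges(fragment, table, context = "fragment")
  m <- length(qc)
  n <- length(qa)
  if (m > n)
    stop("cdr3 is longer than fragment; use pair_score(), which slides ",
         "the shorter sequence along the longer", call. = FALSE)
  if (!is.numeric(offset) || length(offset) != 1L || offset != round(offset))
    stop("'offset' must be a single integer", call. = FALSE)
  if (offset < 0 || offset > n - m)
    stop("offset ", offset, " out of range [0, ", n - m, "]", call. = FALSE)
  .register_score(qc, qa, as.integer(offset), weights)
}

# Core register score on precomputed charge vectors; qa is padded with a
# zero on each side so out-of-range neighbour positions contribute 0.
.register_score <- function(qc, qa, offset, weights) {
  m <- length(qc)
  qap <- c(0, qa, 0)
  idx <- (offset + 1L):(offset + m)     # direct positions, 1-based into qa
  direct <- sum(qc * qa[idx])
  left <- sum(qc * qap[idx])            # qa[idx - 1] with zero padding
  right <- sum(qc * qap[idx + 2L])      # qa[idx + 1] with zero padding
  -(weights$w_direct * direct + weights$w_adjacent * (left + right))
}

#' Electrostatic complementarity score of a CDR3-antigen pair
#'
#' The complementarity score (CS) of a CDR3 peptide against an antigen
#' peptide: the shorter sequence slides along the longer, and the score is
#' the maximum of [alignment_score()] over all registers - the most
#' complementary pose. If the CDR3 is longer than the fragment the roles
#' are swapped, so the result is symmetric in its two sequences.
#'
#' @inheritParams alignment_score
#' @param normalize If `TRUE`, divide by the slider (shorter sequence)
#'   length, giving a per-residue score. Off by default.
#' @return Numeric complementarity score.
#' @examples
#' pair_score("KKKKK", "GGEEEEEGG")  # best register centres on the Es
#' pair_score("GGGGG", "KRDEH")      # neutral slider: 0
#' @export
pair_score <- function(cdr3, fragment, weights = score_weights(),
                       table = charge_table(), normalize = FALSE) {
  qc <- seq_charges(cdr3, table, context = "cdr3")
  qa <- seq_charges(fragment, table, context = "fragment")
  if (length(qc) <= length(qa)) {
    qs <- qc; qt <- qa
  } else {
    qs <- qa; qt <- qc
  }
  m <- length(qs)
  n <- length(qt)
  best <- -Inf
  for (o in 0:(n - m)) {
    s <- .register_score(qs, qt, o, weights)
    if (s > best) best <- s
  }
  if (normalize) best <- best / m
  best
}

#' Matrix of pair scores for CDR3s against antigen fragments
#'
#' @param cdr3s Data frame with columns `case_id`, `chain`, `cdr3_aa`
#'   (the dialect of [read_cdr3_table()]), or a character vector of CDR3
#'   sequences.
#' @param fragments Data frame as returned by [fragment_protein()]
#'   (columns `antigen_name`, `fragment_index`, `sequence`), or a character
#'   vector of peptide sequences.
#' @inheritParams pair_score
#' @return Numeric matrix; entry `(i, j)` is `pair_score()` of CDR3 `i`
#'   against fragment `j`. Rows are labelled `case_id:chain:sequence` and
#'   columns `antigen:fragment_index` when the inputs carry metadata.
#' @export
score_matrix <- function(cdr3s, fragments, weights = score_weights(),
                         table = charge_table(), normalize = FALSE) {
  if (is.data.frame(cdr3s)) {
    stopifnot(all(c("case_id", "chain", "cdr3_aa") %in% names(cdr3s)))
    cseq <- cdr3s$cdr3_aa
    rlab <- paste(cdr3s$case_id, cdr3s$chain, cdr3s$cdr3_aa, sep = ":")
  } else {
    cseq <- as.character(cdr3s)
    rlab <- cseq
  }
  if (is.data.frame(fragments)) {
    stopifnot(all(c("antigen_name", "fragment_index", "sequence")
                  %in% names(fragments)))
    fseq <- fragments$sequence
    clab <- paste(fragments$antigen_name, fragments$fragment_index, sep = ":")
  } else {
    fseq <- as.character(fragments)
    clab <- fseq
  }
  if (length(cseq) == 0L || length(fseq) == 0L)
    stop("score_matrix() needs at least one CDR3 and one fragment",
         call. = FALSE)
  out <- matrix(NA_real_, nrow = length(cseq), ncol = length(fseq),
                dimnames = list(rlab, clab))
  for (j in seq_along(fseq)) {
    for (i in seq_along(cseq)) {
      out[i, j] <- tryCatch(
        pair_score(cseq[i], fseq[j], weights, table, normalize),
        error = function(e) {
          stop("scoring row ", i, " ('", rlab[i], "') against column ", j,
               " ('", clab[j], "'): ", conditionMessage(e), call. = FALSE)
        })
    }
  }
  out
}
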