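#' Divide an antigen protein into near-equal contiguous fragments
#'
#' Partitions a protein sequence into `k` contiguous segments whose lengths
#' differ by at most one residue, for a fragment sweep: scoring each
#' segment separately localises which part of the antigen carries the
#' charge motifs driving a complementarity association. With `L = nchar(sequence)`,
#' the first `L %% k` fragments carry `ceiling(L/k)` residues and the rest
#' `floor(L/k)`; concatenating the fragments in index order reproduces the
#' input exactly.
#'
#' @param sequence Protein sequence (standard amino-acid alphabet).
#' @param k Number of fragments, `1 <= k <= nchar(sequence)`.
#' @param antigen_name Name recorded with each fragment.
#' @return Data frame with columns `antigen_name`, `fragment_index`
#'   (1-based), `start`, `end` (0-based half-open interval into the
#'   protein), and `sequence`.
#' @examples
#' fragment_protein("ACDEFGHIKL", 3)$sequence   # lengths 4, 3, 3
#' @export
fragment_protein <- function(sequence, k, antigen_name = "antigen") {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("'sequence' must be a single string", call. = FALSE)
  seq_charges(sequence, context = antigen_name)  # alphabet validation
  L <- nchar(sequence)
  if (!is.numeric(k) || length(k) != 1L || k != round(k) || k <= 0)
    stop("'k' must be a positive integer", call. = FALSE)
  k <- as.integer(k)
  if (k > L)
    stop("'k' (", k, ") exceeds sequence length (", L, ")", call. = FALSE)
  base <- L %/% k
  extra <- L %% k
  lens <- rep(base, k)
  if (extra > 0) lens[seq_len(extra)] <- base + 1L
  ends <- cumsum(lens)
  starts <- ends - lens
  data.frame(
    antigen_name = antigen_name,
    fragment_index = seq_len(k),
    start = starts,
    end = ends,
    sequence = substring(sequence, starts + 1L, ends),
    stringsAsFactors = FALSE
  )
}

#' Whole-protein "fragment"
#'
#' Wraps a full antigen sequence in the fragment table layout with
#' `fragment_index = 0`, the convention for scoring against the intact
#' protein rather than a segment.
#'
#' @inheritParams fragment_protein
#' @return One-row data frame in the [fragment_protein()] layout.
#' @export
whole_protein <- function(sequence, antigen_name = "antigen") {
  seq_charges(sequence, context = antigen_name)
  data.frame(
    antigen_name = antigen_name,
    fragment_index = 0L,
    start = 0L,
    end = nchar(sequence),
    sequence = sequence,
    stringsAsFactors = FALSE
  )
}
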