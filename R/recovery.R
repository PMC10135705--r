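#' Motif configuration for candidate CDR3 extraction
#'
#' Per-chain settings of the convention-based CDR3 extractor: the J-region
#' anchor pattern (by immunogenetics convention the CDR3 ends at a
#' phenylalanine or tryptophan that starts an F/W-G-X-G motif) and the
#' admissible CDR3 length window in residues (conserved C through the
#' anchor F/W, inclusive).
#'
#' @param j_anchor Regular expression for the J anchor; the match must
#'   start at the CDR3's terminal residue. Default `"[FW]G.G"`.
#' @param min_len,max_len CDR3 length window, default 5 to 30.
#' @param TRA,TRB Optional per-chain lists overriding any of `j_anchor`,
#'   `min_len`, `max_len` for that chain.
#' @return List with class `"motif_config"` holding one settings list per
#'   chain.
#' @export
motif_config <- function(j_anchor = "[FW]G.G", min_len = 5L, max_len = 30L,
                         TRA = list(), TRB = list()) {
  base <- list(j_anchor = j_anchor, min_len = as.integer(min_len),
               max_len = as.integer(max_len))
  build <- function(ov) {
    s <- utils::modifyList(base, ov)
    if (!nzchar(s$j_anchor))
      stop("empty J-anchor pattern", call. = FALSE)
    if (s$min_len >= s$max_len)
      stop("CDR3 length window must satisfy min_len < max_len", call. = FALSE)
    s
  }
  structure(list(TRA = build(TRA), TRB = build(TRB)),
            class = "motif_config")
}

#' Six-frame translation of a read
#'
#' Translates a nucleotide read in all three frames of both strands.
#' Stop codons appear as `*` and codons containing `N` as `X`; spans
#' containing either sentinel are never reported as CDR3 candidates.
#'
#' @param sequence Nucleotide string over `A`, `C`, `G`, `T`, `N`;
#'   length >= 3.
#' @return Named character vector of six peptides (`fwd1`..`fwd3`,
#'   `rev1`..`rev3`); frames with fewer than 3 remaining bases give `""`.
#' @examples
#' translate_frames("ATGGGG")[["fwd1"]]  # "MG"
#' @export
translate_frames <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L)
    stop("'sequence' must be a single string", call. = FALSE)
  translate_frames_batch(sequence)[1, ]
}

# Vectorized six-frame translation: one translate() call per frame over
# the whole read set, which is far cheaper than per-read S4 dispatch.
# Returns a character matrix, reads in rows, frames in columns.
translate_frames_batch <- function(sequences) {
  bad <- grepl("[^ACGTN]", sequences)
  if (any(bad))
    stop("read ", which(bad)[1],
         " contains letters outside {A, C, G, T, N}", call. = FALSE)
  if (any(nchar(sequences) < 3L))
    stop("read shorter than one codon", call. = FALSE)
  fwd <- Biostrings::DNAStringSet(sequences)
  rev <- Biostrings::reverseComplement(fwd)
  frame_of <- function(set, frame) {
    w <- Biostrings::width(set)
    keep <- pmax((w - frame + 1L) %/% 3L, 0L)
    trimmed <- Biostrings::subseq(set, start = pmin(frame, w + 1L),
                                  width = keep * 3L)
    out <- character(length(set))
    nonempty <- keep > 0L
    if (any(nonempty))
      out[nonempty] <- as.character(Biostrings::translate(
        trimmed[nonempty], if.fuzzy.codon = "X"))
    out
  }
  out <- cbind(
    fwd1 = frame_of(fwd, 1L), fwd2 = frame_of(fwd, 2L),
    fwd3 = frame_of(fwd, 3L),
    rev1 = frame_of(rev, 1L), rev2 = frame_of(rev, 2L),
    rev3 = frame_of(rev, 3L))
  rownames(out) <- NULL
  out
}

#' Extract a candidate CDR3 from a translated peptide
#'
#' Scans the peptide for J-anchor motif matches in left-to-right order;
#' for the first anchor admitting one, returns the span from the rightmost
#' upstream cysteine through the anchor F/W (inclusive) whose length falls
#' in the configured window. The rightmost-C rule yields the shortest
#' plausible CDR3 for a given anchor, minimising inclusion of upstream
#' V-region sequence. Spans containing stop (`*`) or unknown (`X`)
#' sentinels are rejected.
#'
#' @param peptide Amino-acid string, possibly containing `*`/`X`
#'   sentinels from [translate_frames()].
#' @param chain `"TRA"` or `"TRB"` (selects the chain's motif settings).
#' @param config A [motif_config()].
#' @return The candidate CDR3 string, or `NA_character_` when the peptide
#'   carries no conforming motif (a normal outcome, not an error).
#' @examples
#' extract_cdr3("XXCASSIRSSYEQYFGPGTRL")  # "CASSIRSSYEQYF"
#' extract_cdr3("GGGGGGGG")               # NA
#' @export
extract_cdr3 <- function(peptide, chain = "TRB", config = motif_config()) {
  stopifnot(inherits(config, "motif_config"))
  chain <- match.arg(chain, c("TRA", "TRB"))
  cfg <- config[[chain]]
  if (!is.character(peptide) || length(peptide) != 1L)
    stop("'peptide' must be a single string", call. = FALSE)
  if (!nzchar(peptide)) return(NA_character_)
  chars <- strsplit(peptide, "", fixed = TRUE)[[1]]
  anchors <- gregexpr(cfg$j_anchor, peptide)[[1]]
  if (anchors[1] == -1L) return(NA_character_)
  c_pos <- which(chars == "C")
  for (a in as.integer(anchors)) {
    # candidate span runs c..a inclusive; rightmost C within the window
    cand <- c_pos[c_pos <= a &
                    (a - c_pos + 1L) >= cfg$min_len &
                    (a - c_pos + 1L) <= cfg$max_len]
    if (length(cand) == 0L) next
    span <- substring(peptide, max(cand), a)
    if (grepl("[*X]", span)) next
    return(span)
  }
  NA_character_
}

#' Recover candidate CDR3s from sequencing reads
#'
#' Simplified stand-in for exome/RNA recombination-read mining: each read
#' is translated in six frames and scanned for the conserved-C-to-J-anchor
#' motif. This is a convention-based extractor, not a V/J reference
#' aligner - chain identity comes from caller metadata, recovered spans
#' are labelled candidates, and no clonotype quantification is attempted.
#'
#' @param reads Named character vector of nucleotide reads (names are read
#'   ids), or a data frame with columns `read_id`, `sequence`.
#' @param case_id Sample identifier recorded with every candidate.
#' @param chain `"TRA"` or `"TRB"`, from caller metadata.
#' @param config A [motif_config()].
#' @return Data frame in the CDR3-table dialect (`case_id`, `chain`,
#'   `cdr3_aa`) plus `read_id` and `frame` provenance columns; one row per
#'   distinct candidate per read. Zero rows when nothing is recovered.
#' @export
recover_cdr3s <- function(reads, case_id, chain = "TRB",
                          config = motif_config()) {
  if (is.data.frame(reads)) {
    stopifnot(all(c("read_id", "sequence") %in% names(reads)))
    ids <- as.character(reads$read_id)
    seqs <- as.character(reads$sequence)
  } else {
    seqs <- as.character(reads)
    ids <- names(reads)
    if (is.null(ids)) ids <- paste0("read", seq_along(seqs))
  }
  chain <- match.arg(chain, c("TRA", "TRB"))
  peps_all <- translate_frames_batch(seqs)
  rows <- list()
  for (i in seq_along(seqs)) {
    peps <- peps_all[i, ]
    seen <- character(0)
    for (f in names(peps)) {
      cdr3 <- extract_cdr3(peps[[f]], chain, config)
      if (!is.na(cdr3) && !cdr3 %in% seen) {
        seen <- c(seen, cdr3)
        rows[[length(rows) + 1L]] <-
          data.frame(case_id = case_id, chain = chain, cdr3_aa = cdr3,
                     read_id = ids[i], frame = f, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L)
    return(data.frame(case_id = character(0), chain = character(0),
                      cdr3_aa = character(0), read_id = character(0),
                      frame = character(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}
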