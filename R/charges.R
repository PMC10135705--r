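#' Standard amino-acid alphabet
#'
#' The 20 standard one-letter amino-acid codes. Nonstandard letters
#' (B, J, O, U, X, Z and the stop character `*`) are deliberately rejected
#' throughout the package rather than silently treated as neutral, so that
#' upstream parsing problems surface immediately.
#'
#' @format Character vector of length 20.
#' @export
AA_STANDARD <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' Residue charge table
#'
#' Builds the per-residue charge assignment used by the complementarity
#' score. The default assigns +1 to lysine (K) and arginine (R), -1 to
#' aspartate (D) and glutamate (E), +0.5 to histidine (H, partially
#' protonated at physiological pH), and 0 to every other standard residue.
#'
#' @param overrides Optional named numeric vector of per-residue charges to
#'   replace the defaults, e.g. `c(H = 0)` to treat histidine as neutral.
#'   Names must be standard one-letter codes; values must lie in `[-1, 1]`.
#' @return Named numeric vector over all 20 standard residues, with class
#'   `"charge_table"`.
#' @examples
#' tab <- charge_table()
#' tab[["K"]]          # +1
#' charge_table(c(H = 0))[["H"]]
#' @export
charge_table <- function(overrides = NULL) {
  tab <- stats::setNames(numeric(length(AA_STANDARD)), AA_STANDARD)
  tab[c("K", "R")] <- 1
  tab["H"] <- 0.5
  tab[c("D", "E")] <- -1
  if (!is.null(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("charge overrides must be a named numeric vector", call. = FALSE)
    bad <- setdiff(names(overrides), AA_STANDARD)
    if (length(bad))
      stop("unknown residue(s) in charge overrides: ",
           paste(bad, collapse = ", "), call. = FALSE)
    tab[names(overrides)] <- as.numeric(overrides)
  }
  if (any(!is.finite(tab)) || any(tab < -1) || any(tab > 1))
    stop("charge values must be finite and within [-1, 1]", call. = FALSE)
  structure(tab, class = "charge_table")
}

#' Charge of a single residue
#'
#' @param aa One standard amino-acid one-letter code.
#' @param table A [charge_table()].
#' @param context Optional string naming where the residue came from, used
#'   to make alphabet errors traceable.
#' @return The residue's charge (numeric scalar).
#' @examples
#' residue_charge("K")  # +1
#' residue_charge("E")  # -1
#' @export
residue_charge <- function(aa, table = charge_table(), context = NULL) {
  if (!is.character(aa) || length(aa) != 1L || nchar(aa) != 1L)
    stop("'aa' must be a single one-letter code", call. = FALSE)
  if (!aa %in% names(table))
    stop("nonstandard residue '", aa, "'",
         if (!is.null(context)) paste0(" in ", context), call. = FALSE)
  unname(table[[aa]])
}

# Vector of charges for a peptide; errors name the offending character and
# its position so callers can trace bad input back to its source.
seq_charges <- function(sequence, table = charge_table(), context = NULL) {
  if (!is.character(sequence) || length(sequence) != 1L || !nzchar(sequence))
    stop("sequence must be a nonempty string",
         if (!is.null(context)) paste0(" (", context, ")"), call. = FALSE)
  chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!chars %in% names(table))
  if (length(bad))
    stop("nonstandard residue '", chars[bad[1]], "' at position ", bad[1],
         if (!is.null(context)) paste0(" in ", context), call. = FALSE)
  unname(table[chars])
}

#' Alignment score weights
#'
#' Weights of the charge-product terms in the complementarity score: the
#' directly opposed position and its two immediate neighbours. Direct
#' opposition of a positive and a negative charge raises the score most;
#' proximity without direct alignment contributes less, which is enforced
#' by requiring `w_adjacent <= w_direct`.
#'
#' @param w_direct Nonnegative weight of the directly aligned position
#'   (default 1).
#' @param w_adjacent Nonnegative weight of each immediate neighbour
#'   position (default 0.5).
#' @return List with class `"score_weights"`.
#' @export
score_weights <- function(w_direct = 1, w_adjacent = 0.5) {
  if (!is.numeric(w_direct) || length(w_direct) != 1L || !is.finite(w_direct) ||
      w_direct < 0)
    stop("'w_direct' must be a single nonnegative number", call. = FALSE)
  if (!is.numeric(w_adjacent) || length(w_adjacent) != 1L ||
      !is.finite(w_adjacent) || w_adjacent < 0)
    stop("'w_adjacent' must be a single nonnegative number", call. = FALSE)
  if (w_adjacent > w_direct)
    stop("'w_adjacent' must not exceed 'w_direct' (proximity without ",
         "direct alignment contributes less)", call. = FALSE)
  structure(list(w_direct = w_direct, w_adjacent = w_adjacent),
            class = "score_weights")
}
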