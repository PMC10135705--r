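# Evaluate code under a temporary RNG state, restoring the caller's state
# afterwards. Each generator consumes its own substream (master seed plus a
# fixed offset), so simulating one table never perturbs another.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

.SUBSTREAM <- c(repertoire = 101L, survival = 202L, expression = 303L,
                reads = 404L)

#' Synthetic cohort specification
#'
#' One seeded specification drives every synthetic generator, emulating
#' the statistical structure of a tumor cohort with receptor
#' recombination-read recoveries: per-case CDR3 repertoires of variable
#' size and residue composition, disease-free survival whose hazard
#' depends on the case's complementarity-score group, and expression
#' values linearly coupled to the score with noise.
#'
#' Defaults describe a 44-case cohort (the size at which a median split
#' gives 21 upper and 23 lower cases under typical score ties), sparse
#' exome-derived repertoires of 2-12 CDR3s of 8-20 residues, a 2.5-fold
#' hazard increase in the upper score group over a 0.05/month baseline,
#' uniform administrative censoring within 60 months, and a six-gene
#' expression panel whose couplings put the population correlation with
#' the score in the 0.35-0.5 band typical of small-cohort immune-marker
#' screens (positive for CIITA/SPHK2-like markers, negative for
#' CD19/apoptosis-effector-like genes).
#'
#' @param seed Master RNG seed (mandatory; all generators derive
#'   substreams from it). Must be below `2^31 - 1000`.
#' @param n_samples Number of cases, >= 4.
#' @param cdr3_per_sample Integer range `c(min, max)` of repertoire size.
#' @param cdr3_length Integer range `c(min, max)` of CDR3 length.
#' @param charge_enrichment Multiplier `rho >= 0` on the sampling weight
#'   of the charged residues K, R, D, E, H for CDR3 interiors, relative
#'   to a uniform background; 1 = no enrichment, 0 = no charged interiors.
#' @param hazard_ratio Hazard ratio (> 0) of the upper versus lower
#'   complementarity-score group.
#' @param baseline_hazard Events per month in the lower group (> 0).
#' @param censor_time_max Upper bound of the uniform censoring time,
#'   months.
#' @param expression_offset Baseline expression level added to every
#'   gene, keeping simulated values nonnegative in practice.
#' @param gene_specs Data frame `gene`, `beta` (coupling of expression to
#'   the standardized score), `sd` (Gaussian noise standard deviation).
#' @return List with class `"cohort_spec"`.
#' @export
cohort_spec <- function(seed,
                        n_samples = 44L,
                        cdr3_per_sample = c(2L, 12L),
                        cdr3_length = c(8L, 20L),
                        charge_enrichment = 1,
                        hazard_ratio = 2.5,
                        baseline_hazard = 0.05,
                        censor_time_max = 60,
                        expression_offset = 10,
                        gene_specs = default_gene_specs()) {
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L ||
      seed != round(seed) || abs(seed) >= 2^31 - 1000)
    stop("'seed' is mandatory and must be a single integer below 2^31-1000",
         call. = FALSE)
  if (!is.numeric(n_samples) || n_samples < 4L)
    stop("'n_samples' must be at least 4", call. = FALSE)
  chk_range <- function(r, nm, lo) {
    if (length(r) != 2L || any(r != round(r)) || r[1] > r[2] || r[1] < lo)
      stop("'", nm, "' must be an integer range c(min, max) with min >= ",
           lo, call. = FALSE)
    as.integer(r)
  }
  cdr3_per_sample <- chk_range(cdr3_per_sample, "cdr3_per_sample", 1L)
  cdr3_length <- chk_range(cdr3_length, "cdr3_length", 5L)
  if (!is.numeric(charge_enrichment) || charge_enrichment < 0)
    stop("'charge_enrichment' must be >= 0", call. = FALSE)
  if (!is.numeric(hazard_ratio) || hazard_ratio <= 0)
    stop("'hazard_ratio' must be > 0", call. = FALSE)
  if (!is.numeric(baseline_hazard) || baseline_hazard <= 0)
    stop("'baseline_hazard' must be > 0", call. = FALSE)
  if (!is.numeric(censor_time_max) || censor_time_max <= 0)
    stop("'censor_time_max' must be > 0", call. = FALSE)
  stopifnot(is.data.frame(gene_specs),
            all(c("gene", "beta", "sd") %in% names(gene_specs)),
            !anyDuplicated(gene_specs$gene), all(gene_specs$sd >= 0))
  structure(list(seed = as.integer(seed),
                 n_samples = as.integer(n_samples),
                 cdr3_per_sample = cdr3_per_sample,
                 cdr3_length = cdr3_length,
                 charge_enrichment = charge_enrichment,
                 hazard_ratio = hazard_ratio,
                 baseline_hazard = baseline_hazard,
                 censor_time_max = censor_time_max,
                 expression_offset = expression_offset,
                 gene_specs = gene_specs),
            class = "cohort_spec")
}

#' Default synthetic gene panel
#'
#' Six genes emulating the shape of immune-marker and apoptosis-effector
#' screens: two positively coupled to the complementarity score and four
#' negatively. With noise sd 2, a coupling `beta` gives population
#' correlation `beta / sqrt(beta^2 + 4)`, i.e. roughly 0.41-0.50 in
#' magnitude here.
#'
#' @return Data frame `gene`, `beta`, `sd`.
#' @export
default_gene_specs <- function() {
  data.frame(
    gene = c("CIITA", "SPHK2", "CD19", "AIFM3", "COX7A2L", "UQCRC2"),
    beta = c(1.15, 0.9, -1.0, -1.05, -1.15, -1.0),
    sd = 2,
    stringsAsFactors = FALSE
  )
}

# Interior residues exclude cysteine, and drawn interiors that would form
# a second J-anchor motif in read context are redrawn, so the conserved-C
# / J-anchor convention used by the extractor stays invertible: embedding
# a simulated CDR3 in a read and re-extracting it returns it exactly.
.INTERIOR_AA <- setdiff(AA_STANDARD, "C")
.CHARGED_AA <- c("K", "R", "D", "E", "H")

.interior_weights <- function(rho) {
  w <- stats::setNames(rep(1, length(.INTERIOR_AA)), .INTERIOR_AA)
  w[.CHARGED_AA] <- rho
  if (sum(w) == 0)
    stop("charge_enrichment = 0 leaves no sampling weight", call. = FALSE)
  w / sum(w)
}

# TRUE when the only J-anchor match in the CDR3 followed by a J tail is
# the terminal F itself.
.cdr3_unambiguous <- function(cdr3) {
  ctx <- paste0(cdr3, "GQG")
  m <- gregexpr("[FW]G.G", ctx)[[1]]
  length(m) == 1L && m[1] == nchar(cdr3)
}

# Uniform integer draw on a closed range, safe when lo == hi (base R's
# sample() would otherwise reinterpret a scalar as 1:n).
.runifint <- function(lo, hi) lo + sample.int(hi - lo + 1L, 1L) - 1L

#' Simulate per-case CDR3 repertoires
#'
#' Draws, for each case, a repertoire of CDR3 amino-acid sequences with
#' the conserved first cysteine and terminal phenylalanine, interior
#' residues sampled with the charged residues up- or down-weighted by
#' `charge_enrichment`, and chain labels alternating over TRA/TRB.
#' Deterministic for a fixed spec seed.
#'
#' @param spec A [cohort_spec()].
#' @return CDR3 table: `case_id`, `chain`, `cdr3_aa`.
#' @export
simulate_repertoires <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  probs <- .interior_weights(spec$charge_enrichment)
  with_seed(spec$seed + .SUBSTREAM[["repertoire"]], {
    rows <- lapply(seq_len(spec$n_samples), function(i) {
      id <- sprintf("case_%03d", i)
      n <- .runifint(spec$cdr3_per_sample[1], spec$cdr3_per_sample[2])
      seqs <- vapply(seq_len(n), function(j) {
        repeat {
          L <- .runifint(spec$cdr3_length[1], spec$cdr3_length[2])
          interior <- sample(names(probs), L - 2L, replace = TRUE,
                             prob = probs)
          cand <- paste0("C", paste(interior, collapse = ""), "F")
          if (.cdr3_unambiguous(cand)) return(cand)
        }
      }, character(1))
      data.frame(case_id = id,
                 chain = rep_len(c("TRA", "TRB"), n),
                 cdr3_aa = seqs, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
}

#' Simulate group-dependent disease-free survival
#'
#' Stratifies the score records at the median and draws exponential event
#' times with rate `baseline_hazard * hazard_ratio` for the upper group
#' and `baseline_hazard` for the lower, with independent uniform
#' censoring on `(0, censor_time_max]`; the recorded time is the earlier
#' of the two and the event indicator marks whether the event came first.
#'
#' @param scores Data frame of score records (`case_id`, `cs`).
#' @param spec A [cohort_spec()].
#' @return Survival table: `case_id`, `time_months`, `event`.
#' @export
simulate_survival <- function(scores, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  strat <- stratify_median(scores)
  ids <- scores$case_id
  upper <- ids %in% strat$upper
  rate <- ifelse(upper, spec$baseline_hazard * spec$hazard_ratio,
                 spec$baseline_hazard)
  with_seed(spec$seed + .SUBSTREAM[["survival"]], {
    et <- stats::rexp(length(ids), rate = rate)
    ct <- stats::runif(length(ids), min = 0, max = spec$censor_time_max)
    data.frame(case_id = ids,
               time_months = pmin(et, ct),
               event = as.integer(et <= ct),
               stringsAsFactors = FALSE)
  })
}

#' Simulate score-coupled gene expression
#'
#' For each gene `g` with coupling `beta_g` and noise sd `sigma_g`, case
#' `i`'s value is `max(0, offset + beta_g * z_i + eps)` where `z_i` is
#' the case's standardized complementarity score. Clipping at zero honors
#' the nonnegativity of normalized expression; the offset keeps clipping
#' negligible in practice.
#'
#' @inheritParams simulate_survival
#' @return Numeric matrix, cases x genes, rownames case ids.
#' @export
simulate_expression <- function(scores, spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  stopifnot(is.data.frame(scores), all(c("case_id", "cs") %in% names(scores)))
  z <- scores$cs - mean(scores$cs)
  s <- stats::sd(scores$cs)
  z <- if (s > 0) z / s else z * 0
  gs <- spec$gene_specs
  with_seed(spec$seed + .SUBSTREAM[["expression"]], {
    out <- sapply(seq_len(nrow(gs)), function(j) {
      pmax(0, spec$expression_offset + gs$beta[j] * z +
             stats::rnorm(length(z), 0, gs$sd[j]))
    })
    out <- matrix(out, nrow = length(z),
                  dimnames = list(scores$case_id, gs$gene))
    out
  })
}

# Inverse genetic code: codons per amino acid (standard table, no stops).
.codons_for <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
}

#' Simulate reads embedding known CDR3s
#'
#' Reverse-translates each CDR3 with uniformly sampled synonymous codons
#' and embeds it between a V-like prefix (random residues excluding C, F
#' and W, so no spurious anchor or junction cysteine precedes the CDR3)
#' and a J-like tail starting `GQG`, completing the terminal-F anchor
#' motif. Half the reads are emitted as the reverse-complement strand.
#' With no sequencing noise the extractor recovers every embedded CDR3
#' exactly.
#'
#' @param cdr3_table CDR3 table (`case_id`, `chain`, `cdr3_aa`).
#' @param spec A [cohort_spec()] (supplies the seed substream).
#' @param prefix_len Integer range of the V-like prefix length, residues.
#' @return Data frame `read_id`, `case_id`, `chain`, `cdr3_aa`,
#'   `sequence` (the nucleotide read).
#' @export
simulate_reads <- function(cdr3_table, spec, prefix_len = c(3L, 8L)) {
  stopifnot(inherits(spec, "cohort_spec"),
            all(c("case_id", "chain", "cdr3_aa") %in% names(cdr3_table)))
  codons <- .codons_for()
  prefix_aa <- setdiff(AA_STANDARD, c("C", "F", "W"))
  rt <- function(pep) {
    aas <- strsplit(pep, "", fixed = TRUE)[[1]]
    paste(vapply(aas, function(a) {
      cs <- codons[[a]]
      cs[sample.int(length(cs), 1L)]
    }, character(1)), collapse = "")
  }
  with_seed(spec$seed + .SUBSTREAM[["reads"]], {
    n <- nrow(cdr3_table)
    seqs <- character(n)
    for (i in seq_len(n)) {
      np <- .runifint(prefix_len[1], prefix_len[2])
      pep <- paste0(paste(sample(prefix_aa, np, replace = TRUE),
                          collapse = ""),
                    cdr3_table$cdr3_aa[i], "GQGTRLTV")
      nt <- rt(pep)
      if (i %% 2L == 0L)
        nt <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(nt)))
      seqs[i] <- nt
    }
    data.frame(read_id = sprintf("read_%04d", seq_len(n)),
               case_id = cdr3_table$case_id,
               chain = cdr3_table$chain,
               cdr3_aa = cdr3_table$cdr3_aa,
               sequence = seqs, stringsAsFactors = FALSE)
  })
}
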