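test_that("cohort_spec validates its fields and demands a seed", {
  expect_error(cohort_spec(), "mandatory")
  expect_error(cohort_spec(seed = 1, n_samples = 3), "at least 4")
  expect_error(cohort_spec(seed = 1, cdr3_length = c(20, 8)), "range")
  expect_error(cohort_spec(seed = 1, hazard_ratio = 0), "> 0")
  expect_error(cohort_spec(seed = 2^31), "below")
  spec <- cohort_spec(seed = 1)
  expect_s3_class(spec, "cohort_spec")
  expect_equal(spec$n_samples, 44L)
})

test_that("repertoire simulation is byte-identical under one seed", {
  spec <- cohort_spec(seed = 11, n_samples = 8)
  r1 <- simulate_repertoires(spec)
  r2 <- simulate_repertoires(spec)
  expect_identical(r1, r2)
  # a different seed moves the draw
  r3 <- simulate_repertoires(cohort_spec(seed = 12, n_samples = 8))
  expect_false(identical(r1, r3))
})

test_that("generators draw independent substreams from the master seed", {
  spec <- cohort_spec(seed = 13, n_samples = 8)
  r1 <- simulate_repertoires(spec)
  sc <- data.frame(case_id = unique(r1$case_id),
                   cs = seq_along(unique(r1$case_id)))
  invisible(simulate_survival(sc, spec))
  r2 <- simulate_repertoires(spec)   # unaffected by the survival draw
  expect_identical(r1, r2)
  s1 <- simulate_survival(sc, spec)
  invisible(simulate_expression(sc, spec))
  s2 <- simulate_survival(sc, spec)
  expect_identical(s1, s2)
})

test_that("repertoires respect structure, lengths and the charge knob", {
  spec <- cohort_spec(seed = 14, n_samples = 20)
  rep_ <- simulate_repertoires(spec)
  expect_equal(length(unique(rep_$case_id)), 20L)
  expect_true(all(grepl("^C", rep_$cdr3_aa)))
  expect_true(all(grepl("F$", rep_$cdr3_aa)))
  expect_true(all(nchar(rep_$cdr3_aa) >= 8 & nchar(rep_$cdr3_aa) <= 20))
  expect_true(all(rep_$chain %in% c("TRA", "TRB")))
  sizes <- table(rep_$case_id)
  expect_true(all(sizes >= 2 & sizes <= 12))
  # zero enrichment excludes charged interiors entirely
  rep0 <- simulate_repertoires(cohort_spec(seed = 15, n_samples = 20,
                                           charge_enrichment = 0))
  interiors <- substr(rep0$cdr3_aa, 2, nchar(rep0$cdr3_aa) - 1)
  expect_false(grepl("[KRDEH]", paste(interiors, collapse = "")))
})

test_that("unit enrichment yields the uniform charged fraction", {
  # interiors draw from the 19 non-C residues, 5 of them charged
  spec <- cohort_spec(seed = 16, n_samples = 150,
                      cdr3_per_sample = c(6, 6), cdr3_length = c(14, 14))
  rep_ <- simulate_repertoires(spec)
  interiors <- paste(substr(rep_$cdr3_aa, 2, 13), collapse = "")
  n <- nchar(interiors)
  frac <- nchar(gsub("[^KRDEH]", "", interiors)) / n
  expect_gt(n, 10000)
  p <- 5 / 19
  expect_lt(abs(frac - p), 4 * sqrt(p * (1 - p) / n))
})

test_that("mean cohort score rises with the charge enrichment", {
  frag <- spag9_fragment6()
  mean_cs <- vapply(c(0.5, 1, 2), function(rho) {
    spec <- cohort_spec(seed = 17, n_samples = 200,
                        charge_enrichment = rho)
    sc <- score_cohort(simulate_repertoires(spec), frag)
    mean(sc$cs)
  }, numeric(1))
  expect_true(all(diff(mean_cs) > 0))
})

test_that("survival hazard follows the score group", {
  spec <- cohort_spec(seed = 18, n_samples = 200, hazard_ratio = 3,
                      censor_time_max = 1e6)
  sc <- data.frame(case_id = sprintf("c%03d", 1:200),
                   cs = stats::rnorm(200))
  surv <- simulate_survival(sc, spec)
  expect_equal(nrow(surv), 200L)
  # essentially no censoring with a huge censor bound
  expect_true(mean(surv$event) > 0.99)
  st <- stratify_median(sc)
  up <- surv$case_id %in% st$upper
  expect_lt(median(surv$time_months[up]), median(surv$time_months[!up]))
})

test_that("upper-group KM median time is shorter in near-all replicates", {
  n <- 200
  wins <- vapply(1:100, function(i) {
    spec <- cohort_spec(seed = 19 + i, hazard_ratio = 3,
                        censor_time_max = 1e6)
    sc <- data.frame(case_id = sprintf("c%03d", 1:n), cs = seq_len(n))
    surv <- simulate_survival(sc, spec)
    up <- surv$case_id %in% stratify_median(sc)$upper
    median(surv$time_months[up]) < median(surv$time_months[!up])
  }, logical(1))
  expect_gte(mean(wins), 0.95)
})

test_that("expression couples to the standardized score as specified", {
  sc <- data.frame(case_id = sprintf("c%03d", 1:60),
                   cs = stats::rnorm(60, 5, 2))
  # exact construction: zero noise, beta = 0 gives a constant column
  spec <- cohort_spec(seed = 20, n_samples = 60,
                      gene_specs = data.frame(gene = c("FLAT", "UP", "DOWN"),
                                              beta = c(0, 3, -3),
                                              sd = c(0, 0.1, 0.1)))
  expr <- simulate_expression(sc, spec)
  expect_equal(dim(expr), c(60L, 3L))
  expect_equal(stats::sd(expr[, "FLAT"]), 0)
  expect_true(all(expr >= 0))
  up <- pearson_cor(sc$cs, expr[, "UP"])
  down <- pearson_cor(sc$cs, expr[, "DOWN"])
  expect_gt(up$r, 0.98)
  expect_lt(down$r, -0.98)
  # symmetric couplings give approximately opposite coefficients
  expect_equal(up$r, -down$r, tolerance = 0.02)
})

test_that("a constant simulated gene trips the screen's degenerate path", {
  sc <- data.frame(case_id = sprintf("c%03d", 1:30),
                   cs = stats::rnorm(30, 5, 2))
  spec <- cohort_spec(seed = 21, n_samples = 30,
                      gene_specs = data.frame(gene = c("FLAT", "UP"),
                                              beta = c(0, 2),
                                              sd = c(0, 0.5)))
  expr <- simulate_expression(sc, spec)
  expect_warning(out <- correlation_screen(sc, expr), "FLAT")
  expect_equal(out$gene, "UP")
})

test_that("simulated survival times respect the censoring bound", {
  spec <- cohort_spec(seed = 22, n_samples = 50, censor_time_max = 24)
  sc <- data.frame(case_id = sprintf("c%02d", 1:50),
                   cs = stats::rnorm(50))
  surv <- simulate_survival(sc, spec)
  expect_true(all(surv$time_months[surv$event == 0] <= 24))
  expect_true(all(surv$event %in% c(0L, 1L)))
})
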