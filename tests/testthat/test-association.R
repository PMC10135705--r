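test_that("perfect linear relations give coefficients of exactly +/-1", {
  x <- c(0.5, 1, 2, 3.5, 7)
  expect_equal(pearson_cor(x, 2 * x + 1)$r, 1)
  expect_equal(pearson_cor(1:4, -(1:4))$r, -1)
})

test_that("pearson matches the closed-form definitional computation", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 1, 4, 3, 6)
  got <- pearson_cor(x, y)
  ref <- closed_form_pearson(x, y)
  expect_equal(got$r, ref$r, tolerance = 1e-12)
  expect_equal(got$p, ref$p, tolerance = 1e-12)
  # frozen values of the same fixture: r = 10/sqrt(148), t = 2.5 on 3 df
  expect_equal(got$r, 10 / sqrt(148), tolerance = 1e-12)
  expect_equal(got$p, 0.087706647008065505, tolerance = 1e-12)
  expect_equal(got$n, 5L)
})

test_that("degenerate correlation inputs are refused", {
  expect_error(pearson_cor(1:2, 2:3), "at least 3")
  expect_error(pearson_cor(1:4, 1:3), "lengths differ")
  expect_error(pearson_cor(rep(1, 5), 1:5), "zero variance")
})

test_that("a gene tracking the score exactly ranks first with r = 1", {
  scores <- data.frame(case_id = letters[1:6], cs = c(3, 1, 4, 1.5, 9, 2.6))
  expr <- matrix(c(scores$cs, stats::runif(6, 1, 5)), ncol = 2,
                 dimnames = list(letters[1:6], c("TRACK", "NOISE")))
  out <- correlation_screen(scores, expr)
  expect_equal(out$gene[1], "TRACK")
  expect_equal(out$r[1], 1)
  expect_equal(out$n, rep(6L, 2))
})

test_that("the screen joins on shared cases only", {
  scores <- data.frame(case_id = c("a", "b", "c", "d", "zz"),
                       cs = c(1, 2, 3, 4, 50))
  expr <- matrix(stats::runif(8, 1, 9), ncol = 2,
                 dimnames = list(c("a", "b", "c", "d"), c("G1", "G2")))
  out <- correlation_screen(scores, expr)
  expect_equal(out$n, rep(4L, 2))
  # the unmatched high-score case must not influence the coefficients
  out2 <- correlation_screen(scores[1:4, ], expr)
  expect_equal(out$r, out2$r)
})

test_that("missing and constant panel genes are skipped with warnings", {
  scores <- data.frame(case_id = letters[1:5], cs = c(1, 2, 3, 4, 6))
  expr <- matrix(c(1:5, rep(7, 5)), ncol = 2,
                 dimnames = list(letters[1:5], c("OK", "FLAT")))
  expect_warning(out <- correlation_screen(scores, expr,
                                           panel = c("OK", "FLAT", "GONE")),
                 "GONE")
  expect_equal(out$gene, "OK")
  suppressWarnings(out <- correlation_screen(scores, expr))
  expect_false("FLAT" %in% out$gene)
  expect_error(correlation_screen(scores, expr, panel = c("NO1", "NO2")),
               "none of the panel genes")
})

test_that("a too-small case intersection is an error", {
  scores <- data.frame(case_id = c("a", "b", "x"), cs = 1:3)
  expr <- matrix(1:4, ncol = 2,
                 dimnames = list(c("a", "b"), c("G1", "G2")))
  expect_error(correlation_screen(scores, expr), "at least 3")
})

test_that("rows sort by ascending p, then descending |r|, then gene", {
  set.seed(501)
  n <- 20
  scores <- data.frame(case_id = sprintf("c%02d", 1:n),
                       cs = stats::rnorm(n))
  z <- scores$cs
  expr <- cbind(STRONG = pmax(0, 10 + 2 * z + stats::rnorm(n, 0, 0.5)),
                WEAK = pmax(0, 10 + 0.2 * z + stats::rnorm(n, 0, 2)),
                NEG = pmax(0, 10 - 2 * z + stats::rnorm(n, 0, 0.5)))
  rownames(expr) <- scores$case_id
  out <- correlation_screen(scores, expr)
  expect_true(!is.unsorted(out$p))
  expect_true(!is.unsorted(out$p_adj))       # BH step-up is monotone here
  expect_true(all(out$p_adj >= out$p))
  expect_equal(out$p_adj, stats::p.adjust(out$p, "BH"))
})

test_that("positive affine rescaling of expression leaves r unchanged", {
  set.seed(502)
  scores <- data.frame(case_id = sprintf("c%02d", 1:15),
                       cs = stats::rnorm(15))
  expr <- matrix(stats::runif(15, 1, 50), ncol = 1,
                 dimnames = list(scores$case_id, "G"))
  r1 <- correlation_screen(scores, expr)$r
  r2 <- correlation_screen(scores, expr * 3.7 + 11)$r
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("log2 transform is applied when requested", {
  scores <- data.frame(case_id = letters[1:5], cs = c(1, 2, 3, 5, 8))
  expr <- matrix(2^scores$cs - 1, ncol = 1,
                 dimnames = list(letters[1:5], "G"))
  out <- correlation_screen(scores, expr, log2_transform = TRUE)
  expect_equal(out$r, 1)
})

test_that("scatter export pairs each shared case's score and expression", {
  scores <- data.frame(case_id = c("a", "b", "c", "d"), cs = 1:4)
  expr <- matrix(c(5:8, 9:12), ncol = 2,
                 dimnames = list(c("a", "b", "c", "d"), c("G1", "G2")))
  sc <- scatter_data(scores, expr)
  expect_equal(nrow(sc), 8L)
  expect_equal(sc$expression[sc$gene == "G1"], 5:8)
  expect_equal(sc$cs[sc$gene == "G2"], 1:4)
})
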