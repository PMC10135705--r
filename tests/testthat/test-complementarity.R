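test_that("default charge table assigns the physiological charges", {
  tab <- charge_table()
  expect_setequal(names(tab), AA_STANDARD)
  expect_equal(unname(tab[c("K", "R")]), c(1, 1))
  expect_equal(unname(tab[c("D", "E")]), c(-1, -1))
  expect_equal(tab[["H"]], 0.5)
  expect_true(all(tab[setdiff(AA_STANDARD, c("K", "R", "D", "E", "H"))] == 0))
  expect_equal(residue_charge("K"), 1)
  expect_equal(residue_charge("E"), -1)
  expect_equal(residue_charge("G"), 0)
})

test_that("charge table construction rejects bad values and letters", {
  expect_error(charge_table(c(K = 2)), "within \\[-1, 1\\]")
  expect_error(charge_table(c(B = 0.5)), "unknown residue")
  expect_error(charge_table(c(0.5)), "named")
  expect_equal(charge_table(c(H = 0))[["H"]], 0)
  expect_error(residue_charge("B"), "nonstandard residue 'B'")
  expect_error(residue_charge("*"), "nonstandard")
})

test_that("score weights enforce that proximity contributes less", {
  w <- score_weights()
  expect_equal(w$w_direct, 1)
  expect_equal(w$w_adjacent, 0.5)
  expect_error(score_weights(0.5, 1), "must not exceed")
  expect_error(score_weights(-1, 0), "nonnegative")
})

test_that("alignment_score matches the hand-derived worked examples", {
  # direct terms 3 x 1, in-range neighbour terms 4 x 0.5
  expect_equal(alignment_score("KKK", "EEE", 0), 5)
  # like charges repel: exact sign flip
  expect_equal(alignment_score("KKK", "KKK", 0), -5)
  # neutral slider annihilates every term
  for (off in 0:2)
    expect_equal(alignment_score("GGG", "KRDEH", off), 0)
})

test_that("alignment_score rejects bad offsets, lengths and letters", {
  expect_error(alignment_score("KKK", "EEE", 1), "out of range")
  expect_error(alignment_score("KKK", "EEE", -1), "out of range")
  expect_error(alignment_score("KKKK", "EEE", 0), "pair_score")
  expect_error(alignment_score("KXK", "EEE", 0),
               "nonstandard residue 'X' at position 2")
  expect_error(pair_score("KKK", "KKZEE"),
               "nonstandard residue 'Z' at position 3")
})

test_that("pair_score picks the most complementary register", {
  # maximum over all 5 offsets sits on the EEE core
  expect_equal(pair_score("KKK", "GGEEEGG"), 5)
  expect_equal(pair_score("GGGGG", "KRDEHKRDEH"), 0)
  # equal lengths, single register, hand-enumerated
  expect_equal(pair_score("KE", "EK"), 1)
})

test_that("pair_score optionally normalizes by slider length", {
  expect_equal(pair_score("KKK", "GGEEEGG", normalize = TRUE), 5 / 3)
  expect_equal(pair_score("GGEEEGG", "KKK", normalize = TRUE), 5 / 3)
})

test_that("pair_score equals the brute-force oracle over {K,E,G}", {
  set.seed(101)
  for (i in 1:300) {
    a <- rand_seq(sample(1:12, 1), c("K", "E", "G"))
    b <- rand_seq(sample(1:12, 1), c("K", "E", "G"))
    expect_equal(pair_score(a, b), brute_pair_score(a, b), tolerance = 0)
  }
})

test_that("neutral sequences score zero against any partner", {
  set.seed(102)
  neutral <- c("A", "G", "S", "T", "P", "Y")
  for (i in 1:100) {
    a <- rand_seq(sample(3:12, 1), neutral)
    b <- rand_seq(sample(3:15, 1), AA_STANDARD)
    expect_equal(pair_score(a, b), 0)
  }
})

test_that("negating every antigen charge negates the fixed-register score", {
  # K<->E and R<->D swaps negate charges over this alphabet
  flip <- c(K = "E", E = "K", R = "D", D = "R", G = "G", A = "A")
  set.seed(103)
  for (i in 1:100) {
    L <- sample(3:10, 1)
    a <- rand_seq(L, names(flip))
    b <- rand_seq(L, names(flip))
    b_neg <- paste(flip[strsplit(b, "")[[1]]], collapse = "")
    expect_equal(alignment_score(a, b_neg, 0), -alignment_score(a, b, 0))
  }
})

test_that("pair_score is symmetric in its two sequences", {
  set.seed(104)
  for (i in 1:100) {
    a <- rand_seq(sample(3:12, 1), c("K", "R", "H", "D", "E", "G", "A"))
    b <- rand_seq(sample(3:12, 1), c("K", "R", "H", "D", "E", "G", "A"))
    expect_equal(pair_score(a, b), pair_score(b, a), tolerance = 0)
  }
})

test_that("appending an opposite-charge pair never lowers the register score", {
  set.seed(105)
  for (i in 1:100) {
    L <- sample(3:10, 1)
    a <- rand_seq(L, c("K", "R", "D", "E", "G", "A"))
    b <- rand_seq(L, c("K", "R", "D", "E", "G", "A"))
    base <- alignment_score(a, b, 0)
    ext <- alignment_score(paste0(a, "K"), paste0(b, "E"), 0)
    expect_gte(ext, base)
  }
})

test_that("score_matrix is the elementwise pair score with labels", {
  expect_equal(unname(score_matrix("KKKEE", "GGEEEGG")[1, 1]),
               pair_score("KKKEE", "GGEEEGG"))
  m <- score_matrix(c("GGGGG", "AAAAA", "SSSSS"), c("KRDE", "EEKK"))
  expect_equal(dim(m), c(3, 2))
  expect_true(all(m == 0))
  set.seed(106)
  cdr3s <- data.frame(
    case_id = paste0("c", 1:5), chain = "TRA",
    cdr3_aa = replicate(5, rand_seq(sample(5:9, 1),
                                    c("K", "R", "D", "E", "G"))))
  frags <- fragment_protein(rand_seq(40, c("K", "R", "D", "E", "G", "A")),
                            4, "ag")
  m <- score_matrix(cdr3s, frags)
  expect_equal(rownames(m),
               paste(cdr3s$case_id, cdr3s$chain, cdr3s$cdr3_aa, sep = ":"))
  expect_equal(colnames(m), paste("ag", 1:4, sep = ":"))
  for (i in 1:5) for (j in 1:4)
    expect_equal(m[i, j], brute_pair_score(cdr3s$cdr3_aa[i],
                                           frags$sequence[j]),
                 tolerance = 0, ignore_attr = TRUE)
})

test_that("score_matrix errors identify the offending cell", {
  expect_error(score_matrix(character(0), "EEE"), "at least one")
  expect_error(score_matrix(c("KKKKK", "KKXKK"), c("EEE")),
               "row 2")
})
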