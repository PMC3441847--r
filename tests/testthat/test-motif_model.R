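test_that("JASPAR count records normalize with the requested pseudocount", {
  f <- write_lines_tmp(c(
    ">M1 pure",
    "A [ 10 0 ]", "C [ 0 10 ]", "G [ 0 0 ]", "T [ 0 0 ]",
    ">M2 flat",
    "A [ 1 ]", "C [ 1 ]", "G [ 1 ]", "T [ 1 ]"), ".jaspar")
  pwms <- suppressWarnings(read_pwms(f, "jaspar", pseudocount = 0))
  expect_length(pwms, 2L)
  expect_equal(unname(pwms[[1]]$probs[1, ]), c(1, 0, 0, 0))
  expect_equal(unname(pwms[[1]]$probs[2, ]), c(0, 1, 0, 0))
  pwms2 <- suppressWarnings(read_pwms(f, "jaspar", pseudocount = 0.5))
  expect_equal(unname(pwms2[[2]]$probs[1, ]), rep(0.25, 4))
  # pseudocount pulls pure counts away from 0/1
  expect_equal(unname(pwms2[[1]]$probs[1, ]),
               c(10.5, 0.5, 0.5, 0.5) / 12)
})

test_that("MEME minimal records parse with per-record widths", {
  f <- write_lines_tmp(c(
    "MEME version 4", "", "ALPHABET= ACGT", "",
    "MOTIF W1", "letter-probability matrix: alength= 4 w= 4",
    " 0.25 0.25 0.25 0.25", " 0.97 0.01 0.01 0.01",
    " 0.01 0.97 0.01 0.01", " 0.25 0.25 0.25 0.25", "",
    "MOTIF W2 name2", "letter-probability matrix: alength= 4 w= 6",
    rep(" 0.4 0.3 0.2 0.1", 6), "",
    "MOTIF W3", "letter-probability matrix: alength= 4 w= 5",
    rep(" 0.1 0.2 0.3 0.4", 5)), ".meme")
  pwms <- read_pwms(f, "meme", pseudocount = 0)
  expect_length(pwms, 3L)
  expect_equal(vapply(pwms, `[[`, 0L, "length"), c(4L, 6L, 5L))
  expect_equal(unname(pwms[[2]]$probs[3, ]), c(0.4, 0.3, 0.2, 0.1))
  # probability floor applies when pseudocount > 0
  pw <- read_pwms(f, "meme", pseudocount = 0.5)
  expect_true(all(pw[[1]]$probs >= 1e-3 / 1.004))
  expect_equal(rowSums(pw[[1]]$probs), rep(1, 4))
})

test_that("malformed and degenerate motif records are rejected", {
  bad <- write_lines_tmp(c(">MX", "A [ 1 2 ]", "C [ oops ]",
                           "G [ 1 2 ]", "T [ 1 2 ]"), ".jaspar")
  expect_error(read_pwms(bad, "jaspar"), "malformed JASPAR record 'MX'")
  empty <- write_lines_tmp(c(">ME", "A [ ]", "C [ ]", "G [ ]", "T [ ]"),
                           ".jaspar")
  expect_error(read_pwms(empty, "jaspar"), "malformed|zero-length")
  uneven <- write_lines_tmp(c(">MU", "A [ 1 1 ]", "C [ 1 ]",
                              "G [ 1 1 ]", "T [ 1 1 ]"), ".jaspar")
  expect_error(read_pwms(uneven, "jaspar"), "unequal")
})

test_that("JASPAR round-trip reproduces probabilities to 1e-9", {
  pwms <- list(random_pwm(8, "R1", 11), random_pwm(5, "R2", 12),
               consensus_pwm("ACGTAC", "R3"))
  f <- tempfile(fileext = ".jaspar")
  write_pwms_jaspar(pwms, f)
  back <- suppressWarnings(read_pwms(f, "jaspar", pseudocount = 0))
  for (i in seq_along(pwms))
    expect_equal(back[[i]]$probs, pwms[[i]]$probs, tolerance = 1e-9)
})

test_that("family map groups matrices and is a partition", {
  f <- write_lines_tmp(c("matrix_id\tfamily_id",
                         "M1\tF1", "M2\tF1", "M3\tF2"))
  fam <- read_family_map(f)
  expect_equal(sort(names(fam$families)), c("F1", "F2"))
  expect_setequal(fam$families$F1, c("M1", "M2"))
  expect_equal(fam$families$F2, "M3")
  # partition: member sets are disjoint and cover the mapped matrices
  members <- unlist(fam$families)
  expect_equal(anyDuplicated(members), 0L)
  expect_setequal(members, names(fam$map))
})

test_that("family map handles empty input, conflicts and unmapped pwms", {
  empty <- write_lines_tmp("matrix_id\tfamily_id")
  fam <- read_family_map(empty)
  expect_length(fam$map, 0L)
  expect_length(fam$families, 0L)
  conflict <- write_lines_tmp(c("matrix_id\tfamily_id", "M1\tF1", "M1\tF2"))
  expect_error(read_family_map(conflict), "conflicting")
  pwms <- list(random_pwm(6, "M1", 1), random_pwm(6, "M9", 2))
  f <- write_lines_tmp(c("matrix_id\tfamily_id", "M1\tF1", "M2\tF1"))
  fam2 <- suppressWarnings(read_family_map(f, pwms = pwms))
  expect_equal(unname(fam2$map[["M9"]]), "M9")  # singleton fallback
  expect_error(read_family_map(f, pwms = pwms, unmapped = "error"),
               "absent")
  expect_warning(read_family_map(write_lines_tmp(
    c("matrix_id\tfamily_id", "M1\tF1", "MZ\tFZ")), pwms = pwms[1]),
    "no loaded PWM")
})

test_that("log-odds transform matches its closed form and brute-force max", {
  flat <- new_pwm("flat", matrix(0.25, nrow = 4, ncol = 4))
  expect_equal(unname(pwm_to_logodds(flat)), matrix(0, 4, 4))
  eps <- 1e-4
  half <- new_pwm("half", matrix(c(0.5 - eps, 0.5 - eps, eps, eps),
                                 nrow = 1))
  lo <- pwm_to_logodds(half)
  expect_equal(unname(lo[1, "A"]), 1, tolerance = 1e-3)
  expect_equal(unname(lo[1, "C"]), 1, tolerance = 1e-3)
  expect_true(all(lo[1, c("G", "T")] < 0))
  expect_error(pwm_to_logodds(flat, c(0.5, 0.5, 0, 0)), "positive")
  expect_error(pwm_to_logodds(flat, c(0.5, 0.3, 0.1, 0.2)), "sum to 1")
  # max attainable score equals exhaustive enumeration over all 4^6 words
  p <- random_pwm(6, "R", 31)
  bg <- c(0.3, 0.2, 0.2, 0.3)
  lo6 <- pwm_to_logodds(p, bg)
  expect_equal(sum(apply(lo6, 1, max)), brute_max_score(p, bg),
               tolerance = 1e-12)
})

test_that("threshold calibration hits its rate and boundary behaviour", {
  pool <- vapply(1:40, function(i) random_dna(500, 100 + i), "")
  p <- random_pwm(8, "P", 5)
  # rate high enough that all positions pass -> minimum attainable score
  th_all <- calibrate_thresholds(list(p), pool, rate = 5000)
  lo <- pwm_to_logodds(p, th_all$background)
  expect_equal(unname(th_all$cutoffs[["P"]]), sum(apply(lo, 1, min)))
  # vanishing rate -> only the best observed site(s) pass
  th_min <- calibrate_thresholds(list(p), pool, rate = 1e-9)
  scores <- c(promfam:::pool_scores_cpp(lapply(pool, promfam:::encode_seq),
                                        lo)$scores,
              promfam:::pool_scores_cpp(lapply(pool, promfam:::encode_seq),
                                        promfam:::revcomp_logodds(lo))$scores)
  expect_equal(unname(th_min$cutoffs[["P"]]), max(scores))
  # intermediate rate: empirical rate respects the target
  th <- calibrate_thresholds(list(p), pool, rate = 0.5)
  n_hits <- sum(scores >= th$cutoffs[["P"]])
  expect_lte(n_hits / (2 * length(scores) / 2 / 1000), 0.5 * 2)
  expect_error(calibrate_thresholds(list(random_pwm(8, "q", 1)), "ACGTACGT"),
               "10x matrix")
})

test_that("planted consensus words score above the calibrated cutoff", {
  p <- consensus_pwm("GGGACTTTCC", "NF")
  soft <- new_pwm("NFs", 0.94 * p$probs + 0.06 * 0.25)
  pool <- vapply(1:60, function(i) random_dna(600, 500 + i), "")
  th <- calibrate_thresholds(list(soft), pool, rate = 0.1)
  lo <- pwm_to_logodds(soft, th$background)
  word_score <- sum(lo[cbind(1:10, match(strsplit("GGGACTTTCC", "")[[1]],
                                         c("A", "C", "G", "T")))])
  expect_gt(word_score, th$cutoffs[["NFs"]])
})
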