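test_that("a hard consensus yields exactly one hit at the planted offset", {
  p <- consensus_pwm("TACA", "TACA")
  ps <- promoter_set(c(gA = "GGTACAGG"))
  hits <- suppressWarnings(
    scan_sequences(ps, list(p), fixed_thresholds(list(p), 0)))
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 2L)
  expect_equal(hits$end, 6L)
  expect_equal(hits$strand, "+")
  expect_equal(hits$score, 8)   # 4 positions x log2(1/0.25)
})

test_that("scanning the reverse complement mirrors coordinates and strands", {
  p <- consensus_pwm("TACA", "TACA")
  s <- random_dna(80, 77)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  th <- fixed_thresholds(list(p), 0)
  h1 <- suppressWarnings(scan_sequences(promoter_set(c(g = s)), list(p), th))
  h2 <- suppressWarnings(scan_sequences(promoter_set(c(g = rc)), list(p), th))
  expect_equal(nrow(h1), nrow(h2))
  if (nrow(h1)) {
    swap <- c("+" = "-", "-" = "+")
    mirrored <- data.frame(start = nchar(s) - h1$end,
                           strand = unname(swap[h1$strand]),
                           score = h1$score)
    got <- data.frame(start = h2$start, strand = h2$strand,
                      score = h2$score)
    expect_equal(got[order(got$start, got$strand), ],
                 mirrored[order(mirrored$start, mirrored$strand), ],
                 ignore_attr = TRUE)
  }
})

test_that("hit sets equal a naive position-by-position rescoring oracle", {
  bg <- c(0.3, 0.2, 0.25, 0.25)
  pwms <- lapply(1:2, function(i) random_pwm(6 + i, paste0("P", i), 60 + i))
  seqs <- setNames(vapply(1:3, function(i) random_dna(300, 70 + i), ""),
                   paste0("g", 1:3))
  # boundary-safe cutoffs: midpoints between adjacent achievable scores
  cutoffs <- vapply(pwms, function(p) {
    sc <- unlist(lapply(seqs, function(s)
      naive_scan(s, p, bg, -Inf)$score))
    sc <- sort(unique(sc), decreasing = TRUE)
    mean(sc[39:40])
  }, numeric(1))
  th <- fixed_thresholds(pwms, cutoffs, bg)
  ps <- promoter_set(seqs)
  hits <- scan_sequences(ps, pwms, th)
  for (i in seq_along(pwms)) {
    for (g in names(seqs)) {
      got <- hits[hits$matrix_id == pwms[[i]]$matrix_id &
                    hits$gene_id == g, c("start", "strand", "score")]
      want <- naive_scan(seqs[[g]], pwms[[i]], bg, cutoffs[i])
      got <- got[order(got$start, got$strand), ]
      want <- want[order(want$start, want$strand), ]
      expect_equal(got$start, want$start)
      expect_equal(got$strand, want$strand)
      expect_equal(got$score, want$score, tolerance = 1e-12)
    }
  }
})

test_that("positions overlapping N are unmatchable", {
  p <- consensus_pwm("AAAA", "A4")
  ps <- promoter_set(c(g = "AAANAAAA"))
  hits <- suppressWarnings(
    scan_sequences(ps, list(p), fixed_thresholds(list(p), 0)))
  # only the N-free suffix AAAA at start 4 can match (both strands identical
  # consensus; minus-strand hit is rc(AAAA)=TTTT, absent)
  expect_equal(hits$start, 4L)
})

test_that("overlapping same-family hits merge; different families never do", {
  h <- hits_df(gene_id = c("g", "g"), family_id = c("F", "F"),
               start = c(10, 14), end = c(20, 24), score = c(5, 7))
  m <- collapse_family_hits(h)
  expect_equal(nrow(m), 1L)
  expect_equal(m$start, 10)
  expect_equal(m$end, 24)
  expect_equal(m$score, 7)   # max score kept
  h2 <- hits_df(gene_id = c("g", "g"), family_id = c("F1", "F2"),
                start = c(10, 14), end = c(20, 24))
  expect_equal(nrow(collapse_family_hits(h2)), 2L)
  # same family, same interval, different promoters: no merge
  h3 <- hits_df(gene_id = c("g1", "g2"), family_id = "F",
                start = 10, end = 20)
  expect_equal(nrow(collapse_family_hits(h3)), 2L)
})

test_that("collapsed hit count equals interval-graph components (oracle)", {
  withr::with_seed(99, {
    for (rep in 1:20) {
      n <- sample(2:12, 1)
      start <- sample(0:80, n, replace = TRUE)
      end <- start + sample(4:12, n, replace = TRUE)
      h <- hits_df(gene_id = "g", family_id = "F", start = start, end = end)
      expect_equal(nrow(collapse_family_hits(h)),
                   interval_components(start, end))
    }
  })
})

test_that("collapse is idempotent and blind to strand by default", {
  h <- hits_df(gene_id = "g", family_id = "F", start = c(0, 5, 30),
               end = c(10, 15, 40), strand = c("+", "-", "+"),
               score = c(3, 9, 1))
  once <- collapse_family_hits(h)
  expect_equal(collapse_family_hits(once), once)
  expect_equal(nrow(once), 2L)
  expect_equal(once$strand[1], "*")   # mixed strands merged
  aware <- collapse_family_hits(h, strand_aware = TRUE)
  expect_equal(nrow(aware), 3L)
})

test_that("family counting sums collapsed hits and records set size", {
  ps <- promoter_set(setNames(vapply(1:27, function(i)
    random_dna(600, 200 + i), ""), paste0("g", 1:27)))
  h <- hits_df(gene_id = paste0("g", 1:27), family_id = "F",
               start = 5, end = 15)
  counts <- count_family_hits(h, ps)
  expect_equal(counts$n_obs[counts$family_id == "F"], 27L)
  expect_equal(attr(counts, "total_bp"), 27 * 600)
  empty <- count_family_hits(h[0, ], ps, families = c("F", "G"))
  expect_equal(empty$n_obs, c(0L, 0L))
  # counting is invariant to promoter order
  perm <- sample(27)
  ps2 <- promoter_set(ps$seqs[perm], ps$info[perm, ], ps$label)
  counts2 <- count_family_hits(h, ps2)
  expect_equal(counts2$n_obs, counts$n_obs)
})
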