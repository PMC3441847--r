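small_cfg <- function(...) {
  simulation_config(seed = 13, n_background = 120, genes_per_set = 10,
                    n_families = 6, ...)
}

test_that("degenerate composition without planting gives pure-base promoters", {
  cfg <- simulation_config(seed = 2, base_composition = c(1, 0, 0, 0),
                           n_families = 3, baseline_rate = 0)
  lib <- toy_pwm_library(cfg)
  bg <- simulate_background_pool(cfg, lib, n_promoters = 5)
  expect_equal(unique(unname(as.character(bg$promoters$seqs))),
               strrep("A", 600))
  expect_equal(nrow(bg$ledger), 0L)
})

test_that("the truth ledger accounts for every plant inside its promoter", {
  cfg <- small_cfg()
  lib <- toy_pwm_library(cfg)
  bg <- simulate_background_pool(cfg, lib, n_promoters = 60)
  led <- bg$ledger
  expect_gt(nrow(led), 0L)
  expect_true(all(led$start >= 0 & led$end <= 600))
  expect_true(all(led$family_id %in% cfg$family_ids))
  # the planted word is actually present in the sequence
  for (i in sample(nrow(led), 10)) {
    s <- as.character(bg$promoters$seqs[[led$gene_id[i]]])
    word <- substr(s, led$start[i] + 1, led$end[i])
    expect_equal(nchar(word), led$end[i] - led$start[i])
    expect_false(grepl("N", word))
  }
  # empirical plant counts match the configured Poisson rate (99% bounds)
  n_cells <- 60 * cfg$n_families
  lambda <- cfg$baseline_rate
  total <- nrow(led)
  expect_lt(abs(total - n_cells * lambda),
            2.6 * sqrt(n_cells * lambda) + 0.05 * n_cells * lambda)
})

test_that("simulation output is byte-identical under a fixed config", {
  cfg <- small_cfg()
  d1 <- file.path(tempdir(), "sim_a")
  d2 <- file.path(tempdir(), "sim_b")
  unlink(c(d1, d2), recursive = TRUE)
  write_simulation(cfg, d1)
  write_simulation(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  # and a different seed changes the sequences
  d3 <- file.path(tempdir(), "sim_c")
  unlink(d3, recursive = TRUE)
  write_simulation(simulation_config(seed = 14, n_background = 120,
                                     genes_per_set = 10, n_families = 6),
                   d3)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "background.fa"))),
    unname(tools::md5sum(file.path(d3, "background.fa")))))
})

test_that("subtype multipliers raise planting rates only where configured", {
  mult <- matrix(1, 6, 5, dimnames = NULL)
  mult[1, 3] <- 3   # family 1 elevated in subtype 3 only
  cfg <- simulation_config(seed = 21, genes_per_set = 60, n_families = 6,
                           multipliers = mult)
  lib <- toy_pwm_library(cfg)
  sub <- simulate_subtype_promoters(cfg, lib)
  expect_equal(unname(sub$rates["V$NFKB", "ERBB2"]), 3 * cfg$baseline_rate)
  counts <- vapply(cfg$subtypes, function(s)
    sum(sub$ledgers[[s]]$family_id == "V$NFKB"), numeric(1))
  lam <- 60 * cfg$baseline_rate
  # elevated cell ~ Poisson(3 lam), others ~ Poisson(lam)
  expect_gt(counts[["ERBB2"]], lam + 2.6 * sqrt(lam))
  for (s in setdiff(cfg$subtypes, "ERBB2"))
    expect_lt(counts[[s]], lam + 3.5 * sqrt(lam))
})

test_that("scanning the pool recovers at least 90% of planted motifs", {
  cfg <- simulation_config(seed = 17, n_families = 10)
  lib <- toy_pwm_library(cfg)
  cal <- simulate_background_pool(cfg, lib, n_promoters = 120,
                                  planted = FALSE, stage = "calibration")
  bg <- simulate_background_pool(cfg, lib, n_promoters = 250)
  th <- calibrate_thresholds(lib$pwms, cal$promoters, rate = 0.1)
  hits <- collapse_family_hits(
    scan_sequences(bg$promoters, lib$pwms, th, lib$map))
  led <- bg$ledger
  rec <- mapply(function(g, f, s, e) {
    any(hits$gene_id == g & hits$family_id == f & hits$start < e &
          hits$end > s)
  }, led$gene_id, led$family_id, led$start, led$end)
  expect_gte(mean(rec), 0.9)
})

test_that("framework plants land in every module promoter with in-range gaps", {
  cfg <- simulation_config(seed = 23, n_families = 6,
                           framework = list(pair = c("V$NFKB", "V$ETSF"),
                                            subtype = "ERBB2",
                                            n_genes = 6))
  lib <- toy_pwm_library(cfg)
  sub <- simulate_subtype_promoters(cfg, lib)
  led <- sub$ledgers$ERBB2
  expect_equal(length(sub$sets$ERBB2), 6L)
  for (g in sub$sets$ERBB2$info$gene_id) {
    a <- led[led$gene_id == g & led$family_id == "V$NFKB", ]
    b <- led[led$gene_id == g & led$family_id == "V$ETSF", ]
    expect_equal(nrow(a), 1L)
    expect_equal(nrow(b), 1L)
    gap <- b$start - a$end
    expect_gte(gap, 29)
    expect_lte(gap, 79)
  }
})

test_that("expression coupling moves from independence to proportionality", {
  mult <- matrix(1, 6, 5)
  diag(mult[1:5, 1:5]) <- 3
  # coupling 1, tiny noise: correlation approaches 1 for mapped pairs
  cfg1 <- small_cfg(multipliers = mult,
                    expression = list(coupling = 1, sdlog = 0.01))
  ex1 <- simulate_expression(cfg1)
  gm1 <- geometric_mean_by_subtype(ex1$expr)
  r1 <- correlate_enrichment_expression(cfg1$multipliers, gm1, ex1$mapping)
  planted <- paste0("V$", c("NFKB", "ETSF"))
  expect_gt(min(r1$r[r1$family_id %in% rownames(cfg1$multipliers)[1:5]], na.rm = TRUE),
            0.99)
  # coupling 0: class means are flat; correlations hover around zero
  cfg0 <- small_cfg(multipliers = mult,
                    expression = list(coupling = 0, sdlog = 0.5))
  ex0 <- simulate_expression(cfg0)
  expect_equal(unname(apply(ex0$class_means, 1, sd)),
               rep(0, nrow(ex0$class_means)))
})

test_that("invalid configurations are rejected up front", {
  expect_error(simulation_config(base_composition = c(1, 1, 0, 0)),
               "summing to 1")
  expect_error(simulation_config(baseline_rate = -1))
  expect_error(simulation_config(framework = list(pair = c("V$NFKB",
                                                           "V$NOPE"))))
  expect_error(simulation_config(expression = list(coupling = 2)))
})
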