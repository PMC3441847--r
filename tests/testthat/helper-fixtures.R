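# Fixture builders shared across the suite. Everything is generated in code.

# hard-consensus PWM: probability 1 on the consensus base
consensus_pwm <- function(consensus, id = paste0("M_", consensus)) {
  bases <- strsplit(consensus, "")[[1]]
  probs <- matrix(0, nrow = length(bases), ncol = 4,
                  dimnames = list(NULL, c("A", "C", "G", "T")))
  probs[cbind(seq_along(bases), match(bases, colnames(probs)))] <- 1
  new_pwm(id, probs)
}

# random informative PWM (Dirichlet-ish rows)
random_pwm <- function(L, id, seed) {
  withr::with_seed(seed, {
    raw <- matrix(rexp(L * 4)^2 + 0.05, nrow = L)
    new_pwm(id, raw / rowSums(raw))
  })
}

random_dna <- function(n, seed, prob = rep(0.25, 4)) {
  withr::with_seed(seed, paste0(
    sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
    collapse = ""))
}

# hand-built ScanThresholds (bypasses empirical calibration)
fixed_thresholds <- function(pwms, cutoff, background = rep(0.25, 4)) {
  ids <- vapply(pwms, `[[`, "", "matrix_id")
  cut <- if (length(cutoff) == 1L) rep(cutoff, length(ids)) else cutoff
  structure(list(cutoffs = stats::setNames(cut, ids), rate = NA_real_,
                 background = stats::setNames(background,
                                              c("A", "C", "G", "T")),
                 pool_bp = NA_real_, seed = 0L),
            class = "ScanThresholds")
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# tiny genome FASTA + BED6 TSS fixture
write_genome_fasta <- function(seqs) {
  f <- tempfile(fileext = ".fa")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), f)
  f
}

write_bed6 <- function(df) {
  f <- tempfile(fileext = ".bed")
  write.table(df, f, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  f
}

# manual hits table constructor
hits_df <- function(gene_id, family_id, start, end,
                    matrix_id = family_id, strand = "+", score = 10) {
  data.frame(gene_id = gene_id, matrix_id = matrix_id,
             family_id = family_id, start = start, end = end,
             strand = strand, score = score, stringsAsFactors = FALSE)
}
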