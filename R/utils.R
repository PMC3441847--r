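#' Derive a stage-specific random seed from a master seed
#'
#' Deterministically maps `(seed, stage)` to an integer below 2^31 so that
#' every pipeline stage draws from its own reproducible substream while the
#' run is controlled by a single master seed.
#'
#' @param seed integer master seed.
#' @param stage character stage name.
#' @return a positive integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  u <- utf8ToInt(stage)
  h <- sum(u * (seq_along(u) %% 97L + 1L))
  as.integer((abs(as.numeric(seed)) * 48271 + h * 7919 + 1) %% 2147483629)
}

# run code under a temporary RNG state
local_seed <- function(seed, code) withr::with_seed(as.integer(seed), code)

# write a data.frame as TSV, optionally with a "# key: value" comment header
write_tsv <- function(df, path, header = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(header)) writeLines(paste0("# ", header), con)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, comment.char = "#", stringsAsFactors = FALSE, ...)
}

# md5 of a character vector (written to a temp file; tools::md5sum is file-based)
text_md5 <- function(lines) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(lines, f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
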