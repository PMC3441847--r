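#' Construct a position weight matrix object
#'
#' @param matrix_id identifier string.
#' @param probs numeric L x 4 matrix of per-position base probabilities
#'   (columns A, C, G, T); rows must sum to 1 within 1e-6.
#' @param name optional human-readable name.
#' @return an object of class `pwm` with fields `matrix_id`, `name`, `probs`
#'   and `length`.
#' @export
new_pwm <- function(matrix_id, probs, name = matrix_id) {
  probs <- as.matrix(probs)
  if (nrow(probs) < 1L || ncol(probs) != 4L)
    stop("PWM '", matrix_id, "': probs must be an L x 4 matrix with L >= 1")
  storage.mode(probs) <- "double"
  colnames(probs) <- DNA_BASES4
  rownames(probs) <- NULL
  rs <- rowSums(probs)
  if (any(abs(rs - 1) > 1e-6))
    stop("PWM '", matrix_id, "': rows must sum to 1 (max deviation ",
         format(max(abs(rs - 1))), ")")
  if (any(probs < 0))
    stop("PWM '", matrix_id, "': negative probabilities")
  structure(list(matrix_id = matrix_id, name = name, probs = probs,
                 length = nrow(probs)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cat("<pwm>", x$matrix_id, " (", x$length, " bp)\n", sep = "")
  cat("consensus:", consensus_string(x), "\n")
  invisible(x)
}

#' Consensus string of a PWM (majority base per position)
#' @param pwm a [new_pwm()] object.
#' @return character consensus.
#' @export
consensus_string <- function(pwm) {
  paste0(DNA_BASES4[apply(pwm$probs, 1L, which.max)], collapse = "")
}

.norm_counts <- function(counts, pseudocount, id) {
  counts <- counts + pseudocount
  rs <- rowSums(counts)
  if (any(rs <= 0))
    stop("PWM '", id, "': zero total count in a row and pseudocount 0")
  counts / rs
}

.floor_probs <- function(probs, floor) {
  probs <- pmax(probs, floor)
  probs / rowSums(probs)
}

#' Read position weight matrices from an open motif format
#'
#' Supports the JASPAR dialect (`>ID name` followed by four base rows,
#' optionally bracketed) holding counts, and the MEME minimal dialect
#' (`MOTIF` blocks with a `letter-probability matrix` section) holding
#' probabilities. JASPAR counts are regularized with an additive
#' `pseudocount` per cell and row-normalized; MEME probabilities are floored
#' at 1e-3 and renormalized when `pseudocount > 0` (set `pseudocount = 0` for
#' verbatim round-trips).
#'
#' @param path motif file path.
#' @param format `"jaspar"` or `"meme"`.
#' @param pseudocount non-negative regularization constant (default 0.5).
#' @return list of [new_pwm()] objects.
#' @export
read_pwms <- function(path, format = c("jaspar", "meme"), pseudocount = 0.5) {
  format <- match.arg(format)
  stopifnot(file.exists(path), pseudocount >= 0)
  lines <- readLines(path, warn = FALSE)
  pwms <- if (format == "jaspar") .parse_jaspar(lines, pseudocount, path)
          else .parse_meme(lines, pseudocount, path)
  short <- vapply(pwms, function(p) p$length < 4L, logical(1))
  if (any(short))
    warning("matrices shorter than 4 bp: ",
            paste(vapply(pwms[short], `[[`, "", "matrix_id"), collapse = ", "))
  pwms
}

.parse_jaspar <- function(lines, pseudocount, path) {
  hdr <- grep("^>", lines)
  if (!length(hdr)) stop("no '>' records found in ", path)
  bounds <- c(hdr, length(lines) + 1L)
  lapply(seq_along(hdr), function(i) {
    first <- hdr[i]
    toks <- strsplit(sub("^>\\s*", "", lines[first]), "\\s+")[[1]]
    id <- toks[1]
    name <- if (length(toks) > 1) paste(toks[-1], collapse = " ") else id
    block <- lines[(first + 1L):(bounds[i + 1L] - 1L)]
    block <- block[nzchar(trimws(block))]
    rows <- list()
    for (j in seq_along(block)) {
      ln <- trimws(block[j])
      if (!grepl("^[ACGTacgt]([^A-Za-z].*)?$", ln))
        stop("malformed JASPAR record '", id, "' at line ", first + j,
             " of ", path, ": ", ln)
      base <- toupper(substr(ln, 1L, 1L))
      rest <- chartr("[]:", "   ", substr(ln, 2L, nchar(ln)))
      nums <- suppressWarnings(as.numeric(strsplit(trimws(rest),
                                                   "\\s+")[[1]]))
      if (!length(nums) || anyNA(nums))
        stop("malformed JASPAR record '", id, "' at line ", first + j,
             " of ", path, ": non-numeric counts")
      rows[[base]] <- nums
    }
    if (!setequal(names(rows), DNA_BASES4))
      stop("JASPAR record '", id, "' must have exactly one row per base A,C,G,T")
    lens <- lengths(rows)
    if (length(unique(lens)) != 1L)
      stop("JASPAR record '", id, "': base rows have unequal lengths")
    if (lens[[1]] == 0L) stop("JASPAR record '", id, "': zero-length matrix")
    counts <- cbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
    new_pwm(id, .norm_counts(counts, pseudocount, id), name)
  })
}

.parse_meme <- function(lines, pseudocount, path) {
  starts <- grep("^MOTIF\\b", lines)
  if (!length(starts)) stop("no 'MOTIF' records found in ", path)
  bounds <- c(starts, length(lines) + 1L)
  lapply(seq_along(starts), function(i) {
    first <- starts[i]
    toks <- strsplit(trimws(lines[first]), "\\s+")[[1]]
    if (length(toks) < 2L) stop("MOTIF line ", first, " of ", path, ": no id")
    id <- toks[2]
    name <- if (length(toks) > 2L) toks[3] else id
    block <- lines[first:(bounds[i + 1L] - 1L)]
    lp <- grep("letter-probability matrix", block)
    if (!length(lp))
      stop("MOTIF '", id, "': missing 'letter-probability matrix' line")
    w <- suppressWarnings(as.integer(
      sub(".*w=\\s*(\\d+).*", "\\1", block[lp[1]])))
    rows <- list()
    for (j in seq.int(lp[1] + 1L, length(block))) {
      ln <- trimws(block[j])
      if (!nzchar(ln)) { if (length(rows)) break else next }
      nums <- suppressWarnings(as.numeric(strsplit(ln, "\\s+")[[1]]))
      if (anyNA(nums) || length(nums) != 4L) {
        if (length(rows)) break
        stop("malformed MEME record '", id, "' at line ", first + j - 1L,
             " of ", path, ": ", ln)
      }
      rows[[length(rows) + 1L]] <- nums
    }
    if (!length(rows)) stop("MEME record '", id, "': zero-length matrix")
    if (!is.na(w) && w != length(rows))
      stop("MEME record '", id, "': declared width ", w,
           " but ", length(rows), " probability rows")
    probs <- do.call(rbind, rows)
    rs <- rowSums(probs)
    if (any(abs(rs - 1) > 1e-3))
      stop("MEME record '", id, "': probability rows do not sum to 1")
    probs <- probs / rs
    if (pseudocount > 0) probs <- .floor_probs(probs, 1e-3)
    new_pwm(id, probs, name)
  })
}

#' Write PWMs in the JASPAR dialect
#'
#' Probabilities are written at full double precision, so reading the file
#' back with `read_pwms(format = "jaspar", pseudocount = 0)` reproduces them
#' to better than 1e-9.
#'
#' @param pwms list of [new_pwm()] objects.
#' @param path output path.
#' @export
write_pwms_jaspar <- function(pwms, path) {
  out <- unlist(lapply(pwms, function(p) {
    c(paste0(">", p$matrix_id, " ", p$name),
      vapply(DNA_BASES4, function(b) {
        paste0(b, " [ ", paste(sprintf("%.17g", p$probs[, b]), collapse = " "),
               " ]")
      }, character(1)))
  }))
  writeLines(out, path)
  invisible(path)
}

#' Read a matrix-to-family membership map
#'
#' The family map groups PWMs that represent the same or functionally similar
#' transcription factors, so that shifted or redundant matches of related
#' matrices are counted as one family unit.
#'
#' @param path two-column TSV with header `matrix_id<TAB>family_id`.
#' @param pwms optional list of loaded PWMs; matrices absent from the map are
#'   then assigned per `unmapped`, and families with no loaded PWM trigger a
#'   warning.
#' @param unmapped `"singleton"` (default: unmapped matrix becomes its own
#'   family, named after the matrix) or `"error"`.
#' @return list with `map` (named character vector, matrix_id -> family_id)
#'   and `families` (named list of member matrix_id vectors).
#' @export
read_family_map <- function(path, pwms = NULL,
                            unmapped = c("singleton", "error")) {
  unmapped <- match.arg(unmapped)
  stopifnot(file.exists(path))
  df <- tryCatch(read_tsv(path), error = function(e) NULL)
  if (is.null(df) || nrow(df) == 0L) {
    df <- data.frame(matrix_id = character(), family_id = character())
  }
  if (!all(c("matrix_id", "family_id") %in% names(df)))
    stop("family map must have columns matrix_id, family_id: ", path)
  df <- unique(df[, c("matrix_id", "family_id")])
  dup <- duplicated(df$matrix_id)
  if (any(dup))
    stop("conflicting family assignment for matrix_id: ",
         paste(unique(df$matrix_id[dup]), collapse = ", "))
  map <- setNames(as.character(df$family_id), df$matrix_id)
  if (!is.null(pwms)) {
    ids <- vapply(pwms, `[[`, "", "matrix_id")
    missing <- setdiff(ids, names(map))
    if (length(missing)) {
      if (unmapped == "error")
        stop("matrices absent from family map: ",
             paste(missing, collapse = ", "))
      map <- c(map, setNames(missing, missing))
    }
    orphan <- setdiff(unique(df$family_id), unique(unname(map[ids])))
    if (length(orphan))
      warning("families with no loaded PWM: ", paste(orphan, collapse = ", "))
  }
  families <- split(names(map), unname(map))
  list(map = map, families = families)
}

#' Convert a PWM to a log-odds score matrix
#'
#' `score[i, b] = log2(probs[i, b] / background[b])`, in bits. The maximum
#' attainable score is the sum of per-position row maxima.
#'
#' @param pwm a [new_pwm()] object.
#' @param background length-4 base frequency vector (A, C, G, T), positive,
#'   summing to 1 within 1e-6.
#' @return L x 4 numeric matrix of scores in bits.
#' @export
pwm_to_logodds <- function(pwm, background = rep(0.25, 4)) {
  background <- as.numeric(background)
  if (length(background) != 4L || any(background <= 0))
    stop("background must be 4 positive frequencies")
  if (abs(sum(background) - 1) > 1e-6)
    stop("background frequencies must sum to 1")
  lo <- log2(sweep(pwm$probs, 2L, background, "/"))
  colnames(lo) <- DNA_BASES4
  lo
}

# reverse-complement a log-odds matrix: reverse positions, swap A<->T, C<->G
revcomp_logodds <- function(lo) {
  out <- lo[rev(seq_len(nrow(lo))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(out) <- DNA_BASES4
  out
}

# coerce PromoterSet / DNAStringSet / character to a list of integer codes
.as_code_list <- function(x) {
  if (inherits(x, "PromoterSet")) x <- x$seqs
  if (methods::is(x, "DNAStringSet")) x <- as.character(x)
  stopifnot(is.character(x))
  lapply(unname(x), encode_seq)
}

.seq_lengths <- function(x) {
  if (inherits(x, "PromoterSet")) return(Biostrings::width(x$seqs))
  if (methods::is(x, "DNAStringSet")) return(Biostrings::width(x))
  nchar(x)
}

# base composition (A,C,G,T) of a sequence collection, ignoring N
.base_composition <- function(x) {
  codes <- unlist(.as_code_list(x))
  tab <- tabulate(codes[codes >= 1L & codes <= 4L], 4L)
  if (sum(tab) == 0) stop("no A/C/G/T bases in pool")
  setNames(tab / sum(tab), DNA_BASES4)
}

#' Calibrate per-matrix score cutoffs on a background pool
#'
#' For each PWM the cutoff is the smallest log-odds value whose empirical hit
#' rate on the pool (both strands pooled) does not exceed `rate` hits per kb
#' per strand. This replaces library-specific proprietary thresholds with a
#' background-calibrated, reproducible rule. Calibration should be run on
#' sequence that is not enriched for the motifs under study.
#'
#' @param pwms list of [new_pwm()] objects.
#' @param background_pool a `PromoterSet`, `DNAStringSet` or character vector
#'   of sequences.
#' @param rate target hits per kb per strand (default 0.1).
#' @param background optional base frequency 4-vector for the log-odds
#'   transform; defaults to the pool's composition.
#' @param seed integer recorded in the result (calibration itself is a
#'   deterministic function of the pool).
#' @return `ScanThresholds` object: named `cutoffs` (bits), `rate`,
#'   `background`, `pool_bp`, `seed`.
#' @export
calibrate_thresholds <- function(pwms, background_pool, rate = 0.1,
                                 background = NULL, seed = 1L) {
  stopifnot(rate > 0, length(pwms) >= 1L)
  codes <- .as_code_list(background_pool)
  pool_bp <- sum(lengths(codes))
  if (is.null(background)) background <- .base_composition(background_pool)
  cutoffs <- vapply(pwms, function(p) {
    if (pool_bp < 10L * p$length)
      stop("background pool (", pool_bp, " bp) shorter than 10x matrix ",
           "length for '", p$matrix_id, "'")
    lo <- pwm_to_logodds(p, background)
    fw <- pool_scores_cpp(codes, lo)
    rv <- pool_scores_cpp(codes, revcomp_logodds(lo))
    scores <- c(fw$scores, rv$scores)
    n_valid <- fw$n_valid + rv$n_valid   # positions per strand, both strands
    allowed <- floor(rate * n_valid / 1000)
    min_attain <- sum(apply(lo, 1L, min))
    if (!length(scores)) return(min_attain)
    if (allowed >= length(scores)) return(min_attain)
    if (allowed < 1) return(max(scores))
    s <- sort(scores, decreasing = TRUE)
    # smallest observed value keeping #{score >= cutoff} <= allowed
    v <- s[allowed]
    if (sum(s >= v) > allowed) {
      higher <- unique(s[s > v])
      v <- NA_real_
      for (h in sort(higher)) {
        if (sum(s >= h) <= allowed) { v <- h; break }
      }
      if (is.na(v)) v <- s[1]
    }
    v
  }, numeric(1))
  names(cutoffs) <- vapply(pwms, `[[`, "", "matrix_id")
  structure(list(cutoffs = cutoffs, rate = rate,
                 background = setNames(as.numeric(background), DNA_BASES4),
                 pool_bp = pool_bp, seed = as.integer(seed)),
            class = "ScanThresholds")
}

#' @export
print.ScanThresholds <- function(x, ...) {
  cat("<ScanThresholds> ", length(x$cutoffs), " matrices, target rate ",
      x$rate, " hits/kb/strand, calibrated on ", x$pool_bp, " bp\n", sep = "")
  invisible(x)
}
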