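#' Scan promoter sequences with PWMs on both strands
#'
#' Every position/strand whose log-odds score reaches the matrix cutoff
#' yields one hit. Coordinates are promoter-relative, 0-based half-open, in
#' the forward (5'->3') frame of the promoter; minus-strand hits are matches
#' of the reverse complement motif at that interval. Positions overlapping N
#' are unmatchable. Matrices longer than a promoter are skipped for that
#' promoter with a warning.
#'
#' @param promoters a [promoter_set()].
#' @param pwms list of [new_pwm()] objects.
#' @param thresholds a [calibrate_thresholds()] result covering all PWMs.
#' @param family_map optional named vector matrix_id -> family_id (see
#'   [read_family_map()]); defaults to singleton families named after each
#'   matrix.
#' @return HitTable: data.frame with columns gene_id, matrix_id, family_id,
#'   start, end, strand, score.
#' @export
scan_sequences <- function(promoters, pwms, thresholds, family_map = NULL) {
  stopifnot(inherits(promoters, "PromoterSet"),
            inherits(thresholds, "ScanThresholds"))
  ids <- vapply(pwms, `[[`, "", "matrix_id")
  missing_cut <- setdiff(ids, names(thresholds$cutoffs))
  if (length(missing_cut))
    stop("no calibrated cutoff for: ", paste(missing_cut, collapse = ", "))
  if (is.null(family_map)) family_map <- setNames(ids, ids)
  if (!is.list(family_map) && is.null(names(family_map)))
    stop("family_map must be a named matrix_id -> family_id vector")
  if (is.list(family_map)) family_map <- family_map$map
  codes <- .as_code_list(promoters)
  genes <- promoters$info$gene_id
  widths <- lengths(codes)
  bg <- thresholds$background
  res <- vector("list", 2L * length(pwms))
  k <- 0L
  warned_short <- FALSE
  for (p in pwms) {
    if (!warned_short && any(widths < p$length)) {
      warning("some promoters are shorter than matrix '", p$matrix_id,
              "'; those matrices are skipped for those promoters")
      warned_short <- TRUE
    }
    lo <- pwm_to_logodds(p, bg)
    cutoff <- thresholds$cutoffs[[p$matrix_id]]
    fam <- family_map[[p$matrix_id]] %||% p$matrix_id
    for (str in c("+", "-")) {
      m <- if (str == "+") lo else revcomp_logodds(lo)
      h <- scan_set_cpp(codes, m, cutoff)
      k <- k + 1L
      if (length(h$seq)) {
        res[[k]] <- data.frame(
          gene_id = genes[h$seq], matrix_id = p$matrix_id,
          family_id = fam, start = h$start, end = h$start + p$length,
          strand = str, score = h$score, stringsAsFactors = FALSE)
      }
    }
  }
  res <- res[!vapply(res, is.null, logical(1))]
  out <- if (length(res)) do.call(rbind, res) else .empty_hits()
  out <- out[order(match(out$gene_id, genes), out$start, out$matrix_id,
                   out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.empty_hits <- function() {
  data.frame(gene_id = character(), matrix_id = character(),
             family_id = character(), start = integer(), end = integer(),
             strand = character(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Merge overlapping same-family hits within a promoter
#'
#' Within one promoter, hits of the same family whose intervals overlap by at
#' least 1 bp (on any strand) are merged into a single family hit spanning
#' their union; the maximum score and its carrying matrix/strand are kept.
#' Hits of different families never merge. This absorbs the redundant,
#' slightly shifted matches that functionally similar matrices produce for
#' one binding site. Idempotent.
#'
#' @param hits HitTable from [scan_sequences()].
#' @param strand_aware merge only hits on the same strand (default FALSE).
#' @return collapsed HitTable.
#' @export
collapse_family_hits <- function(hits, strand_aware = FALSE) {
  if (!nrow(hits)) return(hits)
  stopifnot(all(c("gene_id", "family_id", "start", "end") %in% names(hits)))
  key <- paste(hits$gene_id, hits$family_id,
               if (strand_aware) hits$strand else "", sep = "\r")
  gr <- GenomicRanges::GRanges(
    seqnames = factor(key, levels = unique(key)),
    ranges = IRanges::IRanges(start = hits$start + 1L, end = hits$end))
  red <- GenomicRanges::reduce(gr, with.revmap = TRUE, min.gapwidth = 0L)
  revmap <- as.list(red$revmap)
  best <- vapply(revmap, function(ii) ii[which.max(hits$score[ii])],
                 integer(1))
  out <- data.frame(
    gene_id = hits$gene_id[best],
    matrix_id = hits$matrix_id[best],
    family_id = hits$family_id[best],
    start = GenomicRanges::start(red) - 1L,
    end = GenomicRanges::end(red),
    strand = hits$strand[best],
    score = hits$score[best],
    stringsAsFactors = FALSE)
  mixed <- vapply(revmap, function(ii) length(unique(hits$strand[ii])) > 1L,
                  logical(1))
  if (!strand_aware) out$strand[mixed] <- "*"
  out <- out[order(match(out$gene_id, unique(hits$gene_id)), out$start), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count collapsed family hits over a promoter set
#'
#' `n_obs(X)` is the number of collapsed family-X hits summed over all
#' promoters of the set; the set's total base-pair size is recorded for
#' equal-size background matching.
#'
#' @param hits collapsed HitTable (see [collapse_family_hits()]).
#' @param promoters the scanned [promoter_set()].
#' @param families optional character vector fixing the family universe
#'   (families without hits get n_obs = 0).
#' @return FamilyCounts: data.frame (family_id, n_obs) with attributes
#'   `total_bp` and `n_promoters`.
#' @export
count_family_hits <- function(hits, promoters, families = NULL) {
  stopifnot(inherits(promoters, "PromoterSet"))
  if (is.null(families)) families <- sort(unique(hits$family_id))
  n <- table(factor(hits$family_id, levels = families))
  out <- data.frame(family_id = families, n_obs = as.integer(n),
                    stringsAsFactors = FALSE)
  attr(out, "total_bp") <- sum(Biostrings::width(promoters$seqs))
  attr(out, "n_promoters") <- length(promoters$seqs)
  attr(out, "label") <- promoters$label
  out
}

# promoter x family matrix of collapsed hit counts (all promoters included)
family_count_matrix <- function(hits, promoters, families = NULL) {
  if (is.null(families)) families <- sort(unique(hits$family_id))
  genes <- promoters$info$gene_id
  m <- table(factor(hits$gene_id, levels = genes),
             factor(hits$family_id, levels = families))
  m <- matrix(as.integer(m), nrow = length(genes),
              dimnames = list(genes, families))
  m
}

#' Write a HitTable as TSV
#' @param hits HitTable.
#' @param path output path.
#' @param header optional comment header line.
#' @export
write_hits_tsv <- function(hits, path, header = NULL) {
  write_tsv(hits, path, header)
}
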