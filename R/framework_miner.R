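#' Mine common ordered-motif promoter frameworks
#'
#' A promoter framework (module) is an ordered pair of TFBS family elements
#' that occurs in (nearly) all promoters of a set with a consistent spacing:
#' both order and distance matter. For every ordered family pair (A, B) the
#' miner enumerates, per promoter, occurrences where a B hit starts within
#' `(0, max_gap]` bp after an A hit ends (distance measured end-of-first to
#' start-of-next; strands are recorded but not constrained). It then
#' searches for the gap window of span at most `max_span` that covers the
#' largest fraction of promoters (ties: smaller span, then smaller lower
#' bound), so isolated off-distance co-occurrences cannot veto a consistent
#' module. A framework is emitted when that coverage reaches
#' `min_coverage`; its distance window `[d_min, d_max]` is the observed gap
#' range over the retained witnesses.
#'
#' @param hits collapsed family-level HitTable (see
#'   [collapse_family_hits()]).
#' @param promoters optional [promoter_set()] defining the promoter universe
#'   (coverage denominator); defaults to the promoters present in `hits`.
#' @param min_coverage minimum fraction of promoters containing the chain
#'   (default 1.0).
#' @param max_span maximum allowed span of the gap window in bp (default 60).
#' @param max_gap maximum element-to-element distance considered (default
#'   200).
#' @param chain_length 2 (default) or 3; length-3 chains are composed
#'   greedily from validated pairs sharing their middle element.
#' @return list of `framework` objects (fields `chain`, `d_min`, `d_max`,
#'   `coverage`, `witnesses`), sorted by decreasing coverage, then
#'   increasing span, then lexicographic chain. Empty list if no framework
#'   qualifies.
#' @export
mine_frameworks <- function(hits, promoters = NULL, min_coverage = 1.0,
                            max_span = 60L, max_gap = 200L,
                            chain_length = 2L) {
  stopifnot(min_coverage > 0, min_coverage <= 1, max_span >= 0, max_gap > 0,
            chain_length %in% c(2L, 3L))
  genes <- if (!is.null(promoters)) promoters$info$gene_id
           else unique(hits$gene_id)
  n_prom <- length(genes)
  if (!nrow(hits) || n_prom < 2L) return(list())
  occ <- .pair_occurrences(hits, genes, max_gap)
  if (!nrow(occ)) return(list())
  pairs <- unique(occ[, c("famA", "famB")])
  out <- list()
  for (i in seq_len(nrow(pairs))) {
    po <- occ[occ$famA == pairs$famA[i] & occ$famB == pairs$famB[i], ,
              drop = FALSE]
    fw <- .best_gap_window(po, n_prom, max_span)
    if (!is.null(fw) && fw$coverage >= min_coverage) {
      out[[length(out) + 1L]] <- structure(
        list(chain = c(pairs$famA[i], pairs$famB[i]),
             d_min = fw$d_min, d_max = fw$d_max, coverage = fw$coverage,
             witnesses = fw$witnesses),
        class = "framework")
    }
  }
  out <- .sort_frameworks(out)
  if (chain_length == 3L) out <- .extend_chains(out, n_prom, min_coverage)
  out
}

# all ordered same-promoter co-occurrences with gap in (0, max_gap]
.pair_occurrences <- function(hits, genes, max_gap) {
  res <- lapply(split(hits, hits$gene_id), function(h) {
    n <- nrow(h)
    if (n < 2L) return(NULL)
    idx <- expand.grid(a = seq_len(n), b = seq_len(n))
    idx <- idx[idx$a != idx$b, , drop = FALSE]
    gap <- h$start[idx$b] - h$end[idx$a]
    keep <- gap > 0 & gap <= max_gap
    if (!any(keep)) return(NULL)
    idx <- idx[keep, , drop = FALSE]
    data.frame(gene_id = h$gene_id[idx$a],
               famA = h$family_id[idx$a], famB = h$family_id[idx$b],
               startA = h$start[idx$a], endA = h$end[idx$a],
               strandA = h$strand[idx$a],
               startB = h$start[idx$b], endB = h$end[idx$b],
               strandB = h$strand[idx$b],
               gap = gap[keep], stringsAsFactors = FALSE)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res))
    return(data.frame(gene_id = character(), famA = character(),
                      famB = character(), gap = integer()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# maximal-coverage gap window of span <= max_span for one ordered pair;
# both window ends are enumerated over realized gaps so an isolated extra
# co-occurrence never inflates the span of an equally covering tighter window
.best_gap_window <- function(po, n_prom, max_span) {
  po <- po[order(po$gap, po$gene_id), , drop = FALSE]
  gaps <- sort(unique(po$gap))
  best <- NULL
  for (i in seq_along(gaps)) {
    for (j in seq(i, length(gaps))) {
      if (gaps[j] - gaps[i] > max_span) break
      inwin <- po$gap >= gaps[i] & po$gap <= gaps[j]
      cov <- length(unique(po$gene_id[inwin])) / n_prom
      span <- gaps[j] - gaps[i]
      if (is.null(best) || cov > best$coverage ||
          (cov == best$coverage && span < best$span)) {
        best <- list(coverage = cov, d_min = gaps[i], d_max = gaps[j],
                     span = span, witnesses = po[inwin, , drop = FALSE])
      }
    }
  }
  if (!is.null(best)) rownames(best$witnesses) <- NULL
  best
}

.sort_frameworks <- function(fws) {
  if (!length(fws)) return(fws)
  cov <- vapply(fws, `[[`, numeric(1), "coverage")
  span <- vapply(fws, function(f) f$d_max - f$d_min, numeric(1))
  key <- vapply(fws, function(f) paste(f$chain, collapse = "\r"),
                character(1))
  fws[order(-cov, span, key)]
}

# greedy composition of validated pairs (A,B) + (B,C) into length-3 chains;
# a witness chain must reuse the identical middle hit within one promoter
.extend_chains <- function(pairs2, n_prom, min_coverage) {
  out <- pairs2
  for (f1 in pairs2) {
    for (f2 in pairs2) {
      if (f1$chain[2] != f2$chain[1]) next
      w1 <- f1$witnesses
      w2 <- f2$witnesses
      m <- merge(w1, w2,
                 by.x = c("gene_id", "startB", "endB"),
                 by.y = c("gene_id", "startA", "endA"),
                 suffixes = c(".ab", ".bc"))
      if (!nrow(m)) next
      cov <- length(unique(m$gene_id)) / n_prom
      if (cov < min_coverage) next
      out[[length(out) + 1L]] <- structure(
        list(chain = c(f1$chain, f2$chain[2]),
             d_min = c(min(m$gap.ab), min(m$gap.bc)),
             d_max = c(max(m$gap.ab), max(m$gap.bc)),
             coverage = cov, witnesses = m),
        class = "framework")
    }
  }
  out
}

#' @export
print.framework <- function(x, ...) {
  win <- paste(sprintf("[%d, %d]", x$d_min, x$d_max), collapse = ", ")
  cat("<framework> ", paste(x$chain, collapse = " -> "), "  gap ", win,
      " bp, coverage ", sprintf("%.2f", x$coverage), "\n", sep = "")
  invisible(x)
}

#' Summarize mined frameworks as a flat table
#' @param frameworks list from [mine_frameworks()].
#' @return data.frame (chain, d_min, d_max, coverage, n_witnesses).
#' @export
frameworks_table <- function(frameworks) {
  if (!length(frameworks))
    return(data.frame(chain = character(), d_min = character(),
                      d_max = character(), coverage = numeric(),
                      n_witnesses = integer(), stringsAsFactors = FALSE))
  data.frame(
    chain = vapply(frameworks, function(f)
      paste(f$chain, collapse = "->"), character(1)),
    d_min = vapply(frameworks, function(f)
      paste(f$d_min, collapse = ","), character(1)),
    d_max = vapply(frameworks, function(f)
      paste(f$d_max, collapse = ","), character(1)),
    coverage = vapply(frameworks, `[[`, numeric(1), "coverage"),
    n_witnesses = vapply(frameworks, function(f) nrow(f$witnesses),
                         integer(1)),
    stringsAsFactors = FALSE)
}

#' Write frameworks as JSON
#' @param frameworks list from [mine_frameworks()].
#' @param path output path.
#' @export
write_frameworks_json <- function(frameworks, path) {
  payload <- lapply(frameworks, function(f)
    list(chain = f$chain, d_min = f$d_min, d_max = f$d_max,
         coverage = f$coverage, witnesses = f$witnesses))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
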