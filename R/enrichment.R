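#' Estimate the background hit expectation and dispersion per family
#'
#' Draws `B` seeded resamples from the background promoter pool, each taken
#' without replacement until the cumulative sequence length reaches
#' `target_bp` (an "equally sized sample" of background promoters), and
#' counts collapsed family hits in each. `n_exp` is the mean and `S` the
#' population (divisor-B) standard deviation of those counts. Families with
#' no hits anywhere in the pool get `n_exp = 0`, `S = 0` and are flagged.
#'
#' @param background_promoters background pool [promoter_set()].
#' @param hits collapsed HitTable of the pool (see [collapse_family_hits()]).
#' @param target_bp base-pair size of the promoter set under study.
#' @param B number of resamples (default 1000).
#' @param seed integer seed; results are bit-reproducible given the seed.
#' @param families optional family universe.
#' @return `BackgroundModel`: data.frame (family_id, n_exp, S, flagged) with
#'   attributes `target_bp`, `B`, `seed`.
#' @export
estimate_background <- function(background_promoters, hits, target_bp,
                                B = 1000L, seed = 1L, families = NULL) {
  stopifnot(inherits(background_promoters, "PromoterSet"),
            target_bp > 0, B >= 100L)
  widths <- Biostrings::width(background_promoters$seqs)
  pool_bp <- sum(widths)
  if (pool_bp < 5 * target_bp)
    stop("background pool too small: ", pool_bp, " bp < 5 x target_bp (",
         target_bp, " bp)")
  cm <- family_count_matrix(hits, background_promoters, families)
  n <- nrow(cm)
  counts <- matrix(0L, nrow = B, ncol = ncol(cm),
                   dimnames = list(NULL, colnames(cm)))
  local_seed(seed, {
    for (b in seq_len(B)) {
      perm <- sample.int(n)
      k <- which(cumsum(widths[perm]) >= target_bp)[1L]
      counts[b, ] <- colSums(cm[perm[seq_len(k)], , drop = FALSE])
    }
  })
  n_exp <- colMeans(counts)
  S <- sqrt(colMeans(sweep(counts, 2L, n_exp)^2))   # population form
  flagged <- colSums(cm) == 0L
  if (any(flagged))
    message("families absent from background pool: ",
            paste(colnames(cm)[flagged], collapse = ", "))
  out <- data.frame(family_id = colnames(cm), n_exp = unname(n_exp),
                    S = unname(S), flagged = unname(flagged),
                    stringsAsFactors = FALSE)
  attr(out, "target_bp") <- as.numeric(target_bp)
  attr(out, "B") <- as.integer(B)
  attr(out, "seed") <- as.integer(seed)
  class(out) <- c("BackgroundModel", "data.frame")
  out
}

#' Fold factor of TFBS family overrepresentation
#'
#' `r(X) = n_obs(X) / n_exp(X)`: the observed family hit count in the
#' promoter set relative to its expectation in an equally sized background
#' sample.
#'
#' @param n_obs observed hit count(s).
#' @param n_exp expected count(s); must be positive.
#' @return numeric fold factor(s).
#' @export
fold_factor <- function(n_obs, n_exp) {
  stopifnot(is.numeric(n_obs), is.numeric(n_exp))
  if (any(n_exp <= 0))
    stop("undefined fold factor: n_exp must be positive")
  n_obs / n_exp
}

#' Continuity-corrected z-score of TFBS family overrepresentation
#'
#' `z(X) = (n_obs(X) - n_exp(X) - 0.5) / S(X)`, where S is the population
#' standard deviation of background hit counts. The -0.5 continuity
#' correction is applied exactly as defined, including when
#' `n_obs < n_exp`.
#'
#' @param n_obs observed hit count(s).
#' @param n_exp expected count(s).
#' @param S population standard deviation(s); must be positive.
#' @return numeric z-score(s).
#' @export
z_score <- function(n_obs, n_exp, S) {
  stopifnot(is.numeric(n_obs), is.numeric(n_exp), is.numeric(S))
  if (any(S <= 0))
    stop("undefined z-score: S must be positive")
  (n_obs - n_exp - 0.5) / S
}

#' Per-family enrichment of a promoter set against a background model
#'
#' Combines observed family counts with the background model into fold
#' factors and z-scores. A family is called overrepresented when its z-score
#' reaches `z_cutoff` (default 2.0) and `n_obs > n_exp`;
#' under-representation is never reported as a finding, though the
#' statistics are retained. Families with undefined statistics (`n_exp = 0`
#' or `S = 0`) are excluded and reported.
#'
#' @param counts FamilyCounts from [count_family_hits()].
#' @param background `BackgroundModel` with matching `target_bp`.
#' @param z_cutoff z-score call threshold (default 2.0).
#' @return FamilyEnrichment: data.frame (family_id, n_obs, n_exp, S, fold,
#'   z, overrepresented, excluded).
#' @export
enrich_geneset <- function(counts, background, z_cutoff = 2.0) {
  stopifnot(inherits(background, "BackgroundModel"))
  if (!isTRUE(all.equal(as.numeric(attr(counts, "total_bp")),
                        as.numeric(attr(background, "target_bp")))))
    stop("promoter set size (", attr(counts, "total_bp"),
         " bp) does not match background target_bp (",
         attr(background, "target_bp"), " bp)")
  fam <- sort(union(counts$family_id, background$family_id))
  n_obs <- counts$n_obs[match(fam, counts$family_id)]
  n_obs[is.na(n_obs)] <- 0L
  bi <- match(fam, background$family_id)
  n_exp <- background$n_exp[bi]
  S <- background$S[bi]
  excluded <- is.na(n_exp) | n_exp <= 0 | S <= 0
  fold <- z <- rep(NA_real_, length(fam))
  fold[!excluded] <- fold_factor(n_obs[!excluded], n_exp[!excluded])
  z[!excluded] <- z_score(n_obs[!excluded], n_exp[!excluded], S[!excluded])
  over <- !excluded & z >= z_cutoff & n_obs > n_exp
  if (any(excluded))
    message(sum(excluded), " family(ies) excluded (undefined background): ",
            paste(head(fam[excluded], 5L), collapse = ", "))
  out <- data.frame(family_id = fam, n_obs = n_obs, n_exp = n_exp, S = S,
                    fold = fold, z = z, overrepresented = over,
                    excluded = excluded, stringsAsFactors = FALSE)
  attr(out, "z_cutoff") <- z_cutoff
  attr(out, "label") <- attr(counts, "label")
  out
}

#' Scan, collapse, count and enrich one promoter set in one call
#'
#' Convenience wrapper running [scan_sequences()], [collapse_family_hits()],
#' [count_family_hits()] and [enrich_geneset()].
#'
#' @inheritParams scan_sequences
#' @param background `BackgroundModel` for the set's size.
#' @param z_cutoff call threshold.
#' @return FamilyEnrichment data.frame.
#' @export
enrich_promoters <- function(promoters, pwms, thresholds, background,
                             family_map = NULL, z_cutoff = 2.0) {
  hits <- collapse_family_hits(
    scan_sequences(promoters, pwms, thresholds, family_map))
  counts <- count_family_hits(hits, promoters,
                              families = background$family_id)
  enrich_geneset(counts, background, z_cutoff)
}
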