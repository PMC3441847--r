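#' Construct an expression matrix with subtype labels
#'
#' @param values numeric genes x samples matrix of positive intensities
#'   (positivity is required for geometric means; intensities are modelled
#'   as log-normally distributed).
#' @param labels character/factor of one subtype label per sample (column).
#' @return object of class `ExpressionMatrix` with fields `values`,
#'   `labels`.
#' @export
expression_matrix <- function(values, labels) {
  values <- as.matrix(values)
  if (any(!is.finite(values)) || any(values <= 0))
    stop("expression intensities must be positive and finite")
  if (is.null(rownames(values))) stop("values must have gene rownames")
  labels <- as.character(labels)
  if (length(labels) != ncol(values))
    stop("one label per sample required (", ncol(values), " samples, ",
         length(labels), " labels)")
  tab <- table(labels)
  if (any(tab < 2L))
    stop("every represented subtype needs >= 2 samples; offending: ",
         paste(names(tab)[tab < 2L], collapse = ", "))
  structure(list(values = values, labels = labels),
            class = "ExpressionMatrix")
}

#' @export
print.ExpressionMatrix <- function(x, ...) {
  cat("<ExpressionMatrix> ", nrow(x$values), " genes x ", ncol(x$values),
      " samples, ", length(unique(x$labels)), " subtypes\n", sep = "")
  invisible(x)
}

#' Read an expression matrix and sample labels from TSV
#'
#' @param values_path genes x samples TSV (first column gene ids).
#' @param labels_path two-column TSV (sample, label).
#' @return an [expression_matrix()].
#' @export
read_expression <- function(values_path, labels_path) {
  tab <- read_tsv(values_path, check.names = FALSE)
  values <- as.matrix(tab[, -1, drop = FALSE])
  rownames(values) <- tab[[1]]
  lab <- read_tsv(labels_path)
  labels <- setNames(as.character(lab[[2]]), lab[[1]])
  if (!all(colnames(values) %in% names(labels)))
    stop("samples without labels: ",
         paste(setdiff(colnames(values), names(labels)), collapse = ", "))
  expression_matrix(values, unname(labels[colnames(values)]))
}

# SAM-style moderated multiclass statistic on log intensities:
# d_i = sqrt(between-class mean square) / (pooled within SD + s0)
.sam_stat <- function(logx, labels, s0 = NULL) {
  classes <- unique(labels)
  K <- length(classes)
  n <- ncol(logx)
  nk <- vapply(classes, function(cl) sum(labels == cl), numeric(1))
  means <- vapply(classes, function(cl)
    rowMeans(logx[, labels == cl, drop = FALSE]), numeric(nrow(logx)))
  means <- matrix(means, nrow = nrow(logx))
  grand <- rowMeans(logx)
  ssb <- rowSums(sweep(sweep(means, 1L, grand)^2, 2L, nk, "*"))
  ssw <- rowSums((logx - means[, match(labels, classes), drop = FALSE])^2)
  msb <- ssb / (K - 1)
  s <- sqrt(ssw / (n - K))
  if (is.null(s0)) s0 <- median(s)
  list(d = sqrt(msb) / (s + s0), s0 = s0)
}

#' Select differentially expressed TF genes across subtypes
#'
#' SAM-style multiclass selection: a moderated F-like statistic
#' `d = sqrt(between-class mean square) / (pooled within-class SD + s0)` is
#' computed on log intensities, with the fudge constant `s0` set to the
#' median gene-wise pooled standard error. The null distribution is
#' obtained by seeded label permutation; the q-value at a gene's statistic
#' is the (monotonized) median permutation false-positive count divided by
#' the observed count at that threshold. Genes with `q < fdr` are returned.
#'
#' @param expr an [expression_matrix()] with >= 3 subtype classes.
#' @param fdr false discovery rate threshold (default 0.1).
#' @param n_perm number of label permutations (>= 100, default 200).
#' @param seed integer seed for the permutations.
#' @return data.frame (gene_id, d, q) of selected genes, sorted by
#'   descending d; the full per-gene table is attached as attribute
#'   `all_genes`, the fudge constant as `s0`.
#' @export
select_differential_tfs <- function(expr, fdr = 0.1, n_perm = 200L,
                                    seed = 1L) {
  stopifnot(inherits(expr, "ExpressionMatrix"), n_perm >= 100L, fdr >= 0)
  labels <- expr$labels
  if (length(unique(labels)) < 3L)
    stop("need >= 3 subtype classes")
  logx <- log2(expr$values)
  obs <- .sam_stat(logx, labels)
  d <- obs$d
  m <- length(d)
  nullcount <- matrix(0L, nrow = n_perm, ncol = m)
  ds <- sort(d, decreasing = TRUE)
  local_seed(seed, {
    for (p in seq_len(n_perm)) {
      dp <- .sam_stat(logx, sample(labels), s0 = obs$s0)$d
      # #{null d >= ds[j]} for each observed threshold:
      # dp >= ds[j]  <=>  -dp <= -ds[j]
      nullcount[p, ] <- findInterval(-ds, sort(-dp))
    }
  })
  V <- apply(nullcount, 2L, median)
  R <- seq_len(m)
  fdr_at <- pmin(V / R, 1)
  q_sorted <- rev(cummin(rev(fdr_at)))
  q <- q_sorted[rank(-d, ties.method = "first")]
  all_genes <- data.frame(gene_id = rownames(expr$values), d = d, q = q,
                          stringsAsFactors = FALSE)
  sel <- all_genes[all_genes$q < fdr, , drop = FALSE]
  sel <- sel[order(-sel$d), , drop = FALSE]
  rownames(sel) <- NULL
  attr(sel, "all_genes") <- all_genes
  attr(sel, "s0") <- obs$s0
  sel
}

#' Geometric mean expression per subtype
#'
#' `exp(mean(log(intensity)))` over each subtype's samples; preferred over
#' the arithmetic mean because expression intensities are log-normally
#' distributed.
#'
#' @param expr an [expression_matrix()].
#' @param genes optional gene subset (default all genes).
#' @return gene x subtype matrix of geometric means.
#' @export
geometric_mean_by_subtype <- function(expr, genes = NULL) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  v <- expr$values
  if (!is.null(genes)) {
    missing <- setdiff(genes, rownames(v))
    if (length(missing))
      stop("genes not in expression matrix: ",
           paste(head(missing, 5L), collapse = ", "))
    v <- v[genes, , drop = FALSE]
  }
  if (any(v <= 0)) {
    bad <- which(v <= 0, arr.ind = TRUE)[1L, ]
    stop("non-positive intensity at gene ", rownames(v)[bad[1L]],
         ", sample ", colnames(v)[bad[2L]] %||% bad[2L])
  }
  classes <- unique(expr$labels)
  lv <- log(v)
  gm <- vapply(classes, function(cl)
    exp(rowMeans(lv[, expr$labels == cl, drop = FALSE])),
    numeric(nrow(v)))
  gm <- matrix(gm, nrow = nrow(v), dimnames = list(rownames(v), classes))
  gm
}

#' Correlate family fold overrepresentation with TF expression
#'
#' For each mapped (family, TF gene) pair, computes the Pearson correlation
#' across the shared subtypes between the family's fold-factor vector and
#' the gene's geometric-mean expression vector. Pairs with zero variance in
#' either vector are flagged undefined (NA).
#'
#' @param fold fold matrix from [build_fold_matrix()] (or any
#'   family x subtype matrix).
#' @param gm gene x subtype geometric means from
#'   [geometric_mean_by_subtype()].
#' @param mapping data.frame (family_id, gene_id); one family may map to
#'   several genes and vice versa.
#' @return data.frame (family_id, gene_id, r, n_subtypes).
#' @export
correlate_enrichment_expression <- function(fold, gm, mapping) {
  fold <- unclass(fold)
  stopifnot(is.matrix(fold), is.matrix(gm),
            all(c("family_id", "gene_id") %in% names(mapping)),
            nrow(mapping) >= 1L)
  shared <- intersect(colnames(fold), colnames(gm))
  if (length(shared) < 3L)
    stop("need >= 3 shared subtype columns; got ", length(shared))
  keep <- mapping$family_id %in% rownames(fold) &
    mapping$gene_id %in% rownames(gm)
  mapping <- mapping[keep, , drop = FALSE]
  if (!nrow(mapping))
    stop("no mapped (family, gene) pair present in both matrices")
  r <- mapply(function(f, g) {
    x <- fold[f, shared]
    y <- gm[g, shared]
    if (sd(x) == 0 || sd(y) == 0) NA_real_ else cor(x, y)
  }, mapping$family_id, mapping$gene_id)
  data.frame(family_id = mapping$family_id, gene_id = mapping$gene_id,
             r = unname(r), n_subtypes = length(shared),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Two-group Wilcoxon rank-sum marker test
#'
#' Compares one gene's expression between two groups of subtypes. For a
#' combined sample size of at most 12 the two-sided p-value is computed by
#' exact enumeration of all rank assignments (midranks under ties);
#' otherwise a tie-corrected normal approximation with continuity
#' correction is used.
#'
#' @param expr an [expression_matrix()].
#' @param gene gene_id to test.
#' @param groupA,groupB character vectors of subtype labels (>= 2 samples
#'   each).
#' @return list with `p.value`, `W` (rank-sum of group A), `elevated`
#'   ("A", "B" or "none") and `method`.
#' @export
ranksum_marker_test <- function(expr, gene, groupA, groupB) {
  stopifnot(inherits(expr, "ExpressionMatrix"))
  if (!gene %in% rownames(expr$values)) stop("unknown gene: ", gene)
  x <- expr$values[gene, expr$labels %in% groupA]
  y <- expr$values[gene, expr$labels %in% groupB]
  if (length(x) < 2L || length(y) < 2L)
    stop("both groups need >= 2 samples (A: ", length(x), ", B: ",
         length(y), ")")
  ranksum_test(x, y)
}

#' @rdname ranksum_marker_test
#' @param x,y numeric value vectors for the two groups (direct interface).
#' @export
ranksum_test <- function(x, y) {
  nA <- length(x)
  nB <- length(y)
  n <- nA + nB
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nA)])
  mu <- nA * (n + 1) / 2
  if (n <= 12L) {
    combos <- combn(n, nA)
    ws <- colSums(matrix(r[combos], nrow = nA))
    p <- 2 * min(mean(ws <= w), mean(ws >= w))
    p <- min(p, 1)
    method <- "exact enumeration"
  } else {
    ties <- table(r)
    tie_term <- sum(ties^3 - ties) / (n * (n - 1))
    sigma <- sqrt(nA * nB / 12 * ((n + 1) - tie_term))
    zc <- (w - mu - sign(w - mu) * 0.5) / sigma
    p <- min(2 * pnorm(-abs(zc)), 1)
    method <- "normal approximation with tie correction"
  }
  elevated <- if (w > mu) "A" else if (w < mu) "B" else "none"
  list(p.value = p, W = w, elevated = elevated, method = method)
}
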