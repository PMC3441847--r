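#' Assemble the family x subtype fold-factor matrix
#'
#' Keeps the intersection of families with a defined fold factor in every
#' subtype; dropped families are reported. Rows are ordered
#' lexicographically by family_id.
#'
#' @param enrichments named list (one element per subtype) of
#'   FamilyEnrichment data.frames from [enrich_geneset()].
#' @return numeric matrix, families x subtypes (class `FoldMatrix`).
#' @export
build_fold_matrix <- function(enrichments) {
  stopifnot(is.list(enrichments), length(enrichments) >= 2L)
  if (is.null(names(enrichments)) || any(!nzchar(names(enrichments))))
    stop("enrichments must be a named list (subtype labels)")
  defined <- lapply(enrichments, function(e)
    e$family_id[!e$excluded & is.finite(e$fold)])
  fam <- sort(Reduce(intersect, defined))
  if (!length(fam))
    stop("no family has a defined fold factor in every subtype")
  all_fam <- sort(Reduce(union, lapply(enrichments, `[[`, "family_id")))
  dropped <- setdiff(all_fam, fam)
  if (length(dropped))
    message(length(dropped), " family(ies) dropped (undefined in >=1 ",
            "subtype): ", paste(head(dropped, 5L), collapse = ", "))
  fm <- vapply(enrichments, function(e) e$fold[match(fam, e$family_id)],
               numeric(length(fam)))
  fm <- matrix(fm, nrow = length(fam),
               dimnames = list(fam, names(enrichments)))
  class(fm) <- c("FoldMatrix", class(fm))
  fm
}

#' Pearson correlation matrix of subtype fold-overrepresentation vectors
#'
#' Entry (s, t) is the Pearson correlation across families of the fold
#' vectors of subtypes s and t. Zero-variance columns yield NA entries and a
#' warning; the diagonal is fixed at 1.
#'
#' @param fm fold matrix from [build_fold_matrix()] (>= 3 family rows).
#' @return symmetric subtype x subtype correlation matrix.
#' @export
subtype_correlation_matrix <- function(fm) {
  fm <- unclass(fm)
  stopifnot(is.matrix(fm), nrow(fm) >= 3L)
  sds <- apply(fm, 2L, sd)
  if (any(sds == 0))
    warning("zero-variance subtype column(s): ",
            paste(colnames(fm)[sds == 0], collapse = ", "),
            "; correlations undefined (NA)")
  cc <- suppressWarnings(cor(fm))
  diag(cc) <- 1
  cc
}

#' Centered principal component analysis of the fold matrix
#'
#' Columns (subtypes) are centered by their means; no variance scaling is
#' applied, matching the plain covariance decomposition of the fold-factor
#' matrix with families as observations. Component signs are fixed so that
#' each loading vector's largest-magnitude entry is positive. Eigenvalues
#' are the variances (divisor n-1) of the scores.
#'
#' @param fm fold matrix (>= 3 rows, >= 2 columns).
#' @param scale. optionally scale columns to unit variance (default FALSE).
#' @return `PCAResult`: list with `scores` (family x component), `loadings`
#'   (subtype x component), `eigenvalues`, `var_pct`, `cum_pct`, `center`,
#'   and `degenerate` flag (TRUE when total variance is zero).
#' @export
run_pca <- function(fm, scale. = FALSE) {
  x <- unclass(fm)
  stopifnot(is.matrix(x), nrow(x) >= 3L, ncol(x) >= 2L)
  degenerate <- all(abs(sweep(x, 2L, colMeans(x))) < 1e-300)
  pc <- prcomp(x, center = TRUE, scale. = scale.)
  ev <- pc$sdev^2
  k <- length(ev)
  rot <- pc$rotation
  sco <- pc$x
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      sco[, j] <- -sco[, j]
    }
  }
  tot <- sum(ev)
  var_pct <- if (tot > 0) 100 * ev / tot else rep(0, k)
  if (degenerate)
    warning("constant fold matrix: all eigenvalues are zero")
  structure(list(scores = sco, loadings = rot, eigenvalues = ev,
                 var_pct = var_pct, cum_pct = cumsum(var_pct),
                 center = pc$center, degenerate = degenerate),
            class = "PCAResult")
}

#' @export
print.PCAResult <- function(x, ...) {
  cat("<PCAResult> ", nrow(x$scores), " families x ", nrow(x$loadings),
      " subtypes\n", sep = "")
  cat("explained variance (%):",
      paste(sprintf("%.1f", x$var_pct), collapse = ", "), "\n")
  invisible(x)
}

#' Hotelling's T2 ranking of families
#'
#' T2 of a family is the squared Mahalanobis-type distance of its fold
#' profile from the matrix centroid: the sum over retained components of
#' `score^2 / eigenvalue`, using every component whose eigenvalue exceeds
#' `tol * max(eigenvalue)`. Families are ranked by descending T2, ties
#' broken by family_id.
#'
#' @param pca a [run_pca()] result.
#' @param tol relative eigenvalue tolerance (default 1e-12).
#' @return data.frame (family_id, t2, rank) sorted by descending T2.
#' @export
hotelling_t2 <- function(pca, tol = 1e-12) {
  stopifnot(inherits(pca, "PCAResult"))
  ev <- pca$eigenvalues
  keep <- ev > tol * max(ev)
  if (!any(keep) || max(ev) <= 0)
    stop("all eigenvalues are zero: T2 undefined")
  sco <- pca$scores[, keep, drop = FALSE]
  t2 <- rowSums(sweep(sco^2, 2L, ev[keep], "/"))
  ord <- order(-t2, rownames(pca$scores))
  data.frame(family_id = rownames(pca$scores)[ord], t2 = unname(t2[ord]),
             rank = seq_along(t2), stringsAsFactors = FALSE)
}

#' Check a published fold-overrepresentation table against printed values
#'
#' Given a families x subtypes fold table (TSV, first column family_id,
#' remaining columns the five subtypes), recomputes the subtype
#' fold-vector correlation matrix and the PCA cumulative explained
#' variance, and returns the quantities a reader would compare with the
#' published analysis: the ERBB2+/Basal, LuminalB/ERBB2+ and
#' LuminalA/LuminalB correlation entries and the 2- and 3-component
#' cumulative variance.
#'
#' @param path TSV path of the reference fold table.
#' @param subtype_cols optional named mapping from the roles
#'   `c("lumA","lumB","erbb2","basal")` to column names in the table;
#'   defaults to fuzzy matching on the column names.
#' @return list with `correlations` (full matrix), `entries` (the three
#'   printed pairs), and `cum_pct` (cumulative variance %).
#' @export
reproduce_reference_analysis <- function(path, subtype_cols = NULL) {
  stopifnot(file.exists(path))
  tab <- read_tsv(path)
  fm <- as.matrix(tab[, -1, drop = FALSE])
  rownames(fm) <- tab[[1]]
  if (is.null(subtype_cols)) {
    find <- function(pat) grep(pat, colnames(fm), ignore.case = TRUE)[1]
    subtype_cols <- c(lumA = find("lum.*a|luminal.?a"),
                      lumB = find("lum.*b|luminal.?b"),
                      erbb2 = find("erbb2|her2"),
                      basal = find("basal"))
    if (anyNA(subtype_cols))
      stop("could not identify subtype columns in ", path)
    subtype_cols <- colnames(fm)[subtype_cols]
  }
  cc <- subtype_correlation_matrix(fm)
  pca <- run_pca(fm)
  list(correlations = cc,
       entries = c(
         erbb2_basal = cc[subtype_cols[["erbb2"]], subtype_cols[["basal"]]],
         lumB_erbb2 = cc[subtype_cols[["lumB"]], subtype_cols[["erbb2"]]],
         lumA_lumB = cc[subtype_cols[["lumA"]], subtype_cols[["lumB"]]]),
       cum_pct = pca$cum_pct)
}
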