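#' Build a simulation configuration
#'
#' Defines the statistical structure the analysis assumes: i.i.d. background
#' promoters of a stated base composition carrying family motifs planted at
#' a baseline rate, subtype gene sets whose promoters carry the same motifs
#' at multiplier-elevated rates, an optional ordered-pair framework plant,
#' and a subtype-labeled lognormal expression matrix in which TF genes can
#' be coupled to family enrichment. The defaults mirror the study scale:
#' five subtypes, 50-gene subtype sets of 600-bp promoters (-500..+100),
#' 20 motif families, and roughly 23 expression samples per subtype class
#' (a ~114-sample cohort split over five classes).
#'
#' @param seed master seed; all outputs are byte-identical given the config.
#' @param n_subtypes number of subtype classes (default 5).
#' @param subtypes subtype labels.
#' @param genes_per_set promoters per subtype gene set (default 50).
#' @param n_background background pool size in promoters (default 1000).
#' @param promoter_length promoter window length in bp (default 600).
#' @param base_composition A/C/G/T frequencies (default uniform).
#' @param n_families number of TFBS matrix families (default 20).
#' @param baseline_rate expected planted motifs per promoter per family
#'   under the background (default 0.4).
#' @param multipliers optional family x subtype matrix of planting-rate
#'   multipliers (default all 1 = null).
#' @param framework optional list(pair = c(famA, famB), gap_min, gap_max,
#'   subtype, n_genes) planting an ordered framework with uniform gaps in
#'   every promoter of that subtype set; baseline plants of the two
#'   framework families are suppressed in that set (the module owns those
#'   sites).
#' @param expression list(samples_per_class, baseline_meanlog, sdlog,
#'   coupling, n_null_genes); `coupling` in `[0, 1]` scales how strongly a
#'   TF gene's class log-mean follows the standardized enrichment of its
#'   mapped family.
#' @return `SimulationConfig` object.
#' @export
simulation_config <- function(seed = 1L,
                              n_subtypes = 5L,
                              subtypes = c("LuminalA", "LuminalB", "ERBB2",
                                           "Basal", "NormalLike"),
                              genes_per_set = 50L,
                              n_background = 1000L,
                              promoter_length = 600L,
                              base_composition = c(A = 0.25, C = 0.25,
                                                   G = 0.25, T = 0.25),
                              n_families = 20L,
                              baseline_rate = 0.4,
                              multipliers = NULL,
                              framework = NULL,
                              expression = list()) {
  subtypes <- subtypes[seq_len(n_subtypes)]
  if (anyNA(subtypes))
    subtypes <- paste0("S", seq_len(n_subtypes))
  base_composition <- as.numeric(base_composition)
  if (length(base_composition) != 4L || any(base_composition < 0) ||
      abs(sum(base_composition) - 1) > 1e-6)
    stop("base_composition must be 4 non-negative frequencies summing to 1")
  stopifnot(baseline_rate >= 0, n_families >= 1L, genes_per_set >= 1L,
            promoter_length >= 50L)
  fam_ids <- .family_ids(n_families)
  if (is.null(multipliers)) {
    multipliers <- matrix(1, nrow = n_families, ncol = n_subtypes,
                          dimnames = list(fam_ids, subtypes))
  } else {
    multipliers <- as.matrix(multipliers)
    stopifnot(nrow(multipliers) == n_families,
              ncol(multipliers) == n_subtypes, all(multipliers >= 0))
    dimnames(multipliers) <- list(fam_ids, subtypes)
  }
  expr_defaults <- list(samples_per_class = 23L, baseline_meanlog = 6,
                        sdlog = 0.5, coupling = 0, n_null_genes = 200L)
  expression <- utils::modifyList(expr_defaults, expression)
  stopifnot(expression$coupling >= 0, expression$coupling <= 1,
            expression$samples_per_class >= 2L, expression$sdlog > 0)
  if (!is.null(framework)) {
    stopifnot(length(framework$pair) == 2L,
              all(framework$pair %in% fam_ids))
    framework$gap_min <- framework$gap_min %||% 29L
    framework$gap_max <- framework$gap_max %||% 79L
    framework$subtype <- framework$subtype %||% subtypes[1L]
    framework$n_genes <- framework$n_genes %||% genes_per_set
    stopifnot(framework$gap_min >= 0,
              framework$gap_max >= framework$gap_min,
              framework$subtype %in% subtypes)
  }
  structure(list(seed = as.integer(seed), n_subtypes = n_subtypes,
                 subtypes = subtypes, genes_per_set = genes_per_set,
                 n_background = n_background,
                 promoter_length = promoter_length,
                 base_composition = setNames(base_composition, DNA_BASES4),
                 n_families = n_families, family_ids = fam_ids,
                 baseline_rate = baseline_rate, multipliers = multipliers,
                 framework = framework, expression = expression),
            class = "SimulationConfig")
}

.family_ids <- function(n) {
  base <- c("V$NFKB", "V$ETSF")
  extra <- sprintf("V$FAM%02d", seq_len(max(n - 2L, 0L)))
  c(base, extra)[seq_len(n)]
}

#' Generate a toy PWM library with a family map
#'
#' Each family holds two member matrices of the same sharpness whose
#' consensi are offset by one base pair (the second drops the first
#' consensus base and appends one), emulating the redundant,
#' position-shifted matrices that different sources describe for one
#' factor; family-level collapsing of overlapping matches is thereby
#' genuinely exercised. The first two families carry NF-kB-like
#' (GGGACTTTCC) and ETS-like (ACAGGAAGTG) consensus sequences; the
#' remaining consensi are drawn at random from the configured seed.
#'
#' @param cfg a [simulation_config()].
#' @param motif_length consensus length in bp (default 10).
#' @param p_consensus consensus base probability per position (default
#'   0.95; the remainder is spread over the other bases).
#' @return list with `pwms`, `family_map` (data.frame matrix_id,
#'   family_id) and `map` (named vector).
#' @export
toy_pwm_library <- function(cfg, motif_length = 10L, p_consensus = 0.95) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  fixed <- c("V$NFKB" = "GGGACTTTCC", "V$ETSF" = "ACAGGAAGTG")
  local_seed(derive_seed(cfg$seed, "toy_pwm_library"), {
    consensi <- vapply(cfg$family_ids, function(f) {
      if (f %in% names(fixed)) fixed[[f]]
      else paste0(sample(DNA_BASES4, motif_length, replace = TRUE),
                  collapse = "")
    }, character(1))
    tails <- sample(DNA_BASES4, length(consensi), replace = TRUE)
  })
  mk <- function(consensus, p_cons, id) {
    L <- nchar(consensus)
    probs <- matrix((1 - p_cons) / 3, nrow = L, ncol = 4L)
    hit <- match(strsplit(consensus, "")[[1]], DNA_BASES4)
    probs[cbind(seq_len(L), hit)] <- p_cons
    new_pwm(id, probs)
  }
  pwms <- list()
  rows <- list()
  for (i in seq_along(cfg$family_ids)) {
    f <- cfg$family_ids[i]
    clean <- gsub("[^A-Za-z0-9]", "", f)
    ids <- paste0(clean, c("_01", "_02"))
    cons1 <- consensi[[f]]
    cons2 <- paste0(substr(cons1, 2L, nchar(cons1)), tails[i])
    pwms[[ids[1]]] <- mk(cons1, p_consensus, ids[1])
    pwms[[ids[2]]] <- mk(cons2, p_consensus, ids[2])
    rows[[f]] <- data.frame(matrix_id = ids, family_id = f,
                            stringsAsFactors = FALSE)
  }
  family_map <- do.call(rbind, rows)
  rownames(family_map) <- NULL
  list(pwms = unname(pwms), family_map = family_map,
       map = setNames(family_map$family_id, family_map$matrix_id))
}

# sample one motif instance letter-by-letter from a PWM
.sample_instance <- function(pwm) {
  paste0(vapply(seq_len(pwm$length), function(i)
    sample(DNA_BASES4, 1L, prob = pwm$probs[i, ]), character(1)),
    collapse = "")
}

.revcomp_chr <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# plant motif instances into a character promoter; occupied = intervals
# already taken (0-based half-open). Returns seq, ledger rows, redraw count.
.plant <- function(seqchars, plan, pwms_by_fam, gene_id) {
  L <- length(seqchars)
  occupied <- matrix(numeric(0), ncol = 2L)
  rows <- list()
  redraws <- 0L
  for (i in seq_len(nrow(plan))) {
    fam <- plan$family_id[i]
    members <- pwms_by_fam[[fam]]
    fixed_pos <- !is.na(plan$at[i])
    # framework elements are strong conserved sites: use the sharpest member
    pwm <- if (fixed_pos) members[[1L]]
           else members[[sample.int(length(members), 1L)]]
    w <- pwm$length
    placed <- FALSE
    for (try in seq_len(30L)) {
      gap_spec <- plan$at[i]
      start <- if (!is.na(gap_spec)) gap_spec
               else sample.int(L - w + 1L, 1L) - 1L
      if (start + w > L) { redraws <- redraws + 1L; next }
      if (nrow(occupied) &&
          any(start < occupied[, 2L] & start + w > occupied[, 1L])) {
        if (!is.na(gap_spec)) break   # fixed placement blocked: drop
        redraws <- redraws + 1L
        next
      }
      strand <- sample(c("+", "-"), 1L)
      inst <- if (fixed_pos) consensus_string(pwm) else .sample_instance(pwm)
      if (strand == "-") inst <- .revcomp_chr(inst)
      seqchars[(start + 1L):(start + w)] <- strsplit(inst, "")[[1]]
      occupied <- rbind(occupied, c(start, start + w))
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = gene_id, family_id = fam, matrix_id = pwm$matrix_id,
        start = start, end = start + w, strand = strand,
        stringsAsFactors = FALSE)
      placed <- TRUE
      break
    }
    if (!placed && is.na(plan$at[i])) redraws <- redraws + 1L
  }
  list(seq = seqchars, rows = rows, redraws = redraws)
}

# generate one set of promoters with per-family Poisson planting
.simulate_promoter_set <- function(n, cfg, pwms, map, rates, gene_prefix,
                                   label, framework = NULL) {
  pl <- cfg$promoter_length
  fam_ids <- names(rates)
  pwms_by_fam <- split(pwms, unname(map[vapply(pwms, `[[`, "",
                                               "matrix_id")]))
  seqs <- character(n)
  ledger <- list()
  total_plants <- 0L
  total_redraws <- 0L
  gene_ids <- sprintf("%s%04d", gene_prefix, seq_len(n))
  for (g in seq_len(n)) {
    chars <- sample(DNA_BASES4, pl, replace = TRUE,
                    prob = cfg$base_composition)
    plan <- list()
    if (!is.null(framework)) {
      gap <- sample(seq.int(framework$gap_min, framework$gap_max), 1L)
      wA <- pwms_by_fam[[framework$pair[1]]][[1]]$length
      wB <- pwms_by_fam[[framework$pair[2]]][[1]]$length
      lastA <- pl - (wA + gap + wB)
      if (lastA < 0L) stop("framework does not fit in promoter")
      startA <- sample.int(lastA + 1L, 1L) - 1L
      plan[[length(plan) + 1L]] <- data.frame(
        family_id = framework$pair, at = c(startA, startA + wA + gap),
        stringsAsFactors = FALSE)
    }
    for (fam in fam_ids) {
      k <- rpois(1L, rates[[fam]])
      if (k > 0L)
        plan[[length(plan) + 1L]] <- data.frame(
          family_id = rep(fam, k), at = NA_integer_,
          stringsAsFactors = FALSE)
    }
    if (length(plan)) {
      plan <- do.call(rbind, plan)
      total_plants <- total_plants + nrow(plan)
      res <- .plant(chars, plan, pwms_by_fam, gene_ids[g])
      chars <- res$seq
      ledger <- c(ledger, res$rows)
      total_redraws <- total_redraws + res$redraws
    }
    seqs[g] <- paste0(chars, collapse = "")
  }
  if (total_plants > 0L && total_redraws > 0.5 * total_plants)
    stop("planting re-draw rate exceeded 50% (", total_redraws, "/",
         total_plants, "); promoters too crowded")
  ledger <- if (length(ledger)) do.call(rbind, ledger)
            else data.frame(gene_id = character(), family_id = character(),
                            matrix_id = character(), start = integer(),
                            end = integer(), strand = character(),
                            stringsAsFactors = FALSE)
  rownames(ledger) <- NULL
  ps <- promoter_set(setNames(seqs, gene_ids), label = label)
  list(promoters = ps, ledger = ledger)
}

#' Simulate a background promoter pool
#'
#' I.i.d. sequences from the configured base composition, with family
#' motifs planted at the baseline rate (instances sampled letter-by-letter
#' from a family member PWM, random strand, non-overlapping placements).
#' The ledger records every plant.
#'
#' @param cfg a [simulation_config()].
#' @param pwms toy library from [toy_pwm_library()] (list with `pwms`,
#'   `map`), or a compatible list.
#' @param n_promoters pool size (default `cfg$n_background`).
#' @param planted set FALSE for a motif-free pool (used for threshold
#'   calibration).
#' @param stage seed-substream name.
#' @return list(promoters = [promoter_set()], ledger = data.frame of
#'   plants).
#' @export
simulate_background_pool <- function(cfg, pwms,
                                     n_promoters = cfg$n_background,
                                     planted = TRUE,
                                     stage = "background") {
  stopifnot(inherits(cfg, "SimulationConfig"), n_promoters >= 1L)
  rates <- setNames(rep(if (planted) cfg$baseline_rate else 0,
                        cfg$n_families), cfg$family_ids)
  local_seed(derive_seed(cfg$seed, stage),
             .simulate_promoter_set(n_promoters, cfg, pwms$pwms, pwms$map,
                                    rates, "bg", stage))
}

#' Simulate subtype-specific promoter gene sets
#'
#' For subtype s and family X, plants occur at rate
#' `baseline_rate * multipliers[X, s]`. When the config carries a framework
#' spec, every promoter of the framework subtype additionally receives the
#' ordered pair with a uniform gap from `[gap_min, gap_max]`, and baseline
#' plants of the two framework families are suppressed in that set.
#' Framework elements are planted as consensus sites (the module's ground
#' truth is full coverage, so its sites are modelled as strong conserved
#' sites); all baseline plants are sampled letter-by-letter from the PWM.
#'
#' @inheritParams simulate_background_pool
#' @return list(sets = named list of [promoter_set()], ledgers = named list
#'   of plant data.frames, rates = family x subtype true rate matrix).
#' @export
simulate_subtype_promoters <- function(cfg, pwms) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  sets <- list()
  ledgers <- list()
  rates_mat <- cfg$baseline_rate * cfg$multipliers
  for (s in cfg$subtypes) {
    rates <- setNames(rates_mat[, s], cfg$family_ids)
    fw <- NULL
    n <- cfg$genes_per_set
    if (!is.null(cfg$framework) && identical(cfg$framework$subtype, s)) {
      fw <- cfg$framework
      rates[fw$pair] <- 0
      n <- fw$n_genes
    }
    res <- local_seed(derive_seed(cfg$seed, paste0("subtype_", s)),
                      .simulate_promoter_set(n, cfg, pwms$pwms, pwms$map,
                                             rates,
                                             paste0(sub("V\\$", "", s), "_g"),
                                             s, framework = fw))
    sets[[s]] <- res$promoters
    ledgers[[s]] <- res$ledger
  }
  list(sets = sets, ledgers = ledgers, rates = rates_mat)
}

#' Simulate a subtype-labeled lognormal expression matrix
#'
#' One TF gene per family plus `n_null_genes` unrelated genes. Intensities
#' are drawn lognormally per gene and class; for TF genes the class
#' log-mean is `baseline + coupling * standardized enrichment` of the
#' mapped family in that class (enrichment taken from `fold`, typically
#' the true planting-rate matrix or a measured fold matrix). With
#' `coupling = 0` TF-gene class means are independent of enrichment.
#'
#' @param cfg a [simulation_config()].
#' @param fold family x subtype matrix of enrichment (fold factors or
#'   planting-rate multipliers); default = the config's multipliers.
#' @return list(expr = [expression_matrix()], mapping = data.frame
#'   (family_id, gene_id), class_means = true gene x class log-mean
#'   ledger).
#' @export
simulate_expression <- function(cfg, fold = NULL) {
  stopifnot(inherits(cfg, "SimulationConfig"))
  if (is.null(fold)) fold <- cfg$multipliers
  fold <- as.matrix(fold)
  stopifnot(all(cfg$subtypes %in% colnames(fold)))
  ex <- cfg$expression
  tf_fams <- intersect(cfg$family_ids, rownames(fold))
  tf_genes <- paste0("TF_", gsub("[^A-Za-z0-9]", "", tf_fams))
  null_genes <- sprintf("GENE%04d", seq_len(ex$n_null_genes))
  genes <- c(tf_genes, null_genes)
  K <- length(cfg$subtypes)
  class_means <- matrix(ex$baseline_meanlog, nrow = length(genes), ncol = K,
                        dimnames = list(genes, cfg$subtypes))
  for (i in seq_along(tf_fams)) {
    v <- fold[tf_fams[i], cfg$subtypes]
    if (sd(v) > 0)
      class_means[tf_genes[i], ] <- ex$baseline_meanlog +
        ex$coupling * (v - mean(v)) / sd(v)
  }
  nps <- ex$samples_per_class
  labels <- rep(cfg$subtypes, each = nps)
  values <- local_seed(derive_seed(cfg$seed, "expression"), {
    m <- matrix(0, nrow = length(genes), ncol = length(labels),
                dimnames = list(genes,
                                paste0("sample_", seq_along(labels))))
    for (j in seq_along(labels)) {
      m[, j] <- exp(rnorm(length(genes),
                          mean = class_means[, labels[j]],
                          sd = ex$sdlog))
    }
    m
  })
  mapping <- data.frame(family_id = tf_fams, gene_id = tf_genes,
                        stringsAsFactors = FALSE)
  list(expr = expression_matrix(values, labels), mapping = mapping,
       class_means = class_means)
}

#' Write all simulated inputs as standard pipeline files
#'
#' Emits promoter FASTA files (background, calibration, one per subtype
#' plus a combined file), per-subtype gene list TSVs, the toy PWM library
#' in JASPAR format with its family-map TSV, the expression matrix with
#' sample labels and the family-to-gene mapping, and a JSON truth ledger.
#'
#' @param cfg a [simulation_config()].
#' @param dir output directory (created).
#' @return invisibly, a named list of the written paths.
#' @export
write_simulation <- function(cfg, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  lib <- toy_pwm_library(cfg)
  bg <- simulate_background_pool(cfg, lib)
  cal <- simulate_background_pool(cfg, lib, planted = FALSE,
                                  stage = "calibration")
  sub <- simulate_subtype_promoters(cfg, lib)
  ex <- simulate_expression(cfg)
  paths <- list(
    pwms = file.path(dir, "pwms.jaspar"),
    family_map = file.path(dir, "family_map.tsv"),
    background = file.path(dir, "background.fa"),
    calibration = file.path(dir, "calibration.fa"),
    promoters = file.path(dir, "promoters.fa"),
    expression = file.path(dir, "expression.tsv"),
    labels = file.path(dir, "sample_labels.tsv"),
    mapping = file.path(dir, "family_gene_map.tsv"),
    ledger = file.path(dir, "truth_ledger.json"))
  write_pwms_jaspar(lib$pwms, paths$pwms)
  write_tsv(lib$family_map, paths$family_map)
  write_promoters_fasta(bg$promoters, paths$background)
  write_promoters_fasta(cal$promoters, paths$calibration)
  all_prom <- promoter_set(
    do.call(c, lapply(unname(sub$sets), function(p) p$seqs)),
    label = "all_subtypes")
  write_promoters_fasta(all_prom, paths$promoters)
  gene_lists <- list()
  for (s in cfg$subtypes) {
    p <- file.path(dir, paste0("genes_", s, ".tsv"))
    writeLines(sub$sets[[s]]$info$gene_id, p)
    gene_lists[[s]] <- p
  }
  paths$gene_lists <- gene_lists
  expr_df <- data.frame(gene_id = rownames(ex$expr$values),
                        ex$expr$values, check.names = FALSE,
                        stringsAsFactors = FALSE)
  write_tsv(expr_df, paths$expression)
  write_tsv(data.frame(sample = colnames(ex$expr$values),
                       label = ex$expr$labels, stringsAsFactors = FALSE),
            paths$labels)
  write_tsv(ex$mapping, paths$mapping)
  ledger <- list(seed = cfg$seed,
                 baseline_rate = cfg$baseline_rate,
                 multipliers = as.data.frame(cfg$multipliers),
                 background_plants = bg$ledger,
                 subtype_plants = sub$ledgers,
                 rates = as.data.frame(sub$rates),
                 expression_class_means = as.data.frame(ex$class_means))
  jsonlite::write_json(ledger, paths$ledger, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(paths)
}
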