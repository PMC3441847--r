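.default_params <- function() {
  list(upstream = 500L, downstream = 100L, rate = 0.1, B = 1000L,
       z_cutoff = 2.0, fdr = 0.1, n_perm = 200L,
       framework = list(min_coverage = 1.0, max_span = 60L,
                        max_gap = 200L))
}

#' Validate a pipeline run configuration
#'
#' Reads a YAML config (or takes a list), fills defaults (upstream 500,
#' downstream 100, calibration rate 0.1, B 1000, z_cutoff 2.0, fdr 0.1,
#' n_perm 200), checks every referenced path and parameter range, and
#' reports all violations at once rather than the first.
#'
#' @param config YAML path or list with elements `seed`, `out_dir`,
#'   `params`, and either `simulate` (a list of [simulation_config()]
#'   arguments) or `paths` (genome+tss or promoters FASTA, background,
#'   optional calibration, pwms, family_map, gene_lists, expression,
#'   labels, mapping).
#' @param strict treat unknown keys as errors instead of warnings.
#' @return normalized config list of class `RunConfig`.
#' @export
validate_config <- function(config, strict = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  known <- c("seed", "out_dir", "params", "simulate", "paths")
  unknown <- setdiff(names(config), known)
  if (length(unknown)) {
    msg <- paste("unknown config key(s):", paste(unknown, collapse = ", "))
    if (strict) stop(msg) else warning(msg)
  }
  problems <- character()
  add <- function(msg) problems <<- c(problems, msg)
  cfg <- config
  cfg$seed <- cfg$seed %||% 1L
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1L)
    add("seed must be a single integer")
  if (is.null(cfg$out_dir)) add("out_dir is required")
  defs <- .default_params()
  cfg$params <- utils::modifyList(defs, cfg$params %||% list())
  p <- cfg$params
  if (!is.numeric(p$B) || p$B < 100) add("params$B must be >= 100")
  if (!is.numeric(p$rate) || p$rate <= 0) add("params$rate must be > 0")
  if (!is.numeric(p$upstream) || p$upstream < 0)
    add("params$upstream must be >= 0")
  if (!is.numeric(p$downstream) || p$downstream < 1)
    add("params$downstream must be >= 1")
  if (!is.numeric(p$z_cutoff)) add("params$z_cutoff must be numeric")
  if (!is.numeric(p$fdr) || p$fdr < 0 || p$fdr > 1)
    add("params$fdr must be in [0, 1]")
  if (!is.numeric(p$n_perm) || p$n_perm < 100)
    add("params$n_perm must be >= 100")
  fw <- p$framework
  if (fw$min_coverage <= 0 || fw$min_coverage > 1)
    add("params$framework$min_coverage must be in (0, 1]")
  if (fw$max_span < 0) add("params$framework$max_span must be >= 0")
  if (fw$max_gap <= 0) add("params$framework$max_gap must be > 0")
  simulate <- !is.null(cfg$simulate)
  if (!simulate) {
    pa <- cfg$paths %||% list()
    need <- c("background", "pwms", "family_map", "gene_lists",
              "expression", "labels", "mapping")
    has_genome <- !is.null(pa$genome) && !is.null(pa$tss)
    has_prom <- !is.null(pa$promoters)
    if (!has_genome && !has_prom)
      add("paths must provide either genome+tss or a promoters FASTA")
    for (k in need)
      if (is.null(pa[[k]])) add(paste0("paths$", k, " is required"))
    flat <- unlist(pa[setdiff(names(pa), "gene_lists")])
    for (f in flat)
      if (!file.exists(f)) add(paste0("missing file: ", f))
    for (f in unlist(pa$gene_lists))
      if (!file.exists(f)) add(paste0("missing gene list: ", f))
    if (is.null(names(pa$gene_lists)) && !is.null(pa$gene_lists))
      add("paths$gene_lists must be a named (subtype -> path) map")
  } else {
    bad <- setdiff(names(cfg$simulate),
                   names(formals(simulation_config)))
    if (length(bad))
      add(paste("unknown simulate key(s):", paste(bad, collapse = ", ")))
  }
  if (length(problems))
    stop("invalid configuration:\n  - ",
         paste(problems, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- c("RunConfig", "list")
  cfg
}

.config_hash <- function(cfg) {
  text_md5(yaml::as.yaml(unclass(cfg)))
}

#' Run the full promoter-regulation analysis pipeline
#'
#' Orchestrates: input simulation (optional) -> promoter extraction ->
#' threshold calibration -> scanning -> per-subtype family enrichment ->
#' fold matrix -> subtype correlation + PCA + Hotelling T2 -> framework
#' mining per subtype -> expression linkage. All stage outputs are written
#' under `out_dir/<stage>/` as TSV/JSON, each table carrying the run's
#' config hash in a header comment; a JSON manifest records the config
#' hash, seed, package version and per-stage row counts. Reruns with the
#' same config produce byte-identical outputs.
#'
#' @param config YAML path, list, or validated `RunConfig`.
#' @return invisibly, the manifest list.
#' @export
run_full_pipeline <- function(config) {
  cfg <- if (inherits(config, "RunConfig")) config else
    validate_config(config)
  out_dir <- cfg$out_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- .config_hash(cfg)
  hdr <- paste0("config_hash: ", hash)
  manifest <- list(config_hash = hash, seed = cfg$seed,
                   package_version = as.character(packageVersion("promfam")),
                   stages = list())
  stage_dir <- function(s) {
    d <- file.path(out_dir, s)
    dir.create(d, showWarnings = FALSE)
    d
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      manifest$stages[[name]] <<- list(status = "error",
                                       message = conditionMessage(e))
      jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                           auto_unbox = TRUE, digits = NA)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }
  message("[promfam] run ", hash, " (seed ", cfg$seed, ")")

  paths <- cfg$paths
  if (!is.null(cfg$simulate)) {
    paths <- run_stage("simulate", {
      sim_cfg <- do.call(simulation_config,
                         c(list(seed = cfg$seed), cfg$simulate))
      p <- write_simulation(sim_cfg, file.path(out_dir, "input"))
      manifest$stages$simulate <- list(status = "ok",
                                        n_files = length(unlist(p)))
      p
    })
  }

  motifs <- run_stage("load_motifs", {
    pwms <- read_pwms(paths$pwms, format = "jaspar")
    fam <- read_family_map(paths$family_map, pwms = pwms)
    manifest$stages$load_motifs <- list(status = "ok",
                                         n_matrices = length(pwms),
                                         n_families = length(fam$families))
    list(pwms = pwms, fam = fam)
  })

  proms <- run_stage("promoters", {
    all_prom <- if (!is.null(paths$genome) && !is.null(paths$tss)) {
      extract_promoters(paths$genome, paths$tss,
                        upstream = cfg$params$upstream,
                        downstream = cfg$params$downstream)
    } else read_promoters_fasta(paths$promoters)
    background <- read_promoters_fasta(paths$background, "background")
    sets <- lapply(names(paths$gene_lists), function(s)
      subset_by_genes(all_prom, paths$gene_lists[[s]], s))
    names(sets) <- names(paths$gene_lists)
    manifest$stages$promoters <- list(
      status = "ok", n_background = length(background),
      set_sizes = lapply(sets, length))
    list(background = background, sets = sets)
  })

  thresholds <- run_stage("calibrate", {
    cal_pool <- if (!is.null(paths$calibration))
      read_promoters_fasta(paths$calibration, "calibration")
    else proms$background
    th <- calibrate_thresholds(motifs$pwms, cal_pool,
                               rate = cfg$params$rate,
                               seed = derive_seed(cfg$seed, "calibrate"))
    write_tsv(data.frame(matrix_id = names(th$cutoffs),
                         cutoff_bits = unname(th$cutoffs)),
              file.path(stage_dir("calibrate"), "thresholds.tsv"), hdr)
    manifest$stages$calibrate <- list(status = "ok",
                                       n_matrices = length(th$cutoffs))
    th
  })

  background_model <- run_stage("background", {
    bg_hits <- collapse_family_hits(
      scan_sequences(proms$background, motifs$pwms, thresholds,
                     motifs$fam$map))
    write_hits_tsv(bg_hits,
                   file.path(stage_dir("background"), "background_hits.tsv"),
                   hdr)
    fams <- sort(unique(unname(motifs$fam$map)))
    sizes <- unique(vapply(proms$sets, function(s)
      sum(Biostrings::width(s$seqs)), numeric(1)))
    models <- lapply(sizes, function(bp)
      estimate_background(proms$background, bg_hits, bp,
                          B = cfg$params$B,
                          seed = derive_seed(cfg$seed, "background"),
                          families = fams))
    names(models) <- as.character(sizes)
    manifest$stages$background <- list(status = "ok",
                                        n_hits = nrow(bg_hits),
                                        target_bps = sizes)
    models
  })

  enr <- run_stage("enrich", {
    d <- stage_dir("enrich")
    res <- list()
    hits_by_set <- list()
    for (s in names(proms$sets)) {
      ps <- proms$sets[[s]]
      h <- collapse_family_hits(
        scan_sequences(ps, motifs$pwms, thresholds, motifs$fam$map))
      hits_by_set[[s]] <- h
      counts <- count_family_hits(
        h, ps, families = sort(unique(unname(motifs$fam$map))))
      bp <- as.character(sum(Biostrings::width(ps$seqs)))
      e <- enrich_geneset(counts, background_model[[bp]],
                          z_cutoff = cfg$params$z_cutoff)
      write_tsv(e, file.path(d, paste0("enrichment_", s, ".tsv")), hdr)
      res[[s]] <- e
    }
    manifest$stages$enrich <- list(
      status = "ok",
      n_overrepresented = lapply(res, function(e) sum(e$overrepresented)))
    list(enrichments = res, hits = hits_by_set)
  })

  pca_res <- run_stage("pca", {
    d <- stage_dir("pca")
    fm <- build_fold_matrix(enr$enrichments)
    write_tsv(data.frame(family_id = rownames(fm), unclass(fm),
                         check.names = FALSE),
              file.path(d, "fold_matrix.tsv"), hdr)
    cc <- subtype_correlation_matrix(fm)
    write_tsv(data.frame(subtype = rownames(cc), cc, check.names = FALSE),
              file.path(d, "subtype_correlation.tsv"), hdr)
    pca <- run_pca(fm)
    t2 <- hotelling_t2(pca)
    write_tsv(data.frame(family_id = rownames(pca$scores), pca$scores,
                         check.names = FALSE),
              file.path(d, "pca_scores.tsv"), hdr)
    write_tsv(data.frame(subtype = rownames(pca$loadings), pca$loadings,
                         check.names = FALSE),
              file.path(d, "pca_loadings.tsv"), hdr)
    write_tsv(data.frame(component = seq_along(pca$eigenvalues),
                         eigenvalue = pca$eigenvalues,
                         var_pct = pca$var_pct, cum_pct = pca$cum_pct),
              file.path(d, "pca_variance.tsv"), hdr)
    write_tsv(t2, file.path(d, "hotelling_t2.tsv"), hdr)
    manifest$stages$pca <- list(status = "ok", n_families = nrow(fm),
                                 cum_pct = pca$cum_pct)
    list(fold_matrix = fm, correlation = cc, pca = pca, t2 = t2)
  })

  fw_res <- run_stage("frameworks", {
    d <- stage_dir("frameworks")
    p <- cfg$params$framework
    res <- list()
    for (s in names(enr$hits)) {
      fws <- mine_frameworks(enr$hits[[s]], proms$sets[[s]],
                             min_coverage = p$min_coverage,
                             max_span = p$max_span, max_gap = p$max_gap)
      write_frameworks_json(fws, file.path(d, paste0("frameworks_", s,
                                                     ".json")))
      write_tsv(frameworks_table(fws),
                file.path(d, paste0("frameworks_", s, ".tsv")), hdr)
      res[[s]] <- fws
    }
    manifest$stages$frameworks <- list(status = "ok",
                                        n_frameworks = lapply(res, length))
    res
  })

  expr_res <- run_stage("expression", {
    d <- stage_dir("expression")
    expr <- read_expression(paths$expression, paths$labels)
    mapping <- read_tsv(paths$mapping)
    sel <- select_differential_tfs(expr, fdr = cfg$params$fdr,
                                   n_perm = cfg$params$n_perm,
                                   seed = derive_seed(cfg$seed, "sam"))
    write_tsv(sel, file.path(d, "differential_tfs.tsv"), hdr)
    gm <- geometric_mean_by_subtype(expr)
    write_tsv(data.frame(gene_id = rownames(gm), gm, check.names = FALSE),
              file.path(d, "geometric_means.tsv"), hdr)
    cors <- correlate_enrichment_expression(pca_res$fold_matrix, gm,
                                            mapping)
    write_tsv(cors, file.path(d, "enrichment_expression_cor.tsv"), hdr)
    manifest$stages$expression <- list(status = "ok",
                                        n_selected = nrow(sel),
                                        n_pairs = nrow(cors))
    list(selected = sel, gm = gm, correlations = cors)
  })

  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config_used.yaml"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(c(manifest,
              list(results = list(enrichments = enr$enrichments,
                                  pca = pca_res, frameworks = fw_res,
                                  expression = expr_res))))
}
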