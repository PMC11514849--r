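#' Assemble a pipeline configuration
#'
#' A pipeline run either synthesizes a cohort (`synthesize` = list of
#' [cohort_config()] arguments) or reads real inputs (`inputs` = named list
#' of paths: `clinical`, `protein_batches`, `phospho_batches`, `maf`, `gmt`,
#' `gene_lengths`). Thresholds default to the screening conventions used
#' throughout the package: alpha 0.05, 50% missingness bound, localization
#' probability 0.75, at least 2 unique peptides, hypermutation above 10
#' mutations/Mb on a 38-Mb exome, minimum group proportion 0.1 for the
#' survival cutpoint, cell-experiment ratio bounds 1.2 / 0.83.
#'
#' @param synthesize list of [cohort_config()] arguments, or `NULL`.
#' @param inputs named list of input paths, or `NULL`.
#' @param stages named logical list toggling `ingest`, `associate`,
#'   `somatic`, `survive`, `enrich`.
#' @param thresholds named list overriding individual defaults.
#' @param seed integer seed governing every stochastic step.
#' @param n_perm permutations for cutpoint and enrichment nulls.
#' @return an `mg_pipeline_config` list.
#' @export
pipeline_config <- function(synthesize = list(), inputs = NULL,
                            stages = list(), thresholds = list(),
                            seed = 1L, n_perm = 500) {
  if (is.null(synthesize) && is.null(inputs))
    stopf("either 'synthesize' or 'inputs' must be given")
  def_stages <- list(ingest = TRUE, associate = TRUE, somatic = TRUE,
                     survive = TRUE, enrich = TRUE)
  def_thresholds <- list(alpha = 0.05, max_missing_frac = 0.5,
                         min_localization = 0.75, min_unique_peptides = 2,
                         tmb_threshold = 10, exome_mb = 38, minprop = 0.1,
                         min_pairs = 10, cell_ratio_up = 1.2,
                         cell_ratio_down = 0.83, zscore_axes = c("columns",
                                                                 "rows"))
  bad <- setdiff(names(stages), names(def_stages))
  if (length(bad)) stopf("unknown stage toggle(s): %s",
                         paste(bad, collapse = ", "))
  bad <- setdiff(names(thresholds), names(def_thresholds))
  if (length(bad)) stopf("unknown threshold(s): %s",
                         paste(bad, collapse = ", "))
  structure(
    list(synthesize = synthesize, inputs = inputs,
         stages = utils::modifyList(def_stages, stages),
         thresholds = utils::modifyList(def_thresholds, thresholds),
         seed = assert_count(seed, "seed"),
         n_perm = assert_count(n_perm, "n_perm", 0L)),
    class = "mg_pipeline_config"
  )
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file whose top-level keys are the arguments of
#'   [pipeline_config()].
#' @return an `mg_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config, y)
}

ingest_batches <- function(paths, kind, thr) {
  mats <- lapply(paths, function(p) {
    tab <- read_quant_table(p, kind = kind)
    tab <- filter_features(tab,
                           min_unique_peptides = thr$min_unique_peptides,
                           min_localization = thr$min_localization)
    bridge_to_is(scale_total_intensity(tab))
  })
  m <- combine_batches(mats)
  filter_missing(zscore(m, axes = thr$zscore_axes),
                 max_missing_frac = thr$max_missing_frac)
}

#' Run the full Mg-omics screening pipeline
#'
#' Executes (optionally) cohort synthesis, then ingest, Mg association,
#' somatic association, survival and enrichment, writing every stage's
#' outputs and a JSON manifest (seed, thresholds, input checksums, stage
#' status) into `output_dir`. Re-running with the same configuration and
#' seed reproduces identical outputs. Any stage failure aborts with the
#' stage name; the manifest marks completed stages.
#'
#' @param config an `mg_pipeline_config` (or path to a YAML file).
#' @param output_dir output directory, created if needed.
#' @return the manifest, invisibly. The full in-memory results are attached
#'   as attribute `"results"`.
#' @export
run_pipeline <- function(config, output_dir) {
  if (is.character(config)) config <- read_pipeline_config(config)
  if (!inherits(config, "mg_pipeline_config"))
    stopf("'config' must come from pipeline_config()")
  thr <- config$thresholds
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(package = "mgscreen",
                   version = as.character(utils::packageVersion("mgscreen")),
                   seed = config$seed, thresholds = thr[names(thr) !=
                                                          "zscore_axes"],
                   stages = list(), outputs = character(0),
                   input_md5 = list())
  results <- list()
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  run_stage <- function(name, fun) {
    manifest$stages[[name]] <<- "incomplete"
    write_manifest()
    out <- tryCatch(fun(), error = function(e)
      stopf("stage '%s' failed: %s", name, conditionMessage(e)))
    manifest$stages[[name]] <<- "complete"
    write_manifest()
    out
  }
  emit <- function(df, name) {
    p <- file.path(output_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    manifest$outputs <<- c(manifest$outputs, name)
    p
  }
  emit_json <- function(x, name) {
    p <- file.path(output_dir, name)
    jsonlite::write_json(x, p, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    manifest$outputs <<- c(manifest$outputs, name)
    p
  }

  ## ---- inputs -------------------------------------------------------------
  if (!is.null(config$synthesize)) {
    bundle <- run_stage("simulate", function() {
      args <- config$synthesize
      if (is.null(args$seed)) args$seed <- config$seed
      simulate_cohort(do.call(cohort_config, args))
    })
    cohort_dir <- file.path(output_dir, "cohort")
    write_cohort(bundle, cohort_dir, overwrite = TRUE)
    paths <- list(
      clinical = file.path(cohort_dir, "clinical.csv"),
      protein_batches = file.path(cohort_dir, sprintf("%s_proteins.tsv",
                                                      names(bundle$batches))),
      phospho_batches = file.path(cohort_dir, sprintf("%s_phospho.tsv",
                                                      names(bundle$batches))),
      maf = file.path(cohort_dir, "mutations.maf.tsv"),
      gmt = file.path(cohort_dir, "gene_sets.gmt"),
      gene_lengths = file.path(cohort_dir, "gene_lengths.tsv"))
    results$truth <- bundle$truth
  } else {
    paths <- config$inputs
  }
  flat <- unlist(paths, use.names = FALSE)
  manifest$input_md5 <- as.list(tools::md5sum(flat[file.exists(flat)]))

  clinical <- utils::read.csv(paths$clinical, stringsAsFactors = FALSE)
  mg <- stats::setNames(clinical$mg, clinical$tumor_sample)
  side <- stats::setNames(clinical$side, clinical$tumor_sample)
  surv_tab <- data.frame(sample = clinical$tumor_sample, mg = clinical$mg,
                         os_months = clinical$os_months,
                         os_event = clinical$os_event,
                         stringsAsFactors = FALSE)

  ## ---- ingest -------------------------------------------------------------
  if (config$stages$ingest) {
    results$protein <- run_stage("ingest", function()
      ingest_batches(paths$protein_batches, "protein", thr))
    pm <- results$protein
    emit(data.frame(feature = rownames(pm$values),
                    as.data.frame(pm$values), check.names = FALSE),
         "protein_matrix.tsv")
    emit_json(list(stage = pm$stage, notes = pm$note,
                   batch_map = as.list(pm$batch)),
              "protein_matrix_provenance.json")
    if (!is.null(paths$phospho_batches) && length(paths$phospho_batches) &&
        all(file.exists(paths$phospho_batches))) {
      results$phospho <- ingest_batches(paths$phospho_batches, "phospho", thr)
      emit(data.frame(feature = rownames(results$phospho$values),
                      as.data.frame(results$phospho$values),
                      check.names = FALSE),
           "phospho_matrix.tsv")
    }
  }

  ## ---- association --------------------------------------------------------
  if (config$stages$associate) {
    if (is.null(results$protein))
      stopf("stage 'associate' needs the ingest stage")
    results$groups <- run_stage("associate", function()
      dichotomize_mg(surv_tab, method = "max_logrank",
                     minprop = thr$minprop, n_perm = config$n_perm,
                     seed = derive_seed(config$seed, 11L)))
    results$screen <- spearman_screen(results$protein, mg,
                                      alpha = thr$alpha,
                                      min_pairs = thr$min_pairs)
    emit(results$screen, "protein_mg_screen.tsv")
    results$stratified <- stratified_screen(results$protein, mg, side,
                                            alpha = thr$alpha,
                                            min_pairs = thr$min_pairs)
    emit_json(lapply(results$stratified$overlap, function(o)
      c(o["counts"], lapply(o[seq_len(3)], identity))),
      "stratified_overlap.json")
    if (!is.null(results$phospho)) {
      results$phospho_screen <- protein_adjusted_phospho_screen(
        results$phospho, results$protein, mg, alpha = thr$alpha,
        min_pairs = thr$min_pairs)
      emit(results$phospho_screen, "phospho_mg_screen.tsv")
    }
    emit(data.frame(sample = names(results$groups$labels),
                    group = unname(results$groups$labels)),
         "mg_group_labels.csv")
  }

  ## ---- somatic ------------------------------------------------------------
  if (config$stages$somatic) {
    if (is.null(results$groups))
      stopf("stage 'somatic' needs the associate stage")
    results$somatic <- run_stage("somatic", function() {
      maf <- read_maf(paths$maf)
      samples <- sort(unique(maf$Tumor_Sample_Barcode))
      hf <- hypermutation_filter(maf, samples,
                                 tmb_threshold = thr$tmb_threshold,
                                 exome_mb = thr$exome_mb)
      lengths <- utils::read.delim(paths$gene_lengths,
                                   stringsAsFactors = FALSE)
      maf_f <- gene_size_filter(maf, lengths)
      maf_f <- maf_f[maf_f$Tumor_Sample_Barcode %in% hf$retained, ,
                     drop = FALSE]
      labels <- label_mg(results$groups, mg[hf$retained])
      screen <- fisher_gene_screen(maf_f, labels, alpha = thr$alpha)
      list(tmb = hf$tmb, exclusions = hf$excluded, retained = hf$retained,
           frequency = mutation_frequency(maf_f, hf$retained),
           screen = screen,
           spectrum = snv_class_summary(maf_f, hf$retained, labels),
           interactions = somatic_interactions(maf_f, hf$retained))
    })
    emit(results$somatic$screen, "gene_fisher_screen.tsv")
    emit(results$somatic$spectrum, "snv_spectrum.tsv")
    emit(results$somatic$interactions, "somatic_interactions.tsv")
    emit_json(list(tmb = as.list(results$somatic$tmb),
                   excluded = results$somatic$exclusions),
              "hypermutation_report.json")
  }

  ## ---- survival -----------------------------------------------------------
  if (config$stages$survive) {
    results$survival <- run_stage("survive", function() {
      groups <- results$groups %||%
        dichotomize_mg(surv_tab, method = "median")
      lab <- groups$labels[surv_tab$sample]
      lr <- logrank_test(surv_tab$os_months, surv_tab$os_event, lab)
      km <- lapply(split(surv_tab, lab), function(d)
        km_estimate(d$os_months, d$os_event))
      cox <- cox_fit(surv_tab$os_months, surv_tab$os_event,
                     matrix(as.numeric(scale(surv_tab$mg)),
                            dimnames = list(NULL, "mg_z")))
      list(groups = groups, logrank = lr, km = km, cox = cox)
    })
    for (g in names(results$survival$km))
      emit(as.data.frame(results$survival$km[[g]]),
           sprintf("km_%s.tsv", gsub("[^A-Za-z0-9]", "_", g)))
    emit_json(list(
      logrank = results$survival$logrank[c("statistic", "df", "p")],
      cox = list(coef = as.list(results$survival$cox$coef),
                 hr = as.list(stats::setNames(results$survival$cox$hr,
                                              names(results$survival$cox$coef))),
                 converged = results$survival$cox$converged),
      cutpoint = if (!is.null(results$survival$groups$cutpoint))
        results$survival$groups$cutpoint[c("threshold", "max_stat", "p",
                                           "n_low", "n_high")]),
      "survival_summary.json")
  }

  ## ---- enrichment ---------------------------------------------------------
  if (config$stages$enrich) {
    if (is.null(results$screen))
      stopf("stage 'enrich' needs the associate stage")
    results$enrichment <- run_stage("enrich", function() {
      sets <- read_gmt(paths$gmt)
      sc <- results$screen[results$screen$tested, ]
      ranked <- stats::setNames(sc$rho, sc$feature)
      gsea <- preranked_gsea(ranked, sets, n_perm = config$n_perm,
                             seed = derive_seed(config$seed, 13L))
      hits <- sc$feature[sc$significant]
      ora <- if (length(hits))
        ora_hypergeom(hits, sc$feature, sets) else NULL
      list(gsea = gsea, ora = ora)
    })
    emit(results$enrichment$gsea, "gsea_results.tsv")
    if (!is.null(results$enrichment$ora))
      emit(results$enrichment$ora, "ora_results.tsv")
  }

  write_manifest()
  out <- manifest
  attr(out, "results") <- results
  invisible(out)
}
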