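# End-to-end orchestration: simulate (or load) -> quantify -> call ->
# classify -> secretome -> activity, with TSV outputs and a machine-readable
# summary.

.stage <- function(name, expr) {
  t0 <- Sys.time()
  message(sprintf("[%s] start", name))
  out <- tryCatch(expr, error = function(e)
    stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)), call. = FALSE))
  message(sprintf("[%s] done in %.1f s", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Default pipeline configuration
#'
#' Returns the default configuration list: a \code{simulate} block with the
#' study-scale defaults (476 CAZyme genes in their annotated classes plus
#' 1500 background genes, planted groups 103/29/4/4/1, 3 replicates,
#' dispersion 0.05, library size 2e7), the induction thresholds, classifier
#' and secretome parameters and the activity-curve settings. Any element
#' can be overridden through \code{\link{runPipeline}}'s \code{config}
#' argument or a YAML file with the same structure.
#'
#' @param seed global seed; per-stage seeds are derived from it.
#' @return nested configuration list.
#' @export
defaultPipelineConfig <- function(seed = 1) {
  list(
    seed = seed,
    simulate = list(
      n_per_class = c(GH = 258, CE = 52, AA = 57, PL = 6, GT = 97,
                      `CBM-only` = 6, `non-CAZyme` = 1500),
      group_sizes = c(CS_CONTROLLED = 103, XYR1_SPECIFIC = 29,
                      OTHER_SPECIFIC = 4, XYR1_CS_CO = 4, OTHER_CS_CO = 1),
      n_reps = 3, dispersion = 0.05, library_size_mean = 2e7),
    thresholds = list(min_abs_log2fc = 2, max_p = 0.01, min_expr = 2,
                      pseudocount = 1),
    classifier = list(expr_floor = 2, level_ratio_min = 2, level_p = 0.01),
    secretome = list(noise_cv = 0.2, n_reps = 3, enrich_fold = 1.9,
                     enrich_p = 0.01, ratio_cap = 1000, high_cutoff_pct = 1),
    activity = list(plateau_U = 3.84, rate = 0.5, t_mid = 8.2))
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) the data, quantifies RPKM, calls induction,
#' classifies regulatory groups, compares the secretomes and summarizes the
#' activity kinetics. Writes all intermediate tables and a
#' \code{summary.json} to \code{out_dir}. Stage progress goes to stderr;
#' any stage error aborts with a stage-named message.
#'
#' @param config configuration list (see
#'   \code{\link{defaultPipelineConfig}}) or path to a YAML file with the
#'   same structure; missing entries take their defaults. Instead of a
#'   \code{simulate} block the config may carry an \code{inputs} block with
#'   paths (counts, annotation, design, peptides, protein_annotation,
#'   activity).
#' @param out_dir output directory (created if missing); NULL for none.
#' @param seed overrides the config seed when given.
#' @return (invisibly) a list with the summary plus the main intermediate
#'   objects (experiment, calls, assignments, enrichment, ...).
#' @export
runPipeline <- function(config = list(), out_dir = NULL, seed = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- utils::modifyList(defaultPipelineConfig(), config)
  if (!is.null(seed)) cfg$seed <- seed
  if (!is.null(out_dir) && !dir.exists(out_dir))
    dir.create(out_dir, recursive = TRUE)
  emit <- function(obj, file, writer = .writeTSV) {
    if (!is.null(out_dir)) writer(obj, file.path(out_dir, file))
  }

  sim <- is.null(config$inputs)
  if (sim) {
    s <- cfg$simulate
    sim_out <- .stage("simulate", {
      ann <- generateAnnotation(unlist(s$n_per_class), seed = .childSeed(cfg$seed, 1))
      des <- generateDesign(s$n_reps)
      arch <- plantArchitecture(ann, unlist(s$group_sizes),
                                seed = .childSeed(cfg$seed, 2),
                                dispersion = s$dispersion)
      list(ann = ann, des = des, arch = arch,
           x = simulateCounts(arch, des, s$library_size_mean,
                              seed = .childSeed(cfg$seed, 3), annotation = ann))
    })
    ann <- sim_out$ann; des <- sim_out$des; arch <- sim_out$arch; x <- sim_out$x
    truth <- defaultSecretomeTruth(seed = .childSeed(cfg$seed, 4))
    pep <- simulateSecretome(truth, cfg$secretome$noise_cv,
                             cfg$secretome$n_reps,
                             seed = .childSeed(cfg$seed, 5))
    act <- simulateActivity(cfg$activity$plateau_U, cfg$activity$rate,
                            cfg$activity$t_mid,
                            seed = .childSeed(cfg$seed, 6))
    prot_ann <- truth[, c("protein_id", "functional_group", "is_cazyme")]
    emit(ann, "annotation.tsv"); emit(des, "design.tsv")
    emit(data.frame(gene_id = geneIds(arch), true_group = unname(trueGroups(arch))),
         "truth.tsv")
    emit(assay(x, "counts"), "counts.tsv", writeCountMatrix)
    emit(pep, "peptides.tsv"); emit(act, "activity.tsv")
  } else {
    p <- config$inputs
    x <- .stage("load", {
      cazymeExperiment(readCountMatrix(p$counts),
                       readGeneAnnotation(p$annotation),
                       readSampleDesign(p$design))
    })
    ann <- geneAnnotation(x)
    pep <- if (!is.null(p$peptides)) readPeptideTable(p$peptides)
    prot_ann <- if (!is.null(p$protein_annotation)) .readTSV(p$protein_annotation)
    act <- if (!is.null(p$activity)) readActivityTable(p$activity)
  }

  x <- .stage("quantify", computeRPKM(x))
  emit(rpkm(x), "rpkm.tsv", writeExpressionMatrix)
  profiles <- summarizeProfiles(x)
  emit(profiles, "profiles.tsv")

  thr <- do.call(inductionThresholds, cfg$thresholds)
  caz_genes <- ann$gene_id[ann$enzyme_class != "non-CAZyme"]
  calls <- .stage("call", callInduction(x, thr, genes = caz_genes))
  emit(calls, "calls.tsv")
  fam <- familyInductionSummary(calls, ann)
  emit(fam, "family_summary.tsv")

  cl <- cfg$classifier
  assignments <- .stage("classify",
    classifyRegulons(x, calls, expr_floor = cl$expr_floor,
                     level_ratio_min = cl$level_ratio_min,
                     level_p = cl$level_p))
  emit(assignments, "regulons.tsv")
  absolute <- absolutelyControlledSet(assignments)
  contain <- containmentSummary(calls)

  enrich <- group_sum <- rel <- NULL
  if (!is.null(pep)) {
    se <- .stage("secretome", medianNormalize(proteinAbundance(pep)))
    rel <- relativeAbundance(se, cfg$secretome$high_cutoff_pct)
    enrich <- enrichmentCall(se, cfg$secretome$enrich_fold,
                             cfg$secretome$enrich_p,
                             ratio_cap = cfg$secretome$ratio_cap)
    emit(enrich, "enrichment.tsv")
    if (!is.null(prot_ann)) {
      group_sum <- groupRatioSummary(enrich, prot_ann)
      emit(group_sum, "group_summary.tsv")
    }
  }

  act_sum <- NULL
  if (!is.null(act)) {
    act_sum <- .stage("activity", {
      mean_curve <- stats::aggregate(activity_U_per_mL ~ time_h, data = act, FUN = mean)
      pf <- plateauFraction(mean_curve$activity_U_per_mL)
      data.frame(time_h = mean_curve$time_h,
                 mean_activity_U_per_mL = mean_curve$activity_U_per_mL,
                 plateau_fraction = pf$fraction)
    })
    emit(act_sum, "activity_summary.tsv")
  }

  group_counts <- as.list(table(factor(assignments$group, levels = .REGULON_GROUPS)))
  summary <- list(
    n_genes_classified = nrow(assignments),
    group_counts = group_counts,
    n_absolutely_controlled = absolute$n,
    pct_absolutely_controlled = classPercent(absolute$n, nrow(assignments), 2),
    containment = contain[c("n_cs_induced", "n_poly_induced",
                            "containment_fraction", "remainder_fraction", "nested")],
    class_induction = stats::setNames(as.list(fam$percent), fam$enzyme_class),
    enrichment_counts = if (!is.null(enrich)) as.list(table(enrich$class)),
    high_abundance = if (!is.null(rel))
      lapply(stats::setNames(nm = .SECRETOME_CONDITIONS), function(cc)
        sum(rel$per_condition[[paste0("high_", cc)]])),
    activity = if (!is.null(act_sum))
      list(plateau_fraction_9h = act_sum$plateau_fraction[act_sum$time_h == 9],
           plateau_fraction_16h = act_sum$plateau_fraction[act_sum$time_h == 16]))
  if (!is.null(out_dir))
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(summary = summary, experiment = x, calls = calls,
                 profiles = profiles, assignments = assignments,
                 family_summary = fam, absolute = absolute,
                 containment = contain, enrichment = enrich,
                 group_summary = group_sum, relative = rel,
                 activity_summary = act_sum))
}
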