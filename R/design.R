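#' Panel-design options
#'
#' All tunable thresholds of the design pipeline in one validated list;
#' unknown option names are rejected. Defaults are the published cut-offs:
#' fold change 1.5, p 0.1, individual difference 10, aggregate/module
#' response 10\%, top 10 modules per aggregate, at most 3 sets per aggregate,
#' abundance median 50, correlation r 0.5 at p 0.05, at most 4 genes per set,
#' 176 test and 8 housekeeping genes.
#'
#' @param ... name = value overrides of the defaults listed above.
#' @return named list of options.
#' @export
designOptions <- function(...) {
  opts <- list(
    fcGroup = 1.5, pGroup = 0.1, fcIndiv = 1.5, diffIndiv = 10,
    oneSample = FALSE, logTransform = FALSE, adjust = FALSE,
    aggregateThreshold = 10, aggregateRule = "any_module",
    topK = 10, cutHeight = 0.5, maxSets = 3, singletonRule = "primary",
    minMedian = 50, rMin = 0.5, pMax = 0.05, leaveOneOut = TRUE,
    maxPerSet = 4, relaxedMinMedian = 10,
    targetTestSize = 176, targetHKSize = 8,
    hkPrior = 4, hkLowCV = 2, hkLiterature = 2)
  over <- list(...)
  unknown <- setdiff(names(over), names(opts))
  if (length(unknown))
    stop("unknown option(s): ", paste(unknown, collapse = ", "))
  opts[names(over)] <- over
  opts
}

#' Run the full panel-design pipeline
#'
#' Chains fingerprint computation, aggregate selection, cross-cohort module
#' set delineation, the staggered gene screen, panel supplementation and
#' housekeeping selection, with a per-stage audit report. All thresholds come
#' from [designOptions()] and are echoed into the report.
#'
#' @param rep a [ModuleRepertoire-class].
#' @param mesCounts counts-platform [ModuleExpressionSet-class] (primary
#'   cohort).
#' @param mesIntensity intensity-platform [ModuleExpressionSet-class].
#' @param annotations literature annotation data.frame
#'   ([literatureScore()]).
#' @param priorPanel,literatureHK housekeeping source gene lists
#'   ([selectHousekeeping()]).
#' @param referenceCounts,referenceIntensity reference (postpartum) timepoint
#'   label per cohort.
#' @param pregnancyCounts,pregnancyIntensity pregnancy timepoints used for
#'   aggregate selection, ranking and clustering; default: every
#'   non-reference timepoint.
#' @param options a [designOptions()] list.
#' @param outDir when non-NULL, per-stage TSV/JSON outputs are written there.
#' @return list with \code{panel} (a [PanelDesign-class]), \code{records},
#'   \code{core}, \code{supplements}, \code{housekeeping},
#'   \code{assignment}, \code{profileCounts}, \code{profileIntensity} and
#'   \code{report}.
#' @export
runDesign <- function(rep, mesCounts, mesIntensity, annotations,
                      priorPanel, literatureHK,
                      referenceCounts, referenceIntensity,
                      pregnancyCounts = NULL, pregnancyIntensity = NULL,
                      options = designOptions(), outDir = NULL) {
  stopifnot(platform(mesCounts) == "counts",
            platform(mesIntensity) == "intensity")
  thr <- responseThresholds(options$fcGroup, options$pGroup,
                            options$fcIndiv, options$diffIndiv)

  profileA <- moduleResponseProfile(mesCounts, rep, referenceCounts, thr,
                                    oneSample = options$oneSample,
                                    logTransform = options$logTransform,
                                    adjust = options$adjust)
  profileB <- moduleResponseProfile(mesIntensity, rep, referenceIntensity, thr,
                                    oneSample = options$oneSample,
                                    logTransform = options$logTransform,
                                    adjust = options$adjust)

  assignment <- delineateModuleSets(
    profileA, profileB, rep,
    timepointsA = pregnancyCounts, timepointsB = pregnancyIntensity,
    threshold = options$aggregateThreshold, topK = options$topK,
    cutHeight = options$cutHeight, maxSets = options$maxSets,
    aggregateRule = options$aggregateRule,
    singletonRule = options$singletonRule)
  retained <- assignment@audit$retainedAggregates
  excludedAggs <- setdiff(aggregateIds(rep), retained)

  records <- scoreGenes(assignment, rep, mesCounts, mesIntensity, annotations,
                        minMedian = options$minMedian, rMin = options$rMin,
                        pMax = options$pMax,
                        leaveOneOut = options$leaveOneOut)
  sel <- selectGenesPerSet(records, maxPerSet = options$maxPerSet)
  records <- sel$records

  aggregatePool <- NULL
  if (length(excludedAggs)) {
    aggs <- moduleAggregates(rep)
    mods <- names(aggs)[aggs %in% excludedAggs]
    genes <- unique(unlist(moduleGenes(rep)[mods], use.names = FALSE))
    gs1 <- gs1AbundanceFilter(mesCounts, genes,
                              minMedian = options$relaxedMinMedian)
    lit <- literatureScore(annotations, genes)
    geneAgg <- stats::setNames(rep(aggs[mods], lengths(moduleGenes(rep)[mods])),
                               unlist(moduleGenes(rep)[mods], use.names = FALSE))
    aggregatePool <- data.frame(gene_id = genes,
                                aggregate_id = unname(geneAgg[genes]),
                                median_count = unname(gs1$medians[genes]),
                                lit_score = unname(lit[genes]),
                                stringsAsFactors = FALSE)
  }

  supplements <- supplementPanel(sel$core, records, aggregatePool,
                                 emptySets = sel$emptySets,
                                 shortSets = sel$shortSets,
                                 targetTestSize = options$targetTestSize,
                                 relaxedMinMedian = options$relaxedMinMedian)
  housekeeping <- selectHousekeeping(mesCounts, mesIntensity, priorPanel,
                                     literatureHK,
                                     nPrior = options$hkPrior,
                                     nLowCV = options$hkLowCV,
                                     nLiterature = options$hkLiterature)
  panel <- assemblePanel(sel$core, supplements, housekeeping,
                         targetTestSize = options$targetTestSize,
                         targetHKSize = options$targetHKSize)

  fates <- table(factor(records$fate,
                        levels = c("excluded_gs1", "excluded_gs2",
                                   "selected", "not_ranked")))
  setTab <- setTable(assignment)
  report <- list(
    n_aggregates = nAggregates(rep),
    retained_aggregates = length(retained),
    excluded_aggregates = length(excludedAggs),
    n_module_sets = nrow(unique(setTab[setTab$set_label != "NS",
                                       c("aggregate_id", "set_label")])),
    candidates = nrow(records),
    excluded_gs1 = unname(fates[["excluded_gs1"]]),
    excluded_gs2 = unname(fates[["excluded_gs2"]]),
    survivors = unname(fates[["selected"]] + fates[["not_ranked"]]),
    selected_core = unname(fates[["selected"]]),
    not_ranked = unname(fates[["not_ranked"]]),
    empty_sets = length(sel$emptySets),
    short_sets = length(sel$shortSets),
    supplements = nrow(supplements),
    supplements_by_source = as.list(table(supplements$source)),
    test_genes = nrow(panelGenes(panel)),
    housekeeping_genes = nrow(housekeepingGenes(panel)),
    panel_total = nrow(panelGenes(panel)) + nrow(housekeepingGenes(panel)),
    options = options)

  if (!is.null(outDir)) {
    dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
    writePanel(panel, file.path(outDir, "panel.tsv"))
    utils::write.table(records, file.path(outDir, "gene_scores.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    writeModuleSets(assignment, file.path(outDir, "module_sets.tsv"))
    utils::write.table(responseTable(profileA),
                       file.path(outDir, "responses_counts.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(responseTable(profileB),
                       file.path(outDir, "responses_intensity.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    for (cmp in unique(responseTable(profileA)$comparison))
      writeFingerprintGrid(fingerprintGrid(profileA, rep, cmp),
                           file.path(outDir, sprintf("grid_counts_%s.tsv", cmp)))
    jsonlite::write_json(report, file.path(outDir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(panel = panel, records = records, core = sel$core,
       supplements = supplements, housekeeping = housekeeping,
       assignment = assignment, profileCounts = profileA,
       profileIntensity = profileB, report = report)
}
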