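# shared in-code fixtures; nothing is read from disk

# 3 modules in 2 aggregates
miniRepertoire <- function() {
  suppressWarnings(ModuleRepertoire(
    modules = list(M1.1 = c("GA", "GB", "GC"),
                   M1.2 = c("GD", "GE"),
                   M2.1 = c("GF", "GG", "GH", "GI")),
    aggregates = c(M1.1 = "A1", M1.2 = "A1", M2.1 = "A2")))
}

# quick expression-set builder around a matrix and a timepoint vector
makeMes <- function(mat, timepoints, platform = "intensity",
                    cohort = "TEST", subjects = NULL,
                    timepointLevels = unique(timepoints)) {
  if (is.null(colnames(mat)))
    colnames(mat) <- sprintf("S%02d", seq_len(ncol(mat)))
  if (is.null(subjects)) subjects <- colnames(mat)
  ModuleExpressionSet(
    mat,
    data.frame(sample_id = colnames(mat), subject_id = subjects,
               timepoint = timepoints, cohort = cohort,
               stringsAsFactors = FALSE),
    platform = platform, timepointLevels = timepointLevels)
}

# call table for a set of genes with given calls
makeCalls <- function(genes, calls) {
  data.frame(gene_id = genes, call = calls, stringsAsFactors = FALSE)
}

# hand-built group-level response profile from a modules x timepoints matrix
makeProfile <- function(responses, rep, cohort = "TEST", reference = "PP") {
  rows <- do.call(rbind, lapply(colnames(responses), function(tp) {
    data.frame(module_id = rownames(responses),
               aggregate_id = unname(moduleAggregates(rep)[rownames(responses)]),
               comparison = tp,
               n_genes = lengths(moduleGenes(rep))[rownames(responses)],
               pct_up = pmax(responses[, tp], 0),
               pct_down = pmax(-responses[, tp], 0),
               response = responses[, tp],
               stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  new("ModuleResponseProfile", table = rows, cohort = cohort,
      reference = reference, mode = "group")
}

# small full-study configuration (6 aggregates, 36 modules, 8-gene modules)
miniStudyConfig <- function(seed = 11, ...) {
  simulationConfig(seed = seed, nAggregates = 6, nModules = 36,
                   genesPerModule = 8, activeAggregates = 4,
                   setSplit = c(4, 2), ...)
}

miniStudyPipeline <- function(study, ...) {
  runDesign(study$repertoire, study$counts, study$intensity,
            study$annotations, study$priorPanel, study$literatureHK,
            referenceCounts = "P2", referenceIntensity = "PP",
            pregnancyCounts = c("T1", "T2", "T3", "D"),
            pregnancyIntensity = c("WG16", "WG23", "WG31", "WG40"),
            ...)
}

# brute-force partition meet: same block iff same cluster in BOTH partitions
bruteMeet <- function(partA, partB) {
  mods <- names(partA)
  groups <- list()
  for (m in mods) {
    placed <- FALSE
    for (i in seq_along(groups)) {
      ref <- groups[[i]][1]
      if (partA[[m]] == partA[[ref]] && partB[[m]] == partB[[ref]]) {
        groups[[i]] <- c(groups[[i]], m); placed <- TRUE; break
      }
    }
    if (!placed) groups[[length(groups) + 1]] <- m
  }
  lapply(groups, sort, method = "radix")
}
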