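#' Test-gene capacity of the validation chip layout
#'
#' The validation assay runs each sample on \code{chips} microfluidics chips
#' of \code{wells} assay wells each, with \code{hkWells} wells per chip
#' reserved for the (identical) housekeeping genes; the remaining wells carry
#' test transcripts.
#'
#' @param wells assay wells per chip (default 96).
#' @param hkWells housekeeping wells per chip (default 8).
#' @param chips chips per sample (default 2).
#' @return number of available test-gene slots.
#' @examples
#' panelCapacity()  # 2 x (96 - 8) = 176
#' @export
panelCapacity <- function(wells = 96, hkWells = 8, chips = 2) {
  stopifnot(wells > hkWells, hkWells >= 0, chips >= 1)
  chips * (wells - hkWells)
}

# shared ranking for supplementation: literature profile first, then
# expression magnitude, then gene id
.supplementOrder <- function(df) {
  df[order(-df$lit_score, -df$median_count, df$gene_id, method = "radix"), ,
     drop = FALSE]
}

#' Supplement the core selection up to the target panel size
#'
#' Adds to the per-set core selection (i) one representative gene per module
#' aggregate excluded by the aggregate filter, (ii) one gene per module set
#' for which no gene qualified, then (iii) tops up with additional genes from
#' the sets that did not reach the per-set cap, until \code{targetTestSize}
#' test genes are reached. Supplements are ranked by literature score, then
#' median count, then gene id, among genes passing a relaxed abundance gate
#' (\code{relaxedMinMedian}); genes already chosen are never duplicated.
#'
#' @param core core selection data.frame from [selectGenesPerSet()].
#' @param records score records ([scoreGenes()]), used as the supplement pool
#'   for empty and short sets.
#' @param aggregatePool data.frame (\code{gene_id}, \code{aggregate_id},
#'   \code{median_count}, \code{lit_score}) of candidate genes for the
#'   excluded aggregates.
#' @param emptySets,shortSets set keys from [selectGenesPerSet()].
#' @param targetTestSize total number of test genes to reach (default 176).
#' @param relaxedMinMedian relaxed abundance gate for supplements
#'   (default 10).
#' @return data.frame (\code{gene_id}, \code{source}, \code{detail}) of the
#'   supplements; an error is raised when the pool cannot reach (or
#'   overshoots) the target.
#' @export
supplementPanel <- function(core, records, aggregatePool = NULL,
                            emptySets = character(), shortSets = character(),
                            targetTestSize = 176, relaxedMinMedian = 10) {
  chosen <- core$gene_id
  supp <- list()
  addOne <- function(pool, source, detail) {
    pool <- pool[!pool$gene_id %in% chosen &
                 !is.na(pool$median_count) &
                 pool$median_count >= relaxedMinMedian, , drop = FALSE]
    if (!nrow(pool))
      stop("no supplement candidate available for ", source, " ", detail)
    g <- .supplementOrder(pool)$gene_id[1L]
    chosen <<- c(chosen, g)
    supp[[length(supp) + 1L]] <<- data.frame(gene_id = g, source = source,
                                             detail = detail,
                                             stringsAsFactors = FALSE)
  }

  if (!is.null(aggregatePool) && nrow(aggregatePool))
    for (a in .strSort(unique(aggregatePool$aggregate_id)))
      addOne(aggregatePool[aggregatePool$aggregate_id == a, ],
             "excluded_aggregate", a)
  for (key in .strSort(emptySets))
    addOne(records[records$set_key == key, ], "empty_set", key)

  total <- length(chosen)
  if (total < targetTestSize) {
    pool <- records[records$set_key %in% shortSets &
                    records$fate != "selected" &
                    !records$gene_id %in% chosen &
                    !is.na(records$median_count) &
                    records$median_count >= relaxedMinMedian, , drop = FALSE]
    pool <- .supplementOrder(pool)
    pool <- pool[!duplicated(pool$gene_id), , drop = FALSE]
    need <- targetTestSize - total
    if (nrow(pool) < need)
      stop(sprintf("supplement pool short by %d gene(s) of the %d target",
                   need - nrow(pool), targetTestSize))
    extra <- utils::head(pool, need)
    supp[[length(supp) + 1L]] <- data.frame(gene_id = extra$gene_id,
                                            source = "extra",
                                            detail = extra$set_key,
                                            stringsAsFactors = FALSE)
    chosen <- c(chosen, extra$gene_id)
  }
  if (length(chosen) != targetTestSize)
    stop(sprintf("core + mandatory supplements hold %d genes but the target is %d",
                 length(chosen), targetTestSize))
  out <- if (length(supp)) do.call(rbind, supp) else
    data.frame(gene_id = character(), source = character(),
               detail = character(), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Per-gene coefficient of variation
#'
#' \%CV = 100 x sd / mean per gene over all samples of a dataset; genes with
#' non-positive mean get NA.
#'
#' @param mes a [ModuleExpressionSet-class].
#' @return named numeric vector of percent CVs.
#' @export
percentCV <- function(mes) {
  m <- assay(mes)
  mu <- rowMeans(m)
  sd <- sqrt(.rowVars(m))
  ifelse(mu > 0, 100 * sd / mu, NA_real_)
}

#' Select the housekeeping genes
#'
#' Fills the housekeeping slots from three sources, in order: the first
#' \code{nPrior} genes of a previously validated panel that are present in
#' both datasets; the \code{nLowCV} genes (present in both datasets, not yet
#' chosen) with the lowest mean percent coefficient of variation across the
#' two datasets; and the first \code{nLiterature} literature-reported
#' stable genes not yet chosen. Any source falling short is a hard error
#' naming the source.
#'
#' @param mesA,mesB the two cohort datasets.
#' @param priorPanel ordered gene ids of the prior housekeeping panel.
#' @param literatureHK ordered literature-based housekeeping gene ids.
#' @param nPrior,nLowCV,nLiterature slot counts (defaults 4, 2, 2).
#' @return data.frame (\code{gene_id}, \code{source}) with
#'   \code{nPrior + nLowCV + nLiterature} rows.
#' @export
selectHousekeeping <- function(mesA, mesB, priorPanel, literatureHK,
                               nPrior = 4, nLowCV = 2, nLiterature = 2) {
  common <- intersect(rownames(assay(mesA)), rownames(assay(mesB)))
  prior <- priorPanel[priorPanel %in% common]
  if (length(prior) < nPrior)
    stop("prior panel supplies only ", length(prior),
         " usable gene(s); ", nPrior, " required")
  prior <- utils::head(prior, nPrior)

  cv <- (percentCV(mesA)[common] + percentCV(mesB)[common]) / 2
  cand <- setdiff(common[!is.na(cv[common])], c(prior, literatureHK))
  if (length(cand) < nLowCV)
    stop("low-CV source supplies only ", length(cand),
         " usable gene(s); ", nLowCV, " required")
  low <- cand[order(cv[cand], cand, method = "radix")]
  low <- utils::head(low, nLowCV)

  lit <- literatureHK[literatureHK %in% common &
                      !literatureHK %in% c(prior, low)]
  if (length(lit) < nLiterature)
    stop("literature source supplies only ", length(lit),
         " usable gene(s); ", nLiterature, " required")
  lit <- utils::head(lit, nLiterature)

  data.frame(gene_id = c(prior, low, lit),
             source = c(rep("prior_panel", nPrior), rep("low_cv", nLowCV),
                        rep("literature", nLiterature)),
             stringsAsFactors = FALSE)
}

#' Assemble the final panel
#'
#' Combines the core per-set selections, the supplements and the
#' housekeeping genes into a validated [PanelDesign-class] (exact target
#' sizes, no duplicated gene anywhere).
#'
#' @param core core selection from [selectGenesPerSet()].
#' @param supplements supplement data.frame from [supplementPanel()].
#' @param housekeeping housekeeping data.frame from [selectHousekeeping()].
#' @param targetTestSize,targetHKSize panel size targets (defaults 176, 8).
#' @return a [PanelDesign-class].
#' @export
assemblePanel <- function(core, supplements, housekeeping,
                          targetTestSize = 176, targetHKSize = 8) {
  test <- rbind(
    data.frame(gene_id = core$gene_id, source = "core",
               detail = core$set_key, stringsAsFactors = FALSE),
    supplements[, c("gene_id", "source", "detail")])
  rownames(test) <- NULL
  methods::new("PanelDesign", test = test,
               housekeeping = housekeeping[, c("gene_id", "source")],
               targetTestSize = as.integer(targetTestSize),
               targetHKSize = as.integer(targetHKSize))
}

#' Write a panel design as TSV
#'
#' One row per transcript: \code{gene_id}, \code{role} (test or
#' housekeeping), \code{source} and \code{detail}. Output is deterministic:
#' two runs on identical inputs produce byte-identical files.
#'
#' @param design a [PanelDesign-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writePanel <- function(design, path) {
  t <- panelGenes(design)
  h <- housekeepingGenes(design)
  out <- rbind(
    data.frame(gene_id = t$gene_id, role = "test", source = t$source,
               detail = t$detail, stringsAsFactors = FALSE),
    data.frame(gene_id = h$gene_id, role = "housekeeping", source = h$source,
               detail = "", stringsAsFactors = FALSE))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
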