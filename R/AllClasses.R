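#' @import methods
#' @importFrom S4Vectors DataFrame metadata
#' @importFrom SummarizedExperiment SummarizedExperiment assay colData
NULL

# locale-independent ordering used for every tie-break in the package
.strOrder <- function(x, ...) order(x, ..., method = "radix")
.strSort <- function(x) sort(x, method = "radix")

## ---------------------------------------------------------------------------
## ModuleRepertoire
## ---------------------------------------------------------------------------

#' Fixed transcriptional module repertoire
#'
#' A \code{ModuleRepertoire} holds a fixed, reusable mapping of genes to
#' co-expression modules, of modules to module aggregates, and of modules to
#' positions on a 2-D fingerprint grid (one row per aggregate). The repertoire
#' is "fixed" in the sense that it is defined once and re-applied unchanged to
#' any number of expression datasets.
#'
#' @slot modules named list; one character vector of gene identifiers per
#'   module, named by module id. Gene ids are opaque, case-sensitive strings.
#' @slot aggregates named character vector mapping module id to aggregate id;
#'   every module belongs to exactly one aggregate.
#' @slot grid data.frame with columns \code{module_id}, \code{aggregate_id},
#'   \code{row} (aggregate index) and \code{col} (position within the row).
#'
#' @seealso [loadRepertoire()], [repertoireStats()], [simulateRepertoire()]
#' @export
setClass("ModuleRepertoire",
         slots = c(modules = "list", aggregates = "character",
                   grid = "data.frame"))

setValidity("ModuleRepertoire", function(object) {
  msg <- character()
  mods <- object@modules
  ids <- names(mods)
  if (is.null(ids) || anyNA(ids) || any(ids == ""))
    msg <- c(msg, "all modules must be named")
  if (anyDuplicated(ids))
    msg <- c(msg, sprintf("duplicate module id(s): %s",
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  empty <- ids[lengths(mods) == 0L]
  if (length(empty))
    msg <- c(msg, sprintf("empty gene list for module(s): %s",
                          paste(empty, collapse = ", ")))
  dup <- ids[vapply(mods, anyDuplicated, 0L) > 0L]
  if (length(dup))
    msg <- c(msg, sprintf("duplicated gene ids within module(s): %s",
                          paste(dup, collapse = ", ")))
  if (!setequal(names(object@aggregates), ids) ||
      length(object@aggregates) != length(ids))
    msg <- c(msg, "aggregate assignment must cover every module exactly once")
  g <- object@grid
  need <- c("module_id", "aggregate_id", "row", "col")
  if (!all(need %in% names(g))) {
    msg <- c(msg, "grid must have columns module_id, aggregate_id, row, col")
  } else {
    if (!setequal(g$module_id, ids) || nrow(g) != length(ids))
      msg <- c(msg, "grid must have exactly one row per module")
    if (anyDuplicated(g[, c("row", "col")]))
      msg <- c(msg, "grid positions must be unique per module")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ModuleRepertoire
#'
#' @param modules named list of character gene-id vectors, one per module.
#' @param aggregates named character vector: module id -> aggregate id.
#' @param grid optional layout data.frame (\code{module_id}, \code{aggregate_id},
#'   \code{row}, \code{col}). When \code{NULL}, a layout is derived
#'   deterministically: rows follow the order in which aggregates first appear
#'   in \code{aggregates}, and within a row modules keep their order in
#'   \code{modules}.
#'
#' @return a validated [ModuleRepertoire-class] object.
#' @examples
#' rep <- ModuleRepertoire(
#'   modules = list(M1.1 = c("GA", "GB"), M1.2 = c("GC"), M2.1 = c("GD", "GE")),
#'   aggregates = c(M1.1 = "A1", M1.2 = "A1", M2.1 = "A2"))
#' nModules(rep)
#' @export
ModuleRepertoire <- function(modules, aggregates, grid = NULL) {
  modules <- lapply(modules, as.character)
  aggregates <- aggregates[names(modules)]
  if (is.null(grid)) {
    aggLevels <- unique(unname(aggregates))
    row <- match(unname(aggregates), aggLevels)
    col <- stats::ave(seq_along(row), row, FUN = seq_along)
    grid <- data.frame(module_id = names(modules),
                       aggregate_id = unname(aggregates),
                       row = row, col = col, stringsAsFactors = FALSE)
  }
  dupGenes <- unique(unlist(lapply(modules, unique), use.names = FALSE))
  allGenes <- unlist(modules, use.names = FALSE)
  if (length(allGenes) > length(dupGenes)) {
    shared <- unique(allGenes[duplicated(allGenes)])
    shared <- shared[vapply(shared, function(g)
      sum(vapply(modules, function(m) g %in% m, TRUE)) > 1L, TRUE)]
    if (length(shared))
      warning(sprintf("%d gene(s) appear in more than one module", length(shared)),
              call. = FALSE)
  }
  methods::new("ModuleRepertoire", modules = modules,
               aggregates = aggregates, grid = grid)
}

## ---------------------------------------------------------------------------
## ModuleExpressionSet
## ---------------------------------------------------------------------------

#' Expression dataset for module-repertoire analysis
#'
#' Thin extension of [SummarizedExperiment::SummarizedExperiment] carrying a
#' genes x samples matrix of already-normalized expression values together
#' with the per-sample annotations the panel-design pipeline needs
#' (\code{sample_id}, \code{subject_id}, \code{timepoint}, \code{cohort}).
#' The \code{timepoint} column is an ordered factor whose levels fix the
#' chronological order of the study visits.
#'
#' @slot platform either \code{"counts"} (sequencing-like; values are
#'   normalized counts, non-negative) or \code{"intensity"} (array-like;
#'   background-subtracted normalized intensities).
#' @slot normalization free-text label of the normalization already applied.
#' @export
setClass("ModuleExpressionSet",
         contains = "SummarizedExperiment",
         slots = c(platform = "character", normalization = "character"))

setValidity("ModuleExpressionSet", function(object) {
  msg <- character()
  if (!object@platform %in% c("counts", "intensity"))
    msg <- c(msg, "platform must be 'counts' or 'intensity'")
  cd <- colData(object)
  need <- c("sample_id", "subject_id", "timepoint", "cohort")
  miss <- setdiff(need, names(cd))
  if (length(miss))
    msg <- c(msg, sprintf("colData is missing column(s): %s",
                          paste(miss, collapse = ", ")))
  if (ncol(object) > 0 && "cohort" %in% names(cd) &&
      length(unique(cd$cohort)) > 1L)
    msg <- c(msg, "all samples of one dataset must share a cohort")
  if ("timepoint" %in% names(cd) && anyNA(cd$timepoint))
    msg <- c(msg, "missing timepoint labels are not allowed")
  m <- assay(object)
  if (anyNA(m) || any(!is.finite(m)))
    msg <- c(msg, "expression values must be finite")
  else if (object@platform == "counts" && any(m < 0))
    msg <- c(msg, "counts-platform values must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a ModuleExpressionSet
#'
#' @param matrix numeric genes x samples matrix with gene ids as rownames and
#'   sample ids as colnames.
#' @param samples data.frame with one row per column of \code{matrix} and
#'   columns \code{sample_id}, \code{subject_id}, \code{timepoint},
#'   \code{cohort} (rows are matched to the matrix by \code{sample_id}).
#' @param platform \code{"counts"} or \code{"intensity"}.
#' @param normalization label of the normalization already applied.
#' @param timepointLevels chronological order of timepoint labels; defaults to
#'   the order of first appearance in \code{samples$timepoint}.
#'
#' @return a validated [ModuleExpressionSet-class].
#' @export
ModuleExpressionSet <- function(matrix, samples, platform,
                                normalization = "none",
                                timepointLevels = NULL) {
  matrix <- as.matrix(matrix)
  samples <- as.data.frame(samples)
  stopifnot(!is.null(colnames(matrix)), !is.null(rownames(matrix)))
  idx <- match(colnames(matrix), samples$sample_id)
  if (anyNA(idx))
    stop("sample sheet is missing sample(s): ",
         paste(colnames(matrix)[is.na(idx)], collapse = ", "))
  samples <- samples[idx, , drop = FALSE]
  if (is.null(timepointLevels))
    timepointLevels <- unique(as.character(samples$timepoint))
  samples$timepoint <- factor(as.character(samples$timepoint),
                              levels = timepointLevels, ordered = TRUE)
  se <- SummarizedExperiment(assays = list(exprs = matrix),
                             colData = DataFrame(samples, row.names = samples$sample_id))
  methods::new("ModuleExpressionSet", se,
               platform = platform, normalization = normalization)
}

## ---------------------------------------------------------------------------
## BaselineSpec
## ---------------------------------------------------------------------------

#' Per-gene baseline reference
#'
#' Per-gene arithmetic mean of normalized expression over the samples of the
#' reference (postpartum) timepoint; every differential-expression call in the
#' fingerprint is made against these values.
#'
#' @slot referenceTimepoint label of the reference timepoint.
#' @slot values named numeric vector of per-gene reference means.
#' @slot nSamples number of reference samples averaged.
#' @export
setClass("BaselineSpec",
         slots = c(referenceTimepoint = "character", values = "numeric",
                   nSamples = "integer"))

setValidity("BaselineSpec", function(object) {
  if (object@nSamples < 1L) return("reference sample set is non-empty")
  if (is.null(names(object@values))) return("values must be named by gene")
  TRUE
})

## ---------------------------------------------------------------------------
## ModuleResponseProfile
## ---------------------------------------------------------------------------

#' Module percent-response profile
#'
#' For each (module, comparison) pair: the percentage of constitutive genes
#' called up (\code{pct_up}) and down (\code{pct_down}) versus the baseline,
#' and the signed net response \code{response = pct_up - pct_down}, bounded in
#' [-100, +100] (+100 means every constitutive transcript increased, -100
#' every one decreased).
#'
#' @slot table data.frame with columns \code{module_id}, \code{aggregate_id},
#'   \code{comparison}, \code{n_genes}, \code{pct_up}, \code{pct_down},
#'   \code{response}.
#' @slot cohort cohort label the profile was computed on.
#' @slot reference reference timepoint label.
#' @slot mode \code{"group"} or \code{"individual"}.
#' @export
setClass("ModuleResponseProfile",
         slots = c(table = "data.frame", cohort = "character",
                   reference = "character", mode = "character"))

setValidity("ModuleResponseProfile", function(object) {
  t <- object@table
  need <- c("module_id", "aggregate_id", "comparison", "n_genes",
            "pct_up", "pct_down", "response")
  if (!all(need %in% names(t)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (nrow(t)) {
    if (any(t$pct_up < 0 | t$pct_down < 0 | t$pct_up + t$pct_down > 100 + 1e-9))
      return("pct_up/pct_down must be non-negative and sum to at most 100")
    if (any(abs(t$response) > 100 + 1e-9))
      return("response must lie in [-100, +100]")
  }
  if (!object@mode %in% c("group", "individual"))
    return("mode must be 'group' or 'individual'")
  TRUE
})

## ---------------------------------------------------------------------------
## ModuleSetAssignment
## ---------------------------------------------------------------------------

#' Module set assignment
#'
#' Result of cross-cohort module-set delineation: per aggregate, the labelled
#' sets S1..Sk of consistently co-clustering modules (ordered by decreasing
#' size) plus the NS bucket of non-co-clustered modules.
#'
#' @slot table data.frame with columns \code{aggregate_id}, \code{set_label}
#'   (\code{"S1"}, \code{"S2"}, ... or \code{"NS"}) and \code{module_id}.
#' @slot maxSets maximum number of labelled sets allowed per aggregate.
#' @slot audit per-aggregate list of the two cohort partitions that produced
#'   the assignment (for audit trails).
#' @export
setClass("ModuleSetAssignment",
         slots = c(table = "data.frame", maxSets = "integer", audit = "list"))

setValidity("ModuleSetAssignment", function(object) {
  t <- object@table
  need <- c("aggregate_id", "set_label", "module_id")
  if (!all(need %in% names(t)))
    return(paste("table must have columns:", paste(need, collapse = ", ")))
  if (nrow(t)) {
    if (anyDuplicated(t$module_id))
      return("a module may appear in exactly one set (or NS)")
    if (!all(grepl("^S[0-9]+$|^NS$", t$set_label)))
      return("set labels must be S<k> or NS")
    nlab <- tapply(t$set_label, t$aggregate_id,
                   function(x) length(setdiff(unique(x), "NS")))
    if (any(nlab > object@maxSets))
      return(sprintf("no aggregate may have more than %d labelled sets",
                     object@maxSets))
  }
  TRUE
})

## ---------------------------------------------------------------------------
## PanelDesign
## ---------------------------------------------------------------------------

#' Assembled targeted panel
#'
#' Final panel of test transcripts (core per-set selections plus
#' supplements) and housekeeping genes.
#'
#' @slot test data.frame with columns \code{gene_id}, \code{source}
#'   (\code{"core"}, \code{"excluded_aggregate"}, \code{"empty_set"},
#'   \code{"extra"}) and \code{detail} (the set key or aggregate the gene
#'   represents).
#' @slot housekeeping data.frame with columns \code{gene_id} and \code{source}
#'   (\code{"prior_panel"}, \code{"low_cv"}, \code{"literature"}).
#' @slot targetTestSize,targetHKSize the configured panel sizes.
#' @export
setClass("PanelDesign",
         slots = c(test = "data.frame", housekeeping = "data.frame",
                   targetTestSize = "integer", targetHKSize = "integer"))

setValidity("PanelDesign", function(object) {
  msg <- character()
  if (nrow(object@test) != object@targetTestSize)
    msg <- c(msg, sprintf("panel holds %d test genes but target is %d",
                          nrow(object@test), object@targetTestSize))
  if (nrow(object@housekeeping) != object@targetHKSize)
    msg <- c(msg, sprintf("panel holds %d HK genes but target is %d",
                          nrow(object@housekeeping), object@targetHKSize))
  all_g <- c(object@test$gene_id, object@housekeeping$gene_id)
  if (anyDuplicated(all_g))
    msg <- c(msg, sprintf("duplicated gene(s) in panel: %s",
                          paste(unique(all_g[duplicated(all_g)]), collapse = ", ")))
  if (length(msg)) msg else TRUE
})
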