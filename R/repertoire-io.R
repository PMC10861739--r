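#' Load a module repertoire from GMT + metadata files
#'
#' Reads the gene-set side of a repertoire from a standard GMT file (one
#' tab-separated line per module: id, description, gene ids) and the
#' aggregate/layout side from a 3-column TSV (\code{module_id},
#' \code{aggregate_id}, \code{grid_position}). GMT carries no aggregate slot,
#' hence the split into two files.
#'
#' Validation is strict: duplicated module ids, modules present in the GMT but
#' absent from the metadata, and empty gene lists are hard errors naming the
#' offending module. Genes occurring in more than one module are allowed with
#' a warning.
#'
#' @param genesetPath path to the GMT file.
#' @param metadataPath path to the module-metadata TSV.
#' @return a validated [ModuleRepertoire-class].
#' @seealso [writeRepertoire()], [repertoireStats()]
#' @export
loadRepertoire <- function(genesetPath, metadataPath) {
  modules <- fgsea::gmtPathways(genesetPath)
  ids <- names(modules)
  if (anyDuplicated(ids))
    stop("duplicate module id(s) in GMT: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  empty <- ids[vapply(modules, function(g) length(g[g != "" & !is.na(g)]) == 0L, TRUE)]
  if (length(empty))
    stop("empty gene list for module(s): ", paste(empty, collapse = ", "))
  modules <- lapply(modules, function(g) g[g != "" & !is.na(g)])

  meta <- utils::read.delim(metadataPath, stringsAsFactors = FALSE)
  need <- c("module_id", "aggregate_id", "grid_position")
  if (!all(need %in% names(meta)))
    stop("metadata TSV must have columns: ", paste(need, collapse = ", "))
  missing <- setdiff(ids, meta$module_id)
  if (length(missing))
    stop("module(s) in GMT missing from metadata: ",
         paste(missing, collapse = ", "))
  meta <- meta[match(ids, meta$module_id), ]

  aggLevels <- unique(meta$aggregate_id)
  grid <- data.frame(module_id = meta$module_id,
                     aggregate_id = meta$aggregate_id,
                     row = match(meta$aggregate_id, aggLevels),
                     col = meta$grid_position,
                     stringsAsFactors = FALSE)
  aggregates <- stats::setNames(meta$aggregate_id, meta$module_id)
  ModuleRepertoire(modules, aggregates, grid)
}

#' Write a module repertoire to GMT + metadata files
#'
#' Inverse of [loadRepertoire()]; a save/load round trip reproduces the
#' repertoire bit-exact on all identifiers.
#'
#' @param rep a [ModuleRepertoire-class].
#' @param genesetPath,metadataPath output paths.
#' @return invisibly, the two paths.
#' @export
writeRepertoire <- function(rep, genesetPath, metadataPath) {
  lines <- vapply(moduleIds(rep), function(m)
    paste(c(m, "na", moduleGenes(rep, m)), collapse = "\t"), "")
  writeLines(lines, genesetPath)
  g <- gridLayout(rep)
  meta <- data.frame(module_id = g$module_id, aggregate_id = g$aggregate_id,
                     grid_position = g$col, stringsAsFactors = FALSE)
  utils::write.table(meta, metadataPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(genesetPath, metadataPath))
}

#' Summary statistics of a repertoire
#'
#' @param rep a [ModuleRepertoire-class].
#' @return list with \code{n_modules}, \code{n_aggregates} and the named
#'   integer vector \code{genes_per_module}.
#' @export
repertoireStats <- function(rep) {
  stopifnot(methods::is(rep, "ModuleRepertoire"))
  list(n_modules = nModules(rep),
       n_aggregates = nAggregates(rep),
       genes_per_module = lengths(moduleGenes(rep)))
}

#' Read an expression dataset from TSV files
#'
#' The expression TSV has gene ids in the first column and one column per
#' sample; the sample sheet TSV has columns \code{sample_id},
#' \code{subject_id}, \code{timepoint}, \code{cohort} and \code{platform}
#' (identical for all rows).
#'
#' @param exprPath path to the expression matrix TSV.
#' @param samplesPath path to the sample-sheet TSV.
#' @param normalization label of the normalization applied upstream.
#' @param timepointLevels chronological timepoint order; defaults to order of
#'   first appearance in the sample sheet.
#' @return a [ModuleExpressionSet-class].
#' @export
readExpressionDataset <- function(exprPath, samplesPath,
                                  normalization = "precomputed",
                                  timepointLevels = NULL) {
  ex <- utils::read.delim(exprPath, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(ex[, -1, drop = FALSE])
  rownames(m) <- ex[[1]]
  sheet <- utils::read.delim(samplesPath, stringsAsFactors = FALSE)
  platform <- unique(sheet$platform)
  if (length(platform) != 1L)
    stop("sample sheet must declare a single platform")
  ModuleExpressionSet(m, sheet[, c("sample_id", "subject_id", "timepoint", "cohort")],
                      platform = platform, normalization = normalization,
                      timepointLevels = timepointLevels)
}

#' Write an expression dataset to TSV files
#'
#' @param mes a [ModuleExpressionSet-class].
#' @param exprPath,samplesPath output paths.
#' @return invisibly, the two paths.
#' @export
writeExpressionDataset <- function(mes, exprPath, samplesPath) {
  m <- assay(mes)
  df <- data.frame(gene_id = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, exprPath, sep = "\t", quote = FALSE, row.names = FALSE)
  sheet <- sampleSheet(mes)
  sheet$platform <- platform(mes)
  utils::write.table(sheet, samplesPath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(exprPath, samplesPath))
}
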