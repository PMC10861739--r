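#' Per-timepoint mean expression trajectories
#'
#' Mean expression per gene per timepoint (across the samples of that
#' timepoint), in chronological timepoint order. These trajectories — over
#' pregnancy and postpartum visits alike — are what the correlation screen
#' compares to the module-set mean.
#'
#' @param mes a [ModuleExpressionSet-class].
#' @return numeric genes x timepoints matrix.
#' @export
geneTrajectories <- function(mes) {
  tp <- as.character(colData(mes)$timepoint)
  lv <- timepointLevels(mes)
  m <- assay(mes)
  out <- vapply(lv, function(l) rowMeans(m[, tp == l, drop = FALSE]),
                numeric(nrow(m)))
  dimnames(out) <- list(rownames(m), lv)
  out
}

#' GS1: whole-blood abundance filter
#'
#' Excludes candidate genes whose median normalized count over all samples of
#' the counts cohort is below \code{minMedian}; a median of exactly
#' \code{minMedian} passes. Only the counts platform carries interpretable
#' absolute abundance, so this screen runs on that cohort alone.
#'
#' @param mesCounts the counts-platform [ModuleExpressionSet-class].
#' @param candidates candidate gene ids.
#' @param minMedian abundance cut-off (default 50).
#' @return list with \code{passed} (character), \code{excluded} (data.frame
#'   \code{gene_id}, \code{median_count}, \code{reason}) and \code{medians}
#'   (named numeric over all candidates, NA when absent).
#' @export
gs1AbundanceFilter <- function(mesCounts, candidates, minMedian = 50) {
  if (platform(mesCounts) != "counts")
    stop("GS1 abundance filtering requires the counts platform")
  m <- assay(mesCounts)
  present <- candidates[candidates %in% rownames(m)]
  absent <- setdiff(candidates, present)
  med <- apply(m[present, , drop = FALSE], 1, stats::median)
  medians <- stats::setNames(rep(NA_real_, length(candidates)), candidates)
  medians[present] <- med
  passed <- present[med >= minMedian]
  exc <- data.frame(
    gene_id = c(present[med < minMedian], absent),
    median_count = c(med[med < minMedian], rep(NA_real_, length(absent))),
    reason = c(sprintf("median count %g < %g", med[med < minMedian], minMedian),
               rep("absent", length(absent))),
    row.names = NULL, stringsAsFactors = FALSE)
  list(passed = passed, excluded = exc, medians = medians)
}

# Pearson r with two-sided p from the t distribution on n-2 df;
# stats::cor.test is the oracle for this in the test suite
.corP <- function(x, y) {
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    return(c(r = NA_real_, p = NA_real_))
  r <- stats::cor(x, y)
  n <- length(x)
  tt <- r * sqrt((n - 2) / max(1 - r^2, .Machine$double.eps))
  c(r = r, p = 2 * stats::pt(-abs(tt), n - 2))
}

#' GS2: correlation of a gene with its module-set mean
#'
#' Pearson correlation between the gene's per-timepoint mean-expression
#' trajectory and the mean trajectory of all constitutive genes of the set's
#' modules. By default the gene under evaluation is left out of the set mean
#' to avoid self-correlation inflation.
#'
#' @param mes a [ModuleExpressionSet-class].
#' @param gene the gene id to score.
#' @param setModules module ids making up the module set.
#' @param rep the [ModuleRepertoire-class].
#' @param leaveOneOut exclude the gene from the set mean (default TRUE).
#' @return named numeric \code{c(r =, p =)}; NA for a zero-variance
#'   trajectory.
#' @export
gs2Correlation <- function(mes, gene, setModules, rep, leaveOneOut = TRUE) {
  traj <- geneTrajectories(mes)
  genes <- unique(unlist(moduleGenes(rep)[setModules], use.names = FALSE))
  miss <- setdiff(c(gene, genes), rownames(traj))
  if (length(miss))
    stop("gene(s) absent from the dataset: ", paste(miss, collapse = ", "))
  .gs2FromTraj(traj, gene, genes, leaveOneOut)
}

.gs2FromTraj <- function(traj, gene, setGenes, leaveOneOut = TRUE) {
  x <- traj[gene, ]
  others <- if (leaveOneOut) setdiff(setGenes, gene) else setGenes
  if (!length(others)) others <- gene   # single-gene set: compare to itself
  y <- colMeans(traj[others, , drop = FALSE])
  .corP(x, y)
}

#' R score: average per-cohort correlation
#'
#' Arithmetic mean of a gene's per-cohort Pearson correlations with its
#' module-set mean; e.g. r of 0.8 and 0.6 in the two cohorts gives an R score
#' of 0.7.
#'
#' @param rByCohort numeric vector of per-cohort r values (all cohorts
#'   required; no NA).
#' @return the R score.
#' @export
rScore <- function(rByCohort) {
  if (length(rByCohort) < 1L || anyNA(rByCohort))
    stop("r values are required for every cohort")
  mean(rByCohort)
}

#' GS3: literature score
#'
#' Scores a gene's literature association with pregnancy from a pre-computed
#' annotation table (one row per gene with hits; the search string used is
#' kept as provenance): 2 points when the gene symbol occurred in a title,
#' 1 when only in an abstract, 0 otherwise (including genes with no row).
#'
#' @param annotations data.frame with columns \code{gene_id},
#'   \code{title_hit}, \code{abstract_hit} (logical or 0/1).
#' @param genes gene ids to score.
#' @return named integer vector of scores in \{0, 1, 2\}.
#' @export
literatureScore <- function(annotations, genes) {
  idx <- match(genes, annotations$gene_id)
  title <- as.logical(annotations$title_hit[idx])
  abstr <- as.logical(annotations$abstract_hit[idx])
  score <- ifelse(!is.na(title) & title, 2L,
                  ifelse(!is.na(abstr) & abstr, 1L, 0L))
  stats::setNames(as.integer(score), genes)
}

#' Score every candidate gene of the delineated module sets
#'
#' Runs the staggered screen over all genes of the labelled (non-NS) module
#' sets: GS1 abundance on the counts cohort, GS2 correlation with the set
#' mean in both cohorts (exclusion when r < \code{rMin} or p > \code{pMax}
#' in either cohort), and the GS3 literature score; the final score is
#' literature score + R score. Genes surviving GS1 and GS2 carry fate
#' \code{"survivor"} until [selectGenesPerSet()] resolves them to
#' \code{"selected"} or \code{"not_ranked"}.
#'
#' @param assignment a [ModuleSetAssignment-class].
#' @param rep the [ModuleRepertoire-class].
#' @param mesCounts,mesIntensity the two cohort datasets.
#' @param annotations literature annotation data.frame (see
#'   [literatureScore()]).
#' @param minMedian GS1 cut-off (default 50).
#' @param rMin,pMax GS2 cut-offs (defaults 0.5 and 0.05).
#' @param leaveOneOut passed to the set-mean computation (default TRUE).
#' @return data.frame of gene score records, one row per (gene, set).
#' @export
scoreGenes <- function(assignment, rep, mesCounts, mesIntensity, annotations,
                       minMedian = 50, rMin = 0.5, pMax = 0.05,
                       leaveOneOut = TRUE) {
  t <- setTable(assignment)
  t <- t[t$set_label != "NS", , drop = FALSE]
  setKeys <- unique(paste(t$aggregate_id, t$set_label, sep = "/"))
  trajA <- geneTrajectories(mesCounts)
  trajB <- geneTrajectories(mesIntensity)

  rows <- lapply(.strSort(setKeys), function(key) {
    sub <- t[paste(t$aggregate_id, t$set_label, sep = "/") == key, ]
    genes <- .strSort(unique(unlist(moduleGenes(rep)[sub$module_id],
                                    use.names = FALSE)))
    gs1 <- gs1AbundanceFilter(mesCounts, genes, minMedian)
    lit <- literatureScore(annotations, genes)
    rec <- data.frame(gene_id = genes, set_key = key,
                      aggregate_id = sub$aggregate_id[1L],
                      set_label = sub$set_label[1L],
                      median_count = unname(gs1$medians[genes]),
                      r_counts = NA_real_, p_counts = NA_real_,
                      r_intensity = NA_real_, p_intensity = NA_real_,
                      r_score = NA_real_, lit_score = unname(lit[genes]),
                      final_score = NA_real_,
                      fate = "excluded_gs1", fate_reason = "",
                      stringsAsFactors = FALSE)
    exIdx <- match(gs1$excluded$gene_id, rec$gene_id)
    rec$fate_reason[exIdx] <- gs1$excluded$reason
    for (g in gs1$passed) {
      i <- match(g, rec$gene_id)
      ca <- .gs2FromTraj(trajA, g, intersect(genes, rownames(trajA)), leaveOneOut)
      okB <- g %in% rownames(trajB)
      cb <- if (okB)
        .gs2FromTraj(trajB, g, intersect(genes, rownames(trajB)), leaveOneOut)
      else c(r = NA_real_, p = NA_real_)
      rec$r_counts[i] <- ca[["r"]]; rec$p_counts[i] <- ca[["p"]]
      rec$r_intensity[i] <- cb[["r"]]; rec$p_intensity[i] <- cb[["p"]]
      rs <- c(ca[["r"]], cb[["r"]]); ps <- c(ca[["p"]], cb[["p"]])
      if (anyNA(rs)) {
        rec$fate[i] <- "excluded_gs2"
        rec$fate_reason[i] <- if (!okB) "absent from the intensity cohort"
                              else "constant trajectory"
      } else if (any(rs < rMin) || any(ps > pMax)) {
        rec$fate[i] <- "excluded_gs2"
        rec$fate_reason[i] <- sprintf(
          "r = %.3f/%.3f, p = %.3g/%.3g (needs r >= %g and p <= %g in both cohorts)",
          rs[1], rs[2], ps[1], ps[2], rMin, pMax)
      } else {
        rec$r_score[i] <- rScore(rs)
        rec$final_score[i] <- rec$lit_score[i] + rec$r_score[i]
        rec$fate[i] <- "survivor"
      }
    }
    rec
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Select the top genes of each module set
#'
#' Within each set, ranks the GS1+GS2 survivors by final score (descending;
#' ties by R score, then gene id) and selects at most \code{maxPerSet}.
#' Sets with fewer survivors contribute them all and are flagged short; sets
#' with none are flagged empty. A gene scored in several sets is selected at
#' most once (first set in sorted key order wins).
#'
#' @param records score records from [scoreGenes()].
#' @param maxPerSet per-set selection cap (default 4).
#' @return list with \code{records} (fates resolved to \code{selected} /
#'   \code{not_ranked}), \code{core} (data.frame \code{gene_id},
#'   \code{set_key}), \code{emptySets} and \code{shortSets} (character).
#' @export
selectGenesPerSet <- function(records, maxPerSet = 4) {
  keys <- .strSort(unique(records$set_key))
  chosen <- character()
  coreRows <- list(); emptySets <- character(); shortSets <- character()
  for (key in keys) {
    idx <- which(records$set_key == key & records$fate == "survivor")
    idx <- idx[!records$gene_id[idx] %in% chosen]
    if (!length(idx)) { emptySets <- c(emptySets, key); next }
    ord <- idx[order(-records$final_score[idx], -records$r_score[idx],
                     records$gene_id[idx], method = "radix")]
    take <- utils::head(ord, maxPerSet)
    records$fate[take] <- "selected"
    records$fate[setdiff(ord, take)] <- "not_ranked"
    records$fate_reason[setdiff(ord, take)] <- "below per-set cap"
    chosen <- c(chosen, records$gene_id[take])
    coreRows[[key]] <- data.frame(gene_id = records$gene_id[take],
                                  set_key = key, stringsAsFactors = FALSE)
    if (length(take) < maxPerSet) shortSets <- c(shortSets, key)
  }
  core <- if (length(coreRows)) do.call(rbind, coreRows) else
    data.frame(gene_id = character(), set_key = character(),
               stringsAsFactors = FALSE)
  rownames(core) <- NULL
  list(records = records, core = core,
       emptySets = emptySets, shortSets = shortSets)
}
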