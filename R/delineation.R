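#' Module response trajectories
#'
#' Extracts from a group-level response profile the modules x timepoints
#' matrix of signed percent responses that drives aggregate selection, module
#' ranking and co-clustering. By convention only pregnancy comparisons are
#' used for those steps (the postpartum reference is the baseline itself).
#'
#' @param profile a [ModuleResponseProfile-class] (group mode).
#' @param timepoints comparisons to keep, in order; defaults to all
#'   comparisons present.
#' @return numeric matrix, one row per module.
#' @export
moduleTrajectories <- function(profile, timepoints = NULL) {
  t <- responseTable(profile)
  if (is.null(timepoints)) timepoints <- unique(t$comparison)
  miss <- setdiff(timepoints, t$comparison)
  if (length(miss))
    stop("profile lacks comparison(s): ", paste(miss, collapse = ", "))
  mods <- unique(t$module_id)
  m <- matrix(NA_real_, length(mods), length(timepoints),
              dimnames = list(mods, timepoints))
  for (tp in timepoints) {
    sub <- t[t$comparison == tp, ]
    m[sub$module_id, tp] <- sub$response
  }
  m
}

#' Mean absolute response per module
#'
#' @param traj a trajectory matrix from [moduleTrajectories()].
#' @return named numeric vector of mean |response| over timepoints.
#' @export
avgAbsResponse <- function(traj) rowMeans(abs(traj))

#' Select responsive module aggregates
#'
#' First selection filter: drop aggregates showing no or only modest changes
#' through pregnancy. Two readings of the 10\% cut-off are supported:
#' \code{"any_module"} (default) retains an aggregate when at least one of
#' its constitutive modules has a mean |response| of at least
#' \code{threshold}; \code{"aggregate_mean"} retains it when the mean over
#' its modules of the per-module mean |response| reaches \code{threshold}.
#' When the two rules disagree for an aggregate, the divergence is reported
#' as a message.
#'
#' @param profile group-level [ModuleResponseProfile-class] of the primary
#'   (counts) cohort.
#' @param rep the [ModuleRepertoire-class].
#' @param threshold percent-response cut-off (default 10).
#' @param rule which reading of the cut-off to apply.
#' @param timepoints pregnancy comparisons to average over (default: all in
#'   the profile).
#' @return character vector of retained aggregate ids, in repertoire order.
#' @export
selectAggregates <- function(profile, rep, threshold = 10,
                             rule = c("any_module", "aggregate_mean"),
                             timepoints = NULL) {
  rule <- match.arg(rule)
  avg <- avgAbsResponse(moduleTrajectories(profile, timepoints))
  aggs <- moduleAggregates(rep)
  if (length(setdiff(names(aggs), names(avg))))
    stop("profile does not cover the repertoire")
  byAgg <- split(avg[names(aggs)], unname(aggs))
  anyRule <- vapply(byAgg, function(v) any(v >= threshold), TRUE)
  meanRule <- vapply(byAgg, function(v) mean(v) >= threshold, TRUE)
  div <- names(byAgg)[anyRule != meanRule]
  if (length(div))
    message("aggregate filter rules diverge for: ", paste(.strSort(div), collapse = ", "))
  keep <- names(byAgg)[if (rule == "any_module") anyRule else meanRule]
  intersect(aggregateIds(rep), keep)
}

#' Rank the most responsive modules of an aggregate
#'
#' Keeps the modules with mean |response| strictly above \code{threshold},
#' sorted by decreasing mean |response| (ties broken by module id), truncated
#' to the top \code{k}.
#'
#' @param aggregate an aggregate id.
#' @param traj trajectory matrix of the ranking cohort
#'   ([moduleTrajectories()]).
#' @param rep the [ModuleRepertoire-class].
#' @param k maximum number of modules retained (default 10).
#' @param threshold percent-response qualification cut-off, strict
#'   (default 10).
#' @return character vector of module ids in rank order (possibly empty).
#' @export
rankTopModules <- function(aggregate, traj, rep, k = 10, threshold = 10) {
  aggs <- moduleAggregates(rep)
  mods <- names(aggs)[aggs == aggregate]
  mods <- intersect(mods, rownames(traj))
  if (!length(mods)) return(character())
  avg <- avgAbsResponse(traj[mods, , drop = FALSE])
  qual <- names(avg)[avg > threshold]
  qual <- qual[order(-avg[qual], qual, method = "radix")]
  utils::head(qual, k)
}

#' Hierarchically cluster module trajectories in one cohort
#'
#' Agglomerative clustering of the signed response trajectories with distance
#' 1 - Pearson correlation, average linkage, tree cut at a fixed height.
#' Modules with constant (zero-variance) trajectories have no defined
#' correlation and become singleton clusters with a warning.
#'
#' @param traj trajectory matrix restricted to the modules to cluster.
#' @param modules module ids to cluster (default: all rows of \code{traj}).
#' @param cutHeight tree-cut height on the cophenetic scale (default 0.5).
#' @return named integer vector: module id -> cluster id.
#' @export
clusterModules <- function(traj, modules = rownames(traj), cutHeight = 0.5) {
  traj <- traj[modules, , drop = FALSE]
  n <- nrow(traj)
  if (n == 0L) return(stats::setNames(integer(), character()))
  if (n == 1L) return(stats::setNames(1L, rownames(traj)))
  sds <- apply(traj, 1, stats::sd)
  constant <- rownames(traj)[sds == 0]
  if (length(constant))
    warning("constant trajectory for module(s) ",
            paste(constant, collapse = ", "),
            "; assigned to singleton clusters", call. = FALSE)
  usable <- setdiff(rownames(traj), constant)
  part <- integer()
  if (length(usable) >= 2L) {
    d <- stats::as.dist(1 - stats::cor(t(traj[usable, , drop = FALSE])))
    hc <- stats::hclust(d, method = "average")
    part <- stats::cutree(hc, h = cutHeight)
  } else if (length(usable) == 1L) {
    part <- stats::setNames(1L, usable)
  }
  nxt <- if (length(part)) max(part) else 0L
  if (length(constant))
    part <- c(part, stats::setNames(nxt + seq_along(constant), constant))
  part[modules]
}

.asPartition <- function(p) {
  if (is.list(p)) {
    mods <- unlist(p, use.names = FALSE)
    p <- stats::setNames(rep(seq_along(p), lengths(p)), mods)
  }
  p
}

#' Delineate cross-cohort-consistent module sets
#'
#' Computes the meet of the two cohort partitions: modules are grouped
#' together iff they share a cluster in BOTH cohorts. Meet blocks of two or
#' more modules are candidate sets; a singleton block is a candidate only
#' when the module forms a distinct singleton cluster in the primary cohort
#' (\code{partA}; set \code{singletonRule = "either"} to accept singleton
#' clusters in either cohort). Candidates are ranked by decreasing size (ties
#' by smallest module id) and labelled S1, S2, ... up to \code{maxSets}; all
#' remaining modules fall into the NS (non-co-clustered) bucket.
#'
#' @param partA primary-cohort partition: named integer vector (module ->
#'   cluster) or list of module-id vectors.
#' @param partB second-cohort partition over the same modules.
#' @param maxSets maximum number of labelled sets (default 3).
#' @param singletonRule \code{"primary"} (default) or \code{"either"}.
#' @return list with elements \code{sets} (named list S1, S2, ... of module
#'   ids) and \code{ns} (character vector).
#' @export
delineateSets <- function(partA, partB, maxSets = 3,
                          singletonRule = c("primary", "either")) {
  singletonRule <- match.arg(singletonRule)
  partA <- .asPartition(partA); partB <- .asPartition(partB)
  mods <- names(partA)
  if (!setequal(mods, names(partB)) || length(mods) != length(partB))
    stop("partitions cover different module sets")
  partB <- partB[mods]

  key <- paste(partA, partB, sep = "|")
  blocks <- split(mods, key)
  sizeA <- table(partA); sizeB <- table(partB)
  isCand <- vapply(blocks, function(b) {
    if (length(b) >= 2L) return(TRUE)
    singleA <- sizeA[[as.character(partA[[b]])]] == 1L
    singleB <- sizeB[[as.character(partB[[b]])]] == 1L
    if (singletonRule == "primary") singleA else singleA || singleB
  }, TRUE)
  cand <- blocks[isCand]
  cand <- lapply(cand, .strSort)
  ord <- order(-lengths(cand),
               vapply(cand, function(b) b[[1L]], ""), method = "radix")
  cand <- cand[ord]
  sets <- utils::head(cand, maxSets)
  names(sets) <- if (length(sets)) paste0("S", seq_along(sets)) else character()
  ns <- .strSort(setdiff(mods, unlist(sets, use.names = FALSE)))
  list(sets = sets, ns = ns)
}

#' Delineate module sets across all retained aggregates
#'
#' End-to-end set delineation: select responsive aggregates on the primary
#' cohort, rank each retained aggregate's top modules (primary cohort),
#' cluster their trajectories in each cohort independently, and keep
#' cross-cohort-consistent sets.
#'
#' @param profileA group-level profile of the primary (counts) cohort.
#' @param profileB group-level profile of the second (intensity) cohort.
#' @param rep the [ModuleRepertoire-class].
#' @param timepointsA,timepointsB pregnancy comparisons per cohort (default:
#'   all comparisons in each profile).
#' @param threshold percent-response cut-off for both the aggregate filter
#'   and module qualification (default 10).
#' @param topK maximum modules ranked per aggregate (default 10).
#' @param cutHeight tree-cut height for [clusterModules()] (default 0.5).
#' @param maxSets maximum labelled sets per aggregate (default 3).
#' @param aggregateRule passed to [selectAggregates()].
#' @param singletonRule passed to [delineateSets()].
#' @return a [ModuleSetAssignment-class]; the retained aggregate ids are in
#'   \code{attr(, "retainedAggregates")} of its audit list.
#' @export
delineateModuleSets <- function(profileA, profileB, rep,
                                timepointsA = NULL, timepointsB = NULL,
                                threshold = 10, topK = 10, cutHeight = 0.5,
                                maxSets = 3, aggregateRule = "any_module",
                                singletonRule = "primary") {
  trajA <- moduleTrajectories(profileA, timepointsA)
  trajB <- moduleTrajectories(profileB, timepointsB)
  retained <- selectAggregates(profileA, rep, threshold, aggregateRule,
                               timepointsA)
  rows <- list(); audit <- list()
  for (a in retained) {
    ranked <- rankTopModules(a, trajA, rep, k = topK, threshold = threshold)
    if (!length(ranked)) next
    pA <- clusterModules(trajA, ranked, cutHeight)
    pB <- clusterModules(trajB, ranked, cutHeight)
    d <- delineateSets(pA, pB, maxSets, singletonRule)
    audit[[a]] <- list(ranked = ranked, partitionA = pA, partitionB = pB)
    lab <- c(rep(names(d$sets), lengths(d$sets)),
             rep("NS", length(d$ns)))
    rows[[a]] <- data.frame(aggregate_id = a, set_label = lab,
                            module_id = c(unlist(d$sets, use.names = FALSE), d$ns),
                            stringsAsFactors = FALSE)
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(aggregate_id = character(), set_label = character(),
               module_id = character(), stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  audit$retainedAggregates <- retained
  methods::new("ModuleSetAssignment", table = tab,
               maxSets = as.integer(maxSets), audit = audit)
}

#' Write a module-set assignment as TSV
#'
#' @param assignment a [ModuleSetAssignment-class].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeModuleSets <- function(assignment, path) {
  utils::write.table(setTable(assignment), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
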