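#' Simulation configuration
#'
#' Study conditions for the paired synthetic cohorts. Defaults emulate the
#' reference design: a repertoire of 382 modules in 38 aggregates; a
#' sequencing-like longitudinal cohort with six timepoints (three trimesters,
#' delivery, two postpartum visits) of 15, 15, 15, 15, 13 and 15 samples (88
#' profiles); an array-like cohort with five windows of 38, 37, 37, 35 and 17
#' unpaired samples; 22 of the 38 aggregates carrying planted pregnancy
#' signal, split within each active aggregate into two co-expressed module
#' sets (a declining-then-rebounding shape and a shape peaking in the third
#' trimester) plus null modules; and four planted panel genes per set that
#' track the set mean tightly and carry title-level literature hits.
#'
#' @param seed integer seed; every generator output is a pure function of the
#'   configuration including this seed.
#' @param nAggregates,nModules,genesPerModule repertoire shape (defaults 38,
#'   382, 10; modules are spread evenly over aggregates, remainders going to
#'   the first aggregates).
#' @param activeAggregates number of aggregates with planted signal
#'   (default 22; the remaining aggregates are null and end up excluded by
#'   the aggregate filter).
#' @param setSplit planted set sizes (in modules) within each active
#'   aggregate (default \code{c(5, 3)}; remaining modules are null).
#' @param effectLog2 overall planted effect amplitude in log2 units
#'   (default 1; sized so planted genes clear the 1.5 fold-change gate at the
#'   design sample sizes with high power).
#' @param geneTrackRange range of the per-gene tracking factor (uniform;
#'   default \code{c(0.3, 1.5)}) multiplying the module shape.
#' @param moduleAmpRange per-module amplitude jitter (uniform,
#'   default \code{c(0.85, 1.15)}).
#' @param baselineMeanLog,baselineSdLog log-normal baseline abundance
#'   parameters on the natural-log scale (defaults 6 and 1.5).
#' @param plantedBaselineMin abundance floor for planted panel genes so the
#'   GS1 gate never removes them (default 200).
#' @param dispersion negative-binomial dispersion of the counts platform
#'   (default 0.1).
#' @param intensitySigma log-scale noise sd of the intensity platform
#'   (default 0.2).
#' @param noise global noise multiplier applied to \code{dispersion} and
#'   \code{intensitySigma} (default 1; recovery properties are probed by
#'   raising it).
#' @param plantedPerSet planted panel genes per set (default 4).
#' @param decoyAbstractFraction fraction of non-planted genes given an
#'   abstract-only literature hit (default 0.1).
#' @return a named list of class \code{simulationConfig}.
#' @export
simulationConfig <- function(seed = 1L,
                             nAggregates = 38L, nModules = 382L,
                             genesPerModule = 10L,
                             activeAggregates = 22L,
                             setSplit = c(5L, 3L),
                             effectLog2 = 1,
                             geneTrackRange = c(0.3, 1.5),
                             moduleAmpRange = c(0.85, 1.15),
                             baselineMeanLog = 6, baselineSdLog = 1.5,
                             plantedBaselineMin = 200,
                             dispersion = 0.1, intensitySigma = 0.2,
                             noise = 1,
                             plantedPerSet = 4L,
                             decoyAbstractFraction = 0.1) {
  stopifnot(nAggregates >= 1, nModules >= nAggregates, genesPerModule >= 1,
            activeAggregates <= nAggregates, all(setSplit >= 1),
            sum(setSplit) <= floor(nModules / nAggregates),
            effectLog2 > 0, noise >= 0, dispersion > 0, intensitySigma > 0)
  cfg <- list(
    seed = as.integer(seed),
    nAggregates = as.integer(nAggregates),
    nModules = as.integer(nModules),
    genesPerModule = as.integer(genesPerModule),
    activeAggregates = as.integer(activeAggregates),
    setSplit = as.integer(setSplit),
    effectLog2 = effectLog2,
    geneTrackRange = geneTrackRange,
    moduleAmpRange = moduleAmpRange,
    baselineMeanLog = baselineMeanLog, baselineSdLog = baselineSdLog,
    plantedBaselineMin = plantedBaselineMin,
    dispersion = dispersion, intensitySigma = intensitySigma,
    noise = noise,
    plantedPerSet = as.integer(plantedPerSet),
    decoyAbstractFraction = decoyAbstractFraction,
    # trajectory library: log2 multipliers as functions of pregnancy
    # progress s in (0, 1]; postpartum visits sit at multiplier 0 by
    # construction so the baseline is well defined
    shapes = list(
      down_rebound = function(s) -(0.25 + 0.95 * s),
      up_peak = function(s) 1.3 * ifelse(s <= 0.85, s / 0.85,
                                         1 - 0.5 * (s - 0.85)),
      null = function(s) rep(0, length(s))),
    cohorts = list(
      counts = list(
        cohort = "SIMSEQ", platform = "counts",
        timepoints = c("T1", "T2", "T3", "D", "P1", "P2"),
        n = c(15L, 15L, 15L, 15L, 13L, 15L),
        progress = c(T1 = 0.17, T2 = 0.5, T3 = 0.83, D = 1, P1 = 0, P2 = 0),
        reference = "P2", pregnancy = c("T1", "T2", "T3", "D"),
        longitudinal = TRUE),
      intensity = list(
        cohort = "SIMARR", platform = "intensity",
        timepoints = c("WG16", "WG23", "WG31", "WG40", "PP"),
        n = c(38L, 37L, 37L, 35L, 17L),
        progress = c(WG16 = 0.2, WG23 = 0.45, WG31 = 0.65, WG40 = 0.9, PP = 0),
        reference = "PP", pregnancy = c("WG16", "WG23", "WG31", "WG40"),
        longitudinal = FALSE)))
  class(cfg) <- "simulationConfig"
  cfg
}

#' Simulate a module repertoire
#'
#' Deterministic repertoire of the configured shape: modules
#' \code{M<a>.<i>} spread over aggregates \code{A<a>}, each carrying
#' \code{genesPerModule} genes named \code{M<a>.<i>_g<k>}, plus the
#' housekeeping candidate genes held outside any module.
#'
#' @param cfg a [simulationConfig()].
#' @return a [ModuleRepertoire-class].
#' @export
simulateRepertoire <- function(cfg) {
  stopifnot(inherits(cfg, "simulationConfig"))
  perAgg <- rep(cfg$nModules %/% cfg$nAggregates, cfg$nAggregates)
  extra <- cfg$nModules %% cfg$nAggregates
  if (extra) perAgg[seq_len(extra)] <- perAgg[seq_len(extra)] + 1L
  modules <- list(); aggregates <- character()
  for (a in seq_len(cfg$nAggregates)) {
    for (i in seq_len(perAgg[a])) {
      mid <- sprintf("M%d.%d", a, i)
      modules[[mid]] <- sprintf("%s_g%d", mid, seq_len(cfg$genesPerModule))
      aggregates[mid] <- sprintf("A%d", a)
    }
  }
  ModuleRepertoire(modules, aggregates)
}

# planted ground truth: shapes, sets, panel genes, baselines, tracking
.plantTruth <- function(cfg, rep) {
  set.seed(cfg$seed)
  aggs <- aggregateIds(rep)
  active <- aggs[seq_len(cfg$activeAggregates)]
  modAgg <- moduleAggregates(rep)
  shapeNames <- setdiff(names(cfg$shapes), "null")

  moduleShape <- stats::setNames(rep("null", nModules(rep)), moduleIds(rep))
  setRows <- list(); panelRows <- list()
  for (ai in seq_along(active)) {
    a <- active[ai]
    mods <- names(modAgg)[modAgg == a]
    off <- 0L
    # alternate which shape leads, so both shapes appear as S1 across aggregates
    shapeOrder <- if (ai %% 2L) shapeNames else rev(shapeNames)
    for (si in seq_along(cfg$setSplit)) {
      mem <- mods[off + seq_len(cfg$setSplit[si])]
      off <- off + cfg$setSplit[si]
      moduleShape[mem] <- shapeOrder[(si - 1L) %% length(shapeOrder) + 1L]
      key <- sprintf("%s/S%d", a, si)
      setRows[[key]] <- data.frame(aggregate_id = a,
                                   set_label = sprintf("S%d", si),
                                   module_id = mem, stringsAsFactors = FALSE)
      panelRows[[key]] <- data.frame(
        gene_id = sprintf("%s_g%d", mem[1L], seq_len(cfg$plantedPerSet)),
        set_key = key, stringsAsFactors = FALSE)
    }
  }
  sets <- do.call(rbind, setRows); rownames(sets) <- NULL
  panel <- do.call(rbind, panelRows); rownames(panel) <- NULL

  hk <- list(prior = sprintf("HKP%d", 1:4), lowCV = sprintf("HKLC%d", 1:2),
             literature = sprintf("HKLIT%d", 1:2))
  moduleGenesAll <- unlist(moduleGenes(rep), use.names = FALSE)
  genes <- c(moduleGenesAll, unlist(hk, use.names = FALSE))

  baseline <- stats::setNames(
    stats::rlnorm(length(genes), cfg$baselineMeanLog, cfg$baselineSdLog), genes)
  baseline[panel$gene_id] <- pmax(baseline[panel$gene_id],
                                  cfg$plantedBaselineMin)
  baseline[unlist(hk, use.names = FALSE)] <-
    pmax(baseline[unlist(hk, use.names = FALSE)], 100)

  track <- stats::setNames(
    stats::runif(length(genes), cfg$geneTrackRange[1], cfg$geneTrackRange[2]),
    genes)
  track[panel$gene_id] <- 1
  moduleAmp <- stats::setNames(
    stats::runif(nModules(rep), cfg$moduleAmpRange[1], cfg$moduleAmpRange[2]),
    moduleIds(rep))

  list(activeAggregates = active,
       excludedAggregates = setdiff(aggs, active),
       sets = sets, panelGenes = panel,
       moduleShape = moduleShape, moduleAmp = moduleAmp,
       baseline = baseline, geneTrack = track,
       hk = hk, genes = genes)
}

#' Simulate one cohort
#'
#' Draws a genes x samples dataset under the planted truth: every gene's
#' expected value is its baseline times \code{2^delta}, where \code{delta}
#' is the module's trajectory shape evaluated at the timepoint's pregnancy
#' progress, scaled by the planted effect size, the module amplitude and the
#' per-gene tracking factor (zero for null modules, housekeeping genes and
#' postpartum visits). The counts platform draws negative-binomial counts;
#' the intensity platform multiplies by log-normal noise. The planted low-CV
#' housekeeping genes get near-noiseless draws on both platforms.
#'
#' @param cfg a [simulationConfig()].
#' @param which \code{"counts"} or \code{"intensity"}.
#' @param rep the repertoire from [simulateRepertoire()].
#' @param truth planted truth (from [simulateStudy()]; computed internally
#'   when omitted).
#' @return a [ModuleExpressionSet-class].
#' @export
simulateCohort <- function(cfg, which = c("counts", "intensity"), rep = NULL,
                           truth = NULL) {
  which <- match.arg(which)
  if (is.null(rep)) rep <- simulateRepertoire(cfg)
  if (is.null(truth)) truth <- .plantTruth(cfg, rep)
  dsn <- cfg$cohorts[[which]]
  set.seed(cfg$seed + if (which == "counts") 101L else 202L)

  genes <- truth$genes
  geneMod <- stats::setNames(rep(NA_character_, length(genes)), genes)
  for (m in moduleIds(rep)) geneMod[moduleGenes(rep, m)] <- m

  # per-gene log2 shift at each timepoint
  delta <- matrix(0, length(genes), length(dsn$timepoints),
                  dimnames = list(genes, dsn$timepoints))
  for (tp in dsn$timepoints) {
    s <- dsn$progress[[tp]]
    if (s <= 0) next
    mod <- geneMod[!is.na(geneMod)]
    shp <- truth$moduleShape[mod]
    base <- vapply(names(cfg$shapes), function(nm) cfg$shapes[[nm]](s), 0)
    delta[names(mod), tp] <- cfg$effectLog2 * base[shp] *
      truth$moduleAmp[mod] * truth$geneTrack[names(mod)]
  }

  lowCV <- truth$hk$lowCV
  nTot <- sum(dsn$n)
  mat <- matrix(0, length(genes), nTot, dimnames = list(genes, NULL))
  ids <- character(nTot); subj <- character(nTot); tps <- character(nTot)
  col <- 0L
  for (k in seq_along(dsn$timepoints)) {
    tp <- dsn$timepoints[k]
    mu <- truth$baseline * 2^delta[, tp]
    for (i in seq_len(dsn$n[k])) {
      col <- col + 1L
      if (dsn$platform == "counts") {
        size <- rep(1 / max(cfg$dispersion * cfg$noise, 1e-8), length(genes))
        names(size) <- genes
        size[lowCV] <- 1 / 5e-4
        mat[, col] <- stats::rnbinom(length(genes), mu = mu, size = size)
      } else {
        sigma <- rep(cfg$intensitySigma * cfg$noise, length(genes))
        names(sigma) <- genes
        sigma[lowCV] <- 0.01
        mat[, col] <- mu * exp(stats::rnorm(length(genes), 0, sigma))
      }
      ids[col] <- sprintf("%s_%s_%02d", dsn$cohort, tp, i)
      subj[col] <- if (dsn$longitudinal) sprintf("%s_SUBJ%02d", dsn$cohort, i)
                   else sprintf("%s_%s_SUBJ%02d", dsn$cohort, tp, i)
      tps[col] <- tp
    }
  }
  colnames(mat) <- ids
  samples <- data.frame(sample_id = ids, subject_id = subj, timepoint = tps,
                        cohort = dsn$cohort, stringsAsFactors = FALSE)
  ModuleExpressionSet(mat, samples, platform = dsn$platform,
                      normalization = "simulated",
                      timepointLevels = dsn$timepoints)
}

#' Simulate literature annotations and housekeeping gene lists
#'
#' Planted panel genes receive title-level hits; a configured fraction of the
#' remaining genes receive abstract-only hits; everything else scores 0. The
#' search string emulated by the table is stored as provenance on every row.
#'
#' @param cfg a [simulationConfig()].
#' @param truth planted truth from [simulateStudy()].
#' @return list with \code{annotations} (data.frame \code{gene_id},
#'   \code{title_hit}, \code{abstract_hit}, \code{provenance}),
#'   \code{priorPanel} and \code{literatureHK} (character vectors).
#' @export
simulateAnnotations <- function(cfg, truth) {
  set.seed(cfg$seed + 303L)
  planted <- truth$panelGenes$gene_id
  others <- setdiff(truth$genes, planted)
  nDecoy <- round(cfg$decoyAbstractFraction * length(others))
  decoys <- sort(sample(others, nDecoy))
  ann <- data.frame(
    gene_id = c(planted, decoys),
    title_hit = c(rep(TRUE, length(planted)), rep(FALSE, length(decoys))),
    abstract_hit = c(rep(TRUE, length(planted)), rep(TRUE, length(decoys))),
    provenance = "<gene symbol>[tiab] AND (pregnancy[tiab] OR pregnant[tiab] OR gravid[tiab])",
    stringsAsFactors = FALSE)
  ann <- ann[.strOrder(ann$gene_id), ]
  rownames(ann) <- NULL
  list(annotations = ann, priorPanel = truth$hk$prior,
       literatureHK = truth$hk$literature)
}

#' Simulate a full paired study
#'
#' Generates the repertoire, the planted truth, both cohorts and the
#' literature/housekeeping inputs in one call; deterministic given the
#' configuration.
#'
#' @param cfg a [simulationConfig()].
#' @return list with \code{repertoire}, \code{counts}, \code{intensity},
#'   \code{annotations}, \code{priorPanel}, \code{literatureHK},
#'   \code{truth}.
#' @export
simulateStudy <- function(cfg = simulationConfig()) {
  rep <- simulateRepertoire(cfg)
  truth <- .plantTruth(cfg, rep)
  counts <- simulateCohort(cfg, "counts", rep, truth)
  intensity <- simulateCohort(cfg, "intensity", rep, truth)
  ann <- simulateAnnotations(cfg, truth)
  list(repertoire = rep, counts = counts, intensity = intensity,
       annotations = ann$annotations, priorPanel = ann$priorPanel,
       literatureHK = ann$literatureHK, truth = truth)
}

#' Simulate a candidate pool for the abundance screen
#'
#' Counts-platform pool with a planted number of genes whose median count
#' falls below the abundance gate: low-abundance genes draw around a mean of
#' 10 counts, the rest around 500, so the planted below/above split is
#' recovered exactly by the screen with overwhelming probability.
#'
#' @param nGenes pool size (default 2530).
#' @param nBelow planted sub-threshold genes (default 894).
#' @param nSamples samples drawn (default 88).
#' @param dispersion negative-binomial dispersion (default 0.1).
#' @param seed integer seed.
#' @return list with \code{mes} (a counts [ModuleExpressionSet-class]) and
#'   \code{belowGenes} (character).
#' @export
simulateAbundancePool <- function(nGenes = 2530, nBelow = 894, nSamples = 88,
                                  dispersion = 0.1, seed = 1L) {
  stopifnot(nBelow <= nGenes)
  set.seed(seed)
  genes <- sprintf("CAND%04d", seq_len(nGenes))
  below <- genes[seq_len(nBelow)]
  mu <- ifelse(genes %in% below, 10, 500)
  mat <- matrix(stats::rnbinom(nGenes * nSamples, mu = rep(mu, nSamples),
                               size = 1 / dispersion),
                nGenes, nSamples, dimnames = list(genes, sprintf("S%03d", seq_len(nSamples))))
  samples <- data.frame(sample_id = colnames(mat), subject_id = colnames(mat),
                        timepoint = "T1", cohort = "POOL",
                        stringsAsFactors = FALSE)
  list(mes = ModuleExpressionSet(mat, samples, platform = "counts",
                                 normalization = "simulated"),
       belowGenes = below)
}

#' Simulate a score-record table with planted survivor counts
#'
#' Plants the full gene-screen arithmetic: a candidate pool of
#' \code{nCandidates} genes spread over the module sets, \code{nGs1Excluded}
#' of them below the abundance gate, and exactly \code{survivorsPerSet}
#' GS1+GS2 survivors in each set (sets planted with 0 survivors come out
#' empty). Also returns a supplement pool with one or more candidate genes
#' per excluded aggregate. Used to validate the selection-cap and
#' panel-assembly arithmetic end to end.
#'
#' @param survivorsPerSet integer vector, one entry per module set
#'   (default: 33 sets with 5 survivors — above the cap of 4 — six with 3,
#'   one with 2 and six with 0).
#' @param nCandidates total candidate genes (default 2530).
#' @param nGs1Excluded genes planted below the abundance gate (default 894).
#' @param nExcludedAggregates aggregates dropped by the aggregate filter,
#'   each contributing supplement candidates (default 16).
#' @param seed integer seed.
#' @return list with \code{records}, \code{aggregatePool} (both data.frames)
#'   and \code{truth} (the planted counts).
#' @export
simulateScoreRecords <- function(survivorsPerSet = c(rep(5L, 33), rep(3L, 6),
                                                     2L, rep(0L, 6)),
                                 nCandidates = 2530, nGs1Excluded = 894,
                                 nExcludedAggregates = 16, seed = 1L) {
  nSets <- length(survivorsPerSet)
  nSurv <- sum(survivorsPerSet)
  stopifnot(nGs1Excluded + nSurv <= nCandidates)
  set.seed(seed)

  perSet <- rep(nCandidates %/% nSets, nSets)
  perSet[seq_len(nCandidates %% nSets)] <- perSet[seq_len(nCandidates %% nSets)] + 1L
  gs1PerSet <- rep(nGs1Excluded %/% nSets, nSets)
  gs1PerSet[seq_len(nGs1Excluded %% nSets)] <- gs1PerSet[seq_len(nGs1Excluded %% nSets)] + 1L
  stopifnot(all(gs1PerSet + survivorsPerSet <= perSet))

  keys <- sprintf("A%d/S1", seq_len(nSets))
  rows <- lapply(seq_len(nSets), function(k) {
    n <- perSet[k]
    gene <- sprintf("SET%02d_g%03d", k, seq_len(n))
    fate <- rep("excluded_gs2", n)
    fate[seq_len(gs1PerSet[k])] <- "excluded_gs1"
    if (survivorsPerSet[k] > 0)
      fate[gs1PerSet[k] + seq_len(survivorsPerSet[k])] <- "survivor"
    med <- ifelse(fate == "excluded_gs1", stats::runif(n, 1, 49),
                  stats::runif(n, 60, 5000))
    rA <- ifelse(fate == "survivor", stats::runif(n, 0.7, 0.99),
                 stats::runif(n, -0.2, 0.45))
    rB <- ifelse(fate == "survivor", stats::runif(n, 0.7, 0.99),
                 stats::runif(n, -0.2, 0.45))
    lit <- ifelse(fate == "survivor",
                  sample(0:2, n, replace = TRUE, prob = c(0.2, 0.3, 0.5)),
                  sample(0:1, n, replace = TRUE, prob = c(0.8, 0.2)))
    rs <- ifelse(fate == "survivor", (rA + rB) / 2, NA_real_)
    data.frame(gene_id = gene, set_key = keys[k],
               aggregate_id = sprintf("A%d", k), set_label = "S1",
               median_count = med,
               r_counts = rA, p_counts = ifelse(fate == "survivor", 1e-4, 0.5),
               r_intensity = rB, p_intensity = ifelse(fate == "survivor", 1e-4, 0.5),
               r_score = rs, lit_score = lit,
               final_score = ifelse(fate == "survivor", lit + rs, NA_real_),
               fate = fate, fate_reason = "", stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, rows)
  rownames(records) <- NULL

  aggregatePool <- data.frame(
    aggregate_id = rep(sprintf("AX%d", seq_len(nExcludedAggregates)), each = 3),
    gene_id = sprintf("AGGX%d_g%d",
                      rep(seq_len(nExcludedAggregates), each = 3), 1:3),
    median_count = stats::runif(3 * nExcludedAggregates, 60, 3000),
    lit_score = sample(0:2, 3 * nExcludedAggregates, replace = TRUE),
    stringsAsFactors = FALSE)

  list(records = records, aggregatePool = aggregatePool,
       truth = list(survivorsPerSet = survivorsPerSet,
                    nCandidates = nCandidates, nGs1Excluded = nGs1Excluded,
                    nExcludedAggregates = nExcludedAggregates))
}
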