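test_that("the abundance screen excludes strictly below the median cut-off", {
  m <- rbind(gPass = rep(50, 5), gFail = rep(49, 5), gHigh = rep(500, 5))
  mes <- makeMes(m, rep("T1", 5), platform = "counts")
  gs1 <- gs1AbundanceFilter(mes, rownames(m))
  expect_setequal(gs1$passed, c("gPass", "gHigh"))   # median exactly 50 passes
  expect_equal(gs1$excluded$gene_id, "gFail")
  # all above -> empty excluded set
  expect_equal(nrow(gs1AbundanceFilter(mes, c("gPass", "gHigh"))$excluded), 0)
  # absent candidate excluded with reason
  gs2 <- gs1AbundanceFilter(mes, c("gPass", "gGhost"))
  expect_equal(gs2$excluded$reason, "absent")
  # intensity platform refuses the screen
  expect_error(gs1AbundanceFilter(makeMes(m, rep("T1", 5)), rownames(m)),
               "counts platform")
})

test_that("a calibrated pool reproduces the planted sub-threshold count", {
  pool <- simulateAbundancePool(nGenes = 2530, nBelow = 894, seed = 4)
  gs1 <- gs1AbundanceFilter(pool$mes, rownames(SummarizedExperiment::assay(pool$mes)))
  expect_equal(nrow(gs1$excluded), 894)
  expect_setequal(gs1$excluded$gene_id, pool$belowGenes)
  expect_equal(100 * nrow(gs1$excluded) / 2530, 35.3, tolerance = 0.01)
})

test_that("set-mean correlation matches cor.test and flags degenerate genes", {
  set.seed(51)
  tp <- c("T1", "T2", "T3", "D", "P1", "P2")
  base <- c(100, 80, 60, 50, 95, 100)
  mat <- rbind(gTrack = base,
               gOrtho = c(70, 90, 70, 90, 70, 90),
               gFlat = rep(80, 6),
               m1 = base * 1.1, m2 = base * 0.9, m3 = base + 5)
  mes <- makeMes(mat, tp, timepointLevels = tp)
  rep1 <- suppressWarnings(ModuleRepertoire(
    list(M1 = c("m1", "m2", "m3", "gTrack", "gOrtho", "gFlat")),
    c(M1 = "A1")))
  r <- gs2Correlation(mes, "gTrack", "M1", rep1)
  expect_gt(r[["r"]], 0.95)
  expect_lt(r[["p"]], 0.01)
  # oracle: cor.test on the same trajectories (leave-one-out mean)
  others <- colMeans(mat[c("m1", "m2", "m3", "gOrtho", "gFlat"), ])
  ct <- cor.test(mat["gTrack", ], others)
  expect_equal(unname(r[["r"]]), unname(ct$estimate), tolerance = 1e-12)
  expect_equal(r[["p"]], ct$p.value, tolerance = 1e-12)
  # constant trajectory -> undefined correlation
  expect_true(all(is.na(gs2Correlation(mes, "gFlat", "M1", rep1))))
  # a trajectory uncorrelated with the set mean scores low
  expect_lt(gs2Correlation(mes, "gOrtho", "M1", rep1)[["r"]], 0.5)
  expect_error(gs2Correlation(mes, "gGhost", "M1", rep1), "absent")
})

test_that("a gene tracking the set mean through noise keeps r above 0.9", {
  set.seed(52)
  tp <- sprintf("T%02d", 1:12)
  shape <- seq(50, 160, length.out = 12)
  mat <- do.call(rbind, lapply(1:8, function(i) shape + rnorm(12, 0, 2)))
  rownames(mat) <- sprintf("m%d", 1:8)
  mat <- rbind(mat, gene = shape * (1 + rnorm(12, 0, 0.1)))
  mes <- makeMes(mat, tp, timepointLevels = tp)
  rep1 <- ModuleRepertoire(list(M1 = rownames(mat)), c(M1 = "A1"))
  expect_gt(gs2Correlation(mes, "gene", "M1", rep1)[["r"]], 0.9)
})

test_that("the R score is the arithmetic mean of per-cohort correlations", {
  expect_equal(rScore(c(0.8, 0.6)), 0.7)
  expect_equal(rScore(c(1, 1)), 1)
  expect_equal(rScore(c(0.5, 0.9)), 0.7)
  expect_error(rScore(c(0.8, NA)), "every cohort")
})

test_that("literature scoring is 2 for title, 1 for abstract-only, else 0", {
  ann <- data.frame(gene_id = c("gT", "gA", "gBoth"),
                    title_hit = c(TRUE, FALSE, TRUE),
                    abstract_hit = c(FALSE, TRUE, TRUE))
  sc <- literatureScore(ann, c("gT", "gA", "gBoth", "gNone"))
  expect_equal(unname(sc), c(2L, 1L, 2L, 0L))   # title dominates; no row -> 0
})

test_that("per-set selection caps at four with deterministic tie-breaks", {
  rec <- data.frame(
    gene_id = sprintf("g%d", 1:8),
    set_key = c(rep("A1/S1", 6), rep("A2/S1", 2)),
    median_count = 100, r_score = c(0.9, 0.8, 0.95, 0.7, 0.9, 0.6, 0.8, 0.7),
    lit_score = c(2, 2, 0, 1, 2, 0, 1, 1),
    fate = "survivor", fate_reason = "", stringsAsFactors = FALSE)
  rec$final_score <- rec$lit_score + rec$r_score
  sel <- selectGenesPerSet(rec)
  expect_equal(nrow(sel$core[sel$core$set_key == "A1/S1", ]), 4)
  expect_equal(nrow(sel$core[sel$core$set_key == "A2/S1", ]), 2)
  expect_equal(sel$shortSets, "A2/S1")
  # top of A1/S1 by final score: g1 (2.9), g5 (2.9), g2 (2.8), g4 (1.7)
  expect_setequal(sel$core$gene_id[sel$core$set_key == "A1/S1"],
                  c("g1", "g5", "g2", "g4"))
  # ties on final score resolved by r_score then gene id
  tie <- rec[1:2, ]; tie$gene_id <- c("h2", "h1")
  tie$r_score <- 0.8; tie$final_score <- 2.8; tie$set_key <- "A3/S1"
  selTie <- selectGenesPerSet(rbind(rec, tie), maxPerSet = 1)
  expect_equal(selTie$core$gene_id[selTie$core$set_key == "A3/S1"], "h1")
})

test_that("planted survivor counts give the expected core selection", {
  sim <- simulateScoreRecords(seed = 6)
  sel <- selectGenesPerSet(sim$records)
  expect_equal(nrow(sel$core), 33 * 4 + 6 * 3 + 1 * 2)
  expect_equal(length(sel$emptySets), 6)
  expect_equal(length(sel$shortSets), 7)
})

test_that("every candidate ends with exactly one fate and scores add up", {
  sim <- simulateScoreRecords(seed = 8)
  sel <- selectGenesPerSet(sim$records)
  rec <- sel$records
  expect_equal(nrow(rec), 2530)
  fates <- table(rec$fate)
  expect_setequal(names(fates),
                  c("excluded_gs1", "excluded_gs2", "selected", "not_ranked"))
  expect_equal(sum(fates), 2530)                       # conservation
  expect_equal(unname(fates[["excluded_gs1"]]), 894)
  ok <- rec$fate %in% c("selected", "not_ranked")
  # score algebra: final = literature + R score, R score = mean of cohort r
  expect_equal(rec$final_score[ok], rec$lit_score[ok] + rec$r_score[ok])
  expect_equal(rec$r_score[ok], (rec$r_counts[ok] + rec$r_intensity[ok]) / 2)
})

test_that("tightening any screen threshold never increases survivors", {
  study <- simulateStudy(miniStudyConfig(seed = 14))
  profA <- moduleResponseProfile(study$counts, study$repertoire, "P2")
  profB <- moduleResponseProfile(study$intensity, study$repertoire, "PP")
  asn <- delineateModuleSets(profA, profB, study$repertoire,
                             timepointsA = c("T1", "T2", "T3", "D"),
                             timepointsB = c("WG16", "WG23", "WG31", "WG40"))
  nSurv <- function(...) {
    rec <- scoreGenes(asn, study$repertoire, study$counts, study$intensity,
                      study$annotations, ...)
    sum(rec$fate == "survivor")
  }
  base <- nSurv()
  expect_lte(nSurv(minMedian = 200), nSurv(minMedian = 50))
  expect_lte(nSurv(rMin = 0.8), base)
  expect_lte(nSurv(pMax = 0.01), base)
  # GS1 monotonicity directly
  genes <- rownames(SummarizedExperiment::assay(study$counts))
  expect_lte(length(gs1AbundanceFilter(study$counts, genes, 100)$passed),
             length(gs1AbundanceFilter(study$counts, genes, 50)$passed))
})

test_that("planted tracking genes with title hits are the per-set picks", {
  study <- simulateStudy(miniStudyConfig(seed = 15))
  profA <- moduleResponseProfile(study$counts, study$repertoire, "P2")
  profB <- moduleResponseProfile(study$intensity, study$repertoire, "PP")
  asn <- delineateModuleSets(profA, profB, study$repertoire,
                             timepointsA = c("T1", "T2", "T3", "D"),
                             timepointsB = c("WG16", "WG23", "WG31", "WG40"))
  rec <- scoreGenes(asn, study$repertoire, study$counts, study$intensity,
                    study$annotations)
  sel <- selectGenesPerSet(rec)
  planted <- study$truth$panelGenes
  recovered <- mean(planted$gene_id %in% sel$core$gene_id)
  expect_gte(recovered, 0.95)
})
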