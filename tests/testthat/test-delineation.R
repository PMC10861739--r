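test_that("aggregate selection supports both readings of the 10% cut-off", {
  rep <- suppressWarnings(ModuleRepertoire(
    modules = list(M1.1 = "a", M1.2 = "b", M1.3 = "c",
                   M2.1 = "d", M2.2 = "e", M2.3 = "f"),
    aggregates = c(M1.1 = "A1", M1.2 = "A1", M1.3 = "A1",
                   M2.1 = "A2", M2.2 = "A2", M2.3 = "A2")))
  # A1 modules at {12, 2, 2}%, A2 all zero
  resp <- matrix(c(12, 2, 2, 0, 0, 0), 6, 2,
                 dimnames = list(moduleIds(rep), c("T1", "T2")))
  prof <- makeProfile(resp, rep)
  # zero aggregate dropped under both rules
  expect_false("A2" %in% selectAggregates(prof, rep))
  expect_false("A2" %in% suppressMessages(
    selectAggregates(prof, rep, rule = "aggregate_mean")))
  # {12, 2, 2}: retained by any-module, dropped by aggregate-mean (5.33 < 10)
  expect_message(keepAny <- selectAggregates(prof, rep), "diverge.*A1")
  expect_true("A1" %in% keepAny)
  expect_false("A1" %in% suppressMessages(
    selectAggregates(prof, rep, rule = "aggregate_mean")))
})

test_that("planted above-threshold aggregates are recovered exactly", {
  study <- simulateStudy(simulationConfig(seed = 21))
  prof <- moduleResponseProfile(study$counts, study$repertoire, "P2")
  keep <- selectAggregates(prof, study$repertoire,
                           timepoints = c("T1", "T2", "T3", "D"))
  expect_setequal(keep, study$truth$activeAggregates)
  expect_length(keep, 22)
})

test_that("module ranking filters strictly, sorts and truncates with ties by id", {
  mods <- sprintf("M1.%d", 1:12)
  rep <- suppressWarnings(ModuleRepertoire(
    modules = setNames(as.list(letters[1:12]), mods),
    aggregates = setNames(rep("A1", 12), mods)))
  avg <- c(50, 45, 40, 35, 30, 25, 20, 18, 16, 14, 12, 11)
  traj <- matrix(avg, 12, 2, dimnames = list(mods, c("T1", "T2")))
  top <- rankTopModules("A1", traj, rep)
  expect_length(top, 10)                       # 12 qualify, truncated to 10
  expect_equal(top[1], "M1.1")
  expect_false(any(c("M1.11", "M1.12") %in% top))
  # 3 qualifying -> all 3 in rank order; exactly 10 is not strict enough
  traj2 <- traj; traj2[4:12, ] <- 10
  expect_equal(rankTopModules("A1", traj2, rep), mods[1:3])
  # ties broken lexicographically by module id
  traj3 <- traj; traj3[1:2, ] <- 15; traj3[3:12, ] <- 0
  expect_equal(rankTopModules("A1", traj3, rep), c("M1.1", "M1.2"))
})

test_that("trajectory clustering groups by correlation and isolates constants", {
  base <- c(10, 30, 60, 80)
  traj <- rbind(m1 = base, m2 = base + rnorm(4, 0, 0.01),
                m3 = -base, m4 = -base + rnorm(4, 0, 0.01))
  p <- clusterModules(traj)
  expect_equal(p[["m1"]], p[["m2"]])           # identical -> one cluster
  expect_equal(p[["m3"]], p[["m4"]])
  expect_false(p[["m1"]] == p[["m3"]])         # anti-correlated -> apart
  # constant trajectory becomes a flagged singleton
  traj2 <- rbind(traj, m5 = c(5, 5, 5, 5))
  expect_warning(p2 <- clusterModules(traj2), "constant")
  expect_equal(sum(p2 == p2[["m5"]]), 1)
  # planted 3-group recovery vs brute-force pairwise-correlation grouping
  set.seed(31)
  shapes <- rbind(c(0, 20, 50, 90), c(80, 60, 30, 10), c(50, -40, 50, -40))
  tr <- do.call(rbind, lapply(1:9, function(i)
    shapes[(i - 1) %% 3 + 1, ] + rnorm(4, 0, 2)))
  rownames(tr) <- sprintf("m%d", 1:9)
  p3 <- clusterModules(tr)
  expect_equal(length(unique(p3)), 3)
  expect_equal(unname(p3[c(1, 4, 7)]), rep(p3[[1]], 3))
})

test_that("set delineation reproduces the reference A28 scenario", {
  A <- list(c("M15.65", "M13.17"), "M8.3", c("M15.86", "M10.1", "M15.127"))
  B <- list(c("M15.65", "M13.17"), c("M8.3", "M15.86"), "M10.1", "M15.127")
  d <- delineateSets(A, B)
  expect_equal(d$sets$S1, sort(c("M15.65", "M13.17")))
  expect_equal(d$sets$S2, "M8.3")
  expect_length(d$sets, 2)
  expect_setequal(d$ns, c("M15.86", "M10.1", "M15.127"))
})

test_that("the labelled-set cap sends overflow blocks to NS", {
  part <- list(c("a1", "a2", "a3", "a4"), c("b1", "b2", "b3"),
               c("c1", "c2"), c("d1", "d2"))
  d <- delineateSets(part, part, maxSets = 3)
  expect_equal(names(d$sets), c("S1", "S2", "S3"))
  expect_equal(d$sets$S1, c("a1", "a2", "a3", "a4"))
  # size tie between c and d blocks resolved by smallest module id
  expect_equal(d$sets$S3, c("c1", "c2"))
  expect_setequal(d$ns, c("d1", "d2"))
})

test_that("an empty meet with non-distinct singletons yields only NS", {
  A <- list(c("m1", "m2", "m3"), c("m4", "m5"))
  B <- list(c("m1", "m4"), c("m2", "m5"), c("m3"))
  # meet is all singletons; only m3 is a singleton cluster anywhere, and only
  # in cohort B -> no candidate under the primary rule
  d <- delineateSets(A, B)
  expect_length(d$sets, 0)
  expect_setequal(d$ns, sprintf("m%d", 1:5))
  # under the either-cohort rule m3 becomes a set
  d2 <- delineateSets(A, B, singletonRule = "either")
  expect_equal(d2$sets$S1, "m3")
  expect_error(delineateSets(A, list(c("m1", "m2"))), "different module sets")
})

test_that("set delineation agrees with brute-force meet enumeration", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(3:8, 1)
    mods <- sprintf("m%02d", seq_len(n))
    pA <- setNames(sample(1:3, n, replace = TRUE), mods)
    pB <- setNames(sample(1:3, n, replace = TRUE), mods)
    d <- delineateSets(pA, pB, maxSets = n)
    got <- c(unname(d$sets), as.list(d$ns))
    blocks <- bruteMeet(pA, pB)
    # every labelled set is a meet block; NS modules are unions of blocks
    for (s in d$sets)
      expect_true(any(vapply(blocks, identical, TRUE, s)))
    # coverage: sets + NS partition the module list
    flat <- c(unlist(d$sets, use.names = FALSE), d$ns)
    expect_setequal(flat, mods)
    expect_equal(length(flat), n)
  }
})

test_that("delineation across aggregates recovers the planted sets", {
  study <- simulateStudy(simulationConfig(seed = 21))
  profA <- moduleResponseProfile(study$counts, study$repertoire, "P2")
  profB <- moduleResponseProfile(study$intensity, study$repertoire, "PP")
  asn <- delineateModuleSets(profA, profB, study$repertoire,
                             timepointsA = c("T1", "T2", "T3", "D"),
                             timepointsB = c("WG16", "WG23", "WG31", "WG40"))
  tab <- setTable(asn)
  lab <- tab[tab$set_label != "NS", ]
  # one S1 (5 modules) and one S2 (3 modules) per active aggregate
  expect_equal(nrow(unique(lab[, c("aggregate_id", "set_label")])),
               2 * length(study$truth$activeAggregates))
  truthKey <- paste(study$truth$sets$aggregate_id, study$truth$sets$set_label,
                    study$truth$sets$module_id)
  gotKey <- paste(lab$aggregate_id, lab$set_label, lab$module_id)
  expect_setequal(gotKey, truthKey)
})
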