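test_that("baseline is the per-gene mean over reference samples", {
  m <- rbind(g1 = c(7, 4, 6, 1), g2 = c(2, 2, 4, 9))
  mes <- makeMes(m, timepoints = c("PP", "PP", "PP", "T1"),
                 timepointLevels = c("T1", "PP"))
  # singleton reference
  b1 <- computeBaseline(makeMes(m[, c(1, 4)], c("PP", "T1"),
                                timepointLevels = c("T1", "PP")), "PP")
  expect_equal(unname(referenceValues(b1)["g1"]), 7)
  # mean of (4, 6) = 5
  b <- computeBaseline(mes, "PP")
  expect_equal(unname(referenceValues(b)), c(mean(c(7, 4, 6)), mean(c(2, 2, 4))))
  expect_error(computeBaseline(mes, "P9"), "no samples")
  # recovery of known per-gene means on a simulated cohort
  set.seed(42)
  big <- matrix(rnorm(100 * 6, rep(1:100, 6), 0.1), 100, 6,
                dimnames = list(sprintf("g%03d", 1:100), NULL))
  bmes <- makeMes(big, rep(c("PP", "T1"), each = 3),
                  timepointLevels = c("T1", "PP"))
  expect_equal(unname(referenceValues(computeBaseline(bmes, "PP"))),
               unname(rowMeans(big[, 1:3])), tolerance = 1e-12)
})

test_that("vectorised Welch and one-sample tests match stats::t.test", {
  set.seed(101)
  for (i in 1:20) {
    n1 <- sample(3:12, 1); n2 <- sample(3:12, 1)
    x <- matrix(rnorm(8 * n1, 10, 2), 8, n1)
    y <- matrix(rnorm(8 * n2, 11, 3), 8, n2)
    pW <- modpanel:::.welchRows(x, y)
    pO <- vapply(1:8, function(r) stats::t.test(x[r, ], y[r, ])$p.value, 0)
    expect_equal(pW, pO, tolerance = 1e-12)
    mu <- rnorm(8, 10)
    p1 <- modpanel:::.oneSampleRows(x, mu)
    p1O <- vapply(1:8, function(r) stats::t.test(x[r, ], mu = mu[r])$p.value, 0)
    expect_equal(p1, p1O, tolerance = 1e-12)
  }
  # degenerate zero-variance rows
  z <- matrix(5, 2, 4)
  expect_equal(modpanel:::.welchRows(z, z), c(1, 1))
  expect_equal(modpanel:::.welchRows(z, z + 1), c(0, 0))
})

test_that("group calls apply inclusive fold-change and p cut-offs", {
  # means engineered exactly: test 15 vs ref 10 -> fc exactly 1.5
  m <- rbind(gUp = c(14, 15, 16, 9, 10, 11),
             gFlat = c(9, 10, 11, 9, 10, 11),
             gDown = c(5, 6, 7, 9, 10, 11))
  mes <- makeMes(m, rep(c("T1", "PP"), each = 3),
                 timepointLevels = c("T1", "PP"))
  b <- computeBaseline(mes, "PP")
  calls <- geneCallsGroup(mes, b, "T1")
  expect_equal(calls$fc[1], 1.5)
  expect_lt(calls$p[1], 0.1)
  expect_equal(calls$call[1], "up")          # fc of exactly 1.5 counts
  expect_equal(calls$call[2], "null")        # fc = 1 regardless of p
  expect_equal(calls$call[3], "down")
  # counts platform guards zero reference means with a pseudocount
  m2 <- rbind(g0 = c(30, 40, 50, 0, 0, 0))
  mesC <- makeMes(m2, rep(c("T1", "PP"), each = 3), platform = "counts",
                  timepointLevels = c("T1", "PP"))
  c2 <- geneCallsGroup(mesC, computeBaseline(mesC, "PP"), "T1")
  expect_true(c2$flagged[1])
  expect_equal(c2$fc[1], 41)                 # (40+1)/(0+1)
  expect_error(geneCallsGroup(mes, b, "T9"), "no samples")
})

test_that("a planted 2-fold shift is called up with high power", {
  set.seed(5)
  hits <- 0
  for (i in 1:30) {
    m <- rbind(g = c(rnorm(15, 20, 2), rnorm(15, 10, 2)))
    mes <- makeMes(m, rep(c("T1", "PP"), each = 15),
                   timepointLevels = c("T1", "PP"))
    calls <- geneCallsGroup(mes, computeBaseline(mes, "PP"), "T1")
    hits <- hits + (calls$call == "up")
  }
  expect_gte(hits / 30, 0.9)
})

test_that("individual calls require both the FC and the DIFF gate", {
  m <- rbind(gA = c(25, 10, 10), gB = c(14, 10, 10), gC = c(16, 10, 10))
  mes <- makeMes(m, c("T1", "PP", "PP"), timepointLevels = c("T1", "PP"))
  b <- computeBaseline(mes, "PP")
  calls <- geneCallsIndividual(mes, b, "S01")
  expect_equal(calls$call, c("up", "null", "null"))  # 2.5x/+15; FC fails; DIFF fails
  expect_equal(calls$fc, c(2.5, 1.4, 1.6))
  expect_equal(calls$diff, c(15, 4, 6))
})

test_that("module response counts up/down percentages and nets the trend", {
  genes40 <- sprintf("g%02d", 1:40)
  rep40 <- ModuleRepertoire(list(M13.26 = genes40), c(M13.26 = "A13"))
  allUp <- makeCalls(genes40, rep("up", 40))
  expect_equal(moduleResponse(allUp, rep40, "M13.26")$response, 100)
  allNull <- makeCalls(genes40, rep("null", 40))
  expect_equal(moduleResponse(allNull, rep40, "M13.26")$response, 0)

  genes10 <- sprintf("h%02d", 1:10)
  rep10 <- ModuleRepertoire(list(M1 = genes10), c(M1 = "A1"))
  mixed <- makeCalls(genes10, c(rep("up", 3), "down", rep("null", 6)))
  r <- moduleResponse(mixed, rep10, "M1")
  expect_equal(c(r$pct_up, r$pct_down, r$response), c(30, 10, 20))
  # absent genes count as null
  r2 <- moduleResponse(mixed[1:4, ], rep10, "M1")
  expect_equal(r2$response, 20)
  expect_error(moduleResponse(mixed, rep10, "M99"), "unknown module")
})

test_that("module response equals an exhaustive recount and stays in bounds", {
  set.seed(77)
  for (i in 1:25) {
    n <- sample(1:10, 1)
    genes <- sprintf("x%02d", seq_len(n))
    rep1 <- ModuleRepertoire(list(M = genes), c(M = "A1"))
    calls <- makeCalls(genes, sample(c("up", "down", "null"), n, replace = TRUE))
    r <- moduleResponse(calls, rep1, "M")
    # brute-force recount oracle
    expect_equal(r$pct_up, 100 * sum(calls$call == "up") / n)
    expect_equal(r$pct_down, 100 * sum(calls$call == "down") / n)
    expect_equal(r$response, r$pct_up - r$pct_down)
    expect_lte(abs(r$response), 100)
    expect_lte(r$pct_up + r$pct_down, 100)
  }
})

test_that("swapping test and reference flips every call direction", {
  set.seed(9)
  m <- matrix(rlnorm(50 * 10, 3, 0.5), 50, 10,
              dimnames = list(sprintf("g%02d", 1:50), NULL))
  m[1:10, 1:5] <- m[1:10, 1:5] * 3
  mesAB <- makeMes(m, rep(c("T1", "PP"), each = 5),
                   timepointLevels = c("T1", "PP"))
  mesBA <- makeMes(m, rep(c("PP", "T1"), each = 5),
                   timepointLevels = c("T1", "PP"))
  cAB <- geneCallsGroup(mesAB, computeBaseline(mesAB, "PP"), "T1")
  cBA <- geneCallsGroup(mesBA, computeBaseline(mesBA, "PP"), "T1")
  flip <- c(up = "down", down = "up", null = "null")
  expect_equal(cBA$call, unname(flip[cAB$call]))
})

test_that("raising the fold-change cut-off never increases pct_up or pct_down", {
  set.seed(13)
  m <- matrix(rlnorm(80 * 12, 3, 0.6), 80, 12,
              dimnames = list(sprintf("g%02d", 1:80), NULL))
  m[1:40, 1:6] <- m[1:40, 1:6] * runif(40, 0.3, 3)
  rep1 <- ModuleRepertoire(list(M = rownames(m)), c(M = "A1"))
  mes <- makeMes(m, rep(c("T1", "PP"), each = 6),
                 timepointLevels = c("T1", "PP"))
  b <- computeBaseline(mes, "PP")
  prev <- NULL
  for (fc in c(1.2, 1.5, 2, 3)) {
    calls <- geneCallsGroup(mes, b, "T1", responseThresholds(fcGroup = fc))
    r <- moduleResponse(calls, rep1, "M")
    if (!is.null(prev)) {
      expect_lte(r$pct_up, prev$pct_up)
      expect_lte(r$pct_down, prev$pct_down)
    }
    prev <- r
  }
})

test_that("fingerprint grids put responses at fixed positions with the colour code", {
  rep <- miniRepertoire()
  zero <- makeProfile(matrix(0, 3, 1, dimnames = list(moduleIds(rep), "T1")),
                      rep)
  gz <- fingerprintGrid(zero, rep, "T1")
  expect_true(all(gz$hue == "blank"))
  expect_true(all(gz$saturation == 0))

  one <- makeProfile(matrix(c(100, 0, 0), 3, 1,
                            dimnames = list(moduleIds(rep), "T1")), rep)
  go <- fingerprintGrid(one, rep, "T1")
  hot <- go[go$module_id == "M1.1", ]
  expect_equal(hot$hue, "red")
  expect_equal(hot$saturation, 1)
  expect_equal(c(hot$row, hot$col), c(1, 1))
  expect_equal(sum(go$hue != "blank"), 1)

  # TSV round trip is value-exact
  p <- withr::local_tempfile(fileext = ".tsv")
  writeFingerprintGrid(go, p)
  expect_equal(readFingerprintGrid(p), go)
})
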