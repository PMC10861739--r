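#' Differential-call thresholds
#'
#' Fixed cut-offs used for the fingerprint differential-expression calls.
#' Group-level calls require a fold change of at least \code{fcGroup}
#' (inclusive) and a t-test p-value below \code{pGroup}; individual-sample
#' calls require fold change strictly above \code{fcIndiv} AND an absolute
#' expression difference strictly above \code{diffIndiv} (in the dataset's
#' own normalized units).
#'
#' @param fcGroup group-level fold-change cut-off (default 1.5).
#' @param pGroup group-level p-value cut-off (default 0.1).
#' @param fcIndiv individual-level fold-change cut-off (default 1.5).
#' @param diffIndiv individual-level absolute-difference cut-off (default 10).
#' @return a named list of thresholds.
#' @export
responseThresholds <- function(fcGroup = 1.5, pGroup = 0.1,
                               fcIndiv = 1.5, diffIndiv = 10) {
  stopifnot(fcGroup > 0, fcIndiv > 0, diffIndiv > 0,
            pGroup > 0, pGroup < 1)
  list(fcGroup = fcGroup, pGroup = pGroup,
       fcIndiv = fcIndiv, diffIndiv = diffIndiv)
}

#' Compute the per-gene postpartum baseline
#'
#' The per-gene arithmetic mean of normalized expression over all samples at
#' the reference timepoint (the postpartum visit); all fingerprint calls are
#' made against these reference values.
#'
#' @param mes a [ModuleExpressionSet-class].
#' @param referenceTimepoint timepoint label of the reference samples.
#' @return a [BaselineSpec-class].
#' @export
computeBaseline <- function(mes, referenceTimepoint) {
  sel <- as.character(colData(mes)$timepoint) == referenceTimepoint
  if (!any(sel))
    stop("no samples at reference timepoint '", referenceTimepoint, "'")
  vals <- rowMeans(assay(mes)[, sel, drop = FALSE])
  methods::new("BaselineSpec", referenceTimepoint = referenceTimepoint,
               values = vals, nSamples = sum(sel))
}

# row-wise sample variance
.rowVars <- function(m) {
  if (ncol(m) < 2L) return(rep(NA_real_, nrow(m)))
  rowSums((m - rowMeans(m))^2) / (ncol(m) - 1L)
}

# vectorised Welch two-sample t-test over matrix rows; stats::t.test is the
# test-suite oracle for this implementation
.welchRows <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- .rowVars(x); v2 <- .rowVars(y)
  se2 <- v1 / n1 + v2 / n2
  tt <- (m1 - m2) / sqrt(se2)
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1L) + (v2 / n2)^2 / (n2 - 1L))
  p <- 2 * stats::pt(-abs(tt), df)
  # both groups constant: p=1 when means agree, p=0 otherwise
  degen <- !is.na(se2) & se2 == 0
  p[degen] <- ifelse(m1[degen] == m2[degen], 1, 0)
  p
}

# one-sample t-test of matrix rows against per-row constants
.oneSampleRows <- function(x, mu) {
  n <- ncol(x)
  m <- rowMeans(x); v <- .rowVars(x)
  tt <- (m - mu) / sqrt(v / n)
  p <- 2 * stats::pt(-abs(tt), n - 1L)
  degen <- !is.na(v) & v == 0
  p[degen] <- ifelse(m[degen] == mu[degen], 1, 0)
  p
}

# fold change on the linear normalized scale; counts platform guards the zero
# denominator with a pseudocount of 1 on both means, the intensity platform
# flags non-positive reference means instead
.foldChange <- function(meanTest, meanRef, platform) {
  if (platform == "counts") {
    fc <- (meanTest + 1) / (meanRef + 1)
    flag <- meanRef == 0
  } else {
    fc <- ifelse(meanRef > 0, meanTest / meanRef, NA_real_)
    flag <- meanRef <= 0
  }
  list(fc = fc, flag = flag)
}

#' Group-level differential-expression calls versus the baseline
#'
#' Compares the samples at a test timepoint against the reference-timepoint
#' samples, gene by gene. The default test is a Welch two-sample t-test
#' (test-timepoint samples vs reference samples); \code{oneSample = TRUE}
#' instead tests the test-timepoint samples against the per-gene reference
#' mean as a constant. A gene is called \code{up} when its fold change is at
#' least \code{fcGroup} and p < \code{pGroup}; \code{down} when the fold
#' change is at most \code{1/fcGroup} and p < \code{pGroup}; \code{null}
#' otherwise. Fold changes are ratios of means on the linear normalized scale.
#'
#' @param mes a [ModuleExpressionSet-class].
#' @param baseline a [BaselineSpec-class] computed on the same dataset.
#' @param timepoint the test timepoint label.
#' @param thresholds a [responseThresholds()] list.
#' @param oneSample test against the reference mean as a constant instead of
#'   the Welch two-sample test (default \code{FALSE}).
#' @param logTransform apply \code{log2(x + 1)} before testing (fold changes
#'   stay on the linear scale); default \code{FALSE}.
#' @param adjust apply Benjamini-Hochberg correction across genes within the
#'   timepoint before thresholding (default \code{FALSE}: the stated cut-off
#'   for this path is a raw p < 0.1).
#' @return data.frame with columns \code{gene_id}, \code{mean_test},
#'   \code{mean_ref}, \code{fc}, \code{p}, \code{call}, \code{flagged}.
#' @export
geneCallsGroup <- function(mes, baseline, timepoint,
                           thresholds = responseThresholds(),
                           oneSample = FALSE, logTransform = FALSE,
                           adjust = FALSE) {
  tp <- as.character(colData(mes)$timepoint)
  selT <- tp == timepoint
  if (!any(selT))
    stop("no samples at test timepoint '", timepoint, "'")
  selR <- tp == referenceTimepoint(baseline)
  m <- assay(mes)
  if (!identical(names(referenceValues(baseline)), rownames(m)))
    stop("baseline was not computed on this dataset (gene mismatch)")
  x <- m[, selT, drop = FALSE]
  r <- m[, selR, drop = FALSE]
  if (ncol(x) < 2L)
    stop("need >= 2 samples at the test timepoint for a t-statistic")

  meanTest <- rowMeans(x)
  meanRef <- referenceValues(baseline)
  tx <- if (logTransform) log2(pmax(x, 0) + 1) else x
  tr <- if (logTransform) log2(pmax(r, 0) + 1) else r
  p <- if (oneSample) {
    mu <- if (logTransform) rowMeans(tr) else meanRef
    .oneSampleRows(tx, mu)
  } else {
    if (ncol(r) < 2L)
      stop("need >= 2 reference samples for the Welch test; use oneSample = TRUE")
    .welchRows(tx, tr)
  }
  if (adjust) p <- stats::p.adjust(p, method = "BH")

  f <- .foldChange(meanTest, meanRef, platform(mes))
  call <- rep("null", nrow(m))
  ok <- !is.na(f$fc) & !is.na(p)
  call[ok & f$fc >= thresholds$fcGroup & p < thresholds$pGroup] <- "up"
  call[ok & f$fc <= 1 / thresholds$fcGroup & p < thresholds$pGroup] <- "down"
  data.frame(gene_id = rownames(m), mean_test = meanTest,
             mean_ref = unname(meanRef), fc = unname(f$fc), p = unname(p),
             call = call, flagged = unname(f$flag),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Individual-sample differential-expression calls versus the baseline
#'
#' Calls a gene \code{up} in one sample when its fold change over the
#' reference mean is strictly above \code{fcIndiv} AND the expression
#' difference is strictly above \code{diffIndiv} (both gates must pass);
#' \code{down} symmetrically; \code{null} otherwise.
#'
#' @inheritParams geneCallsGroup
#' @param sample a sample id present in the dataset.
#' @return data.frame with columns \code{gene_id}, \code{value},
#'   \code{mean_ref}, \code{fc}, \code{diff}, \code{call}, \code{flagged}.
#' @export
geneCallsIndividual <- function(mes, baseline, sample,
                                thresholds = responseThresholds()) {
  m <- assay(mes)
  if (!sample %in% colnames(m))
    stop("unknown sample: ", sample)
  if (!identical(names(referenceValues(baseline)), rownames(m)))
    stop("baseline was not computed on this dataset (gene mismatch)")
  v <- m[, sample]
  ref <- referenceValues(baseline)
  f <- .foldChange(v, ref, platform(mes))
  d <- v - ref
  call <- rep("null", nrow(m))
  ok <- !is.na(f$fc)
  call[ok & f$fc > thresholds$fcIndiv & d > thresholds$diffIndiv] <- "up"
  call[ok & f$fc < 1 / thresholds$fcIndiv & d < -thresholds$diffIndiv] <- "down"
  data.frame(gene_id = rownames(m), value = unname(v), mean_ref = unname(ref),
              fc = unname(f$fc), diff = unname(d), call = call,
              flagged = unname(f$flag), row.names = NULL,
              stringsAsFactors = FALSE)
}

#' Percent response of one module from a call table
#'
#' \code{pct_up} is the percentage of the module's constitutive genes called
#' up, \code{pct_down} analogous, and the signed response is
#' \code{pct_up - pct_down} (+100 when every constitutive transcript
#' increased, -100 when every one decreased). Constitutive genes absent from
#' the call table count as null.
#'
#' @param calls a call data.frame from [geneCallsGroup()] or
#'   [geneCallsIndividual()].
#' @param rep a [ModuleRepertoire-class].
#' @param module a module id of \code{rep}.
#' @return one-row data.frame with \code{module_id}, \code{n_genes},
#'   \code{pct_up}, \code{pct_down}, \code{response}.
#' @export
moduleResponse <- function(calls, rep, module) {
  genes <- moduleGenes(rep, module)   # errors on unknown module
  cv <- stats::setNames(calls$call, calls$gene_id)[genes]
  n <- length(genes)
  up <- sum(cv == "up", na.rm = TRUE)
  down <- sum(cv == "down", na.rm = TRUE)
  data.frame(module_id = module, n_genes = n,
             pct_up = 100 * up / n, pct_down = 100 * down / n,
             response = 100 * (up - down) / n,
             stringsAsFactors = FALSE)
}

.profileFromCalls <- function(callList, rep) {
  mods <- moduleIds(rep)
  aggs <- moduleAggregates(rep)
  out <- lapply(names(callList), function(cmp) {
    cv <- stats::setNames(callList[[cmp]]$call, callList[[cmp]]$gene_id)
    rows <- lapply(mods, function(m) {
      g <- moduleGenes(rep, m)
      v <- cv[g]
      n <- length(g)
      up <- sum(v == "up", na.rm = TRUE)
      down <- sum(v == "down", na.rm = TRUE)
      c(n = n, up = up, down = down)
    })
    rows <- do.call(rbind, rows)
    data.frame(module_id = mods, aggregate_id = unname(aggs[mods]),
               comparison = cmp, n_genes = rows[, "n"],
               pct_up = 100 * rows[, "up"] / rows[, "n"],
               pct_down = 100 * rows[, "down"] / rows[, "n"],
               response = 100 * (rows[, "up"] - rows[, "down"]) / rows[, "n"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Module response fingerprint over all modules and comparisons
#'
#' Computes group-level (one comparison per non-reference timepoint) or
#' individual-level (one comparison per non-reference sample) percent-response
#' profiles for every module of the repertoire versus the postpartum baseline.
#'
#' @inheritParams geneCallsGroup
#' @param rep a [ModuleRepertoire-class].
#' @param referenceTimepoint reference (postpartum) timepoint label.
#' @param timepoints comparisons to compute (group mode); defaults to every
#'   non-reference timepoint in chronological order.
#' @param mode \code{"group"} or \code{"individual"}.
#' @param ... passed on to [geneCallsGroup()] (e.g. \code{oneSample},
#'   \code{logTransform}, \code{adjust}).
#' @return a [ModuleResponseProfile-class].
#' @export
moduleResponseProfile <- function(mes, rep, referenceTimepoint,
                                  thresholds = responseThresholds(),
                                  timepoints = NULL, mode = c("group", "individual"),
                                  ...) {
  mode <- match.arg(mode)
  baseline <- computeBaseline(mes, referenceTimepoint)
  if (mode == "group") {
    if (is.null(timepoints))
      timepoints <- setdiff(timepointLevels(mes), referenceTimepoint)
    callList <- lapply(stats::setNames(timepoints, timepoints), function(tp)
      geneCallsGroup(mes, baseline, tp, thresholds, ...))
  } else {
    cd <- colData(mes)
    smp <- cd$sample_id[as.character(cd$timepoint) != referenceTimepoint]
    callList <- lapply(stats::setNames(smp, smp), function(s)
      geneCallsIndividual(mes, baseline, s, thresholds))
  }
  methods::new("ModuleResponseProfile", table = .profileFromCalls(callList, rep),
               cohort = cohortLabel(mes), reference = referenceTimepoint,
               mode = mode)
}

#' Fingerprint grid table for one comparison
#'
#' Places each module's signed response at its fixed (row, column) grid
#' position and maps it to the display encoding: hue red for positive, blue
#' for negative, blank at zero response; saturation proportional to
#' |response| (fraction of 1 at |response| = 100).
#'
#' @param profile a [ModuleResponseProfile-class].
#' @param rep the [ModuleRepertoire-class] the profile was computed against.
#' @param comparison comparison label to extract; defaults to the only one
#'   present.
#' @return data.frame with columns \code{module_id}, \code{aggregate_id},
#'   \code{row}, \code{col}, \code{response}, \code{hue}, \code{saturation}.
#' @export
fingerprintGrid <- function(profile, rep, comparison = NULL) {
  t <- responseTable(profile)
  if (is.null(comparison)) {
    comparison <- unique(t$comparison)
    if (length(comparison) > 1L)
      stop("profile has several comparisons; pick one")
  }
  t <- t[t$comparison == comparison, c("module_id", "response")]
  g <- merge(gridLayout(rep), t, by = "module_id", all.x = TRUE, sort = FALSE)
  if (anyNA(g$response))
    stop("profile does not cover the repertoire")
  g$hue <- ifelse(g$response > 0, "red", ifelse(g$response < 0, "blue", "blank"))
  g$saturation <- abs(g$response) / 100
  g <- g[.strOrder(g$row, g$col), ]
  rownames(g) <- NULL
  g
}

#' Write / read a fingerprint grid as TSV
#'
#' Plain-text serialization of [fingerprintGrid()] output; the round trip is
#' value-exact.
#'
#' @param grid a grid data.frame from [fingerprintGrid()].
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
writeFingerprintGrid <- function(grid, path) {
  utils::write.table(grid, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname writeFingerprintGrid
#' @export
readFingerprintGrid <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Plot a fingerprint grid
#'
#' Fixed-position heat map of one comparison: red tiles for upregulated
#' modules, blue for downregulated, saturation proportional to |response|,
#' blank at zero.
#'
#' @inheritParams fingerprintGrid
#' @return a ggplot object.
#' @export
plotFingerprint <- function(profile, rep, comparison = NULL) {
  g <- fingerprintGrid(profile, rep, comparison)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$col, y = -.data$row,
                                  fill = .data$response)) +
    ggplot2::geom_tile(color = "grey80") +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-100, 100), name = "% response") +
    ggplot2::labs(x = "module position", y = "aggregate") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
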