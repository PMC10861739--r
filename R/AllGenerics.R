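#' @include AllClasses.R
NULL

#' Accessors for modpanel classes
#'
#' Small accessor generics for the package's S4 containers; slot access is
#' never needed by user code.
#'
#' @param x a modpanel object.
#' @param ... passed to methods.
#' @return see the individual methods.
#' @name modpanel-accessors
NULL

#' @rdname modpanel-accessors
#' @export
setGeneric("moduleIds", function(x, ...) standardGeneric("moduleIds"))
#' @rdname modpanel-accessors
#' @export
setGeneric("aggregateIds", function(x, ...) standardGeneric("aggregateIds"))
#' @rdname modpanel-accessors
#' @export
setGeneric("moduleGenes", function(x, module, ...) standardGeneric("moduleGenes"))
#' @rdname modpanel-accessors
#' @export
setGeneric("moduleAggregates", function(x, ...) standardGeneric("moduleAggregates"))
#' @rdname modpanel-accessors
#' @export
setGeneric("gridLayout", function(x, ...) standardGeneric("gridLayout"))
#' @rdname modpanel-accessors
#' @export
setGeneric("nModules", function(x, ...) standardGeneric("nModules"))
#' @rdname modpanel-accessors
#' @export
setGeneric("nAggregates", function(x, ...) standardGeneric("nAggregates"))
#' @rdname modpanel-accessors
#' @export
setGeneric("platform", function(x, ...) standardGeneric("platform"))
#' @rdname modpanel-accessors
#' @export
setGeneric("normalizationMethod", function(x, ...) standardGeneric("normalizationMethod"))
#' @rdname modpanel-accessors
#' @export
setGeneric("cohortLabel", function(x, ...) standardGeneric("cohortLabel"))
#' @rdname modpanel-accessors
#' @export
setGeneric("timepointLevels", function(x, ...) standardGeneric("timepointLevels"))
#' @rdname modpanel-accessors
#' @export
setGeneric("sampleSheet", function(x, ...) standardGeneric("sampleSheet"))
#' @rdname modpanel-accessors
#' @export
setGeneric("responseTable", function(x, ...) standardGeneric("responseTable"))
#' @rdname modpanel-accessors
#' @export
setGeneric("setTable", function(x, ...) standardGeneric("setTable"))
#' @rdname modpanel-accessors
#' @export
setGeneric("panelGenes", function(x, ...) standardGeneric("panelGenes"))
#' @rdname modpanel-accessors
#' @export
setGeneric("housekeepingGenes", function(x, ...) standardGeneric("housekeepingGenes"))
#' @rdname modpanel-accessors
#' @export
setGeneric("referenceValues", function(x, ...) standardGeneric("referenceValues"))
#' @rdname modpanel-accessors
#' @export
setGeneric("referenceTimepoint", function(x, ...) standardGeneric("referenceTimepoint"))

## ---- ModuleRepertoire methods ---------------------------------------------

#' @rdname modpanel-accessors
#' @aliases moduleIds,ModuleRepertoire-method
setMethod("moduleIds", "ModuleRepertoire", function(x, ...) names(x@modules))

#' @rdname modpanel-accessors
setMethod("aggregateIds", "ModuleRepertoire", function(x, ...)
  unique(unname(x@aggregates)))

#' @rdname modpanel-accessors
setMethod("moduleGenes", "ModuleRepertoire", function(x, module, ...) {
  if (missing(module)) return(x@modules)
  if (!module %in% names(x@modules))
    stop("unknown module: ", module)
  x@modules[[module]]
})

#' @rdname modpanel-accessors
setMethod("moduleAggregates", "ModuleRepertoire", function(x, ...) x@aggregates)

#' @rdname modpanel-accessors
setMethod("gridLayout", "ModuleRepertoire", function(x, ...) x@grid)

#' @rdname modpanel-accessors
setMethod("nModules", "ModuleRepertoire", function(x, ...) length(x@modules))

#' @rdname modpanel-accessors
setMethod("nAggregates", "ModuleRepertoire", function(x, ...)
  length(unique(x@aggregates)))

setMethod("show", "ModuleRepertoire", function(object) {
  cat(sprintf("ModuleRepertoire: %d modules in %d aggregates, %d gene assignments\n",
              nModules(object), nAggregates(object),
              sum(lengths(object@modules))))
})

## ---- ModuleExpressionSet methods ------------------------------------------

#' @rdname modpanel-accessors
setMethod("platform", "ModuleExpressionSet", function(x, ...) x@platform)

#' @rdname modpanel-accessors
setMethod("normalizationMethod", "ModuleExpressionSet", function(x, ...)
  x@normalization)

#' @rdname modpanel-accessors
setMethod("cohortLabel", "ModuleExpressionSet", function(x, ...)
  as.character(unique(colData(x)$cohort)))

#' @rdname modpanel-accessors
setMethod("timepointLevels", "ModuleExpressionSet", function(x, ...)
  levels(colData(x)$timepoint))

#' @rdname modpanel-accessors
setMethod("sampleSheet", "ModuleExpressionSet", function(x, ...) {
  df <- as.data.frame(colData(x))
  df$timepoint <- as.character(df$timepoint)
  rownames(df) <- NULL
  df
})

setMethod("show", "ModuleExpressionSet", function(object) {
  cat(sprintf("ModuleExpressionSet (%s platform, %s): %d genes x %d samples\n",
              object@platform, object@normalization,
              nrow(object), ncol(object)))
  cat(sprintf("  cohort: %s; timepoints: %s\n",
              paste(cohortLabel(object), collapse = ", "),
              paste(timepointLevels(object), collapse = " < ")))
})

## ---- BaselineSpec methods -------------------------------------------------

#' @rdname modpanel-accessors
setMethod("referenceValues", "BaselineSpec", function(x, ...) x@values)

#' @rdname modpanel-accessors
setMethod("referenceTimepoint", "BaselineSpec", function(x, ...)
  x@referenceTimepoint)

setMethod("show", "BaselineSpec", function(object) {
  cat(sprintf("BaselineSpec: %d genes averaged over %d '%s' samples\n",
              length(object@values), object@nSamples,
              object@referenceTimepoint))
})

## ---- result-table methods -------------------------------------------------

#' @rdname modpanel-accessors
setMethod("responseTable", "ModuleResponseProfile", function(x, ...) x@table)

setMethod("show", "ModuleResponseProfile", function(object) {
  cat(sprintf("ModuleResponseProfile (%s-level, cohort %s, ref %s): %d modules x %d comparisons\n",
              object@mode, object@cohort, object@reference,
              length(unique(object@table$module_id)),
              length(unique(object@table$comparison))))
})

#' @rdname modpanel-accessors
setMethod("setTable", "ModuleSetAssignment", function(x, ...) x@table)

setMethod("show", "ModuleSetAssignment", function(object) {
  t <- object@table
  nset <- nrow(unique(t[t$set_label != "NS", c("aggregate_id", "set_label")]))
  cat(sprintf("ModuleSetAssignment: %d labelled sets over %d aggregates (%d modules, %d in NS)\n",
              nset, length(unique(t$aggregate_id)), nrow(t),
              sum(t$set_label == "NS")))
})

#' @rdname modpanel-accessors
setMethod("panelGenes", "PanelDesign", function(x, ...) x@test)

#' @rdname modpanel-accessors
setMethod("housekeepingGenes", "PanelDesign", function(x, ...) x@housekeeping)

setMethod("show", "PanelDesign", function(object) {
  cat(sprintf("PanelDesign: %d test + %d housekeeping = %d transcripts\n",
              nrow(object@test), nrow(object@housekeeping),
              nrow(object@test) + nrow(object@housekeeping)))
  src <- table(object@test$source)
  cat("  test sources:", paste(sprintf("%s=%d", names(src), src), collapse = ", "), "\n")
})
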