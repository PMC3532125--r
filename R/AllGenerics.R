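#' @rdname accessors
#' @export
setGeneric("geneIds", function(x) standardGeneric("geneIds"))
#' @rdname accessors
#' @export
setGeneric("cellIds", function(x) standardGeneric("cellIds"))
#' @rdname accessors
#' @export
setGeneric("drugIds", function(x) standardGeneric("drugIds"))
#' @rdname accessors
#' @export
setGeneric("termIds", function(x) standardGeneric("termIds"))
#' @rdname accessors
#' @export
setGeneric("geneSets", function(x) standardGeneric("geneSets"))
#' @rdname accessors
#' @export
setGeneric("compendiumPairs", function(x) standardGeneric("compendiumPairs"))
#' @rdname accessors
#' @export
setGeneric("predictions", function(x) standardGeneric("predictions"))
#' @rdname accessors
#' @export
setGeneric("pipelineReports", function(x) standardGeneric("pipelineReports"))
#' @rdname accessors
#' @export
setGeneric("pipelineConfigOf", function(x) standardGeneric("pipelineConfigOf"))

#' Accessors for crgnet data classes
#'
#' Small accessor generics so downstream code never touches slots directly:
#' `geneIds()`/`cellIds()`/`drugIds()` return the identifier vectors of the
#' screen matrices and compendium, `termIds()`/`geneSets()` the annotation
#' contents, `compendiumPairs()` the compendium rows, and `predictions()`,
#' `pipelineReports()`, `pipelineConfigOf()` the components of a
#' [PredictionTable-class].
#'
#' @param x the object.
#' @return the corresponding component (character vector, list or
#'   data.frame).
#' @name accessors
NULL

#' @rdname accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("cellIds", "ExpressionMatrix", function(x) colnames(x))
#' @rdname accessors
#' @export
setMethod("drugIds", "ActivityMatrix", function(x) rownames(x))
#' @rdname accessors
#' @export
setMethod("cellIds", "ActivityMatrix", function(x) colnames(x))
#' @rdname accessors
#' @export
setMethod("compendiumPairs", "Compendium", function(x) x@pairs)
#' @rdname accessors
#' @export
setMethod("drugIds", "Compendium", function(x) sort(unique(x@pairs$drug)))
#' @rdname accessors
#' @export
setMethod("geneIds", "Compendium", function(x) sort(unique(x@pairs$gene)))
#' @rdname accessors
#' @export
setMethod("termIds", "GeneAnnotation", function(x) names(x@sets))
#' @rdname accessors
#' @export
setMethod("geneSets", "GeneAnnotation", function(x) x@sets)
#' @rdname accessors
#' @export
setMethod("termIds", "OntologyDAG", function(x) names(x@depths))
#' @rdname accessors
#' @export
setMethod("predictions", "PredictionTable", function(x) x@table)
#' @rdname accessors
#' @export
setMethod("pipelineReports", "PredictionTable", function(x) x@reports)
#' @rdname accessors
#' @export
setMethod("pipelineConfigOf", "PredictionTable", function(x) x@config)

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix: %d genes x %d cell lines\n",
              nrow(object), ncol(object)))
  cat("  genes:", paste(head(rownames(object), 4), collapse = ", "),
      if (nrow(object) > 4) "..." else "", "\n")
})

setMethod("show", "ActivityMatrix", function(object) {
  nmiss <- sum(is.na(object@.Data))
  cat(sprintf("ActivityMatrix: %d drugs x %d cell lines (%d missing, %.1f%%)\n",
              nrow(object), ncol(object), nmiss,
              100 * nmiss / length(object@.Data)))
})

setMethod("show", "Compendium", function(object) {
  s <- compendiumSummary(object)
  cat(sprintf("Compendium: %d drug-gene pairs (%d drugs, %d genes)\n",
              s["n_pairs"], s["n_drugs"], s["n_genes"]))
})

setMethod("show", "GeneAnnotation", function(object) {
  cat(sprintf("GeneAnnotation: %d terms, %d distinct genes\n",
              length(object@sets), length(unique(unlist(object@sets)))))
})

setMethod("show", "OntologyDAG", function(object) {
  cat(sprintf("OntologyDAG: %d terms, %d root(s), max depth %d\n",
              length(object@depths), length(object@roots),
              max(object@depths)))
})

setMethod("show", "PredictionTable", function(object) {
  cat(sprintf("PredictionTable: %d drug-gene predictions (%d drugs, %d genes)\n",
              nrow(object@table), length(unique(object@table$drug)),
              length(unique(object@table$gene))))
  if (!is.null(object@config$tau))
    cat(sprintf("  |PCC| threshold tau = %.4g\n", object@config$tau))
})
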