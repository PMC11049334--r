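#' Accessors for multiscale network objects
#'
#' `nodeIds()` returns node ids in index order; `proteinIds()` and
#' `functionIds()` subset by node kind; `nodeTable()` and `edgeTable()`
#' return the underlying data frames; `profileVector()` extracts the named
#' probability vector of a diffusion profile; `scoreFrame()` the ranked
#' score data frame; `compoundIds()` and `compoundTargets()` the compound
#' library contents.
#'
#' @param x the object.
#' @param ... unused.
#' @return See each generic's description.
#' @name accessors
#' @examples
#' net <- buildNetwork(
#'   data.frame(id = c("P1", "P2"), kind = "protein", label = ""),
#'   data.frame(source = "P1", target = "P2", kind = "ppi"))
#' nodeIds(net)
#' proteinIds(net)
NULL

#' @rdname accessors
#' @export
setGeneric("nodeIds", function(x, ...) standardGeneric("nodeIds"))
#' @rdname accessors
#' @export
setGeneric("proteinIds", function(x, ...) standardGeneric("proteinIds"))
#' @rdname accessors
#' @export
setGeneric("functionIds", function(x, ...) standardGeneric("functionIds"))
#' @rdname accessors
#' @export
setGeneric("nodeTable", function(x, ...) standardGeneric("nodeTable"))
#' @rdname accessors
#' @export
setGeneric("edgeTable", function(x, ...) standardGeneric("edgeTable"))
#' @rdname accessors
#' @export
setGeneric("profileVector", function(x, ...) standardGeneric("profileVector"))
#' @rdname accessors
#' @export
setGeneric("scoreFrame", function(x, ...) standardGeneric("scoreFrame"))
#' @rdname accessors
#' @export
setGeneric("scoreMetadata", function(x, ...) standardGeneric("scoreMetadata"))
#' @rdname accessors
#' @export
setGeneric("compoundIds", function(x, ...) standardGeneric("compoundIds"))
#' @rdname accessors
#' @export
setGeneric("compoundTargets", function(x, ...) standardGeneric("compoundTargets"))

#' @rdname accessors
#' @export
setMethod("nodeIds", "MultiscaleNetwork", function(x, ...) x@nodes$id)
#' @rdname accessors
#' @export
setMethod("nodeIds", "TransitionMatrix", function(x, ...) x@ids)
#' @rdname accessors
#' @export
setMethod("proteinIds", "MultiscaleNetwork",
          function(x, ...) x@nodes$id[x@nodes$kind == "protein"])
#' @rdname accessors
#' @export
setMethod("functionIds", "MultiscaleNetwork",
          function(x, ...) x@nodes$id[x@nodes$kind == "function"])
#' @rdname accessors
#' @export
setMethod("nodeTable", "MultiscaleNetwork", function(x, ...) x@nodes)
#' @rdname accessors
#' @export
setMethod("edgeTable", "MultiscaleNetwork", function(x, ...) x@edges)
#' @rdname accessors
#' @export
setMethod("profileVector", "DiffusionProfile", function(x, ...) x@r)
#' @rdname accessors
#' @export
setMethod("scoreFrame", "ScoreTable", function(x, ...) x@scores)
#' @rdname accessors
#' @export
setMethod("scoreMetadata", "ScoreTable", function(x, ...) x@metadata)
#' @rdname accessors
#' @export
setMethod("compoundIds", "CompoundLibrary", function(x, ...) x@info$id)
#' @rdname accessors
#' @export
setMethod("compoundTargets", "CompoundLibrary", function(x, ...) x@targets)

setMethod("show", "MultiscaleNetwork", function(object) {
  nk <- table(object@nodes$kind)
  ek <- table(object@edges$kind)
  cat("MultiscaleNetwork with", nrow(object@nodes), "nodes (",
      sum(object@nodes$kind == "protein"), "proteins,",
      sum(object@nodes$kind == "function"), "functions ) and",
      nrow(object@edges), "edges\n")
  if (length(ek))
    cat("  edges:", paste(names(ek), as.integer(ek), collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "TransitionMatrix", function(object) {
  cat("TransitionMatrix:", nrow(object@M), "x", ncol(object@M),
      "with", length(object@M@x), "nonzeros;",
      length(object@dangling), "dangling node(s)\n")
  cat("  class weights:",
      paste(names(object@weights), format(object@weights), sep = "=",
            collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "DiffusionProfile", function(object) {
  top <- sort(object@r, decreasing = TRUE)
  top <- top[seq_len(min(3L, length(top)))]
  cat("DiffusionProfile over", length(object@r), "nodes (alpha =",
      object@alpha, ")\n  iterations:", object@iterations,
      if (object@converged) "(converged)" else "(NOT converged)", "\n")
  cat("  top nodes:",
      paste(names(top), signif(top, 3), sep = "=", collapse = ", "), "\n")
  invisible(NULL)
})

setMethod("show", "ScoreTable", function(object) {
  cat("ScoreTable:", nrow(object@scores), "compounds ranked against",
      sQuote(object@metadata$disease), "\n")
  print(utils::head(object@scores, 5))
  nEx <- NROW(object@metadata$excluded)
  if (nEx > 0) cat("  (", nEx, "compound(s) excluded by the target filter )\n")
  invisible(NULL)
})

setMethod("show", "OverlapTest", function(object) {
  cat(sprintf("OverlapTest: k=%d of n=%d targets vs K=%d disease proteins in N=%d; P(X>=k) = %.4g\n",
              object@k, object@n, object@K, object@N, object@pValue))
  invisible(NULL)
})

setMethod("show", "ClassificationEval", function(object) {
  cat(sprintf("ClassificationEval: AUROC = %.4f, AUPR = %.4f (%d positives of %d)\n",
              object@auroc, object@aupr, object@nPositive, object@nTotal))
  invisible(NULL)
})

setMethod("show", "MechanismSubnetwork", function(object) {
  cat("MechanismSubnetwork for", object@compoundId, "vs", object@diseaseName,
      ":", nrow(object@nodes), "nodes,", nrow(object@edges), "edges\n")
  prim <- object@nodes$id[object@nodes$primary]
  if (length(prim)) cat("  primary mechanism candidate:", prim, "\n")
  invisible(NULL)
})

setMethod("show", "SyntheticBenchmark", function(object) {
  cat("SyntheticBenchmark (seed", object@provenance$seed, "):\n  ")
  show(object@network)
  cat("  disease module:", length(object@disease@proteins), "proteins;",
      nrow(object@compounds@info), "compounds (",
      sum(object@labels$label == 1L), "planted positives )\n")
  invisible(NULL)
})
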