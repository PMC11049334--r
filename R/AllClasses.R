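#' @import methods
#' @importFrom Matrix sparseMatrix rowSums
#' @importClassesFrom Matrix dgCMatrix
NULL

.NODE_KINDS <- c("protein", "function")
.EDGE_KINDS <- c("ppi", "annotation", "hierarchy")
.MOVE_CLASSES <- c("pp", "pf", "fp", "ff_up", "ff_down")

#' Multiscale protein-function network
#'
#' A heterogeneous network with two node kinds (`protein`, `function`) and
#' three typed edge classes: `ppi` (protein-protein, undirected),
#' `annotation` (protein-function, undirected) and `hierarchy`
#' (function-function, stored child -> parent). The node index is fixed at
#' build time, lexicographic by node id, so downstream matrices and
#' diffusion profiles are reproducible.
#'
#' @slot nodes data.frame with columns `id`, `kind`, `label`, sorted by id.
#' @slot edges data.frame with columns `source`, `target`, `kind`;
#'   `ppi` edges are stored with `source < target`, `annotation` edges with
#'   the protein as source, `hierarchy` edges child -> parent.
#' @slot index named integer vector mapping node id to ordinal.
#'
#' @seealso [buildNetwork()]
#' @export
setClass("MultiscaleNetwork",
  representation(nodes = "data.frame", edges = "data.frame",
                 index = "integer"))

setValidity("MultiscaleNetwork", function(object) {
  nd <- object@nodes
  ed <- object@edges
  msg <- character()
  if (!all(c("id", "kind", "label") %in% names(nd)))
    return("nodes must have columns id, kind, label")
  if (!all(c("source", "target", "kind") %in% names(ed)))
    return("edges must have columns source, target, kind")
  if (anyDuplicated(nd$id))
    msg <- c(msg, "duplicate node ids")
  if (!all(nd$kind %in% .NODE_KINDS))
    msg <- c(msg, "node kind must be 'protein' or 'function'")
  if (is.unsorted(nd$id))
    msg <- c(msg, "nodes must be sorted by id")
  if (!identical(object@index, stats::setNames(seq_len(nrow(nd)), nd$id)))
    msg <- c(msg, "index must map sorted node ids to ordinals")
  if (nrow(ed) > 0) {
    if (!all(ed$kind %in% .EDGE_KINDS))
      msg <- c(msg, "edge kind must be ppi, annotation or hierarchy")
    if (!all(c(ed$source, ed$target) %in% nd$id))
      msg <- c(msg, "edge endpoint not present among nodes")
    if (any(ed$source == ed$target))
      msg <- c(msg, "self-loops are not allowed")
    if (anyDuplicated(ed[, c("source", "target", "kind")]))
      msg <- c(msg, "duplicate (source, target, kind) edges")
    kindOf <- stats::setNames(nd$kind, nd$id)
    sk <- kindOf[ed$source]; tk <- kindOf[ed$target]
    bad <- (ed$kind == "ppi" & !(sk == "protein" & tk == "protein")) |
      (ed$kind == "annotation" & !(sk == "protein" & tk == "function")) |
      (ed$kind == "hierarchy" & !(sk == "function" & tk == "function"))
    if (any(bad, na.rm = TRUE))
      msg <- c(msg, "edge kind inconsistent with endpoint kinds")
    hi <- ed[ed$kind == "hierarchy", , drop = FALSE]
    if (nrow(hi) > 0) {
      g <- igraph::graph_from_data_frame(hi[, c("source", "target")],
                                         directed = TRUE)
      if (!igraph::is_dag(g))
        msg <- c(msg, "hierarchy subgraph (child -> parent) contains a cycle")
    }
  }
  if (length(msg)) msg else TRUE
})

#' Biased row-stochastic transition matrix
#'
#' Walk matrix over the node index of a [MultiscaleNetwork-class]. Each
#' typed edge is expanded into directed moves whose weights depend only on
#' the move class (see [edgeWeightScheme()]); rows are normalized to sum to
#' one. Nodes with no outgoing moves form the dangling set `J` and keep an
#' all-zero row; their walk mass is redistributed through the restart
#' vector during diffusion.
#'
#' @slot M sparse `dgCMatrix`, rows sum to 1 or to 0 (dangling).
#' @slot dangling integer ordinals of dangling nodes.
#' @slot weights the edge-class weight scheme used.
#' @slot ids node ids in index order.
#'
#' @seealso [buildTransitionMatrix()]
#' @export
setClass("TransitionMatrix",
  representation(M = "dgCMatrix", dangling = "integer",
                 weights = "numeric", ids = "character"))

setValidity("TransitionMatrix", function(object) {
  M <- object@M
  n <- nrow(M)
  msg <- character()
  if (n != ncol(M)) return("M must be square")
  if (length(object@ids) != n) return("ids length must match matrix order")
  rs <- Matrix::rowSums(M)
  dang <- sort(object@dangling)
  if (any(M@x < 0)) msg <- c(msg, "M must be nonnegative")
  ok <- abs(rs - 1) < 1e-12
  zero <- rs == 0
  if (!all(ok | zero))
    msg <- c(msg, "every row must sum to 1 (within 1e-12) or be all-zero")
  if (!identical(dang, as.integer(which(zero))))
    msg <- c(msg, "dangling set must equal the all-zero rows")
  if (length(msg)) msg else TRUE
})

#' Diffusion profile
#'
#' Stationary visitation-probability vector of a random walk with restart;
#' nonnegative, L1-normalized over the node index. Carries the iteration
#' trace so convergence behaviour can be inspected.
#'
#' @slot r named numeric vector, entries >= 0, sum 1 (within 1e-9).
#' @slot alpha continuation probability used.
#' @slot epsilon L1 convergence tolerance used (NA for the exact solver).
#' @slot iterations number of power iterations performed (0 for exact).
#' @slot converged logical; FALSE if `max_iter` was hit first.
#' @slot residuals L1 residual after each iteration.
#'
#' @seealso [diffusePower()], [diffuseExact()]
#' @export
setClass("DiffusionProfile",
  representation(r = "numeric", alpha = "numeric", epsilon = "numeric",
                 iterations = "integer", converged = "logical",
                 residuals = "numeric"))

setValidity("DiffusionProfile", function(object) {
  r <- object@r
  msg <- character()
  if (is.null(names(r))) msg <- c(msg, "profile vector must be named")
  if (any(r < 0)) msg <- c(msg, "profile entries must be nonnegative")
  if (abs(sum(r) - 1) > 1e-9) msg <- c(msg, "profile must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Compound library
#'
#' Compounds with identifiers and protein target sets, as parsed from the
#' compound table dialect (`compound_id`, `name`, `pubchem_cid`, `targets`
#' with semicolon-separated node ids).
#'
#' @slot info data.frame with columns `id`, `name`, `pubchem_cid`.
#' @slot targets named list (by compound id) of character vectors of
#'   protein node ids.
#' @export
setClass("CompoundLibrary",
  representation(info = "data.frame", targets = "list"))

setValidity("CompoundLibrary", function(object) {
  if (!all(c("id", "name", "pubchem_cid") %in% names(object@info)))
    return("info must have columns id, name, pubchem_cid")
  if (anyDuplicated(object@info$id))
    return(paste0("duplicate compound id: ",
                  object@info$id[duplicated(object@info$id)][1]))
  if (!identical(sort(names(object@targets)), sort(object@info$id)))
    return("targets must be a list named by compound id")
  TRUE
})

#' Disease signature
#'
#' A disease represented by its associated protein set; the restart vector
#' of the disease diffusion profile is uniform over these proteins.
#'
#' @slot name disease name.
#' @slot proteins character vector of protein node ids.
#' @export
setClass("DiseaseSignature",
  representation(name = "character", proteins = "character"))

setValidity("DiseaseSignature", function(object) {
  if (length(object@proteins) == 0) return("protein set must be nonempty")
  if (anyDuplicated(object@proteins)) return("duplicate disease proteins")
  TRUE
})

#' Ranked compound score table
#'
#' Per-compound correlation scores against one disease, ranked descending
#' (ties broken by compound id). Metadata records the diffusion parameters,
#' edge-class weights, disease name and any compounds excluded by the
#' minimum-target filter.
#'
#' @slot scores data.frame with columns `compound_id`, `name`,
#'   `n_targets_in_network`, `score`, `rank`.
#' @slot metadata list (alpha, epsilon, weights, disease, min_targets,
#'   excluded).
#' @export
setClass("ScoreTable",
  representation(scores = "data.frame", metadata = "list"))

setValidity("ScoreTable", function(object) {
  sc <- object@scores
  need <- c("compound_id", "name", "n_targets_in_network", "score", "rank")
  if (!all(need %in% names(sc)))
    return(paste("scores must have columns", paste(need, collapse = ", ")))
  if (nrow(sc) > 0) {
    if (any(sc$score < -1 - 1e-12 | sc$score > 1 + 1e-12))
      return("scores must lie in [-1, 1]")
    if (!identical(sc$rank, seq_len(nrow(sc))))
      return("ranks must be 1..N in table order")
    if (is.unsorted(-sc$score)) return("table must be sorted by descending score")
  }
  TRUE
})

#' Hypergeometric overlap test result
#'
#' Upper-tail hypergeometric test of the overlap between a compound's
#' target set and the disease protein set within a fixed universe.
#'
#' @slot k observed overlap count.
#' @slot n compound targets in the universe.
#' @slot K disease proteins in the universe.
#' @slot N universe size.
#' @slot pValue upper-tail probability P(X >= k).
#' @export
setClass("OverlapTest",
  representation(k = "integer", n = "integer", K = "integer",
                 N = "integer", pValue = "numeric"))

#' Ranking evaluation against known positives
#'
#' AUROC and AUPR of a score table labelled by membership in a known
#' positive set, plus the ROC and precision-recall curve points.
#'
#' @slot auroc area under the ROC curve (pairwise concordance).
#' @slot aupr area under the precision-recall curve (average precision).
#' @slot nPositive,nTotal label counts.
#' @slot pairs data.frame of `(id, score, label)` in rank order.
#' @slot rocPoints data.frame `(fpr, tpr)`.
#' @slot prPoints data.frame `(recall, precision)`.
#' @export
setClass("ClassificationEval",
  representation(auroc = "numeric", aupr = "numeric",
                 nPositive = "integer", nTotal = "integer",
                 pairs = "data.frame", rocPoints = "data.frame",
                 prPoints = "data.frame"))

#' Top-k mechanism subnetwork
#'
#' Induced subnetwork over the top-k nodes of the compound and disease
#' diffusion profiles plus their seed nodes. Every node carries origin tags
#' (`top-k-of-compound`, `top-k-of-disease`, `compound-target`,
#' `disease-protein`) and both profile values; compound targets with no
#' link to disease-associated nodes or selected functions are omitted.
#'
#' @slot compoundId,diseaseName identifiers of the pair.
#' @slot nodes data.frame `(id, kind, origins, r_compound, r_disease,
#'   primary)`; `origins` is comma-separated, `primary` marks the
#'   highest-visitation mechanism candidate.
#' @slot edges data.frame `(source, target, kind)` induced typed edges.
#' @export
setClass("MechanismSubnetwork",
  representation(compoundId = "character", diseaseName = "character",
                 nodes = "data.frame", edges = "data.frame"))

setValidity("MechanismSubnetwork", function(object) {
  nd <- object@nodes; ed <- object@edges
  if (nrow(nd) == 0) return("subnetwork has no nodes")
  if (any(!nzchar(nd$origins))) return("every node needs an origin tag")
  if (nrow(ed) > 0 && !all(c(ed$source, ed$target) %in% nd$id))
    return("induced edge with unselected endpoint")
  TRUE
})

#' Synthetic benchmark bundle
#'
#' A generated multiscale network, disease signature and compound library
#' with planted positive compounds, plus truth labels and full provenance
#' (configuration, seed, RNG kind, package version) for reproducibility.
#'
#' @slot network the [MultiscaleNetwork-class].
#' @slot disease the [DiseaseSignature-class].
#' @slot compounds the [CompoundLibrary-class].
#' @slot labels data.frame `(compound_id, label)` with 1 = planted positive.
#' @slot provenance list recording config, seed and generator identity.
#' @export
setClass("SyntheticBenchmark",
  representation(network = "MultiscaleNetwork",
                 disease = "DiseaseSignature",
                 compounds = "CompoundLibrary",
                 labels = "data.frame", provenance = "list"))
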