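#' Build a validated multiscale network
#'
#' Assembles a [MultiscaleNetwork-class] from node and edge records.
#' `ppi` and `annotation` edges are undirected relations and are stored
#' once in canonical orientation (`ppi` with `source < target`,
#' `annotation` with the protein as source); `hierarchy` edges keep their
#' direction, read child -> parent. Duplicate edges (in either orientation
#' for the undirected classes) are deduplicated with a warning: the
#' interactome is a binary relation, not a multigraph. The node index is
#' lexicographic by id and fixed at build time.
#'
#' @param nodeRecords data.frame with columns `id`, `kind`
#'   (`protein`/`function`) and optionally `label`.
#' @param edgeRecords data.frame with columns `source`, `target`, `kind`
#'   (`ppi`/`annotation`/`hierarchy`).
#' @return A validated [MultiscaleNetwork-class].
#' @examples
#' nodes <- data.frame(id = c("P1", "P2", "F1"),
#'                     kind = c("protein", "protein", "function"),
#'                     label = "")
#' edges <- data.frame(source = c("P1", "P1"), target = c("P2", "F1"),
#'                     kind = c("ppi", "annotation"))
#' buildNetwork(nodes, edges)
#' @export
buildNetwork <- function(nodeRecords, edgeRecords) {
  stopifnot(is.data.frame(nodeRecords))
  if (is.null(edgeRecords))
    edgeRecords <- data.frame(source = character(), target = character(),
                              kind = character())
  stopifnot(is.data.frame(edgeRecords))
  if (!all(c("id", "kind") %in% names(nodeRecords)))
    stop("node records need columns 'id' and 'kind'")
  nodes <- data.frame(id = as.character(nodeRecords$id),
                      kind = as.character(nodeRecords$kind),
                      label = if ("label" %in% names(nodeRecords))
                        as.character(nodeRecords$label) else "",
                      stringsAsFactors = FALSE)
  if (nrow(nodes) == 0) stop("empty network: no nodes")
  if (anyDuplicated(nodes$id))
    stop("duplicate node id: ", nodes$id[duplicated(nodes$id)][1])
  bad <- setdiff(nodes$kind, .NODE_KINDS)
  if (length(bad)) stop("unknown node kind: ", bad[1])
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  rownames(nodes) <- NULL

  edges <- data.frame(source = as.character(edgeRecords$source),
                      target = as.character(edgeRecords$target),
                      kind = as.character(edgeRecords$kind),
                      stringsAsFactors = FALSE)
  if (nrow(edges) > 0) {
    unknown <- setdiff(c(edges$source, edges$target), nodes$id)
    if (length(unknown))
      stop("edge endpoint not declared as a node: ", unknown[1])
    badKind <- setdiff(edges$kind, .EDGE_KINDS)
    if (length(badKind)) stop("unknown edge kind: ", badKind[1])
    if (any(edges$source == edges$target))
      stop("self-loop on node ",
           edges$source[edges$source == edges$target][1])
    kindOf <- stats::setNames(nodes$kind, nodes$id)
    sk <- kindOf[edges$source]; tk <- kindOf[edges$target]
    # canonical orientation for the undirected classes
    flip <- edges$kind == "ppi" & edges$source > edges$target
    tmp <- edges$source[flip]
    edges$source[flip] <- edges$target[flip]; edges$target[flip] <- tmp
    flip <- edges$kind == "annotation" & sk == "function"
    tmp <- edges$source[flip]
    edges$source[flip] <- edges$target[flip]; edges$target[flip] <- tmp
    sk <- kindOf[edges$source]; tk <- kindOf[edges$target]
    bad <- (edges$kind == "ppi" & !(sk == "protein" & tk == "protein")) |
      (edges$kind == "annotation" &
         !(sk == "protein" & tk == "function")) |
      (edges$kind == "hierarchy" & !(sk == "function" & tk == "function"))
    if (any(bad)) {
      i <- which(bad)[1]
      stop(sprintf("edge kind '%s' inconsistent with endpoint kinds (%s: %s, %s: %s)",
                   edges$kind[i], edges$source[i], sk[i],
                   edges$target[i], tk[i]))
    }
    dup <- duplicated(edges[, c("source", "target", "kind")])
    if (any(dup)) {
      warning(sum(dup), " duplicate edge(s) dropped")
      edges <- edges[!dup, , drop = FALSE]
    }
    hi <- edges[edges$kind == "hierarchy", , drop = FALSE]
    if (nrow(hi) > 0) {
      g <- igraph::graph_from_data_frame(hi[, c("source", "target")],
                                         directed = TRUE)
      if (!igraph::is_dag(g))
        stop("hierarchy cycle detected among function nodes")
    }
    edges <- edges[order(edges$kind, edges$source, edges$target), ,
                   drop = FALSE]
    rownames(edges) <- NULL
  }
  new("MultiscaleNetwork", nodes = nodes, edges = edges,
      index = stats::setNames(seq_len(nrow(nodes)), nodes$id))
}

#' Edge-class weight scheme for the biased walk
#'
#' One strictly positive scalar per transition class. The five classes are
#' the directed moves a typed edge permits: `pp` (protein -> protein along
#' ppi), `pf` (protein -> function along annotation), `fp` (function ->
#' protein), `ff_up` (function -> parent function) and `ff_down`
#' (function -> child function). The default is the unbiased scheme (all
#' 1); raising `pf`, `ff_up`/`ff_down` relative to `pp` biases the walk
#' toward the biological-function layer. Per-node normalization makes the
#' scheme scale-invariant: multiplying all weights by a constant leaves
#' the transition matrix unchanged.
#'
#' @param pp,pf,fp,ff_up,ff_down positive class weights.
#' @return Named numeric vector of length 5.
#' @examples
#' edgeWeightScheme()                # unbiased
#' edgeWeightScheme(pf = 2, ff_up = 2, ff_down = 2)  # favour functions
#' @export
edgeWeightScheme <- function(pp = 1, pf = 1, fp = 1, ff_up = 1,
                             ff_down = 1) {
  w <- c(pp = pp, pf = pf, fp = fp, ff_up = ff_up, ff_down = ff_down)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("all edge-class weights must be finite and > 0")
  w
}

# expand typed edges into directed moves with a class label each
.directedMoves <- function(net) {
  ed <- net@edges
  if (nrow(ed) == 0)
    return(data.frame(from = character(), to = character(),
                      class = character()))
  pieces <- list()
  ppi <- ed[ed$kind == "ppi", , drop = FALSE]
  if (nrow(ppi))
    pieces$pp <- data.frame(
      from = c(ppi$source, ppi$target), to = c(ppi$target, ppi$source),
      class = "pp")
  ann <- ed[ed$kind == "annotation", , drop = FALSE]
  if (nrow(ann))
    pieces$ann <- data.frame(
      from = c(ann$source, ann$target), to = c(ann$target, ann$source),
      class = rep(c("pf", "fp"), each = nrow(ann)))
  hi <- ed[ed$kind == "hierarchy", , drop = FALSE]
  if (nrow(hi))
    pieces$hi <- data.frame(
      from = c(hi$source, hi$target), to = c(hi$target, hi$source),
      class = rep(c("ff_up", "ff_down"), each = nrow(hi)))
  do.call(rbind, pieces)
}

#' Derive the biased row-stochastic transition matrix
#'
#' Expands every typed edge of a [MultiscaleNetwork-class] into its
#' directed moves, weights each move by its class weight, and normalizes
#' per source node: for node i with outgoing moves e,
#' `M[i, target(e)] = w(class(e)) / sum(w(class(e')))`. Nodes with no
#' outgoing moves (isolated nodes) get an all-zero row and enter the
#' dangling set.
#'
#' @param net a [MultiscaleNetwork-class].
#' @param weights a weight scheme from [edgeWeightScheme()].
#' @return A [TransitionMatrix-class].
#' @examples
#' nodes <- data.frame(id = c("F1", "P1", "P2"),
#'                     kind = c("function", "protein", "protein"),
#'                     label = "")
#' edges <- data.frame(source = c("P1", "P1"), target = c("P2", "F1"),
#'                     kind = c("ppi", "annotation"))
#' net <- buildNetwork(nodes, edges)
#' tm <- buildTransitionMatrix(net, edgeWeightScheme(pf = 2))
#' Matrix::rowSums(tm@M)   # 1 everywhere: no dangling node here
#' @export
buildTransitionMatrix <- function(net, weights = edgeWeightScheme()) {
  stopifnot(is(net, "MultiscaleNetwork"))
  weights <- edgeWeightScheme(weights[["pp"]], weights[["pf"]],
                              weights[["fp"]], weights[["ff_up"]],
                              weights[["ff_down"]])
  n <- nrow(net@nodes)
  if (n == 0) stop("empty network")
  mv <- .directedMoves(net)
  if (nrow(mv) == 0) {
    M <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                              dims = c(n, n))
    return(new("TransitionMatrix", M = as(M, "CsparseMatrix"),
               dangling = seq_len(n), weights = weights,
               ids = net@nodes$id))
  }
  i <- unname(net@index[mv$from])
  j <- unname(net@index[mv$to])
  w <- unname(weights[mv$class])
  rowTot <- rep(0, n)
  agg <- tapply(w, i, sum)
  rowTot[as.integer(names(agg))] <- agg
  x <- w / rowTot[i]
  M <- Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
  dangling <- as.integer(which(rowTot == 0))
  new("TransitionMatrix", M = as(M, "CsparseMatrix"), dangling = dangling,
      weights = weights, ids = net@nodes$id)
}

#' Construct a transition matrix from an explicit walk matrix
#'
#' Low-level constructor for tests and custom walk structures: wraps an
#' explicit nonnegative matrix whose rows each sum to 1 or to 0 (dangling).
#'
#' @param M square matrix (dense or sparse).
#' @param ids node ids for the rows/columns.
#' @param weights optional weight scheme to record.
#' @return A [TransitionMatrix-class].
#' @export
transitionMatrix <- function(M, ids, weights = edgeWeightScheme()) {
  M <- as(as(Matrix::Matrix(M, sparse = TRUE), "generalMatrix"),
          "CsparseMatrix")
  rs <- Matrix::rowSums(M)
  new("TransitionMatrix", M = M, dangling = as.integer(which(rs == 0)),
      weights = weights, ids = as.character(ids))
}
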