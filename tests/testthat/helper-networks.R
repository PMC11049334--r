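# Small fixture builders used across the suite.

# two proteins joined by one ppi edge
twoProteinNet <- function() {
  buildNetwork(
    data.frame(id = c("P1", "P2"), kind = "protein", label = ""),
    data.frame(source = "P1", target = "P2", kind = "ppi"))
}

# P1 -ppi- P2, P1 -annotation- F1
mixedNet <- function() {
  buildNetwork(
    data.frame(id = c("F1", "P1", "P2"),
               kind = c("function", "protein", "protein"), label = ""),
    data.frame(source = c("P1", "P1"), target = c("P2", "F1"),
               kind = c("ppi", "annotation")))
}

# random typed network: gnp-style ppi layer, tree-ish hierarchy, random
# annotations; optionally a few isolated proteins (dangling rows in the
# transition matrix). Independent of the package's synthetic generator.
randomTypedNet <- function(nP = 20, nF = 8, pEdge = 0.15,
                           nIsolated = 0, seed = 1) {
  set.seed(seed)
  pid <- sprintf("p%02d", seq_len(nP))
  fid <- sprintf("f%02d", seq_len(nF))
  pairs <- utils::combn(nP, 2)
  keep <- stats::runif(ncol(pairs)) < pEdge
  ppi <- if (any(keep)) data.frame(source = pid[pairs[1, keep]],
                                   target = pid[pairs[2, keep]],
                                   kind = "ppi") else NULL
  hier <- if (nF >= 2) data.frame(
    source = fid[2:nF],
    target = fid[vapply(2:nF, function(i) sample.int(i - 1, 1), 1L)],
    kind = "hierarchy") else NULL
  nAnn <- max(1, round(nP * 0.8))
  ann <- data.frame(source = pid[sample.int(nP, nAnn, replace = TRUE)],
                    target = fid[sample.int(nF, nAnn, replace = TRUE)],
                    kind = "annotation")
  ann <- ann[!duplicated(ann[, c("source", "target")]), , drop = FALSE]
  edges <- do.call(rbind, Filter(Negate(is.null), list(ppi, hier, ann)))
  if (nIsolated > 0) {
    iso <- sprintf("z%02d", seq_len(nIsolated))  # sorts last, stays isolated
    pid <- c(pid, iso)
  }
  nodes <- data.frame(id = c(pid, fid),
                      kind = rep(c("protein", "function"),
                                 c(length(pid), nF)),
                      label = "")
  buildNetwork(nodes, edges)
}

randomRestart <- function(net, nSeeds = 2, seed = 1) {
  set.seed(seed)
  makeRestartVector(net, sample(nodeIds(net), nSeeds))
}
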