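#' Top-k nodes of a diffusion profile
#'
#' The k highest-probability nodes of a profile, in descending order with
#' ties broken by node id, optionally after removing an exclusion set.
#' The default k = 20 captures a substantial share of the visitation
#' frequency on interactome-scale profiles.
#'
#' @param profile a [DiffusionProfile-class] or named numeric vector.
#' @param k number of nodes to keep (>= 1); if k exceeds the number of
#'   available nodes, all are returned.
#' @param exclude character vector of node ids to skip.
#' @return Character vector of node ids, length `min(k, available)`.
#' @export
topKNodes <- function(profile, k = 20L, exclude = character()) {
  r <- if (is(profile, "DiffusionProfile")) profile@r else profile
  if (is.null(names(r))) stop("profile must be named by node id")
  k <- as.integer(k)
  if (is.na(k) || k < 1) stop("k must be >= 1")
  r <- r[!(names(r) %in% exclude)]
  ord <- order(-r, names(r))
  names(r)[ord[seq_len(min(k, length(r)))]]
}

#' Extract the compound-disease mechanism subnetwork
#'
#' Selects the union of the top-k nodes of the compound profile, the
#' top-k nodes of the disease profile, the compound's in-network targets
#' and the disease proteins; tags each node with its origin(s); attaches
#' the induced typed edges; and then omits any compound-target node that
#' is not linked (within `maxHops` hops inside the induced subnetwork,
#' default adjacency) to a disease-associated node (disease protein or
#' top-k disease node) or to any selected biological-function node.
#' Disease proteins and top-k disease nodes are never removed. The
#' selected node with the highest compound-profile visitation is flagged
#' as the primary mechanism candidate.
#'
#' @param net a [MultiscaleNetwork-class].
#' @param rc,rd compound and disease [DiffusionProfile-class] objects on
#'   `net`'s node index.
#' @param compound a [CompoundLibrary-class] row subset (single compound)
#'   or a character vector of target ids; used for the `compound-target`
#'   origin.
#' @param disease a [DiseaseSignature-class] or character vector.
#' @param compoundId,diseaseName identifiers recorded in the result (taken
#'   from the objects when available).
#' @param k top-k cutoff per profile (default 20).
#' @param maxHops linkage radius for the omission rule (default 1 =
#'   direct adjacency in the induced subnetwork).
#' @return A [MechanismSubnetwork-class].
#' @export
extractMechanism <- function(net, rc, rd, compound, disease,
                             k = 20L, maxHops = 1L,
                             compoundId = NULL, diseaseName = NULL) {
  stopifnot(is(net, "MultiscaleNetwork"))
  rcv <- if (is(rc, "DiffusionProfile")) rc@r else rc
  rdv <- if (is(rd, "DiffusionProfile")) rd@r else rd
  if (!identical(names(rcv), nodeIds(net)) ||
      !identical(names(rdv), nodeIds(net)))
    stop("profiles must be computed on this network's node index")
  if (is(compound, "CompoundLibrary")) {
    if (nrow(compound@info) != 1) stop("pass a single compound")
    if (is.null(compoundId)) compoundId <- compound@info$id
    targets <- compound@targets[[1]]
  } else targets <- as.character(compound)
  if (is(disease, "DiseaseSignature")) {
    if (is.null(diseaseName)) diseaseName <- disease@name
    disProt <- disease@proteins
  } else disProt <- as.character(disease)
  if (is.null(compoundId)) compoundId <- "compound"
  if (is.null(diseaseName)) diseaseName <- "disease"
  targets <- intersect(targets, nodeIds(net))
  disProt <- intersect(disProt, nodeIds(net))

  topC <- topKNodes(rcv, k)
  topD <- topKNodes(rdv, k)
  selected <- sort(unique(c(topC, topD, targets, disProt)))
  origins <- lapply(stats::setNames(selected, selected), function(id) {
    o <- character()
    if (id %in% topC) o <- c(o, "top-k-of-compound")
    if (id %in% topD) o <- c(o, "top-k-of-disease")
    if (id %in% targets) o <- c(o, "compound-target")
    if (id %in% disProt) o <- c(o, "disease-protein")
    o
  })

  inducedEdges <- function(sel) {
    ed <- net@edges
    ed <- ed[ed$source %in% sel & ed$target %in% sel, , drop = FALSE]
    rownames(ed) <- NULL
    ed
  }
  ed <- inducedEdges(selected)

  kindOf <- stats::setNames(net@nodes$kind, net@nodes$id)
  diseaseAssoc <- selected[vapply(origins[selected], function(o)
    any(o %in% c("disease-protein", "top-k-of-disease")), logical(1))]
  funcSel <- selected[kindOf[selected] == "function"]
  anchors <- union(diseaseAssoc, funcSel)
  removable <- selected[vapply(origins[selected], function(o)
    "compound-target" %in% o &&
      !any(o %in% c("disease-protein", "top-k-of-disease")), logical(1))]
  removable <- setdiff(removable, anchors)

  if (length(removable)) {
    keepAnchors <- setdiff(anchors, removable)
    linked <- if (length(keepAnchors) == 0) character() else {
      g <- igraph::graph_from_data_frame(
        ed[, c("source", "target")], directed = FALSE,
        vertices = data.frame(name = selected))
      d <- igraph::distances(g, v = removable, to = keepAnchors)
      removable[apply(d, 1, function(x) any(x <= maxHops))]
    }
    drop <- setdiff(removable, linked)
    if (length(drop)) {
      selected <- setdiff(selected, drop)
      origins <- origins[selected]
      ed <- inducedEdges(selected)
    }
  }
  if (length(selected) == 0)
    stop("mechanism subnetwork is empty after filtering: compound ",
         compoundId, " is disconnected from the disease context")

  rSel <- rcv[selected]
  primary <- selected[order(-rSel, selected)][1]
  nodes <- data.frame(
    id = selected,
    kind = unname(kindOf[selected]),
    origins = vapply(origins[selected], paste, "", collapse = ","),
    r_compound = unname(rcv[selected]),
    r_disease = unname(rdv[selected]),
    primary = selected == primary,
    stringsAsFactors = FALSE)
  rownames(nodes) <- NULL
  new("MechanismSubnetwork", compoundId = as.character(compoundId),
      diseaseName = as.character(diseaseName), nodes = nodes, edges = ed)
}

#' Export a mechanism subnetwork
#'
#' Writes the subnetwork as SIF (`node <TAB> edge-kind <TAB> node`, rows
#' sorted deterministically) or GraphML (with node attributes `kind`,
#' `origins`, `r_compound`, `r_disease`, `primary`). A companion node
#' attribute TSV (`<path>.nodes.tsv`) is always written alongside.
#'
#' @param sub a [MechanismSubnetwork-class].
#' @param path output file path.
#' @param format `"sif"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
exportSubnetwork <- function(sub, path, format = c("sif", "graphml")) {
  stopifnot(is(sub, "MechanismSubnetwork"))
  format <- match.arg(format)
  if (nrow(sub@nodes) == 0) stop("empty subnetwork; nothing to export")
  ed <- sub@edges
  ed <- ed[order(ed$source, ed$kind, ed$target), , drop = FALSE]
  nd <- sub@nodes[order(sub@nodes$id), , drop = FALSE]
  if (format == "sif") {
    lines <- if (nrow(ed)) paste(ed$source, ed$kind, ed$target, sep = "\t")
             else character()
    isolated <- setdiff(nd$id, c(ed$source, ed$target))
    writeLines(c(lines, isolated), path)
  } else {
    g <- igraph::graph_from_data_frame(
      if (nrow(ed)) ed[, c("source", "target", "kind")] else
        data.frame(source = character(), target = character(),
                   kind = character()),
      directed = FALSE, vertices = nd)
    igraph::write_graph(g, path, format = "graphml")
  }
  ndOut <- nd
  ndOut$r_compound <- sprintf("%.12g", ndOut$r_compound)
  ndOut$r_disease <- sprintf("%.12g", ndOut$r_disease)
  utils::write.table(ndOut, paste0(path, ".nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
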