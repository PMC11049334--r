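#' Configuration for the synthetic benchmark generator
#'
#' Defines the study conditions the generator emulates: a connected
#' scale-free protein-protein interaction layer (preferential attachment),
#' a rooted biological-function hierarchy (b-ary tree plus occasional
#' extra parents, acyclic by construction), locality-aware
#' protein-function annotations (proteins near a function's anchor protein
#' in the PPI layer are annotated to it more often), a connected disease
#' module grown by snowball sampling, and a compound library in which
#' planted positives draw their targets from within `locality` hops of
#' the disease module (with a global `noise` fraction of uniformly drawn
#' targets) while negatives draw uniformly. Positives and negatives draw
#' their target counts from the same long-tailed distribution, so
#' recovery of the planted signal cannot be a target-set-size artifact.
#'
#' @param nProteins number of proteins in the PPI layer.
#' @param ppiAttachment edges added per new protein in the preferential
#'   attachment process (controls density).
#' @param nFunctions number of biological-function nodes.
#' @param branching branching factor of the function hierarchy tree.
#' @param annotationsPerProtein mean annotations per protein (Poisson).
#' @param diseaseSize disease module size (proteins).
#' @param nCompounds library size.
#' @param nPositives number of planted positive compounds
#'   (< `nCompounds`).
#' @param targetRange `c(min, max)` bounds on targets per compound; the
#'   count distribution is a truncated geometric (long-tailed), identical
#'   for positives and negatives.
#' @param locality hop radius around the disease module from which
#'   positives draw targets (0 = inside the module only).
#' @param noise fraction of each positive's targets drawn uniformly from
#'   all proteins instead of the locality pool; `noise = 1` disables
#'   planting entirely.
#' @param seed integer random seed.
#' @return Validated configuration list.
#' @export
syntheticConfig <- function(nProteins = 500L, ppiAttachment = 2L,
                            nFunctions = 150L, branching = 3L,
                            annotationsPerProtein = 2,
                            diseaseSize = 20L, nCompounds = 40L,
                            nPositives = 8L, targetRange = c(3L, 30L),
                            locality = 1L, noise = 0.1, seed = 1L) {
  cfg <- list(nProteins = as.integer(nProteins),
              ppiAttachment = as.integer(ppiAttachment),
              nFunctions = as.integer(nFunctions),
              branching = as.integer(branching),
              annotationsPerProtein = as.numeric(annotationsPerProtein),
              diseaseSize = as.integer(diseaseSize),
              nCompounds = as.integer(nCompounds),
              nPositives = as.integer(nPositives),
              targetRange = as.integer(targetRange),
              locality = as.integer(locality),
              noise = as.numeric(noise),
              seed = as.integer(seed))
  with(cfg, {
    if (nProteins < 3 || nFunctions < 2) stop("network too small")
    if (ppiAttachment < 1 || branching < 1) stop("invalid attachment/branching")
    if (annotationsPerProtein < 0) stop("annotationsPerProtein must be >= 0")
    if (diseaseSize < 1 || diseaseSize > nProteins)
      stop("disease module size out of range")
    if (nCompounds < 2 || nPositives < 1 || nPositives >= nCompounds)
      stop("need 1 <= nPositives < nCompounds")
    if (length(targetRange) != 2 || targetRange[1] < 1 ||
        targetRange[2] < targetRange[1])
      stop("targetRange must be c(min, max) with 1 <= min <= max")
    if (targetRange[2] > nProteins)
      stop("targetRange exceeds the number of proteins")
    if (locality < 0) stop("locality must be >= 0")
    if (noise < 0 || noise > 1) stop("noise must be in [0, 1]")
  })
  cfg
}

.proteinId <- function(i) sprintf("P%04d", i)
.functionId <- function(i) sprintf("F%04d", i)

# PPI layer as an igraph object (for distance computations)
.ppiGraph <- function(net) {
  ppi <- net@edges[net@edges$kind == "ppi", , drop = FALSE]
  igraph::graph_from_data_frame(ppi[, c("source", "target")],
                                directed = FALSE,
                                vertices = data.frame(name = proteinIds(net)))
}

.genNetwork <- function(cfg) {
  nP <- cfg$nProteins; nF <- cfg$nFunctions
  pg <- igraph::sample_pa(nP, m = cfg$ppiAttachment, directed = FALSE)
  el <- igraph::as_edgelist(pg, names = FALSE)
  ppi <- unique(data.frame(
    source = .proteinId(pmin(el[, 1], el[, 2])),
    target = .proteinId(pmax(el[, 1], el[, 2])),
    kind = "ppi", stringsAsFactors = FALSE))
  # rooted hierarchy: b-ary tree, child -> parent, plus sparse extra parents
  child <- seq(2L, nF)
  parent <- ((child - 2L) %/% cfg$branching) + 1L
  hier <- data.frame(source = .functionId(child),
                     target = .functionId(parent),
                     kind = "hierarchy", stringsAsFactors = FALSE)
  extra <- which(child >= 3L & stats::runif(length(child)) < 0.1)
  if (length(extra)) {
    ep <- vapply(child[extra],
                 function(i) sample.int(i - 1L, 1L), integer(1))
    hier <- rbind(hier, data.frame(source = .functionId(child[extra]),
                                   target = .functionId(ep),
                                   kind = "hierarchy"))
    hier <- hier[hier$source != hier$target, , drop = FALSE]
    hier <- hier[!duplicated(hier[, c("source", "target")]), , drop = FALSE]
  }
  # locality-aware annotations: each function anchors at a protein;
  # a protein is annotated preferentially to functions anchored nearby
  anchors <- sample.int(nP, nF, replace = TRUE)
  ua <- unique(anchors)
  D <- igraph::distances(pg, v = seq_len(nP), to = ua)[, match(anchors, ua),
                                                       drop = FALSE]
  nAnn <- stats::rpois(nP, cfg$annotationsPerProtein)
  annList <- lapply(seq_len(nP), function(p) {
    k <- min(nAnn[p], nF)
    if (k == 0) return(NULL)
    w <- exp(-D[p, ] / 2)
    w[!is.finite(w)] <- 1e-12
    f <- sample.int(nF, k, prob = w)
    data.frame(source = .proteinId(p), target = .functionId(f),
               kind = "annotation", stringsAsFactors = FALSE)
  })
  ann <- do.call(rbind, annList[!vapply(annList, is.null, logical(1))])
  nodes <- data.frame(
    id = c(.proteinId(seq_len(nP)), .functionId(seq_len(nF))),
    kind = rep(c("protein", "function"), c(nP, nF)),
    label = c(sprintf("protein %d", seq_len(nP)),
              sprintf("function %d", seq_len(nF))),
    stringsAsFactors = FALSE)
  edges <- rbind(ppi, hier, ann)
  edges <- edges[!duplicated(edges[, c("source", "target", "kind")]), ,
                 drop = FALSE]
  buildNetwork(nodes, edges)
}

.genDisease <- function(net, cfg) {
  pg <- .ppiGraph(net)
  prots <- proteinIds(net)
  module <- sample(prots, 1L)
  while (length(module) < cfg$diseaseSize) {
    nb <- unique(unlist(lapply(module, function(v)
      igraph::neighbors(pg, v)$name)))
    frontier <- setdiff(nb, module)
    if (length(frontier) == 0) break   # cannot happen on a connected layer
    module <- c(module, sample(frontier, 1L))
  }
  diseaseSignature("synthetic-disease", module)
}

.targetCounts <- function(n, range) {
  # truncated geometric: long-tailed target counts, shared by all compounds
  pmin(range[2], range[1] + stats::rgeom(n, prob = 0.15))
}

.genCompounds <- function(net, disease, cfg) {
  prots <- proteinIds(net)
  pg <- .ppiGraph(net)
  dmin <- apply(igraph::distances(pg, v = prots, to = disease@proteins),
                1, min)
  pool <- prots[dmin <= cfg$locality]
  sizes <- .targetCounts(cfg$nCompounds, cfg$targetRange)
  posIdx <- sort(sample.int(cfg$nCompounds, cfg$nPositives))
  targets <- vector("list", cfg$nCompounds)
  for (i in seq_len(cfg$nCompounds)) {
    sz <- sizes[i]
    if (i %in% posIdx) {
      nNoise <- stats::rbinom(1L, sz, cfg$noise)
      nLocal <- min(sz - nNoise, length(pool))
      tLocal <- sample(pool, nLocal)
      tNoise <- sample(setdiff(prots, tLocal), sz - nLocal)
      targets[[i]] <- sort(c(tLocal, tNoise))
    } else {
      targets[[i]] <- sort(sample(prots, sz))
    }
  }
  ids <- sprintf("C%03d", seq_len(cfg$nCompounds))
  names(targets) <- ids
  lib <- compoundLibrary(
    data.frame(id = ids, name = sprintf("compound-%03d", seq_len(cfg$nCompounds)),
               pubchem_cid = NA_character_, stringsAsFactors = FALSE),
    targets)
  labels <- data.frame(compound_id = ids,
                       label = as.integer(seq_len(cfg$nCompounds) %in% posIdx),
                       stringsAsFactors = FALSE)
  list(compounds = lib, labels = labels)
}

#' Generate a synthetic multiscale network
#'
#' Seeds the RNG from `cfg$seed` and builds the three-layer network (see
#' [syntheticConfig()] for what each layer emulates). Deterministic:
#' identical configurations reproduce identical networks.
#'
#' @param cfg a [syntheticConfig()] list.
#' @return A [MultiscaleNetwork-class].
#' @export
generateNetwork <- function(cfg = syntheticConfig()) {
  set.seed(cfg$seed)
  .genNetwork(cfg)
}

#' Generate a synthetic disease signature
#'
#' Grows a connected protein module of size `cfg$diseaseSize` by snowball
#' sampling from a random anchor protein in the PPI layer. Seeds the RNG
#' from `cfg$seed + 1` when called standalone.
#'
#' @param net a [MultiscaleNetwork-class].
#' @param cfg a [syntheticConfig()] list.
#' @return A [DiseaseSignature-class].
#' @export
generateDisease <- function(net, cfg = syntheticConfig()) {
  set.seed(cfg$seed + 1L)
  .genDisease(net, cfg)
}

#' Generate a synthetic compound library with planted positives
#'
#' Positives draw targets from within `cfg$locality` hops of the disease
#' module (minus a `cfg$noise` fraction drawn uniformly); negatives draw
#' uniformly; both share the same target-count distribution. Seeds the
#' RNG from `cfg$seed + 2` when called standalone.
#'
#' @param net a [MultiscaleNetwork-class].
#' @param disease a [DiseaseSignature-class].
#' @param cfg a [syntheticConfig()] list.
#' @return List with `compounds` (a [CompoundLibrary-class]) and `labels`
#'   (data.frame `compound_id`, `label`).
#' @export
generateCompounds <- function(net, disease, cfg = syntheticConfig()) {
  set.seed(cfg$seed + 2L)
  .genCompounds(net, disease, cfg)
}

#' Generate a full synthetic benchmark
#'
#' Seeds a single RNG stream from `cfg$seed` and draws the network, the
#' disease module and the compound library from it in that documented
#' order, so the whole benchmark is reproducible from the configuration
#' alone. Optionally serializes everything to the package's standard TSV
#' dialects (`nodes.tsv`, `edges.tsv`, `compounds.tsv`,
#' `disease_proteins.txt`, `truth_labels.tsv`, `provenance.json`); truth
#' labels are written only to the separate truth file, never into the
#' standard inputs.
#'
#' @param cfg a [syntheticConfig()] list.
#' @param dir optional directory to write the TSV inputs to.
#' @return A [SyntheticBenchmark-class].
#' @export
generateBenchmark <- function(cfg = syntheticConfig(), dir = NULL) {
  set.seed(cfg$seed)
  net <- .genNetwork(cfg)
  disease <- .genDisease(net, cfg)
  cl <- .genCompounds(net, disease, cfg)
  prov <- list(config = cfg, seed = cfg$seed,
               rng_kind = RNGkind()[1],
               generator = "multiscaleRWR::generateBenchmark",
               package_version = as.character(utils::packageVersion("multiscaleRWR")))
  bench <- new("SyntheticBenchmark", network = net, disease = disease,
               compounds = cl$compounds, labels = cl$labels,
               provenance = prov)
  if (!is.null(dir)) writeBenchmark(bench, dir)
  bench
}

#' Serialize a benchmark to the standard input files
#'
#' @param bench a [SyntheticBenchmark-class].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
writeBenchmark <- function(bench, dir) {
  stopifnot(is(bench, "SyntheticBenchmark"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(df, f) utils::write.table(
    df, file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(bench@network@nodes, "nodes.tsv")
  wt(bench@network@edges, "edges.tsv")
  info <- bench@compounds@info
  wt(data.frame(compound_id = info$id, name = info$name,
                pubchem_cid = ifelse(is.na(info$pubchem_cid), "",
                                     info$pubchem_cid),
                targets = vapply(bench@compounds@targets[info$id],
                                 paste, "", collapse = ";")),
     "compounds.tsv")
  writeLines(bench@disease@proteins, file.path(dir, "disease_proteins.txt"))
  wt(bench@labels, "truth_labels.tsv")
  jsonlite::write_json(bench@provenance, file.path(dir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
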