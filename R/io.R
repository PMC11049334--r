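.readTsv <- function(path, required) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (nrow(df) == 0) stop("empty input file: ", path)
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("missing column(s) ", paste(missing, collapse = ", "),
         " in ", path)
  df
}

#' Read the standard input tables
#'
#' Readers for the package's TSV dialects. `readNodeTable` expects columns
#' `id`, `kind`, `label` (label optional); `readEdgeTable` expects
#' `source`, `target`, `kind` — edge kinds are case-folded to lower case
#' (with a message when folding changed anything) and must then be one of
#' `ppi`, `annotation`, `hierarchy`; malformed rows are reported with line
#' numbers. `readCompoundTable` expects `compound_id`, `name`,
#' `pubchem_cid`, `targets` (semicolon-separated node ids) and rejects
#' duplicated compound ids by name. `readDiseaseProteins` reads one id per
#' line (blank lines and `#` comments skipped). `readTruthLabels` reads
#' `compound_id`, `label`. `readGeneSets` parses GMT.
#'
#' @param path input file path.
#' @param name disease name for `readDiseaseProteins`.
#' @return The parsed object (data.frame, [CompoundLibrary-class],
#'   [DiseaseSignature-class], or named list of gene sets).
#' @name readers
NULL

#' @rdname readers
#' @export
readNodeTable <- function(path) {
  df <- .readTsv(path, c("id", "kind"))
  if (!"label" %in% names(df)) df$label <- ""
  df$kind <- tolower(df$kind)
  bad <- which(!df$kind %in% .NODE_KINDS)
  if (length(bad))
    stop("unknown node kind '", df$kind[bad[1]], "' at ", path,
         " line ", bad[1] + 1L)
  df[, c("id", "kind", "label")]
}

#' @rdname readers
#' @export
readEdgeTable <- function(path) {
  df <- .readTsv(path, c("source", "target", "kind"))
  folded <- tolower(df$kind)
  if (any(folded != df$kind)) {
    message("edge kinds case-folded to lower case in ", path)
    df$kind <- folded
  }
  bad <- which(!df$kind %in% .EDGE_KINDS)
  if (length(bad))
    stop("unknown edge kind '", df$kind[bad[1]], "' at ", path,
         " line ", bad[1] + 1L)
  df
}

#' @rdname readers
#' @export
readCompoundTable <- function(path) {
  df <- .readTsv(path, c("compound_id", "name", "targets"))
  if (anyDuplicated(df$compound_id))
    stop("duplicated compound id in ", path, ": ",
         df$compound_id[duplicated(df$compound_id)][1])
  targets <- lapply(strsplit(df$targets, ";", fixed = TRUE),
                    function(x) x[nzchar(x)])
  names(targets) <- df$compound_id
  info <- data.frame(id = df$compound_id, name = df$name,
                     pubchem_cid = if ("pubchem_cid" %in% names(df))
                       ifelse(nzchar(df$pubchem_cid), df$pubchem_cid, NA)
                     else NA_character_,
                     stringsAsFactors = FALSE)
  compoundLibrary(info, targets)
}

#' @rdname readers
#' @export
readDiseaseProteins <- function(path, name = "disease") {
  if (!file.exists(path)) stop("input file not found: ", path)
  ids <- trimws(readLines(path))
  ids <- ids[nzchar(ids) & !startsWith(ids, "#")]
  if (length(ids) == 0) stop("empty disease protein list: ", path)
  diseaseSignature(name, ids)
}

#' @rdname readers
#' @export
readTruthLabels <- function(path) {
  df <- .readTsv(path, c("compound_id", "label"))
  df$label <- as.integer(df$label)
  df
}

#' @rdname readers
#' @export
readGeneSets <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  fgsea::gmtPathways(path)
}

#' Pipeline configuration
#'
#' Assembles (or reads from YAML) the configuration that drives
#' [runPipeline()]: input paths, diffusion parameters, edge-class weights,
#' the top-k cutoff, the minimum-target filter, the overlap universe and
#' the output directory. Defaults follow the method's stated values where
#' it states them (epsilon = 1e-6, k = 20, min_targets = 3); alpha and
#' the class weights are configuration choices (defaults 0.85 and the
#' unbiased scheme).
#'
#' @param nodes,edges,compounds,disease_proteins input file paths.
#' @param gene_sets optional GMT path for enrichment.
#' @param positives optional truth-label TSV for evaluation.
#' @param alpha,epsilon,max_iter diffusion parameters.
#' @param weights named list/vector of edge-class weights (pp, pf, fp,
#'   ff_up, ff_down).
#' @param k top-k cutoff for mechanism extraction.
#' @param min_targets minimum in-network targets per compound.
#' @param universe `"network_proteins"` (default) or `"all_nodes"`.
#' @param mechanism_top number of top-ranked compounds to export
#'   mechanism subnetworks for.
#' @param outdir output directory.
#' @param seed integer seed recorded in the manifest.
#' @return Validated configuration list.
#' @export
pipelineConfig <- function(nodes, edges, compounds, disease_proteins,
                           gene_sets = NULL, positives = NULL,
                           alpha = 0.85, epsilon = 1e-6,
                           max_iter = 10000L,
                           weights = edgeWeightScheme(), k = 20L,
                           min_targets = 3L,
                           universe = c("network_proteins", "all_nodes"),
                           mechanism_top = 2L, outdir = "pipeline_out",
                           seed = 1L) {
  universe <- match.arg(universe)
  w <- unlist(weights)
  w <- edgeWeightScheme(w[["pp"]], w[["pf"]], w[["fp"]], w[["ff_up"]],
                        w[["ff_down"]])
  list(nodes = nodes, edges = edges, compounds = compounds,
       disease_proteins = disease_proteins, gene_sets = gene_sets,
       positives = positives, alpha = alpha, epsilon = epsilon,
       max_iter = as.integer(max_iter), weights = as.list(w),
       k = as.integer(k), min_targets = as.integer(min_targets),
       universe = universe, mechanism_top = as.integer(mechanism_top),
       outdir = outdir, seed = as.integer(seed))
}

#' @rdname pipelineConfig
#' @param path YAML file with the fields above.
#' @export
readPipelineConfig <- function(path) {
  y <- yaml::read_yaml(path)
  need <- c("nodes", "edges", "compounds", "disease_proteins")
  missing <- setdiff(need, names(y))
  if (length(missing))
    stop("config missing field(s): ", paste(missing, collapse = ", "))
  args <- y[names(y) %in% names(formals(pipelineConfig))]
  do.call(pipelineConfig, args)
}

#' Read and validate all pipeline inputs
#'
#' @param cfg a [pipelineConfig()] list.
#' @return List with `network`, `compounds`, `disease`, and (possibly
#'   NULL) `geneSets`, `positives`.
#' @export
readInputs <- function(cfg) {
  net <- buildNetwork(readNodeTable(cfg$nodes), readEdgeTable(cfg$edges))
  list(network = net,
       compounds = readCompoundTable(cfg$compounds),
       disease = readDiseaseProteins(cfg$disease_proteins),
       geneSets = if (!is.null(cfg$gene_sets)) readGeneSets(cfg$gene_sets),
       positives = if (!is.null(cfg$positives))
         readTruthLabels(cfg$positives))
}

.stage <- function(name, outdir, expr) {
  tryCatch(expr, error = function(e) {
    qdir <- file.path(outdir, "quarantine")
    if (dir.exists(outdir)) {
      done <- list.files(outdir, full.names = TRUE)
      done <- done[!dir.exists(done) | basename(done) != "quarantine"]
      if (length(done)) {
        dir.create(qdir, showWarnings = FALSE, recursive = TRUE)
        file.rename(done, file.path(qdir, basename(done)))
      }
    }
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Run the full prioritization pipeline
#'
#' Reads and validates the inputs, builds the biased transition matrix,
#' ranks all compounds by diffusion-profile correlation with the disease,
#' runs the per-compound hypergeometric overlap tests (unadjusted, as
#' overlap reporting), optionally runs gene-set enrichment of the pooled
#' in-network targets of the ranked compounds, optionally evaluates the
#' ranking against known positives (AUROC/AUPR), exports mechanism
#' subnetworks for the top-ranked compounds, and writes a run manifest
#' (config snapshot, input checksums, package version, per-stage row
#' counts). Outputs are deterministic given the config and inputs; on any
#' stage error the partial outputs are moved to a `quarantine/`
#' subdirectory and the error is rethrown with the stage name.
#'
#' @param cfg a [pipelineConfig()] list, or the path to a YAML config.
#' @return The output directory, invisibly.
#' @export
runPipeline <- function(cfg) {
  if (is.character(cfg)) cfg <- readPipelineConfig(cfg)
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  inp <- .stage("read_inputs", outdir, readInputs(cfg))
  net <- inp$network
  counts$nodes <- nrow(net@nodes); counts$edges <- nrow(net@edges)
  counts$compounds <- nrow(inp$compounds@info)

  tm <- .stage("transition_matrix", outdir,
               buildTransitionMatrix(net, unlist(cfg$weights)))
  params <- diffusionParams(cfg$alpha, cfg$epsilon, cfg$max_iter)

  st <- .stage("rank", outdir,
               rankCompounds(net, tm, inp$compounds, inp$disease,
                             params, cfg$min_targets))
  .stage("rank", outdir,
         writeScoreTable(st, file.path(outdir, "score_table.tsv")))
  counts$ranked <- nrow(st@scores)

  universe <- if (cfg$universe == "all_nodes") nodeIds(net)
              else proteinIds(net)
  ov <- .stage("overlap", outdir, {
    rows <- lapply(st@scores$compound_id, function(cid) {
      t <- overlapTest(inp$compounds@targets[[cid]], inp$disease, universe)
      data.frame(compound_id = cid, overlap = t@k, n_targets = t@n,
                 n_disease = t@K, universe = t@N,
                 p_value = sprintf("%.6g", t@pValue))
    })
    do.call(rbind, rows)
  })
  utils::write.table(ov, file.path(outdir, "overlap_tests.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  if (!is.null(inp$geneSets)) {
    en <- .stage("enrich", outdir, {
      pooled <- unique(unlist(inp$compounds@targets[st@scores$compound_id]))
      enrichGeneSets(intersect(pooled, proteinIds(net)),
                     inp$geneSets, universe)
    })
    en$p_value <- sprintf("%.6g", en$p_value)
    en$p_adjust <- sprintf("%.6g", en$p_adjust)
    utils::write.table(en, file.path(outdir, "enrichment.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    counts$gene_sets <- nrow(en)
  }

  if (!is.null(inp$positives)) {
    ev <- .stage("evaluate", outdir, {
      pos <- inp$positives$compound_id[inp$positives$label == 1L]
      evaluateKnownPositives(st, pos)
    })
    jsonlite::write_json(
      list(auroc = ev@auroc, aupr = ev@aupr,
           n_positive = ev@nPositive, n_total = ev@nTotal),
      file.path(outdir, "evaluation.json"), auto_unbox = TRUE, digits = NA)
    utils::write.table(ev@rocPoints, file.path(outdir, "roc_points.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(ev@prPoints, file.path(outdir, "pr_points.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  nMech <- min(cfg$mechanism_top, nrow(st@scores))
  if (nMech > 0) {
    .stage("mechanism", outdir, {
      disProt <- intersect(inp$disease@proteins, proteinIds(net))
      rd <- diffusePower(tm, makeRestartVector(net, disProt), params)
      for (i in seq_len(nMech)) {
        cid <- st@scores$compound_id[i]
        tin <- intersect(inp$compounds@targets[[cid]], proteinIds(net))
        rc <- diffusePower(tm, makeRestartVector(net, tin), params)
        sub <- extractMechanism(net, rc, rd, tin, inp$disease,
                                k = cfg$k, compoundId = cid)
        exportSubnetwork(sub, file.path(outdir,
                                        paste0("mechanism_", cid, ".sif")),
                         format = "sif")
      }
    })
    counts$mechanisms <- nMech
  }

  manifest <- list(
    config = cfg,
    input_checksums = as.list(tools::md5sum(stats::na.omit(unlist(
      cfg[c("nodes", "edges", "compounds", "disease_proteins",
            "gene_sets", "positives")])))),
    package_version = as.character(utils::packageVersion("multiscaleRWR")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    row_counts = counts)
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(outdir)
}
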