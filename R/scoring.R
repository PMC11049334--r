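#' Compound library constructor
#'
#' @param info data.frame with columns `id`, `name` and optionally
#'   `pubchem_cid`.
#' @param targets named list (by compound id) of character vectors of
#'   protein node ids.
#' @return A [CompoundLibrary-class].
#' @export
compoundLibrary <- function(info, targets) {
  info <- data.frame(id = as.character(info$id),
                     name = as.character(info$name),
                     pubchem_cid = if ("pubchem_cid" %in% names(info))
                       as.character(info$pubchem_cid) else NA_character_,
                     stringsAsFactors = FALSE)
  targets <- lapply(targets, function(x) sort(unique(as.character(x))))
  new("CompoundLibrary", info = info, targets = targets)
}

#' Disease signature constructor
#'
#' @param name disease name.
#' @param proteins character vector of protein node ids.
#' @return A [DiseaseSignature-class].
#' @export
diseaseSignature <- function(name, proteins) {
  new("DiseaseSignature", name = as.character(name),
      proteins = sort(unique(as.character(proteins))))
}

#' Correlation between two diffusion profiles
#'
#' The ranking statistic: the centered cosine (Pearson correlation)
#' between the compound and disease diffusion profiles,
#' \deqn{\frac{(r^{(c)} - \bar r^{(c)}) \cdot (r^{(d)} - \bar r^{(d)})}
#'   {\|r^{(c)} - \bar r^{(c)}\|_2 \, \|r^{(d)} - \bar r^{(d)}\|_2},}
#' always in [-1, 1]. A constant profile has zero centered norm and
#' raises an error rather than silently returning 0.
#'
#' @param rc,rd [DiffusionProfile-class] objects (or named numeric
#'   vectors) over the same node index.
#' @return A single correlation value.
#' @export
profileCorrelation <- function(rc, rd) {
  a <- if (is(rc, "DiffusionProfile")) rc@r else rc
  b <- if (is(rd, "DiffusionProfile")) rd@r else rd
  if (length(a) != length(b))
    stop("profiles are over different node indices")
  if (!is.null(names(a)) && !is.null(names(b)) &&
      !identical(names(a), names(b)))
    stop("profiles are over different node indices")
  ac <- a - mean(a)
  bc <- b - mean(b)
  na <- sqrt(sum(ac^2)); nb <- sqrt(sum(bc^2))
  if (na == 0 || nb == 0)
    stop("constant diffusion profile: correlation undefined")
  v <- sum(ac * bc) / (na * nb)
  min(1, max(-1, v))
}

#' Rank compounds by diffusion-profile correlation with a disease
#'
#' Computes the disease diffusion profile once, then for every compound
#' with at least `minTargets` in-network protein targets computes its
#' profile (restart uniform over the targets) and its correlation with
#' the disease profile. Compounds below the target filter, or whose
#' targets all fall outside the network, are excluded and listed with a
#' reason in the table metadata. The table is sorted by descending score
#' with ties broken by compound id, ranks 1..N.
#'
#' @param net a [MultiscaleNetwork-class].
#' @param transition the matching [TransitionMatrix-class].
#' @param compounds a [CompoundLibrary-class].
#' @param disease a [DiseaseSignature-class].
#' @param params diffusion parameters ([diffusionParams()]).
#' @param minTargets minimum in-network target count (default 3, the
#'   sufficiency filter applied before evaluation; set to 1 to keep every
#'   mappable compound).
#' @return A [ScoreTable-class].
#' @export
rankCompounds <- function(net, transition, compounds, disease,
                          params = diffusionParams(), minTargets = 3L) {
  stopifnot(is(net, "MultiscaleNetwork"),
            is(transition, "TransitionMatrix"),
            is(compounds, "CompoundLibrary"),
            is(disease, "DiseaseSignature"))
  minTargets <- as.integer(minTargets)
  if (minTargets < 1) stop("minTargets must be >= 1")
  prot <- proteinIds(net)
  disProt <- intersect(disease@proteins, prot)
  if (length(disProt) == 0)
    stop("disease signature is empty after intersection with the network")
  rd <- diffusePower(transition,
                     makeRestartVector(net, disProt), params)
  ids <- compounds@info$id
  rows <- vector("list", length(ids))
  excluded <- list()
  for (i in seq_along(ids)) {
    cid <- ids[i]
    tin <- intersect(compounds@targets[[cid]], prot)
    if (length(tin) < minTargets) {
      excluded[[cid]] <- data.frame(
        compound_id = cid,
        n_targets_in_network = length(tin),
        reason = if (length(tin) == 0) "no targets in network"
                 else sprintf("fewer than %d targets in network", minTargets),
        stringsAsFactors = FALSE)
      next
    }
    rc <- diffusePower(transition, makeRestartVector(net, tin), params)
    rows[[i]] <- data.frame(
      compound_id = cid,
      name = compounds@info$name[i],
      n_targets_in_network = length(tin),
      score = profileCorrelation(rc, rd),
      stringsAsFactors = FALSE)
  }
  sc <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(sc))
    sc <- data.frame(compound_id = character(), name = character(),
                     n_targets_in_network = integer(), score = numeric())
  if (nrow(sc) > 0) {
    sc <- sc[order(-sc$score, sc$compound_id), , drop = FALSE]
    rownames(sc) <- NULL
  }
  sc$rank <- seq_len(nrow(sc))
  exDf <- if (length(excluded)) do.call(rbind, unname(excluded)) else
    data.frame(compound_id = character(),
               n_targets_in_network = integer(), reason = character())
  rownames(exDf) <- NULL
  new("ScoreTable", scores = sc,
      metadata = list(alpha = params$alpha, epsilon = params$epsilon,
                      weights = transition@weights,
                      disease = disease@name,
                      min_targets = minTargets,
                      disease_proteins_in_network = length(disProt),
                      excluded = exDf))
}

#' Write / read a score table
#'
#' TSV with a `#` metadata header block (alpha, epsilon, weights, disease,
#' min_targets, excluded compounds). Scores print with 6 decimal places.
#'
#' @param st a [ScoreTable-class].
#' @param path output path.
#' @return `writeScoreTable` returns `path` invisibly; `readScoreTable`
#'   a [ScoreTable-class] (metadata restored from the header).
#' @export
writeScoreTable <- function(st, path) {
  stopifnot(is(st, "ScoreTable"))
  md <- st@metadata
  hdr <- c(
    sprintf("# disease: %s", md$disease),
    sprintf("# alpha: %.10g", md$alpha),
    sprintf("# epsilon: %.10g", md$epsilon),
    sprintf("# weights: %s",
            paste(names(md$weights), format(md$weights, digits = 10),
                  sep = "=", collapse = ",")),
    sprintf("# min_targets: %d", md$min_targets),
    sprintf("# excluded: %s",
            if (nrow(md$excluded) == 0) "none" else
              paste(md$excluded$compound_id, collapse = ",")))
  sc <- st@scores
  sc$score <- sprintf("%.6f", sc$score)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(sc, con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname writeScoreTable
#' @export
readScoreTable <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  getv <- function(key) sub(sprintf("^# %s: ", key), "",
                            grep(sprintf("^# %s:", key), hdr, value = TRUE))
  sc <- utils::read.delim(textConnection(lines[!grepl("^#", lines)]),
                          stringsAsFactors = FALSE)
  sc$compound_id <- as.character(sc$compound_id)
  sc$name <- as.character(sc$name)
  wparts <- strsplit(strsplit(getv("weights"), ",")[[1]], "=")
  w <- stats::setNames(as.numeric(vapply(wparts, `[`, "", 2)),
                       vapply(wparts, `[`, "", 1))
  new("ScoreTable", scores = sc,
      metadata = list(alpha = as.numeric(getv("alpha")),
                      epsilon = as.numeric(getv("epsilon")),
                      weights = w, disease = getv("disease"),
                      min_targets = as.integer(getv("min_targets")),
                      excluded = data.frame(compound_id = character(),
                                            n_targets_in_network = integer(),
                                            reason = character())))
}
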