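#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X ~ Hypergeometric(N, K, n): the probability of observing
#' at least `k` disease proteins among `n` targets drawn without
#' replacement from a universe of `N` proteins containing `K` disease
#' proteins. Delegates to the stable distribution implementation in
#' \pkg{stats}.
#'
#' @param k observed overlap, 0 <= k <= min(n, K).
#' @param n draw size (compound targets in universe).
#' @param K number of successes in the universe (disease proteins).
#' @param N universe size.
#' @return The upper-tail probability, in (0, 1].
#' @examples
#' hypergeomUpperTail(3, 4, 5, 10)   # 55/210
#' hypergeomUpperTail(0, 4, 5, 10)   # 1
#' @export
hypergeomUpperTail <- function(k, n, K, N) {
  k <- as.integer(k); n <- as.integer(n); K <- as.integer(K)
  N <- as.integer(N)
  if (any(is.na(c(k, n, K, N)))) stop("non-integer parameter")
  if (N < 1 || n < 1 || n > N || K < 1 || K > N)
    stop("require 0 < n, K <= N")
  if (k < 0 || k > min(n, K))
    stop("require 0 <= k <= min(n, K)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Overlap test between compound targets and disease proteins
#'
#' Intersects both sets with the universe and applies
#' [hypergeomUpperTail()]. The default universe is all protein-kind nodes
#' of the network the sets live in; pass any other character vector to
#' change it.
#'
#' @param compound a [CompoundLibrary-class] single-compound subset, a
#'   character vector of target ids, or a [MechanismSubnetwork-class].
#' @param disease a [DiseaseSignature-class] or character vector.
#' @param universe character vector defining the universe.
#' @return An [OverlapTest-class].
#' @export
overlapTest <- function(compound, disease, universe) {
  targets <- if (is(compound, "CompoundLibrary")) {
    if (nrow(compound@info) != 1)
      stop("pass a single compound (or its target id vector)")
    compound@targets[[1]]
  } else as.character(compound)
  dis <- if (is(disease, "DiseaseSignature")) disease@proteins
         else as.character(disease)
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  tIn <- intersect(targets, universe)
  dIn <- intersect(dis, universe)
  k <- length(intersect(tIn, dIn))
  p <- hypergeomUpperTail(k, length(tIn), length(dIn), length(universe))
  new("OverlapTest", k = as.integer(k), n = length(tIn),
      K = length(dIn), N = length(universe), pValue = p)
}

#' Hypergeometric over-representation across a gene-set collection
#'
#' One upper-tail test per set in the collection (each set first
#' intersected with the universe; sets entirely outside it are skipped
#' with a warning), Benjamini-Hochberg adjusted across the collection and
#' sorted by raw p-value.
#'
#' @param targets character vector of query ids (e.g. the pooled
#'   in-network targets of a compound panel).
#' @param geneSets named list of character vectors, e.g. from
#'   [readGeneSets()].
#' @param universe character vector defining the universe.
#' @return data.frame with columns `set_name`, `overlap`, `set_size`,
#'   `p_value`, `p_adjust`.
#' @export
enrichGeneSets <- function(targets, geneSets, universe) {
  if (length(geneSets) == 0) stop("empty gene-set collection")
  if (is.null(names(geneSets)) || any(!nzchar(names(geneSets))))
    stop("gene sets must be named")
  universe <- unique(as.character(universe))
  if (length(universe) == 0) stop("empty universe")
  tIn <- intersect(unique(as.character(targets)), universe)
  rows <- lapply(names(geneSets), function(nm) {
    set <- intersect(unique(as.character(geneSets[[nm]])), universe)
    if (length(set) == 0) {
      warning("gene set '", nm, "' lies entirely outside the universe; skipped")
      return(NULL)
    }
    k <- length(intersect(tIn, set))
    p <- if (length(tIn) == 0) 1.0 else
      hypergeomUpperTail(k, length(tIn), length(set), length(universe))
    data.frame(set_name = nm, overlap = k, set_size = length(set),
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no gene set intersects the universe")
  out$p_adjust <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$set_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

.checkLabels <- function(scores, labels) {
  labels <- as.integer(as.logical(labels))
  if (length(scores) != length(labels)) stop("length mismatch")
  if (any(is.na(scores)) || any(is.na(labels))) stop("NA in scores or labels")
  P <- sum(labels == 1L); N <- sum(labels == 0L)
  if (P == 0 || N == 0)
    stop("need at least one positive and one negative label")
  list(labels = labels, P = P, N = N)
}

#' Area under the ROC curve (pairwise concordance)
#'
#' Rank-based AUROC: the fraction of positive-negative pairs where the
#' positive scores higher, with ties half-credited — the Mann-Whitney U
#' relation. Invariant under strictly monotone transforms of the scores.
#'
#' @param scores numeric prediction scores (higher = more positive).
#' @param labels binary labels (logical or 0/1).
#' @return AUROC in [0, 1].
#' @examples
#' aurocScore(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))  # 0.75
#' @export
aurocScore <- function(scores, labels) {
  chk <- .checkLabels(scores, labels)
  rk <- rank(scores)   # mean ranks handle ties
  (sum(rk[chk$labels == 1L]) - chk$P * (chk$P + 1) / 2) / (chk$P * chk$N)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-wise average precision: the sum over positives, taken in rank
#' order, of the precision at that rank, divided by the number of
#' positives — no linear interpolation, which is conservative for small
#' positive counts. Tied score blocks are processed jointly: all items
#' sharing a score enter together, with the precision evaluated at the
#' end of the block.
#'
#' @inheritParams aurocScore
#' @return AUPR in [0, 1].
#' @examples
#' auprScore(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0))  # (1 + 2/3)/2 = 5/6
#' @export
auprScore <- function(scores, labels) {
  chk <- .checkLabels(scores, labels)
  labels <- chk$labels
  ord <- order(-scores)
  s <- scores[ord]; y <- labels[ord]
  blocks <- cumsum(!duplicated(s))      # block index per item, rank order
  tpBlock <- tapply(y, blocks, sum)
  nBlock <- tapply(rep(1L, length(y)), blocks, sum)
  tpCum <- cumsum(tpBlock)
  nCum <- cumsum(nBlock)
  sum(tpBlock * (tpCum / nCum)) / chk$P
}

.curvePoints <- function(scores, labels) {
  ord <- order(-scores)
  s <- scores[ord]; y <- as.integer(as.logical(labels))[ord]
  blocks <- cumsum(!duplicated(s))
  tpCum <- cumsum(tapply(y, blocks, sum))
  nCum <- cumsum(tapply(rep(1L, length(y)), blocks, sum))
  fpCum <- nCum - tpCum
  P <- sum(y); N <- length(y) - P
  roc <- data.frame(fpr = c(0, fpCum / N), tpr = c(0, tpCum / P))
  pr <- data.frame(recall = c(0, tpCum / P),
                   precision = c(1, tpCum / nCum))
  list(roc = roc, pr = pr)
}

#' Evaluate a score table against known positives
#'
#' Labels every ranked compound by membership in `positiveIds` and
#' computes AUROC and AUPR, with ROC and precision-recall curve points
#' for plotting.
#'
#' @param st a [ScoreTable-class].
#' @param positiveIds character vector of known-positive compound ids.
#' @return A [ClassificationEval-class].
#' @export
evaluateKnownPositives <- function(st, positiveIds) {
  stopifnot(is(st, "ScoreTable"))
  sc <- st@scores
  if (nrow(sc) < 2) stop("score table too small to evaluate")
  labels <- as.integer(sc$compound_id %in% positiveIds)
  if (sum(labels) == 0)
    stop("no known positive appears in the score table")
  if (all(labels == 1L))
    stop("every ranked compound is a known positive; nothing to discriminate")
  curves <- .curvePoints(sc$score, labels)
  new("ClassificationEval",
      auroc = aurocScore(sc$score, labels),
      aupr = auprScore(sc$score, labels),
      nPositive = sum(labels), nTotal = nrow(sc),
      pairs = data.frame(id = sc$compound_id, score = sc$score,
                         label = labels, stringsAsFactors = FALSE),
      rocPoints = curves$roc, prPoints = curves$pr)
}
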