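#' Diffusion parameters
#'
#' Parameters of the random walk with restart. `alpha` is the probability
#' that the walker continues along the network at each step (restart
#' probability `1 - alpha`); `epsilon` is the L1 tolerance on successive
#' iterates that stops the power iteration; `maxIter` bounds the number of
#' iterations. The default `alpha = 0.85` is a conventional choice for
#' restart walks on interactomes, exposed here as configuration; the
#' default tolerance is 1e-6.
#'
#' @param alpha continuation probability, in (0, 1).
#' @param epsilon L1 convergence tolerance, > 0.
#' @param maxIter positive integer iteration cap.
#' @return A validated list with the three components.
#' @export
diffusionParams <- function(alpha = 0.85, epsilon = 1e-6,
                            maxIter = 10000L) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("alpha must be a single number in (0, 1)")
  if (!is.numeric(epsilon) || length(epsilon) != 1 || epsilon <= 0)
    stop("epsilon must be > 0")
  maxIter <- as.integer(maxIter)
  if (is.na(maxIter) || maxIter < 1) stop("maxIter must be >= 1")
  list(alpha = alpha, epsilon = epsilon, maxIter = maxIter)
}

#' Restart vector over seed nodes
#'
#' Builds the restart distribution `s`: uniform over the given seed nodes,
#' zero elsewhere. A compound's seeds are its in-network protein targets; a
#' disease's seeds are its associated proteins.
#'
#' @param net a [MultiscaleNetwork-class] (or a [TransitionMatrix-class];
#'   only the node index is used).
#' @param seedIds nonempty character vector of node ids.
#' @return Named numeric vector summing to 1.
#' @examples
#' net <- buildNetwork(
#'   data.frame(id = c("P1", "P2"), kind = "protein", label = ""),
#'   data.frame(source = "P1", target = "P2", kind = "ppi"))
#' makeRestartVector(net, c("P1", "P2"))
#' @export
makeRestartVector <- function(net, seedIds) {
  ids <- if (is(net, "TransitionMatrix")) net@ids else nodeIds(net)
  seedIds <- unique(as.character(seedIds))
  if (length(seedIds) == 0) stop("seed set must be nonempty")
  missing <- setdiff(seedIds, ids)
  if (length(missing))
    stop("seed id not in network: ", paste(missing, collapse = ", "))
  s <- stats::setNames(numeric(length(ids)), ids)
  s[seedIds] <- 1 / length(seedIds)
  s
}

.checkRestart <- function(s, ids) {
  if (length(s) != length(ids)) stop("restart vector length mismatch")
  if (!is.null(names(s)) && !identical(names(s), ids))
    stop("restart vector names do not match the node index")
  if (any(s < 0) || abs(sum(s) - 1) > 1e-12)
    stop("restart vector must be nonnegative and sum to 1")
  stats::setNames(as.numeric(s), ids)
}

#' Diffusion profile by power iteration
#'
#' Iterates the restart-walk update
#' \deqn{r^{k+1} = (1-\alpha)\,s + \alpha\, r^k M +
#'   \alpha \big(\sum_{j \in J} r^k_j\big)\, s}
#' from \eqn{r^0 = s}, where `J` is the dangling set of the transition
#' matrix: mass sitting on nodes with no outgoing moves is re-injected
#' through the restart vector, scaled by `alpha` so that total mass is
#' conserved exactly at every step. Iteration stops when the L1 difference
#' of successive iterates drops to `epsilon` or below, or when `maxIter`
#' is reached (flagged via the `converged` slot and a warning, never
#' silently). The returned vector is renormalized to sum exactly to 1.
#'
#' The update is an L1-contraction with factor `alpha`, so the residual
#' shrinks geometrically and the fixed point is unique; see
#' [diffuseExact()] for the closed-form solution of the same fixed point.
#'
#' @param transition a [TransitionMatrix-class].
#' @param s restart vector from [makeRestartVector()].
#' @param params list from [diffusionParams()].
#' @param checkMass if TRUE, assert per-iteration mass conservation
#'   (|sum(r) - 1| <= 1e-9); a debugging aid.
#' @return A [DiffusionProfile-class].
#' @examples
#' net <- buildNetwork(
#'   data.frame(id = c("P1", "P2"), kind = "protein", label = ""),
#'   data.frame(source = "P1", target = "P2", kind = "ppi"))
#' tm <- buildTransitionMatrix(net)
#' s <- makeRestartVector(net, "P1")
#' diffusePower(tm, s, diffusionParams(alpha = 0.5))  # r = (2/3, 1/3)
#' @export
diffusePower <- function(transition, s, params = diffusionParams(),
                         checkMass = FALSE) {
  stopifnot(is(transition, "TransitionMatrix"))
  M <- transition@M
  ids <- transition@ids
  s <- .checkRestart(s, ids)
  alpha <- params$alpha; eps <- params$epsilon; maxIter <- params$maxIter
  r <- s
  residuals <- numeric(0)
  converged <- FALSE
  iter <- 0L
  dang <- transition@dangling
  while (iter < maxIter) {
    iter <- iter + 1L
    dangMass <- if (length(dang)) sum(r[dang]) else 0
    rNew <- (1 - alpha) * s + alpha * as.numeric(r %*% M) +
      (alpha * dangMass) * s
    if (checkMass && abs(sum(rNew) - 1) > 1e-9)
      stop("mass conservation violated at iteration ", iter)
    res <- sum(abs(rNew - r))
    residuals[iter] <- res
    r <- rNew
    if (res <= eps) { converged <- TRUE; break }
  }
  if (!converged)
    warning("power iteration did not converge within ", maxIter,
            " iterations (last residual ", signif(residuals[iter], 3), ")")
  r <- pmax(r, 0)
  r <- r / sum(r)
  new("DiffusionProfile", r = stats::setNames(as.numeric(r), ids),
      alpha = alpha, epsilon = eps, iterations = iter,
      converged = converged, residuals = residuals)
}

#' Closed-form diffusion profile (dense linear solve)
#'
#' Solves the restart-walk fixed point directly:
#' `r = (1 - alpha) s + alpha r Mtilde`, where `Mtilde` equals the
#' transition matrix with each dangling row replaced by the restart
#' vector. This is the same fixed point [diffusePower()] iterates toward
#' and serves as an independent cross-check; it is guarded to networks of
#' at most 2000 nodes because the solve is dense.
#'
#' @inheritParams diffusePower
#' @param alpha continuation probability in (0, 1).
#' @return A [DiffusionProfile-class] with `iterations = 0`.
#' @export
diffuseExact <- function(transition, s, alpha = 0.85) {
  stopifnot(is(transition, "TransitionMatrix"))
  n <- length(transition@ids)
  if (n > 2000) stop("diffuseExact is limited to networks of <= 2000 nodes")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  s <- .checkRestart(s, transition@ids)
  Mt <- as.matrix(transition@M)
  if (length(transition@dangling))
    Mt[transition@dangling, ] <- matrix(s, nrow = length(transition@dangling),
                                        ncol = n, byrow = TRUE)
  A <- diag(n) - alpha * t(Mt)
  r <- solve(A, (1 - alpha) * s)
  r <- pmax(as.numeric(r), 0)
  r <- r / sum(r)
  new("DiffusionProfile", r = stats::setNames(r, transition@ids),
      alpha = alpha, epsilon = NA_real_, iterations = 0L,
      converged = TRUE, residuals = numeric(0))
}

#' Write / read a diffusion profile
#'
#' Profiles serialize as a two-column TSV (`node_id`, `probability`) plus
#' a JSON sidecar (`<path>.json`) recording alpha, epsilon,
#' iterations_used and converged.
#'
#' @param profile a [DiffusionProfile-class].
#' @param path TSV path to write.
#' @return `writeProfile` returns `path` invisibly; `readProfile` a
#'   [DiffusionProfile-class].
#' @export
writeProfile <- function(profile, path) {
  stopifnot(is(profile, "DiffusionProfile"))
  df <- data.frame(node_id = names(profile@r),
                   probability = sprintf("%.12g", profile@r))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  side <- list(alpha = profile@alpha, epsilon = profile@epsilon,
               iterations_used = profile@iterations,
               converged = profile@converged)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname writeProfile
#' @export
readProfile <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  r <- stats::setNames(as.numeric(df$probability), df$node_id)
  new("DiffusionProfile", r = r / sum(r), alpha = side$alpha,
      epsilon = if (is.null(side$epsilon)) NA_real_ else side$epsilon,
      iterations = as.integer(side$iterations_used),
      converged = side$converged, residuals = numeric(0))
}
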