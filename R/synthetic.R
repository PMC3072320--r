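.withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  expr
}

.truncNormScores <- function(n, mean, sd) {
  s <- rnorm(n, mean, sd)
  while (any(bad <- s <= 0)) s[bad] <- rnorm(sum(bad), mean, sd)
  s
}

#' Simulate uniformly placed fragments
#'
#' The benchmark distribution for the chainer: fixed-length fragments whose
#' query starts are uniform over a short query sequence and whose database
#' starts are uniform over a much larger virtual database, with
#' independent truncated-normal scores.  Defaults follow the performance
#' benchmark geometry: length-100 fragments covering a 1 kb query sampled
#' from a 100 kb database.  Score mean 20 and sd 5 are arbitrary (only the
#' distribution family is prescribed); scores are resampled until positive.
#'
#' @param n number of fragments.
#' @param fragLen fragment length on both axes (default 100).
#' @param queryLen query sequence length (default 1000).
#' @param dbLen database sequence length (default 100000).
#' @param scoreMean,scoreSd normal score parameters (defaults 20, 5).
#' @param seed optional integer; fixes the full output and leaves the
#'   caller's RNG state untouched.
#' @param queryId,subjectId ids stamped on every fragment.
#' @return A [FragmentSet-class] of `n` fragments.
#' @export
simulateUniformFragments <- function(n, fragLen = 100, queryLen = 1000,
                                     dbLen = 100000, scoreMean = 20,
                                     scoreSd = 5, seed = NULL,
                                     queryId = "query", subjectId = "db") {
  stopifnot(fragLen <= queryLen, queryLen <= dbLen, n >= 0)
  if (n == 0) return(fragmentSet(.emptyFragDf()))
  .withSeed(seed, {
    begY <- if (n) sample.int(queryLen - fragLen + 1L, n, replace = TRUE) - 1 else numeric()
    begX <- if (n) sample.int(dbLen - fragLen + 1L, n, replace = TRUE) - 1 else numeric()
    score <- if (n) .truncNormScores(n, scoreMean, scoreSd) else numeric()
    fragmentSet(data.frame(
      uid = seq_len(n) - 1L, queryId = queryId, subjectId = subjectId,
      strand = "+", begX = begX, endX = begX + fragLen,
      begY = begY, endY = begY + fragLen, score = score,
      stringsAsFactors = FALSE))
  })
}

#' Simulate a scattered homology with decoys
#'
#' Plants one colinear chain of short conserved blocks whose inter-block
#' distances on database and query differ by at most `jitter` while the
#' absolute distances are large -- the scenario where the sum-of-pair model
#' (small `|d_x - d_y|`, cost near zero with `epsilon = 0`) far outscores
#' the linear model (which pays for every skipped character).  Uniform
#' decoy fragments are added around the planted chain; decoys may overlap
#' planted blocks.
#'
#' @param nBlocks number of planted blocks (>= 2).
#' @param blockLen length of each planted block (default 20).
#' @param jitter maximal absolute difference between the database and
#'   query inter-block distances (default 0: distances match exactly and
#'   the planted chain has zero sum-of-pair gap cost at `epsilon = 0`).
#' @param decoyRate decoy fragments per planted block (default 3); the
#'   decoy count is `round(decoyRate * nBlocks)`.
#' @param scoreMean,scoreSd truncated-normal score parameters.
#' @param seed optional integer seed.
#' @return `list(fragments = FragmentSet, truthUids = integer)`: the
#'   planted blocks' `uid`s in chain order.
#' @export
simulateScatteredHomology <- function(nBlocks, blockLen = 20, jitter = 0,
                                      decoyRate = 3, scoreMean = 20,
                                      scoreSd = 5, seed = NULL) {
  stopifnot(nBlocks >= 2)
  .withSeed(seed, {
    delta <- if (jitter > 0)
      sample(seq.int(-jitter, jitter), nBlocks - 1L, replace = TRUE)
    else rep(0L, nBlocks - 1L)
    gapX <- sample(200:2000, nBlocks - 1L, replace = TRUE)
    gapY <- pmax(gapX + delta, 0L)  # query distance tracks database distance
    begX <- cumsum(c(0, gapX + blockLen))
    begY <- cumsum(c(0, gapY + blockLen))
    planted <- data.frame(
      queryId = "q", subjectId = "s", strand = "+",
      begX = begX, endX = begX + blockLen,
      begY = begY, endY = begY + blockLen,
      score = .truncNormScores(nBlocks, scoreMean, scoreSd),
      stringsAsFactors = FALSE)

    nDecoys <- round(decoyRate * nBlocks)
    spanX <- max(planted$endX) + 1000
    spanY <- max(planted$endY) + 1000
    decoys <- if (nDecoys > 0) {
      dx <- sample.int(spanX - blockLen, nDecoys, replace = TRUE) - 1
      dy <- sample.int(spanY - blockLen, nDecoys, replace = TRUE) - 1
      data.frame(queryId = "q", subjectId = "s", strand = "+",
                 begX = dx, endX = dx + blockLen,
                 begY = dy, endY = dy + blockLen,
                 score = .truncNormScores(nDecoys, scoreMean, scoreSd),
                 stringsAsFactors = FALSE)
    } else planted[0, ]

    all <- rbind(planted, decoys)
    all$uid <- seq_len(nrow(all)) - 1L
    list(fragments = fragmentSet(all),
         truthUids = all$uid[seq_len(nBlocks)])
  })
}
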