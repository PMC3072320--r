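#' Line-sweep local chaining over one fragment group
#'
#' Runs the sparse-DP sweep over the start and end points of one group of
#' fragments (same query, subject and strand), ordered by database
#' position.  At a fragment's start point the optimal predecessor among the
#' active chains (those whose last fragment has already ended) is retrieved
#' by range-maximum queries; the candidate's true value
#' `pred_score - gap(pred, f)` is recomputed exactly and the fragment is
#' connected only if the value is non-negative (a tie connects, preferring
#' the longer chain).  At its end point the fragment's chain becomes active
#' and is inserted with the model's priority transform.  Local chaining:
#' every chain score is at least the fragment's own score.
#'
#' @param frags a `data.frame` of fragments from one group (columns as in
#'   [fragments()]), or a [FragmentSet-class] holding a single group.
#' @param params a [GapParams-class].
#' @param octants sum-of-pair diagnostic only: integer subset of `c(1, 2)`
#'   selecting which octant structures to use (both by default; disabling
#'   one demonstrates its necessity).
#' @return A `data.frame` with one row per input fragment, in input order:
#'   `uid`, `score` (best local chain score ending at the fragment), `pred`
#'   (row index of the predecessor in `frags`, `NA` for a chain start) and
#'   `first` (row index of the chain's first fragment).
#' @seealso [bruteForceChain()] for the quadratic reference
#'   implementation, [reportChains()] to turn records into reports.
#' @export
sweepChain <- function(frags, params, octants = c(1L, 2L)) {
  df <- if (is(frags, "FragmentSet")) fragments(frags) else frags
  stopifnot(is(params, "GapParams"))
  mask <- sum(unique(as.integer(octants)))
  res <- cpp_sweep_chain(df$begX, df$endX, df$begY, df$endY, df$score,
                         params@model, params@lambda, params@epsilon,
                         as.integer(mask))
  data.frame(uid = df$uid, score = res$score, pred = res$pred,
             first = res$first)
}

#' Quadratic reference chainer
#'
#' Direct `O(n^2)` dynamic program over fragments sorted by database end:
#' each fragment considers every chainable predecessor and applies the gap
#' cost formula without priority transforms, octants or sweep structures.
#' Semantically identical to [sweepChain()]; used as the independent oracle
#' in tests and sanity checks.  Intended for small `n` only.
#'
#' @inheritParams sweepChain
#' @return Same record `data.frame` as [sweepChain()].
#' @export
bruteForceChain <- function(frags, params) {
  df <- if (is(frags, "FragmentSet")) fragments(frags) else frags
  stopifnot(is(params, "GapParams"))
  n <- nrow(df)
  score <- numeric(n); pred <- rep(NA_integer_, n); first <- integer(n)
  ord <- order(df$endX)
  for (j in ord) {
    score[j] <- df$score[j]
    first[j] <- j
    ok <- which(df$endX <= df$begX[j] & df$endY <= df$begY[j])
    ok <- ok[ok != j]
    if (length(ok)) {
      g <- gapCost(df$begX[j] - df$endX[ok], df$begY[j] - df$endY[ok], params)
      v <- score[ok] - g
      b <- which.max(v)
      if (v[b] >= 0) {
        score[j] <- df$score[j] + v[b]
        pred[j] <- ok[b]
        first[j] <- first[ok[b]]
      }
    }
  }
  data.frame(uid = df$uid, score = score, pred = pred, first = first)
}

#' Connect decision of the local chainer
#'
#' A fragment is chained to its optimal predecessor only when the
#' predecessor chain's score is at least the gap cost, i.e. when
#' `predValue = pred_score - gap >= 0`.  An exact tie connects, preferring
#' the longer chain over an equal-scoring fresh start.
#'
#' @param predValue numeric, `pred_score - gap` (vectorised).
#' @return logical.
#' @export
connectDecision <- function(predValue) {
  predValue >= 0
}

#' Report best-scoring chains per first fragment
#'
#' Backtraces every chain record to its first fragment, groups records by
#' first fragment, and reports the best-scoring record of each group (a
#' fragment interior to chains need not head any report).  Reports scoring
#' below `minScore` are dropped.
#'
#' @param records record `data.frame` from [sweepChain()] or
#'   [bruteForceChain()].
#' @param frags the fragment `data.frame` (or [FragmentSet-class]) the
#'   records were computed from.
#' @param minScore minimal reported chain score (default 0; sensitive
#'   BLAST screens typically use 30 with length-based fragment scores).
#' @return A [ChainSet-class], sorted by descending chain score.
#' @export
reportChains <- function(records, frags, minScore = 0) {
  df <- if (is(frags, "FragmentSet")) fragments(frags) else frags
  stopifnot(nrow(records) == nrow(df))
  if (!nrow(df)) return(.emptyChainSet())

  best <- tapply(seq_len(nrow(records)), records$first, function(ix)
    ix[which.max(records$score[ix])])
  best <- as.integer(best)
  keep <- records$score[best] >= minScore
  best <- best[keep]
  if (!length(best)) return(.emptyChainSet())

  members <- lapply(best, function(i) {
    path <- integer(0)
    while (!is.na(i)) {
      path <- c(i, path)
      i <- records$pred[i]
    }
    path
  })

  rows <- lapply(seq_along(best), function(k) {
    m <- members[[k]]
    data.frame(queryId = df$queryId[m[1L]], subjectId = df$subjectId[m[1L]],
               strand = df$strand[m[1L]],
               chainScore = records$score[best[k]],
               begX = min(df$begX[m]), endX = max(df$endX[m]),
               begY = min(df$begY[m]), endY = max(df$endY[m]),
               nFragments = length(m), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  uids <- lapply(members, function(m) as.integer(df$uid[m]))
  ord <- order(-tab$chainScore, tab$subjectId, tab$begX)
  new("ChainSet", chains = tab[ord, , drop = FALSE], members = uids[ord])
}

.emptyChainSet <- function() {
  new("ChainSet",
      chains = data.frame(queryId = character(), subjectId = character(),
                          strand = character(), chainScore = numeric(),
                          begX = numeric(), endX = numeric(),
                          begY = numeric(), endY = numeric(),
                          nFragments = integer(), stringsAsFactors = FALSE),
      members = list())
}

#' Recompute a chain's score from its member fragments
#'
#' Sum of the member fragment scores minus the gap costs between
#' consecutive members, under the given model.  Used to validate reported
#' chains and to score a fixed chain under a different gap model.
#'
#' @param frags fragment `data.frame` or [FragmentSet-class].
#' @param uids ordered member fragment `uid`s.
#' @param params a [GapParams-class].
#' @return numeric chain score.
#' @export
scoreChain <- function(frags, uids, params) {
  df <- if (is(frags, "FragmentSet")) fragments(frags) else frags
  ix <- match(uids, df$uid)
  stopifnot(!anyNA(ix))
  s <- sum(df$score[ix])
  if (length(ix) > 1L) {
    a <- ix[-length(ix)]; b <- ix[-1L]
    s <- s - sum(gapCost(df$begX[b] - df$endX[a], df$begY[b] - df$endY[a], params))
  }
  s
}

#' Chain a fragment set
#'
#' The full pipeline over a [FragmentSet-class]: partition by
#' `(query, subject, strand)`, optionally split each group into
#' independently chainable clusters along the database axis
#' ([clusterFragments()]; output-preserving), run the line sweep per
#' cluster, and report the best chain per first fragment at or above
#' `minScore`.
#'
#' @param x a [FragmentSet-class].
#' @param params a [GapParams-class].
#' @param minScore minimal reported chain score.
#' @param cluster use the clustering pre-pass (default `TRUE`; the result
#'   is identical either way, clustering only reduces sweep sizes).
#' @param octants see [sweepChain()].
#' @return A [ChainSet-class] sorted by descending chain score.
#' @examples
#' fs <- simulateUniformFragments(200, seed = 7)
#' cs <- chainFragments(fs, gapParams("sop", lambda = 0.5, epsilon = 0),
#'                      minScore = 30)
#' head(chains(cs))
#' @export
chainFragments <- function(x, params, minScore = 0, cluster = TRUE,
                           octants = c(1L, 2L)) {
  stopifnot(is(x, "FragmentSet"), is(params, "GapParams"))
  groups <- partitionByGroup(x)
  parts <- lapply(groups, function(g) {
    pieces <- if (cluster) clusterFragments(g, params) else list(g)
    res <- lapply(pieces, function(piece) {
      rec <- sweepChain(piece, params, octants = octants)
      reportChains(rec, piece, minScore = minScore)
    })
    res
  })
  parts <- unlist(parts, recursive = FALSE, use.names = FALSE)
  if (!length(parts)) return(.emptyChainSet())
  tab <- do.call(rbind, lapply(parts, chains))
  mem <- do.call(c, lapply(parts, chainMembers))
  ord <- order(-tab$chainScore, tab$subjectId, tab$begX)
  new("ChainSet", chains = `rownames<-`(tab[ord, , drop = FALSE], NULL),
      members = mem[ord])
}
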