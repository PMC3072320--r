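#' Database gap above which fragments can never be co-chained
#'
#' Smallest database-axis gap `D` whose minimum possible gap cost exceeds
#' `maxScoreBound` (an upper bound on any chain score achievable from the
#' fragments seen so far) for every admissible query-axis distance
#' `d_y <= maxY`.  Since a fragment is connected only when the predecessor
#' chain's score covers the gap cost, no connection can bridge a database
#' gap larger than `D`, so the fragment set may be split there without
#' changing the chaining outcome.
#'
#' Sum-of-pair: the cost of bridging `d_x = D` is at least
#' `lambda * (D - maxY)`, hence
#' `D = floor(maxScoreBound / lambda) + maxY + 1`.  Linear: the cost is at
#' least `lambda * D`, hence `D = floor(maxScoreBound / lambda) + 1`.
#' With `lambda = 0` the database axis is cost-free and no split is ever
#' safe (`Inf`).
#'
#' @param maxScoreBound upper bound on any achievable chain score.
#' @param maxY maximal query-axis distance between fragments.
#' @param params a [GapParams-class].
#' @return numeric threshold (possibly `Inf`).
#' @examples
#' clusterGapThreshold(30, 1000, gapParams("sop", 0.5, 0))  # 1061
#' @export
clusterGapThreshold <- function(maxScoreBound, maxY, params) {
  stopifnot(is(params, "GapParams"))
  if (params@lambda <= 0) return(Inf)
  base <- floor(maxScoreBound / params@lambda) + 1
  if (params@model == "sop") base + maxY else base
}

#' Split a fragment group into independently chainable clusters
#'
#' Output-preserving pre-pass: scans the group in database order and opens
#' a new cluster whenever the gap between the database frontier (maximal
#' `endX` so far in the current cluster) and the next fragment's `begX`
#' exceeds [clusterGapThreshold()].  The score bound is the running sum of
#' fragment scores already scanned (every chain's score is at most the sum
#' of its member scores, and all possible predecessors of a split point
#' precede it in the scan); the query-axis extent bound
#' `maxY = max(endY) - min(begY)` is taken over the whole group, standing
#' in for the query length.  Chaining each cluster separately yields
#' exactly the chains of a single sweep over the whole group.
#'
#' @param frags fragment `data.frame` or [FragmentSet-class]; one group
#'   (same query, subject, strand).
#' @param params a [GapParams-class].
#' @return List of fragment `data.frame`s, in database order; their union
#'   is the input.
#' @seealso [chainFragments()]
#' @export
clusterFragments <- function(frags, params) {
  df <- if (is(frags, "FragmentSet")) fragments(frags) else frags
  stopifnot(is(params, "GapParams"))
  n <- nrow(df)
  if (n == 0L) return(list())
  ord <- order(df$begX, df$endX)
  df <- df[ord, , drop = FALSE]
  if (n == 1L || params@lambda <= 0) return(list(df))

  maxY <- max(df$endY) - min(df$begY)
  frontier <- cummax(df$endX)[-n]              # before each candidate split
  bound <- cumsum(df$score)[-n]                # scores scanned so far
  thr <- clusterGapThreshold(bound, maxY, params)
  gap <- df$begX[-1L] - frontier
  newCluster <- c(FALSE, gap > thr)
  id <- cumsum(newCluster)
  unname(split(df, id))
}
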