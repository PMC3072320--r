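#' Chainability of an ordered fragment pair
#'
#' A fragment `pred` may precede `succ` in a chain iff `pred` ends at or
#' before `succ`'s start on both the database (`x`) and the query (`y`)
#' axis.  Under the half-open coordinate convention equality means the
#' fragments abut with a zero-length gap, which is allowed; any overlap on
#' either axis (including overlap on the query only, as for two hits on the
#' same query interval) forbids chaining.
#'
#' @param pred,succ single fragments: one-row data frames or lists with
#'   fields `begX`, `endX`, `begY`, `endY` (0-based half-open).  Vectorised
#'   over rows when both have equal length.
#' @return logical.
#' @examples
#' isChainable(list(begX = 0, endX = 10, begY = 0, endY = 10),
#'             list(begX = 20, endX = 30, begY = 15, endY = 25))
#' @export
isChainable <- function(pred, succ) {
  pred$endX <= succ$begX & pred$endY <= succ$begY
}

#' Gap distances between chainable fragments
#'
#' Number of characters strictly between the two matched blocks on each
#' axis.  With half-open coordinates this is simply `succ_beg - pred_end`;
#' abutting fragments have distance 0.
#'
#' @inheritParams isChainable
#' @return list with components `dx` (database axis) and `dy` (query axis).
#' @export
gapDistances <- function(pred, succ) {
  dx <- succ$begX - pred$endX
  dy <- succ$begY - pred$endY
  if (any(dx < 0) || any(dy < 0))
    stop("gapDistances called on a non-chainable pair (negative distance)")
  list(dx = dx, dy = dy)
}

#' Gap cost models
#'
#' `gapLinear()` returns `lambda * dx + epsilon * dy`: every skipped
#' character on either sequence is penalised.  `gapSop()` returns the
#' sum-of-pair cost `lambda * |dx - dy| + epsilon * min(dx, dy)`, the cost
#' of optimally aligning the two anonymous gap blocks when `lambda` is the
#' character-against-gap penalty and `epsilon` the
#' character-against-character penalty (`epsilon <= 2 * lambda`).  With
#' `epsilon = 0` the sum-of-pair cost depends only on the difference of the
#' two distances, so long gaps of matched length are free.
#'
#' @param dx,dy non-negative inter-fragment distances (database, query);
#'   vectorised.
#' @param params a [GapParams-class]; `gapLinear` requires `model="linear"`,
#'   `gapSop` requires `model="sop"`.
#' @return numeric gap cost(s), always `>= 0`.
#' @examples
#' gapLinear(10, 4, gapParams("linear", 1, 1))   # 14
#' gapSop(10, 4, gapParams("sop", 1, 0.5))       # 8
#' @export
gapLinear <- function(dx, dy, params) {
  stopifnot(is(params, "GapParams"), params@model == "linear")
  params@lambda * dx + params@epsilon * dy
}

#' @rdname gapLinear
#' @export
gapSop <- function(dx, dy, params) {
  stopifnot(is(params, "GapParams"), params@model == "sop")
  params@lambda * abs(dx - dy) + params@epsilon * pmin(dx, dy)
}

#' Gap cost under the model selected by `params`
#' @inheritParams gapLinear
#' @return numeric gap cost(s).
#' @export
gapCost <- function(dx, dy, params) {
  stopifnot(is(params, "GapParams"))
  if (params@model == "linear") params@lambda * dx + params@epsilon * dy
  else params@lambda * abs(dx - dy) + params@epsilon * pmin(dx, dy)
}

#' Sweep priorities that make the optimal predecessor the RMQ maximum
#'
#' For a fixed successor start point, `score - gap(pred, succ)` differs from
#' these priorities only by a term independent of the predecessor, so the
#' maximum-priority element of the admissible range is the optimal
#' predecessor.  `priorityLinear()` is the linear-model transform
#' `score + lambda * endX + epsilon * endY`.  `prioritySop()` is the
#' sum-of-pair transform for one octant of the predecessor half-plane:
#' octant 1 covers `dx >= dy` (predecessor end diagonal `endX - endY` at or
#' below the successor start diagonal) with
#' `score + lambda * endX + (epsilon - lambda) * endY`; octant 2 covers
#' `dx < dy` with `score + (epsilon - lambda) * endX + lambda * endY`.
#'
#' @param score accumulated chain score at the predecessor.
#' @param endX,endY predecessor end coordinates (0-based exclusive).
#' @param params a [GapParams-class].
#' @param octant 1 or 2 (sum-of-pair only).
#' @return numeric priority (vectorised).
#' @export
priorityLinear <- function(score, endX, endY, params) {
  stopifnot(params@model == "linear")
  score + params@lambda * endX + params@epsilon * endY
}

#' @rdname priorityLinear
#' @export
prioritySop <- function(score, endX, endY, params, octant) {
  stopifnot(params@model == "sop", all(octant %in% c(1, 2)))
  lam <- params@lambda
  eps <- params@epsilon
  o1 <- score + lam * endX + (eps - lam) * endY
  o2 <- score + (eps - lam) * endX + lam * endY
  ifelse(rep_len(octant == 1, length(o1)), o1, o2)
}

# Independent alignment oracle for the sum-of-pair closed form: cheapest
# alignment of two anonymous blocks of lengths dx and dy, pairing a
# characters (cost eps each) and gapping the rest (cost lam each).
# Used only by tests; scalar inputs.
.sopAlignmentOracle <- function(dx, dy, lam, eps) {
  a <- 0:min(dx, dy)
  min(eps * a + lam * (dx + dy - 2 * a))
}
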