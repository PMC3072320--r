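#' Gap cost model parameters
#'
#' Container for the gap cost model and its two weights.  Under the linear
#' model the cost of connecting chain fragments separated by `d_x` characters
#' on the database and `d_y` on the query is `lambda * d_x + epsilon * d_y`.
#' Under the sum-of-pair model it is
#' `lambda * |d_x - d_y| + epsilon * min(d_x, d_y)`: `lambda` is the penalty
#' for aligning an anonymous character against a gap position, `epsilon` the
#' penalty for aligning two anonymous characters.  With `epsilon = 0` the
#' sum-of-pair model penalises only the difference of the two distances.
#'
#' @slot model `"linear"` or `"sop"`.
#' @slot lambda non-negative weight (database-side distance for the linear
#'   model; gap-against-character penalty for sum-of-pair).
#' @slot epsilon non-negative weight (query-side distance for the linear
#'   model; character-against-character penalty for sum-of-pair).
#' @seealso [gapParams()], [gapLinear()], [gapSop()]
#' @exportClass GapParams
setClass("GapParams",
  representation(model = "character", lambda = "numeric", epsilon = "numeric"),
  prototype(model = "linear", lambda = 1, epsilon = 1))

setValidity("GapParams", function(object) {
  msg <- character()
  if (length(object@model) != 1L || !object@model %in% c("linear", "sop"))
    msg <- c(msg, "model must be \"linear\" or \"sop\"")
  if (length(object@lambda) != 1L || is.na(object@lambda) || object@lambda < 0)
    msg <- c(msg, "lambda must be a single non-negative number")
  if (length(object@epsilon) != 1L || is.na(object@epsilon) || object@epsilon < 0)
    msg <- c(msg, "epsilon must be a single non-negative number")
  if (length(msg)) msg else TRUE
})

#' Construct gap cost parameters
#'
#' @param model gap cost model, `"linear"` or `"sop"` (sum-of-pair).
#' @param lambda,epsilon non-negative model weights; see [GapParams-class].
#' @return A [GapParams-class] object.
#' @details For the sum-of-pair model, `epsilon > 2 * lambda` triggers a
#'   warning: the closed form then no longer equals the cheapest alignment of
#'   the two anonymous gap blocks (pairing two characters would cost more
#'   than putting both against gaps), so the "align two anonymous
#'   characters" reading of `epsilon` breaks down.  The value is still used
#'   as given.
#' @examples
#' gapParams("sop", lambda = 0.5, epsilon = 0)
#' @export
gapParams <- function(model = c("linear", "sop"), lambda = 1, epsilon = 1) {
  model <- match.arg(model)
  p <- new("GapParams", model = model, lambda = as.numeric(lambda),
           epsilon = as.numeric(epsilon))
  if (model == "sop" && p@epsilon > 2 * p@lambda)
    warning("epsilon > 2 * lambda: sum-of-pair cost exceeds the cheapest ",
            "alignment of the gap regions", call. = FALSE)
  p
}

setMethod("show", "GapParams", function(object) {
  cat(sprintf("GapParams: model=%s lambda=%g epsilon=%g\n",
              object@model, object@lambda, object@epsilon))
})

.FRAG_COLS <- c("uid", "queryId", "subjectId", "strand",
                "begX", "endX", "begY", "endY", "score")

#' Set of match fragments
#'
#' A set of scored match fragments between query sequences (axis `y`) and
#' database sequences (axis `x`).  Coordinates are held 0-based half-open
#' internally; all text input and output is 1-based inclusive.  Each
#' fragment keeps the stable 0-based index `uid` it had in its input.
#'
#' @slot frags `data.frame` with columns `uid`, `queryId`, `subjectId`,
#'   `strand` (`"+"`/`"-"`), `begX`, `endX`, `begY`, `endY`, `score`.
#' @seealso [fragmentSet()], [fragments()], [chainFragments()]
#' @exportClass FragmentSet
setClass("FragmentSet", representation(frags = "data.frame"))

setValidity("FragmentSet", function(object) {
  df <- object@frags
  if (!all(.FRAG_COLS %in% names(df)))
    return(paste("missing fragment columns:",
                 paste(setdiff(.FRAG_COLS, names(df)), collapse = ", ")))
  msg <- character()
  if (nrow(df)) {
    if (!all(df$strand %in% c("+", "-")))
      msg <- c(msg, "strand must be '+' or '-'")
    if (any(df$begX < 0) || any(df$begY < 0))
      msg <- c(msg, "coordinates must be non-negative")
    if (any(df$endX <= df$begX) || any(df$endY <= df$begY))
      msg <- c(msg, "fragments must be non-empty on both axes (beg < end)")
    if (any(df$score < 0) || anyNA(df$score))
      msg <- c(msg, "scores must be non-negative")
    if (anyDuplicated(df$uid))
      msg <- c(msg, "uids must be unique")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a FragmentSet from a data frame
#'
#' @param frags `data.frame` with columns `queryId`, `subjectId`, `begX`,
#'   `endX`, `begY`, `endY`, `score` and optionally `strand` (default `"+"`)
#'   and `uid` (default `0:(n-1)` in input order).  Coordinates are 0-based
#'   half-open.
#' @return A [FragmentSet-class].
#' @examples
#' fragmentSet(data.frame(queryId = "q", subjectId = "s",
#'                        begX = 0, endX = 10, begY = 0, endY = 10, score = 5))
#' @export
fragmentSet <- function(frags) {
  frags <- as.data.frame(frags)
  if (is.null(frags$strand)) frags$strand <- rep("+", nrow(frags))
  if (is.null(frags$uid)) frags$uid <- seq_len(nrow(frags)) - 1L
  frags$uid <- as.integer(frags$uid)
  for (col in c("begX", "endX", "begY", "endY", "score"))
    frags[[col]] <- as.numeric(frags[[col]])
  for (col in c("queryId", "subjectId", "strand"))
    frags[[col]] <- as.character(frags[[col]])
  rownames(frags) <- NULL
  new("FragmentSet", frags = frags[, .FRAG_COLS])
}

#' Set of reported chains
#'
#' Result container of [chainFragments()] / [reportChains()].  One row per
#' reported chain; `members` holds, parallel to the rows, the ordered `uid`s
#' of the member fragments.
#'
#' @slot chains `data.frame` with columns `queryId`, `subjectId`, `strand`,
#'   `chainScore`, `begX`, `endX`, `begY`, `endY` (the chain's bounding span,
#'   0-based half-open), `nFragments`.
#' @slot members list of integer vectors of member fragment `uid`s, ordered
#'   along the chain (strictly increasing in all four coordinates).
#' @seealso [chains()], [chainMembers()], [writeChains()]
#' @exportClass ChainSet
setClass("ChainSet", representation(chains = "data.frame", members = "list"))

setValidity("ChainSet", function(object) {
  need <- c("queryId", "subjectId", "strand", "chainScore",
            "begX", "endX", "begY", "endY", "nFragments")
  if (!all(need %in% names(object@chains)))
    return("chains data.frame is missing required columns")
  if (nrow(object@chains) != length(object@members))
    return("members list must parallel the chain rows")
  TRUE
})

setMethod("show", "FragmentSet", function(object) {
  df <- object@frags
  cat(sprintf("FragmentSet with %d fragment(s), %d group(s)\n", nrow(df),
              if (nrow(df)) nrow(unique(df[c("queryId", "subjectId", "strand")])) else 0L))
  if (nrow(df)) print(utils::head(df, 5L))
  if (nrow(df) > 5L) cat(sprintf("... and %d more\n", nrow(df) - 5L))
})

setMethod("show", "ChainSet", function(object) {
  df <- object@chains
  cat(sprintf("ChainSet with %d chain(s)\n", nrow(df)))
  if (nrow(df)) print(utils::head(df, 5L))
  if (nrow(df) > 5L) cat(sprintf("... and %d more\n", nrow(df) - 5L))
})

setMethod("length", "FragmentSet", function(x) nrow(x@frags))
setMethod("length", "ChainSet", function(x) nrow(x@chains))
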