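#' Dominance staircase for 1D range maximum queries
#'
#' A semi-dynamic priority structure over a fixed, rank-condensed key
#' universe declared at construction.  Only non-dominated entries are kept
#' (an entry is dominated when another entry has a more permissive key and
#' at least its priority), so the stored priorities are strictly monotone in
#' the key and a range-maximum query reduces to a single predecessor or
#' successor lookup in the ordered entry map.
#'
#' Direction `"max-below"` answers "maximum priority among keys strictly
#' below a bound"; `"max-above"` answers the mirrored query.  Objects have
#' reference semantics: `staircaseInsert()` mutates in place.
#'
#' @slot ptr external pointer to the native structure.
#' @slot direction `"max-below"` or `"max-above"`.
#' @seealso [Staircase()], [staircaseInsert()], [staircaseQuery()]
#' @exportClass Staircase
setClass("Staircase", representation(ptr = "externalptr", direction = "character"))

#' Create a dominance staircase
#'
#' @param universe numeric vector of every key value that may ever be
#'   inserted (duplicates allowed; condensed to sorted unique ranks).
#'   Query bounds need not belong to the universe.
#' @param direction `"max-below"` (default) or `"max-above"`.
#' @return A [Staircase-class] object.
#' @examples
#' s <- Staircase(1:10)
#' staircaseInsert(s, 3, 7, payload = 1L)
#' staircaseInsert(s, 5, 10, payload = 2L)
#' staircaseQuery(s, 6)   # priority 10
#' @export
Staircase <- function(universe, direction = c("max-below", "max-above")) {
  direction <- match.arg(direction)
  new("Staircase",
      ptr = cpp_staircase_new(as.numeric(universe), direction == "max-below"),
      direction = direction)
}

#' @rdname Staircase
#' @param s a [Staircase-class].
#' @param key key value; must be a member of the universe.
#' @param priority numeric priority.
#' @param payload integer handle stored with the entry.
#' @export
staircaseInsert <- function(s, key, priority, payload) {
  cpp_staircase_insert(s@ptr, key, priority, as.integer(payload))
  invisible(s)
}

#' @rdname Staircase
#' @param bound query bound (strict, per the direction).
#' @return `staircaseQuery` returns `list(priority=, payload=)` or `NULL`
#'   when the range holds no entry.
#' @export
staircaseQuery <- function(s, bound) {
  cpp_staircase_query(s@ptr, bound)
}

#' @rdname Staircase
#' @return `staircaseEntries` returns the live (non-dominated) entries as a
#'   `data.frame(key, priority, payload)` in key order.
#' @export
staircaseEntries <- function(s) {
  cpp_staircase_entries(s@ptr)
}

setMethod("show", "Staircase", function(object) {
  cat(sprintf("Staircase (%s) with %d live entrie(s)\n",
              object@direction, nrow(staircaseEntries(object))))
})

#' Range tree for 2D octant range maximum queries
#'
#' A primary balanced search tree over the first-dimension key universe;
#' every node holds a max-below [Staircase-class] over the second dimension
#' for its canonical subset (the elements in the subtree below it).  A query
#' for the maximum priority among elements with `key1 <= bound1` and
#' `key2 < bound2` decomposes the dimension-1 prefix into `O(log U)`
#' canonical nodes and takes the best staircase answer among them.
#' Reference semantics, like [Staircase-class].
#'
#' @slot ptr external pointer to the native structure.
#' @seealso [RangeTree2D()], [rangeTreeInsert()], [rangeTreeQuery()]
#' @exportClass RangeTree2D
setClass("RangeTree2D", representation(ptr = "externalptr"))

#' Create a 2D range tree
#'
#' @param universe1,universe2 numeric vectors of every key value that may be
#'   inserted in the respective dimension (condensed to sorted unique).
#' @return A [RangeTree2D-class] object.
#' @examples
#' t <- RangeTree2D(1:4, 1:10)
#' rangeTreeInsert(t, 1, 1, 5, payload = 1L)
#' rangeTreeInsert(t, 2, 9, 9, payload = 2L)
#' rangeTreeQuery(t, 2, 5)   # priority 5: the p=9 element fails key2 < 5
#' @export
RangeTree2D <- function(universe1, universe2) {
  new("RangeTree2D",
      ptr = cpp_rangetree_new(as.numeric(universe1), as.numeric(universe2)))
}

#' @rdname RangeTree2D
#' @param t a [RangeTree2D-class].
#' @param key1,key2 key values; must be members of the universes.
#' @param priority numeric priority.
#' @param payload integer handle stored with the element.
#' @export
rangeTreeInsert <- function(t, key1, key2, priority, payload) {
  cpp_rangetree_insert(t@ptr, key1, key2, priority, as.integer(payload))
  invisible(t)
}

#' @rdname RangeTree2D
#' @param bound1 dimension-1 bound, non-strict (`key1 <= bound1`).
#' @param bound2 dimension-2 bound, strict (`key2 < bound2`).
#' @return `rangeTreeQuery` returns `list(priority=, payload=)` or `NULL`.
#' @export
rangeTreeQuery <- function(t, bound1, bound2) {
  cpp_rangetree_query(t@ptr, bound1, bound2)
}

#' @rdname RangeTree2D
#' @return `rangeTreeQueryCount` returns the number of node staircases
#'   probed by the most recent query (at most `ceil(log2(U)) + 1`).
#' @export
rangeTreeQueryCount <- function(t) {
  cpp_rangetree_query_count(t@ptr)
}

setMethod("show", "RangeTree2D", function(object) {
  cat("RangeTree2D over fixed key universes\n")
})

# ---- linear-scan reference oracles (tests) ---------------------------------
# Both scan every element ever inserted; domination pruning in the real
# structures must never change a query answer.  Return NULL or
# list(priority=, payloads=<all payloads attaining the max>).

.oracleScan1d <- function(keys, priorities, payloads, bound,
                          direction = c("max-below", "max-above")) {
  direction <- match.arg(direction)
  keep <- if (direction == "max-below") keys < bound else keys > bound
  if (!any(keep)) return(NULL)
  p <- priorities[keep]
  best <- max(p)
  list(priority = best, payloads = payloads[keep][p == best])
}

.oracleScan2d <- function(keys1, keys2, priorities, payloads, bound1, bound2) {
  keep <- keys1 <= bound1 & keys2 < bound2
  if (!any(keep)) return(NULL)
  p <- priorities[keep]
  best <- max(p)
  list(priority = best, payloads = payloads[keep][p == best])
}
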