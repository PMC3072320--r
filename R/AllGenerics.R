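#' Accessors for FragmentSet and ChainSet
#'
#' `fragments()` returns the fragment table of a [FragmentSet-class];
#' `chains()` returns the chain table of a [ChainSet-class];
#' `chainMembers()` returns the list of ordered member fragment `uid`s,
#' one integer vector per chain row.
#'
#' @param x a `FragmentSet` or `ChainSet`.
#' @return A `data.frame` (or, for `chainMembers`, a list of integer
#'   vectors).
#' @name accessors
#' @examples
#' fs <- simulateUniformFragments(5, seed = 1)
#' fragments(fs)
NULL

#' @rdname accessors
#' @export
setGeneric("fragments", function(x) standardGeneric("fragments"))

#' @rdname accessors
#' @export
setGeneric("chains", function(x) standardGeneric("chains"))

#' @rdname accessors
#' @export
setGeneric("chainMembers", function(x) standardGeneric("chainMembers"))

#' @rdname accessors
setMethod("fragments", "FragmentSet", function(x) x@frags)

#' @rdname accessors
setMethod("chains", "ChainSet", function(x) x@chains)

#' @rdname accessors
setMethod("chainMembers", "ChainSet", function(x) x@members)
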