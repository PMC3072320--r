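# Random problem generators shared across the suite.  All take the RNG
# state as-is; tests wrap them in withr::with_seed / set.seed.

# Unstructured random fragments in one (query, subject, strand) group:
# coordinates in [0, coordMax), fragment lengths up to lenMax (independent
# on the two axes, as for gapped hits), scores uniform in [1, scoreMax].
randomInstance <- function(n, coordMax = 5000, lenMax = 120, scoreMax = 100) {
  begX <- sample.int(coordMax, n, replace = TRUE) - 1
  begY <- sample.int(coordMax, n, replace = TRUE) - 1
  fragmentSet(data.frame(
    queryId = "q", subjectId = "s",
    begX = begX, endX = begX + sample.int(lenMax, n, replace = TRUE),
    begY = begY, endY = begY + sample.int(lenMax, n, replace = TRUE),
    score = runif(n, 1, scoreMax), stringsAsFactors = FALSE))
}

# Random gap parameters valid for the model (sop keeps eps <= 2 * lam).
randomParams <- function(model) {
  lam <- runif(1, 0.05, 2)
  eps <- if (model == "sop") runif(1, 0, 2 * lam) else runif(1, 0, 2)
  gapParams(model, lam, eps)
}

# Fragments arranged in bundles widely separated on the database axis but
# sharing a short query extent -- the geometry the clustering pre-pass is
# for.  Scores are kept small so the separation gaps are unaffordable.
bundledInstance <- function(nBundles = 5, perBundle = 8, bundleSpan = 2000,
                            gapRange = c(5e4, 1e6), queryMax = 3000,
                            lenMax = 120, scoreMax = 20) {
  offs <- cumsum(c(0, bundleSpan + runif(nBundles - 1, gapRange[1], gapRange[2])))
  rows <- lapply(seq_len(nBundles), function(b) {
    bx <- offs[b] + sample.int(bundleSpan, perBundle, replace = TRUE) - 1
    by <- sample.int(queryMax, perBundle, replace = TRUE) - 1
    data.frame(queryId = "q", subjectId = "s",
               begX = bx, endX = bx + sample.int(lenMax, perBundle, replace = TRUE),
               begY = by, endY = by + sample.int(lenMax, perBundle, replace = TRUE),
               score = runif(perBundle, 1, scoreMax), stringsAsFactors = FALSE)
  })
  fragmentSet(do.call(rbind, rows))
}

# Build a FragmentSet from a compact coordinate matrix for directed tests:
# each row is c(begX, endX, begY, endY, score).
frags <- function(...) {
  m <- do.call(rbind, list(...))
  fragmentSet(data.frame(
    queryId = "q", subjectId = "s",
    begX = m[, 1], endX = m[, 2], begY = m[, 3], endY = m[, 4],
    score = m[, 5], stringsAsFactors = FALSE))
}
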