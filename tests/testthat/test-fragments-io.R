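blastLine <- function(qid = "q1", sid = "s1", pident = 100, len = 50,
                      qstart = 1, qend = 50, sstart = 101, send = 150,
                      bits = 99) {
  paste(qid, sid, pident, len, 0, 0, qstart, qend, sstart, send, "1e-20", bits,
        sep = "\t")
}

test_that("BLAST tabular parsing converts coordinates, strand and scores", {
  f <- tempfile()
  writeLines(c("# comment", blastLine()), f)

  fs <- readBlastTabular(f, scoreMode = "length")
  df <- fragments(fs)
  expect_equal(nrow(df), 1L)
  expect_equal(df[, c("begY", "endY", "begX", "endX")],
               data.frame(begY = 0, endY = 50, begX = 100, endX = 150))
  expect_equal(df$strand, "+")
  expect_equal(df$score, 50)

  expect_equal(fragments(readBlastTabular(f, scoreMode = "bitscore"))$score, 99)
  writeLines(blastLine(pident = 90), f)
  expect_equal(fragments(readBlastTabular(f, scoreMode = "identity_x_length"))$score,
               0.9 * 50)

  # minus strand: sstart > send swaps subject coordinates
  writeLines(blastLine(sstart = 150, send = 101), f)
  df <- fragments(readBlastTabular(f))
  expect_equal(df$strand, "-")
  expect_equal(df$begX, 100)
  expect_equal(df$endX, 150)
  # length preserved by the swap, 1-based inclusive span == half-open width
  expect_equal(df$endX - df$begX, 150 - 101 + 1)
})

test_that("malformed BLAST lines are fatal when strict, skipped otherwise", {
  f <- tempfile()
  writeLines(c(blastLine(), "q1\ts1\tshort"), f)
  expect_error(readBlastTabular(f, strict = TRUE), "line\\(s\\) 2")
  expect_warning(fs <- readBlastTabular(f, strict = FALSE), "skipping 1")
  expect_equal(length(fs), 1L)

  writeLines(blastLine(sstart = "abc"), f)
  expect_error(readBlastTabular(f, strict = FALSE), "non-numeric")
})

test_that("fragment TSV reads 1-based inclusive coordinates", {
  f <- tempfile()
  writeLines("q\ts\t10\t1\t10\t1\t10", f)
  df <- fragments(readFragmentTsv(f))
  expect_equal(df[, c("score", "begY", "endY", "begX", "endX")],
               data.frame(score = 10, begY = 0, endY = 10, begX = 0, endX = 10))
  expect_equal(df$uid, 0L)

  writeLines(character(0), f)
  expect_equal(length(readFragmentTsv(f)), 0L)
  writeLines("# header only", f)
  expect_equal(length(readFragmentTsv(f)), 0L)
  writeLines("q\ts\t10\t10\t1\t1\t10", f)
  expect_error(readFragmentTsv(f), "end < start at line 1")
})

test_that("fragment TSV round trip reproduces fragments exactly", {
  set.seed(42)
  fs <- randomInstance(50)
  df <- fragments(fs)
  df$strand[1:10] <- "-"
  df$queryId[1:25] <- "q2"
  fs <- fragmentSet(df)

  f <- tempfile()
  writeFragmentTsv(fs, f)
  back <- fragments(readFragmentTsv(f))
  expect_equal(back[c("queryId", "subjectId", "strand",
                      "begX", "endX", "begY", "endY", "score")],
               df[c("queryId", "subjectId", "strand",
                    "begX", "endX", "begY", "endY", "score")])
})

test_that("partitionByGroup separates queries, subjects and strands", {
  df <- fragments(frags(c(0, 10, 0, 10, 5), c(20, 30, 20, 30, 5)))
  df$queryId <- c("q1", "q2")
  expect_length(partitionByGroup(fragmentSet(df)), 2L)

  df$queryId <- "q"
  df$strand <- c("+", "-")
  groups <- partitionByGroup(fragmentSet(df))
  expect_length(groups, 2L)
  expect_equal(sum(vapply(groups, nrow, 0L)), 2L)

  expect_length(partitionByGroup(fragmentSet(fragchain:::.emptyFragDf())), 0L)
})

test_that("writeChains sorts by score and formats 1-based spans", {
  fs <- frags(c(0, 10, 0, 10, 30), c(100, 120, 100, 120, 40))
  cs <- reportChains(sweepChain(fs, gapParams("linear")), fs)
  f <- tempfile()
  writeChains(cs, f, emitMembers = TRUE)
  lines <- readLines(f)
  expect_match(lines[1], "^# query_id")
  got <- read.delim(f, header = FALSE, comment.char = "#")
  expect_equal(got$V4, c(40, 30))            # descending score
  expect_equal(got$V7[2], 1)                 # s_start back to 1-based
  expect_equal(got$V9, c(1L, 1L))

  writeChains(fragchain:::.emptyChainSet(), f)
  expect_length(readLines(f), 1L)            # header only
})

test_that("BED export carries span, query id and rounded score", {
  fs <- frags(c(5, 15, 0, 10, 12.4))
  cs <- reportChains(sweepChain(fs, gapParams("linear")), fs)
  f <- tempfile()
  writeChainsBed(cs, f)
  got <- read.delim(f, header = FALSE)
  expect_equal(unname(unlist(got[1, ])),
               c("s", "5", "15", "q", "12", "+"))
})
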