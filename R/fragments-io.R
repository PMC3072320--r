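#' Read fragments from BLAST tabular output
#'
#' Parses classic 12-column BLAST tabular output (`-m 8` / `-outfmt 6`:
#' qseqid, sseqid, pident, length, mismatch, gapopen, qstart, qend, sstart,
#' send, evalue, bitscore).  The query is the `y` axis, the subject/database
#' the `x` axis.  BLAST's 1-based inclusive coordinates are converted to the
#' internal 0-based half-open convention.  Hits with `sstart > send` (or
#' `qstart > qend`) are minus-strand: the offending coordinate pair is
#' swapped and the fragment labelled strand `"-"`.
#'
#' @param file path or connection to the tabular file; lines starting with
#'   `#` are skipped.
#' @param scoreMode how to score each fragment: `"length"` (alignment
#'   length, the scoring used for chaining sensitive short-word BLAST
#'   screens), `"bitscore"`, or `"identity_x_length"`
#'   (`pident/100 * length`).
#' @param strict if `TRUE` (default) a line with fewer than 12 tab-separated
#'   fields is a fatal error; if `FALSE` it is skipped with a warning.
#'   Non-numeric coordinates are always fatal.
#' @return A [FragmentSet-class]; `uid` is the 0-based index among parsed
#'   fragments.
#' @seealso [readFragmentTsv()], [chainFragments()]
#' @export
readBlastTabular <- function(file,
                             scoreMode = c("length", "bitscore", "identity_x_length"),
                             strict = TRUE) {
  scoreMode <- match.arg(scoreMode)
  lines <- readLines(file)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(fragmentSet(.emptyFragDf()))

  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- nf < 12L
  if (any(bad)) {
    where <- paste(utils::head(lineNo[bad], 5L), collapse = ", ")
    if (strict)
      stop(sprintf("malformed BLAST tabular line(s) (< 12 fields) at line(s) %s", where))
    warning(sprintf("skipping %d malformed line(s) at line(s) %s", sum(bad), where))
    parts <- parts[!bad]
    lineNo <- lineNo[!bad]
  }
  if (!length(parts)) return(fragmentSet(.emptyFragDf()))

  field <- function(i) vapply(parts, `[[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(field(i)))
    if (anyNA(v))
      stop(sprintf("non-numeric %s at line %d", what, lineNo[which(is.na(v))[1L]]))
    v
  }
  pident <- num(3L, "percent identity")
  alnlen <- num(4L, "alignment length")
  qstart <- num(7L, "qstart"); qend <- num(8L, "qend")
  sstart <- num(9L, "sstart"); send  <- num(10L, "send")
  bits   <- num(12L, "bitscore")

  qminus <- qstart > qend
  sminus <- sstart > send
  tmp <- qstart[qminus]; qstart[qminus] <- qend[qminus]; qend[qminus] <- tmp
  tmp <- sstart[sminus]; sstart[sminus] <- send[sminus]; send[sminus] <- tmp
  strand <- ifelse(xor(qminus, sminus), "-", "+")

  score <- switch(scoreMode,
    length = alnlen,
    bitscore = bits,
    identity_x_length = pident / 100 * alnlen)

  fragmentSet(data.frame(
    uid = seq_along(parts) - 1L,
    queryId = field(1L), subjectId = field(2L), strand = strand,
    begX = sstart - 1, endX = send,
    begY = qstart - 1, endY = qend,
    score = score, stringsAsFactors = FALSE))
}

.emptyFragDf <- function() {
  data.frame(uid = integer(), queryId = character(), subjectId = character(),
             strand = character(), begX = numeric(), endX = numeric(),
             begY = numeric(), endY = numeric(), score = numeric(),
             stringsAsFactors = FALSE)
}

#' Read and write the generic fragment TSV format
#'
#' A minimal tab-separated fragment exchange format with columns
#' `query_id`, `subject_id`, `score`, `q_start`, `q_end`, `s_start`,
#' `s_end` and an optional eighth `strand` column (`+` assumed when
#' absent).  Coordinates are 1-based inclusive on disk; an optional header
#' line starting with `#` is ignored on input and written on output.
#' `writeFragmentTsv()` followed by `readFragmentTsv()` reproduces
#' coordinates, scores, ids and strands exactly.
#'
#' @param file path or connection.
#' @return `readFragmentTsv` returns a [FragmentSet-class] with `uid` the
#'   0-based input index.
#' @export
readFragmentTsv <- function(file) {
  lines <- readLines(file)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineNo <- which(keep)
  lines <- lines[keep]
  if (!length(lines)) return(fragmentSet(.emptyFragDf()))

  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 7L))
    stop(sprintf("fragment TSV line %d has fewer than 7 fields",
                 lineNo[which(nf < 7L)[1L]]))
  field <- function(i) vapply(parts, `[[`, "", i)
  num <- function(i, what) {
    v <- suppressWarnings(as.numeric(field(i)))
    if (anyNA(v))
      stop(sprintf("non-numeric %s at line %d", what, lineNo[which(is.na(v))[1L]]))
    v
  }
  score <- num(3L, "score")
  qs <- num(4L, "q_start"); qe <- num(5L, "q_end")
  ss <- num(6L, "s_start"); se <- num(7L, "s_end")
  bad <- qe < qs | se < ss
  if (any(bad))
    stop(sprintf("end < start at line %d", lineNo[which(bad)[1L]]))
  strand <- vapply(parts, function(p) if (length(p) >= 8L) p[[8L]] else "+", "")

  fragmentSet(data.frame(
    uid = seq_along(parts) - 1L,
    queryId = field(1L), subjectId = field(2L), strand = strand,
    begX = ss - 1, endX = se, begY = qs - 1, endY = qe,
    score = score, stringsAsFactors = FALSE))
}

#' @rdname readFragmentTsv
#' @param x a [FragmentSet-class] to write.
#' @export
writeFragmentTsv <- function(x, file) {
  stopifnot(is(x, "FragmentSet"))
  df <- fragments(x)
  out <- data.frame(df$queryId, df$subjectId, df$score,
                    df$begY + 1, df$endY, df$begX + 1, df$endX, df$strand)
  con <- .openOut(file)
  if (!is.null(attr(con, "fragchainOwned"))) on.exit(close(con))
  writeLines("# query_id\tsubject_id\tscore\tq_start\tq_end\ts_start\ts_end\tstrand", con)
  if (nrow(out))
    write.table(out, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(x)
}

#' Partition fragments into independently chained groups
#'
#' Fragments from different queries, database sequences, or strands are
#' never chained together; this splits a [FragmentSet-class] by the
#' `(queryId, subjectId, strand)` triple.  Every fragment lands in exactly
#' one group.
#'
#' @param x a [FragmentSet-class].
#' @return Named list of `data.frame`s (one per group, names
#'   `queryId|subjectId|strand`), in order of first appearance.
#' @export
partitionByGroup <- function(x) {
  df <- if (is(x, "FragmentSet")) fragments(x) else x
  if (!nrow(df)) return(structure(list(), names = character()))
  key <- paste(df$queryId, df$subjectId, df$strand, sep = "|")
  split(df, factor(key, levels = unique(key)))
}

#' Write chain reports
#'
#' `writeChains()` writes one tab-separated row per chain: `query_id`,
#' `subject_id`, `strand`, `chain_score`, `q_start`, `q_end`, `s_start`,
#' `s_end` (1-based inclusive), `n_fragments`, and with
#' `emitMembers = TRUE` a final column of `;`-joined member fragment uids.
#' Rows are sorted by descending score, ties by `(subject_id, s_start)`.
#' `writeChainsBed()` writes the chain spans as BED6 on the database
#' sequence (`name` = query id, `score` = rounded chain score).
#'
#' @param x a [ChainSet-class].
#' @param file path or connection.
#' @param emitMembers include the member-uid column.
#' @return `x`, invisibly.
#' @export
writeChains <- function(x, file, emitMembers = FALSE) {
  stopifnot(is(x, "ChainSet"))
  df <- chains(x)
  mem <- chainMembers(x)
  ord <- order(-df$chainScore, df$subjectId, df$begX)
  df <- df[ord, , drop = FALSE]
  mem <- mem[ord]

  header <- c("query_id", "subject_id", "strand", "chain_score",
              "q_start", "q_end", "s_start", "s_end", "n_fragments")
  out <- data.frame(df$queryId, df$subjectId, df$strand,
                    .fmtNum(df$chainScore),
                    df$begY + 1, df$endY, df$begX + 1, df$endX,
                    df$nFragments, stringsAsFactors = FALSE)
  if (emitMembers) {
    header <- c(header, "fragments")
    out$fragments <- vapply(mem, paste, "", collapse = ";")
  }
  con <- .openOut(file)
  if (!is.null(attr(con, "fragchainOwned"))) on.exit(close(con))
  writeLines(paste0("# ", paste(header, collapse = "\t")), con)
  if (nrow(out))
    write.table(out, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(x)
}

#' @rdname writeChains
#' @export
writeChainsBed <- function(x, file) {
  stopifnot(is(x, "ChainSet"))
  df <- chains(x)
  ord <- order(-df$chainScore, df$subjectId, df$begX)
  df <- df[ord, , drop = FALSE]
  out <- data.frame(df$subjectId, df$begX, df$endX, df$queryId,
                    round(df$chainScore), df$strand)
  con <- .openOut(file)
  if (!is.null(attr(con, "fragchainOwned"))) on.exit(close(con))
  if (nrow(out))
    write.table(out, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  else writeLines(character(0), con)
  invisible(x)
}

# print scores without scientific notation or trailing-zero churn
.fmtNum <- function(v) {
  ifelse(v == round(v), format(round(v), scientific = FALSE, trim = TRUE),
         format(v, scientific = FALSE, trim = TRUE, digits = 10))
}

.openOut <- function(file) {
  if (is.character(file)) {
    if (!nzchar(file)) return(stdout())
    con <- file(file, "w")
    attr(con, "fragchainOwned") <- TRUE
    return(con)
  }
  file
}
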