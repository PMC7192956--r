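#' @title FASTA reading, writing and the five sequence transforms
#'
#' @description Sequence-side operations used while staging barcode
#' records: parse single- or multi-line FASTA into a
#' \code{\linkS4class{FastaDocument}}, write the single-line dialect,
#' remove alignment gaps, rank records shortest-to-longest, dereplicate
#' by header or by sequence, and convert multi-line files to single-line
#' form under the date-stamped naming convention. Input files are never
#' modified.
#'
#' @name fasta
NULL

#' Read a FASTA file
#'
#' Parses a multiple-sequence FASTA file in file order. Multi-line
#' sequences are concatenated; the dialect is recorded as
#' \code{"single_line"} only when every record's sequence occupied
#' exactly one source line. A UTF-8 byte-order mark and blank leading
#' lines are tolerated; blank lines inside the body are skipped with a
#' warning. Sequence case and gap characters are preserved verbatim.
#'
#' @param path path to the FASTA file.
#' @return a \code{\linkS4class{FastaDocument}}.
#' @section Errors: a file with no \code{">"} header is rejected as
#'   not-FASTA; a record with an empty sequence, or a sequence line
#'   containing \code{">"} after the first character, is rejected naming
#'   the offending record.
#' @examples
#' f <- tempfile(fileext = ".fas")
#' writeLines(c(">a", "ACGT", "ACGT", ">b", "TTTT"), f)
#' doc <- readFasta(f)
#' dialect(doc)  # "multi_line"
#' @export
readFasta <- function(path) {
  if (!is.character(path) || length(path) != 1L || !file.exists(path))
    stop("FASTA file '", paste(path, collapse = ","),
         "' does not exist", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- gsub("\r", "", lines, fixed = TRUE)
  if (length(lines))
    lines[1] <- sub("^\ufeff", "", lines[1])

  ## drop blank leading lines
  first <- which(nzchar(trimws(lines)))[1]
  if (is.na(first) || !startsWith(lines[first], ">"))
    stop("'", path, "' is not a FASTA file (no '>' header found)",
         call. = FALSE)
  lines <- lines[first:length(lines)]

  isHeader <- startsWith(lines, ">")
  blank <- !isHeader & !nzchar(trimws(lines))
  if (any(blank)) {
    warning("skipped ", sum(blank), " blank line(s) inside '", path, "'",
            call. = FALSE)
    keep <- !blank
    lines <- lines[keep]
    isHeader <- isHeader[keep]
  }

  bad <- !isHeader & grepl(">", lines, fixed = TRUE)
  if (any(bad))
    stop("malformed FASTA '", path, "': '>' inside a sequence line (line ",
         which(bad)[1], " of the record body)", call. = FALSE)

  rec <- cumsum(isHeader)
  headersRaw <- trimws(sub("^>", "", lines[isHeader]), which = "right")
  if (any(!nzchar(headersRaw)))
    stop("malformed FASTA '", path, "': empty header", call. = FALSE)

  seqLines <- split(lines[!isHeader], rec[!isHeader])
  nRec <- sum(isHeader)
  seqs <- character(nRec)
  nLines <- integer(nRec)
  idx <- as.integer(names(seqLines))
  seqs[idx] <- vapply(seqLines, function(x) paste(trimws(x), collapse = ""),
                      "")
  nLines[idx] <- lengths(seqLines)

  empty <- !nzchar(seqs)
  if (any(empty))
    stop("malformed FASTA '", path, "': record '",
         headersRaw[which(empty)[1]], "' has an empty sequence",
         call. = FALSE)

  dial <- if (all(nLines == 1L)) "single_line" else "multi_line"
  FastaDocument(headersRaw, seqs, dialect = dial)
}

#' Write a FastaDocument in the single-line dialect
#'
#' Writes \code{">header"} then the whole sequence on one line, per
#' record in order, LF line endings. Re-reading the file yields an equal
#' document with dialect \code{"single_line"}.
#'
#' @param doc a \code{\linkS4class{FastaDocument}}.
#' @param path destination file; an existing file is an error, never
#'   overwritten.
#' @return the written path, invisibly usable downstream.
#' @export
writeFastaSingleLine <- function(doc, path) {
  stopifnot(is(doc, "FastaDocument"))
  if (!dir.exists(dirname(path)))
    stop("output directory '", dirname(path), "' does not exist",
         call. = FALSE)
  stopIfExists(path)
  con <- file(path, open = "wb")
  on.exit(close(con))
  n <- length(doc)
  if (n) {
    seqs <- as.character(doc@sequences)
    writeLines(as.vector(rbind(paste0(">", doc@headers), seqs)), con,
               useBytes = TRUE)
  }
  path
}

#' Remove alignment gaps from every sequence
#'
#' Deletes every \code{"-"} character — and only \code{"-"}; \code{"."}
#' and \code{"~"} pass through untouched — so that unaligned sequences
#' can be submitted to repositories that reject alignment padding.
#' Headers, record order and record count are unchanged. A record whose
#' sequence is nothing but gaps would become empty and is rejected by
#' name: a gap-only record is not uploadable.
#'
#' @param doc a \code{\linkS4class{FastaDocument}}.
#' @return a new \code{FastaDocument} with gap-free sequences.
#' @examples
#' degap(FastaDocument("a", "AC-GT--A"))  # ACGTA
#' @export
degap <- function(doc) {
  stopifnot(is(doc, "FastaDocument"))
  seqs <- gsub("-", "", as.character(doc@sequences), fixed = TRUE)
  empty <- !nzchar(seqs)
  if (any(empty))
    stop("record '", doc@headers[which(empty)[1]],
         "' is empty after gap removal", call. = FALSE)
  FastaDocument(doc@headers, seqs, dialect = doc@dialect)
}

#' Rank records from shortest to longest sequence
#'
#' Stable sort on sequence length: the output is a permutation of the
#' input with non-decreasing lengths, and records of equal length keep
#' their input order. Useful for eyeballing an alignment and trimming
#' short sequences off the top of the file.
#'
#' @param doc a \code{\linkS4class{FastaDocument}}.
#' @return a new \code{FastaDocument}, length-sorted.
#' @export
rankSeq <- function(doc) {
  stopifnot(is(doc, "FastaDocument"))
  ord <- order(Biostrings::width(doc@sequences))  # radix sort, stable
  FastaDocument(doc@headers[ord],
                as.character(doc@sequences)[ord],
                dialect = doc@dialect)
}

#' Dereplicate by header
#'
#' Keeps, for each distinct header, exactly the first record bearing it,
#' in first-occurrence order. Headers are compared verbatim (the whole
#' definition line after \code{">"}, trailing whitespace trimmed) — no
#' tokenization at the first space, since specimen-ID headers routinely
#' carry meaningful pipes and spaces. Idempotent.
#'
#' @param doc a \code{\linkS4class{FastaDocument}}.
#' @return a new \code{FastaDocument} with pairwise-distinct headers.
#' @export
headDerep <- function(doc) {
  stopifnot(is(doc, "FastaDocument"))
  keep <- !duplicated(doc@headers)
  FastaDocument(doc@headers[keep],
                as.character(doc@sequences)[keep],
                dialect = doc@dialect)
}

#' Dereplicate by sequence
#'
#' Keeps, for each distinct sequence, exactly the first record bearing
#' it, in first-occurrence order — the distinct-sequence count
#' approximates the haplotype diversity of the file. Comparison is
#' case-insensitive (soft-masked lowercase is a formatting artifact, not
#' a haplotype difference) over the raw sequence string: gap characters
#' are part of the key, so \code{\link{degap}} first if gapped and
#' ungapped copies of one haplotype should collapse. Idempotent.
#'
#' @param doc a \code{\linkS4class{FastaDocument}}.
#' @return a new \code{FastaDocument} with pairwise-distinct sequences.
#' @export
seqDerep <- function(doc) {
  stopifnot(is(doc, "FastaDocument"))
  seqs <- as.character(doc@sequences)
  keep <- !duplicated(toupper(seqs))
  FastaDocument(doc@headers[keep], seqs[keep], dialect = doc@dialect)
}

#' Convert a multi-line FASTA file to single-line form
#'
#' Reads \code{inPath} and writes it back in the single-line dialect
#' under the name \code{YYYYMMDD_multi_to_single_fasta.fas} in
#' \code{outDir}. Record count, headers and concatenated sequences are
#' identical to the input; only the line wrapping changes.
#'
#' @param inPath input FASTA path (single- or multi-line).
#' @param outDir directory for the converted file.
#' @param runDate run date, injectable for reproducibility.
#' @return path of the written file.
#' @export
multiToSingleFasta <- function(inPath, outDir, runDate = Sys.Date()) {
  if (!dir.exists(outDir))
    stop("output directory '", outDir, "' does not exist", call. = FALSE)
  doc <- readFasta(inPath)
  out <- file.path(outDir, renderName("multi_to_single_fasta", runDate))
  writeFastaSingleLine(doc, out)
}
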