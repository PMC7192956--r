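#' @import methods
#' @importClassesFrom Biostrings BStringSet
NULL

#' FastaDocument: an ordered multiple-sequence FASTA file in memory
#'
#' Holds the records of one FASTA file in file order: headers verbatim
#' (text after \code{">"}, trailing whitespace trimmed) and sequences as
#' a \code{\link[Biostrings]{BStringSet}} so that case and gap characters
#' (\code{"-"}) survive untouched — lowercase soft-masking and alignment
#' gaps are meaningful to downstream transforms. The dialect records
#' whether every sequence occupied exactly one line in the source
#' (\code{"single_line"}) or not (\code{"multi_line"}).
#'
#' @slot headers character vector of record headers, no leading
#'   \code{">"}, non-empty.
#' @slot sequences \code{BStringSet}, parallel to \code{headers};
#'   no whitespace or \code{">"} inside a sequence.
#' @slot dialect \code{"single_line"} or \code{"multi_line"}.
#'
#' @seealso \code{\link{readFasta}}, \code{\link{writeFastaSingleLine}},
#'   \code{\link{degap}}, \code{\link{rankSeq}}, \code{\link{headDerep}},
#'   \code{\link{seqDerep}}
#' @export
setClass("FastaDocument",
  representation(headers = "character",
                 sequences = "BStringSet",
                 dialect = "character"))

setValidity("FastaDocument", function(object) {
  msg <- character()
  if (length(object@headers) != length(object@sequences))
    msg <- c(msg, "headers and sequences differ in length")
  if (length(object@dialect) != 1L ||
      !object@dialect %in% c("single_line", "multi_line"))
    msg <- c(msg, "dialect must be 'single_line' or 'multi_line'")
  if (any(!nzchar(object@headers)))
    msg <- c(msg, "empty header")
  seqs <- as.character(object@sequences)
  if (any(grepl("[[:space:]>]", seqs)))
    msg <- c(msg, "sequence contains whitespace or '>'")
  if (length(msg)) msg else TRUE
})

#' Construct a FastaDocument from character vectors
#'
#' @param headers character vector of headers (no leading \code{">"}).
#' @param sequences character vector of sequences, same length.
#' @param dialect \code{"single_line"} (default) or \code{"multi_line"}.
#' @return a \code{\linkS4class{FastaDocument}}.
#' @examples
#' FastaDocument(c("a", "b"), c("ACGT", "AC-GT"))
#' @export
FastaDocument <- function(headers = character(), sequences = character(),
                          dialect = "single_line") {
  new("FastaDocument",
      headers = trimws(as.character(headers), which = "right"),
      sequences = Biostrings::BStringSet(as.character(sequences)),
      dialect = dialect)
}

#' @describeIn FastaDocument-class number of records
#' @param x a \code{FastaDocument}
#' @export
setMethod("length", "FastaDocument", function(x) length(x@headers))

#' Accessors for FastaDocument
#'
#' \code{headers()} returns the record headers; \code{sequences()} the
#' sequences as a \code{BStringSet}; \code{dialect()} the source dialect.
#'
#' @param x a \code{\linkS4class{FastaDocument}}.
#' @return see each accessor.
#' @name FastaDocument-accessors
NULL

#' @rdname FastaDocument-accessors
#' @export
setGeneric("headers", function(x) standardGeneric("headers"))

#' @rdname FastaDocument-accessors
#' @export
setMethod("headers", "FastaDocument", function(x) x@headers)

#' @rdname FastaDocument-accessors
#' @export
setGeneric("sequences", function(x) standardGeneric("sequences"))

#' @rdname FastaDocument-accessors
#' @export
setMethod("sequences", "FastaDocument", function(x) x@sequences)

#' @rdname FastaDocument-accessors
#' @export
setGeneric("dialect", function(x) standardGeneric("dialect"))

#' @rdname FastaDocument-accessors
#' @export
setMethod("dialect", "FastaDocument", function(x) x@dialect)

setMethod("show", "FastaDocument", function(object) {
  n <- length(object)
  cat("FastaDocument with", n, if (n == 1) "record" else "records",
      sprintf("(%s dialect)\n", object@dialect))
  if (n) {
    w <- Biostrings::width(object@sequences)
    show <- utils::head(seq_len(n), 5L)
    for (i in show)
      cat(sprintf("  >%s  [%d nt]\n", object@headers[i], w[i]))
    if (n > 5L) cat("  ...", n - 5L, "more\n")
  }
})

#' PackPlan: an assignment of files to size-capped upload packs
#'
#' The result of \code{\link{planPacks}}: an ordered list of packs, each
#' an ordered data.frame of files (\code{path}, \code{name},
#' \code{size}), such that every input file appears in exactly one pack
#' and each pack's byte sum respects \code{maxBytes}.
#'
#' @slot maxBytes positive byte cap per pack.
#' @slot packs list of data.frames, each with columns \code{path},
#'   \code{name}, \code{size}.
#' @seealso \code{\link{planPacks}}, \code{\link{executePacks}}
#' @export
setClass("PackPlan",
  representation(maxBytes = "numeric", packs = "list"))

setValidity("PackPlan", function(object) {
  msg <- character()
  if (length(object@maxBytes) != 1L || is.na(object@maxBytes) ||
      object@maxBytes <= 0)
    msg <- c(msg, "maxBytes must be a single positive number")
  for (pk in object@packs) {
    if (!is.data.frame(pk) ||
        !all(c("path", "name", "size") %in% names(pk)))
      msg <- c(msg, "each pack must be a data.frame with path/name/size")
    else if (sum(pk$size) > object@maxBytes)
      msg <- c(msg, "pack byte sum exceeds maxBytes")
  }
  if (length(msg)) unique(msg) else TRUE
})

#' @describeIn PackPlan-class number of packs
#' @param x a \code{PackPlan}
#' @export
setMethod("length", "PackPlan", function(x) length(x@packs))

#' Accessors for PackPlan
#'
#' \code{packs()} returns the list of per-pack file tables;
#' \code{maxBytes()} the byte cap.
#'
#' @param x a \code{\linkS4class{PackPlan}}.
#' @name PackPlan-accessors
NULL

#' @rdname PackPlan-accessors
#' @export
setGeneric("packs", function(x) standardGeneric("packs"))

#' @rdname PackPlan-accessors
#' @export
setMethod("packs", "PackPlan", function(x) x@packs)

#' @rdname PackPlan-accessors
#' @export
setGeneric("maxBytes", function(x) standardGeneric("maxBytes"))

#' @rdname PackPlan-accessors
#' @export
setMethod("maxBytes", "PackPlan", function(x) x@maxBytes)

setMethod("show", "PackPlan", function(object) {
  cat("PackPlan:", length(object@packs), "pack(s), cap",
      format(object@maxBytes, scientific = FALSE), "bytes\n")
  for (i in seq_along(object@packs)) {
    pk <- object@packs[[i]]
    cat(sprintf("  pack %d: %d file(s), %s bytes\n", i, nrow(pk),
                format(sum(pk$size), scientific = FALSE)))
  }
})
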