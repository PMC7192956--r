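#' @title Seeded synthetic fixtures with known ground truth
#'
#' @description Test inputs for every operation are generated, never
#' downloaded: random directory trees of opaque JPG/AB1/FAS payload
#' files, and FASTA files with controlled duplication, gapping, case and
#' line wrapping. Each generator is a deterministic function of its
#' parameters and seed, and returns the ground truth (manifest, inserted
#' gap counts, distinct-key counts) that the corresponding operation
#' must reproduce.
#'
#' @name fixtures
NULL

#' Generate a random directory tree of target files
#'
#' Builds a tree of up to \code{depth} nested directory levels under
#' \code{root}, each directory holding a uniform-random number of files
#' in \code{filesPerDir}. Each file's type is drawn from \code{typeMix}
#' (\code{JPG}, \code{AB1}, \code{FAS} get matching extensions with
#' random upper/lower casing; \code{other} gets a never-matching
#' extension), and its content is an opaque random-byte payload of a
#' size drawn from \code{sizeRange} — sufficient because no file-level
#' operation inspects content. With probability
#' \code{duplicateNameRate}, a file in a subdirectory reuses an
#' earlier file's base name, exercising collision handling.
#'
#' @param root destination directory; must be empty (or absent, in which
#'   case it is created) — a non-empty root is refused to protect user
#'   data.
#' @param depth maximum nesting depth below \code{root} (0 = flat).
#' @param filesPerDir integer range \code{c(min, max)} of files per
#'   directory.
#' @param typeMix named proportions over \code{JPG}, \code{AB1},
#'   \code{FAS}, \code{other}; must sum to 1.
#' @param sizeRange byte-size range \code{c(min, max)} per file.
#' @param duplicateNameRate probability in \code{[0, 1]} that a file
#'   reuses an already-generated base name.
#' @param seed integer seed; identical arguments and seed give an
#'   identical tree.
#' @return the manifest: a data.frame with columns \code{path},
#'   \code{name}, \code{size}, \code{type} (one of \code{"JPG"},
#'   \code{"AB1"}, \code{"FAS"}, \code{"other"}); it is the oracle for
#'   scan/copy/pack tests.
#' @export
generateTree <- function(root, depth = 2L, filesPerDir = c(1L, 4L),
                         typeMix = c(JPG = 0.4, AB1 = 0.3, FAS = 0.2,
                                     other = 0.1),
                         sizeRange = c(10L, 200L),
                         duplicateNameRate = 0, seed = 1L) {
  if (dir.exists(root)) {
    if (length(list.files(root, all.files = TRUE, no.. = TRUE)))
      stop("refusing to generate into non-empty directory '", root, "'",
           call. = FALSE)
  } else dir.create(root, recursive = TRUE)
  if (abs(sum(typeMix) - 1) > 1e-8)
    stop("'typeMix' proportions must sum to 1", call. = FALSE)
  if (!all(c("JPG", "AB1", "FAS", "other") %in% names(typeMix)))
    stop("'typeMix' must name JPG, AB1, FAS and other", call. = FALSE)
  stopifnot(filesPerDir[1] >= 0, filesPerDir[2] >= filesPerDir[1],
            sizeRange[1] >= 1, sizeRange[2] >= sizeRange[1],
            duplicateNameRate >= 0, duplicateNameRate <= 1)
  set.seed(as.integer(seed))
  root <- normalizePath(root, winslash = "/")

  ## random extension casing per type; "other" never matches a target type
  extPool <- list(JPG = c("jpg", "JPG", "Jpg"),
                  AB1 = c("ab1", "AB1"),
                  FAS = c("fas", "FAS", "fasta", "FASTA"),
                  other = c("txt", "png", "csv", "fa"))

  dirs <- root
  if (depth > 0) {
    level <- root
    for (d in seq_len(depth)) {
      nNew <- sample(1:2, length(level), replace = TRUE)
      nxt <- character()
      for (i in seq_along(level)) {
        for (j in seq_len(nNew[i])) {
          p <- file.path(level[i], sprintf("d%d_%d", d, j))
          dir.create(p)
          nxt <- c(nxt, p)
        }
      }
      dirs <- c(dirs, nxt)
      level <- nxt
    }
  }

  rows <- list()
  counter <- 0L
  madeNames <- character()
  for (dd in dirs) {
    n <- sample(seq(filesPerDir[1], filesPerDir[2]), 1L)
    for (k in seq_len(n)) {
      counter <- counter + 1L
      type <- sample(names(typeMix), 1L, prob = typeMix)
      ext <- sample(extPool[[type]], 1L)
      if (length(madeNames) && stats::runif(1) < duplicateNameRate) {
        nm <- sample(madeNames, 1L)
        if (file.exists(file.path(dd, nm)))
          nm <- sprintf("f%05d.%s", counter, ext)
      } else {
        nm <- sprintf("f%05d.%s", counter, ext)
      }
      size <- sample(seq(sizeRange[1], sizeRange[2]), 1L)
      path <- file.path(dd, nm)
      writeBin(as.raw(sample(0:255, size, replace = TRUE)), path)
      ## type as scanTargets would classify it, not as drawn: a duplicated
      ## name keeps its original extension
      realExt <- tolower(tools::file_ext(nm))
      realType <- if (realExt == "jpg") "JPG"
                  else if (realExt == "ab1") "AB1"
                  else if (realExt %in% c("fas", "fasta")) "FAS"
                  else "other"
      rows[[counter]] <- data.frame(path = path, name = nm, size = size,
                                    type = realType,
                                    stringsAsFactors = FALSE)
      madeNames <- c(madeNames, nm)
    }
  }
  if (!length(rows))
    return(data.frame(path = character(), name = character(),
                      size = numeric(), type = character(),
                      stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Generate a FASTA file with known ground truth
#'
#' Writes \code{nRecords} nucleotide records to \code{path}. Duplicate
#' headers and duplicate sequences are injected at the requested rates
#' (a duplicated sequence may additionally be case-flipped when
#' \code{lowercaseRate > 0}, exercising case-insensitive sequence
#' keying); gap characters are inserted at random positions at rate
#' \code{gapFraction} of each sequence's length; \code{wrapWidth > 0}
#' wraps sequences to that many columns (multi-line dialect), 0 writes
#' single-line.
#'
#' @param path destination FASTA file (must not already exist).
#' @param nRecords number of records.
#' @param lengthRange ungapped sequence length range \code{c(min, max)}.
#' @param gapFraction fraction in \code{[0, 1]}: gaps inserted per record
#'   = \code{round(gapFraction * length)}.
#' @param duplicateHeaderRate probability a record reuses an earlier
#'   header.
#' @param duplicateSequenceRate probability a record reuses an earlier
#'   sequence (same gapped form, possibly re-cased).
#' @param lowercaseRate probability a duplicated sequence is emitted in
#'   lower case.
#' @param wrapWidth 0 for single-line output, else the wrap column.
#' @param seed integer seed; same arguments and seed give a byte-identical
#'   file.
#' @return ground truth, a list: \code{records} (data.frame with
#'   \code{header}, \code{sequence} as written, \code{gaps} inserted per
#'   record), \code{nDistinctHeaders}, \code{nDistinctSeqKeys}
#'   (case-insensitive, gaps included), \code{totalGaps}.
#' @export
generateFasta <- function(path, nRecords = 50L, lengthRange = c(80L, 400L),
                          gapFraction = 0, duplicateHeaderRate = 0,
                          duplicateSequenceRate = 0, lowercaseRate = 0,
                          wrapWidth = 0L, seed = 1L) {
  stopifnot(nRecords >= 1, lengthRange[1] >= 1,
            lengthRange[2] >= lengthRange[1],
            gapFraction >= 0, gapFraction <= 1,
            duplicateHeaderRate >= 0, duplicateHeaderRate <= 1,
            duplicateSequenceRate >= 0, duplicateSequenceRate <= 1,
            wrapWidth >= 0)
  stopIfExists(path)
  set.seed(as.integer(seed))

  headersOut <- character(nRecords)
  seqsOut <- character(nRecords)
  gaps <- integer(nRecords)
  for (i in seq_len(nRecords)) {
    ## header: fresh specimen id, or reuse of an earlier one
    if (i > 1 && stats::runif(1) < duplicateHeaderRate) {
      headersOut[i] <- sample(headersOut[seq_len(i - 1L)], 1L)
    } else {
      headersOut[i] <- sprintf("specimen_%04d|COI-5P", i)
    }
    ## sequence: fresh, or reuse (possibly re-cased) of an earlier one
    if (i > 1 && stats::runif(1) < duplicateSequenceRate) {
      s <- sample(seqsOut[seq_len(i - 1L)], 1L)
      if (stats::runif(1) < lowercaseRate) s <- tolower(s)
      seqsOut[i] <- s
      gaps[i] <- sum(strsplit(s, "")[[1]] == "-")
    } else {
      len <- sample(seq(lengthRange[1], lengthRange[2]), 1L)
      s <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = "")
      g <- as.integer(round(gapFraction * len))
      if (g > 0) {
        chars <- strsplit(s, "")[[1]]
        for (unused in seq_len(g))
          chars <- append(chars, "-",
                          after = sample(0:length(chars), 1L))
        s <- paste(chars, collapse = "")
      }
      seqsOut[i] <- s
      gaps[i] <- g
    }
  }

  lines <- character()
  for (i in seq_len(nRecords)) {
    lines <- c(lines, paste0(">", headersOut[i]))
    if (wrapWidth > 0) {
      s <- seqsOut[i]
      starts <- seq(1L, nchar(s), by = wrapWidth)
      lines <- c(lines, substring(s, starts,
                                  pmin(starts + wrapWidth - 1L, nchar(s))))
    } else {
      lines <- c(lines, seqsOut[i])
    }
  }
  con <- file(path, open = "wb")
  writeLines(lines, con, useBytes = TRUE)
  close(con)

  list(records = data.frame(header = headersOut, sequence = seqsOut,
                            gaps = gaps, stringsAsFactors = FALSE),
       nDistinctHeaders = length(unique(headersOut)),
       nDistinctSeqKeys = length(unique(toupper(seqsOut))),
       totalGaps = sum(gaps))
}
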