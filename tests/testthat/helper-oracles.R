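# Independent brute-force oracles the implementation is checked against.
# These deliberately use different machinery (base::list.files walks,
# readBStringSet, explicit loops) than the package internals.

# extensions each target type must match, lower case
oracleExts <- list(JPG = "jpg", AB1 = "ab1", FAS = c("fas", "fasta"))

# full-tree (or depth-0) enumeration filtered by case-insensitive extension
oracleScan <- function(root, type, recursive = TRUE, exclude = character()) {
  root <- normalizePath(root, winslash = "/")
  files <- list.files(root, recursive = recursive, full.names = TRUE)
  files <- files[!dir.exists(files)]
  if (length(exclude))
    files <- files[!startsWith(files, paste0(normalizePath(exclude,
                                                           winslash = "/"),
                                             "/"))]
  ext <- tolower(tools::file_ext(files))
  sort(files[ext %in% oracleExts[[type]]], method = "radix")
}

# sorted md5 multiset of every file under a tree (source-integrity checks)
treeChecksums <- function(root) {
  files <- list.files(root, recursive = TRUE, full.names = TRUE)
  files <- sort(files[!dir.exists(files)], method = "radix")
  unname(tools::md5sum(files))
}

# brute-force per-record FASTA parse: header lines vs concatenated bodies
oracleParseFasta <- function(path) {
  lines <- gsub("\r", "", readLines(path, warn = FALSE), fixed = TRUE)
  lines <- lines[nzchar(trimws(lines))]
  isHead <- startsWith(lines, ">")
  rec <- cumsum(isHead)
  headers <- sub("^>", "", lines[isHead])
  seqs <- vapply(split(lines[!isHead], rec[!isHead]),
                 paste, "", collapse = "")
  list(headers = trimws(headers, which = "right"), sequences = unname(seqs))
}

# stable length sort by explicit decorate-sort-undecorate
oracleRank <- function(headers, seqs) {
  key <- nchar(seqs)
  ord <- order(key, seq_along(key))  # tie-break on input position = stable
  list(headers = headers[ord], sequences = seqs[ord])
}

# fresh scratch directory per call
scratchDir <- function() {
  d <- tempfile("fixture")
  dir.create(d)
  d
}

refDate <- as.Date("2020-04-23")

# a small tree written by hand (no generator) for targeted cases
makeTree <- function(spec) {
  root <- scratchDir()
  for (rel in names(spec)) {
    p <- file.path(root, rel)
    dir.create(dirname(p), recursive = TRUE, showWarnings = FALSE)
    writeBin(as.raw(rep(seq_len(max(spec[[rel]], 1)) %% 256, length.out =
                          spec[[rel]])), p)
  }
  root
}
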