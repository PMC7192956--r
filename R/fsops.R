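#' @title File discovery, listing, copying and partitioning
#'
#' @description The file-level half of the toolkit: find every specimen
#' image (JPG), chromatogram trace (AB1) or sequence file (FASTA/FAS)
#' under a directory tree, write the list to a text file, flatten the
#' matches into a single upload folder, partition a folder's files into
#' size-capped upload packs, or copy a subset named by a plain-text list.
#' All operations are non-destructive: sources are only ever read.
#'
#' @name fsops
NULL

## discovery ------------------------------------------------------------------

#' List target files under a directory
#'
#' Scans \code{root} for regular files whose extension matches
#' \code{fileType}: \code{"JPG"} matches \code{.jpg}, \code{"AB1"} matches
#' \code{.ab1}, and \code{"FAS"} matches \code{.fasta} or \code{.fas}
#' (case-insensitive throughout; field cameras and sequencers emit
#' mixed-case extensions). With \code{recursive = TRUE} all
#' subdirectories are descended; symbolic links to directories are not
#' followed. The result is ordered lexicographically by full path
#' (C locale, so ordering is machine-independent).
#'
#' @param root directory to scan.
#' @param fileType \code{"JPG"}, \code{"AB1"} or \code{"FAS"}.
#' @param recursive descend subdirectories? Default \code{TRUE}.
#' @param exclude character vector of directory paths whose contents are
#'   skipped (used internally so a copy destination inside \code{root} is
#'   never re-scanned).
#' @return a data.frame with columns \code{path} (absolute path),
#'   \code{name} (base name with extension) and \code{size} (bytes),
#'   zero rows if nothing matches.
#' @examples
#' d <- tempfile(); dir.create(file.path(d, "sub"), recursive = TRUE)
#' file.create(file.path(d, "a.jpg"), file.path(d, "sub", "b.JPG"))
#' scanTargets(d, "JPG")
#' @export
scanTargets <- function(root, fileType, recursive = TRUE,
                        exclude = character()) {
  if (!is.character(root) || length(root) != 1L || !dir.exists(root))
    stop("input path '", paste(root, collapse = ","),
         "' does not exist or is not a directory", call. = FALSE)
  ft <- normalizeFileType(fileType)
  exts <- .TYPE_EXTENSIONS[[ft]]
  root <- normalizePath(root, winslash = "/")
  exclude <- vapply(exclude[dir.exists(exclude)],
                    normalizePath, "", winslash = "/")

  files <- .walkFiles(root, recursive = recursive, exclude = exclude)
  ext <- tolower(tools::file_ext(files))
  files <- files[ext %in% exts]
  files <- sort(files, method = "radix")

  sizes <- if (length(files)) file.size(files) else numeric()
  data.frame(path = files, name = basename(files), size = as.numeric(sizes),
             stringsAsFactors = FALSE)
}

## Depth-first walk that never follows directory symlinks (cycle safety).
#' @keywords internal
.walkFiles <- function(dir, recursive, exclude) {
  entries <- list.files(dir, full.names = TRUE, no.. = TRUE,
                        all.files = FALSE)
  if (!length(entries)) return(character())
  isDir <- dir.exists(entries)
  out <- entries[!isDir & file.exists(entries)]
  if (recursive) {
    subdirs <- entries[isDir]
    link <- vapply(subdirs, function(p) {
      l <- Sys.readlink(p); !is.na(l) && nzchar(l)
    }, logical(1))
    subdirs <- subdirs[!link]
    subdirs <- subdirs[!subdirs %in% exclude]
    for (s in subdirs)
      out <- c(out, .walkFiles(s, recursive = TRUE, exclude = exclude))
  }
  out
}

#' Write a file list to a date-stamped text file
#'
#' Saves one record per discovered file — full path and base name,
#' tab-separated — under the name
#' \code{YYYYMMDD_target_file_list_TYP.txt} in \code{dest}. Line order
#' equals the order of \code{entries}.
#'
#' @param entries a data.frame as returned by \code{\link{scanTargets}}.
#' @param dest directory in which to create the list file.
#' @param fileType the target type the list was scanned for (names the
#'   output).
#' @param runDate run date, injectable for reproducibility.
#' @return path of the created text file.
#' @export
writeFileList <- function(entries, dest, fileType, runDate = Sys.Date()) {
  if (!dir.exists(dest))
    stop("output directory '", dest, "' does not exist", call. = FALSE)
  out <- file.path(dest, renderName("target_file_list", runDate,
                                    fileType = fileType))
  stopIfExists(out)
  con <- file(out, open = "wb")
  on.exit(close(con))
  if (nrow(entries))
    writeLines(paste(entries$path, entries$name, sep = "\t"), con,
               useBytes = TRUE)
  out
}

#' Flatten all target files in a tree into one folder
#'
#' Copies every file matching \code{fileType} anywhere under \code{root}
#' (recursively) into a newly created folder
#' \code{YYYYMMDD_recursive_copy_TYP} directly under \code{root}. Sources
#' are untouched; the output folder itself is excluded from the scan, so
#' re-running on another date never re-copies its own output. Two source
#' files sharing a base name are both kept: the later one (in scan order)
#' is renamed with a deterministic \code{_1}, \code{_2}, ... suffix
#' before the extension, with a warning.
#'
#' @param root directory tree to scan; also the parent of the output.
#' @param fileType \code{"JPG"}, \code{"AB1"} or \code{"FAS"}.
#' @param runDate run date, injectable for reproducibility.
#' @return path of the created folder.
#' @export
recursiveCopy <- function(root, fileType, runDate = Sys.Date()) {
  if (!dir.exists(root))
    stop("input path '", root, "' does not exist", call. = FALSE)
  outDir <- file.path(normalizePath(root, winslash = "/"),
                      renderName("recursive_copy", runDate,
                                 fileType = fileType))
  stopIfExists(outDir)
  entries <- scanTargets(root, fileType, recursive = TRUE,
                         exclude = outDir)
  dir.create(outDir)
  used <- character()
  for (i in seq_len(nrow(entries))) {
    nm <- entries$name[i]
    if (nm %in% used) {
      base <- tools::file_path_sans_ext(nm)
      ext <- tools::file_ext(nm)
      k <- 1L
      repeat {
        cand <- paste0(base, "_", k, if (nzchar(ext)) paste0(".", ext))
        if (!cand %in% used) break
        k <- k + 1L
      }
      warning("duplicate base name '", nm, "' copied as '", cand, "'",
              call. = FALSE)
      nm <- cand
    }
    ok <- file.copy(entries$path[i], file.path(outDir, nm))
    if (!ok)
      stop("failed to copy '", entries$path[i], "'", call. = FALSE)
    used <- c(used, nm)
  }
  outDir
}

## packing --------------------------------------------------------------------

#' Partition files into size-capped upload packs
#'
#' First-fit sequential packing: files are taken in the order given,
#' appended to the current pack while the pack's byte total stays within
#' \code{maxBytes}, and a new pack is opened otherwise. The result is a
#' true partition — every input file lands in exactly one pack, and
#' concatenating the packs reproduces the input order. This is not an
#' optimal bin packing; it is deterministic and order-stable, which
#' matters more for reproducible uploads.
#'
#' @param entries a data.frame as returned by \code{\link{scanTargets}}.
#' @param maxBytes positive cap on the byte sum of each pack. A single
#'   file larger than the cap is an error naming the offending file.
#' @return a \code{\linkS4class{PackPlan}}.
#' @examples
#' e <- data.frame(path = c("/a", "/b", "/c"), name = c("a", "b", "c"),
#'                 size = c(40, 40, 40))
#' planPacks(e, 100)  # packs of 2 + 1 files
#' @export
planPacks <- function(entries, maxBytes) {
  if (!is.numeric(maxBytes) || length(maxBytes) != 1L || is.na(maxBytes) ||
      maxBytes <= 0)
    stop("'maxBytes' must be a single positive number", call. = FALSE)
  oversize <- entries$size > maxBytes
  if (any(oversize))
    stop("file '", entries$name[which(oversize)[1]], "' (",
         format(entries$size[which(oversize)[1]], scientific = FALSE),
         " bytes) exceeds the pack size cap of ",
         format(maxBytes, scientific = FALSE), " bytes", call. = FALSE)

  packs <- list()
  cur <- integer()
  curSum <- 0
  for (i in seq_len(nrow(entries))) {
    sz <- entries$size[i]
    if (length(cur) && curSum + sz > maxBytes) {
      packs[[length(packs) + 1L]] <- entries[cur, , drop = FALSE]
      cur <- integer(); curSum <- 0
    }
    cur <- c(cur, i)
    curSum <- curSum + sz
  }
  if (length(cur))
    packs[[length(packs) + 1L]] <- entries[cur, , drop = FALSE]
  new("PackPlan", maxBytes = as.numeric(maxBytes), packs = packs)
}

#' Materialize a pack plan as indexed folders
#'
#' Creates one folder per pack, named
#' \code{YYYYMMDD_max_packs_TYP_#} with \code{#} the 1-based pack index,
#' inside \code{target}, and copies each pack's files into its folder.
#'
#' @param plan a \code{\linkS4class{PackPlan}} from \code{\link{planPacks}}.
#' @param target directory in which pack folders are created.
#' @param fileType target type token naming the folders.
#' @param runDate run date, injectable for reproducibility.
#' @return character vector of created folder paths, in index order
#'   (empty if the plan has no packs).
#' @export
executePacks <- function(plan, target, fileType, runDate = Sys.Date()) {
  stopifnot(is(plan, "PackPlan"))
  if (!dir.exists(target))
    stop("output directory '", target, "' does not exist", call. = FALSE)
  n <- length(plan@packs)
  dirs <- character(n)
  for (i in seq_len(n))
    dirs[i] <- file.path(target, renderName("max_packs", runDate,
                                            fileType = fileType, index = i))
  for (d in dirs) stopIfExists(d)
  for (i in seq_len(n)) {
    dir.create(dirs[i])
    pk <- plan@packs[[i]]
    for (j in seq_len(nrow(pk))) {
      ok <- file.copy(pk$path[j], file.path(dirs[i], pk$name[j]))
      if (!ok)
        stop("failed to copy '", pk$path[j], "' into '", dirs[i], "'",
             call. = FALSE)
    }
  }
  dirs
}

## copy by list ---------------------------------------------------------------

#' Parse a plain-text file-name list
#'
#' Reads one file name per line; a single trailing blank line is the
#' documented convention but its absence is tolerated, as are CRLF line
#' endings and surrounding whitespace. Blank interior lines are dropped.
#' Duplicate names are preserved in the returned vector (callers
#' de-duplicate for copying, with a warning).
#'
#' @param listFile path to the text file.
#' @return character vector of names, in file order; errors if the file
#'   contains no non-blank line.
#' @export
parseFileList <- function(listFile) {
  if (!is.character(listFile) || length(listFile) != 1L ||
      !file.exists(listFile))
    stop("list file '", paste(listFile, collapse = ","),
         "' does not exist", call. = FALSE)
  lines <- readLines(listFile, warn = FALSE)
  lines <- trimws(gsub("\r", "", lines, fixed = TRUE))
  lines <- lines[nzchar(lines)]
  if (!length(lines))
    stop("list file '", listFile, "' contains no file names", call. = FALSE)
  lines
}

#' Copy files named in a list into a date-stamped folder
#'
#' Copies exactly those files directly inside \code{source} (never in
#' subdirectories) whose base name appears in \code{names} into a new
#' folder \code{YYYYMMDD_copy_by_list} under \code{source}. Requested
#' names with no match are reported, not fatal, so a quality-filtered
#' list can be reconciled against what is actually on disk.
#'
#' @param source directory holding the candidate files.
#' @param names character vector of file names (e.g. from
#'   \code{\link{parseFileList}}). Duplicates are copied once, with a
#'   warning.
#' @param runDate run date, injectable for reproducibility.
#' @return a list with \code{folder} (created folder path) and
#'   \code{missing} (sorted unique requested names not found).
#' @export
copyByList <- function(source, names, runDate = Sys.Date()) {
  if (!dir.exists(source))
    stop("input path '", source, "' does not exist", call. = FALSE)
  if (anyDuplicated(names)) {
    warning("duplicate names in list; each file is copied once",
            call. = FALSE)
    names <- unique(names)
  }
  source <- normalizePath(source, winslash = "/")
  outDir <- file.path(source, renderName("copy_by_list", runDate))
  stopIfExists(outDir)
  present <- list.files(source, no.. = TRUE)
  present <- present[!dir.exists(file.path(source, present))]
  hit <- names[names %in% present]
  dir.create(outDir)
  for (nm in hit) {
    ok <- file.copy(file.path(source, nm), file.path(outDir, nm))
    if (!ok) stop("failed to copy '", nm, "'", call. = FALSE)
  }
  list(folder = outDir, missing = sort(setdiff(names, hit)))
}
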