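#' @title Output naming for upload-staging operations
#'
#' @description Every operation in the package writes its output under a
#' deterministic, date-stamped name of the form
#' \code{YYYYMMDD_<operation>[_TYP][_#][.ext]}. The date is injectable so
#' that runs are reproducible; the operation token is one of the nine
#' fixed operation names; \code{TYP} is the target file type
#' (\code{"JPG"}, \code{"AB1"} or \code{"FAS"}) for the file-level
#' operations that need one; \code{#} is the 1-based pack index used only
#' by \code{max_packs}.
#'
#' @name naming
NULL

## fixed vocabulary -----------------------------------------------------------

.OP_NAMES <- c(
  "target_file_list", "recursive_copy", "max_packs", "copy_by_list",
  "degap", "rank_seq", "head_derep", "seq_derep", "multi_to_single_fasta"
)

.OPS_NEEDING_TYPE <- c("target_file_list", "recursive_copy", "max_packs")
.SEQ_OPS <- c("degap", "rank_seq", "head_derep", "seq_derep",
              "multi_to_single_fasta")

.FILE_TYPES <- c("JPG", "AB1", "FAS")

## extensions matched by each target file type, lower case
.TYPE_EXTENSIONS <- list(
  JPG = "jpg",
  AB1 = "ab1",
  FAS = c("fasta", "fas")
)

#' Validate and normalize a target file type token
#'
#' @param fileType character scalar; one of \code{"JPG"}, \code{"AB1"},
#'   \code{"FAS"} (case-insensitive on input).
#' @return the canonical upper-case token.
#' @keywords internal
normalizeFileType <- function(fileType) {
  if (!is.character(fileType) || length(fileType) != 1L || is.na(fileType))
    stop("'fileType' must be a single string (JPG, AB1 or FAS)", call. = FALSE)
  ft <- toupper(trimws(fileType))
  if (ft == "FASTA") ft <- "FAS"
  if (!ft %in% .FILE_TYPES)
    stop("unknown file type '", fileType, "'; expected JPG, AB1 or FAS",
         call. = FALSE)
  ft
}

#' Render a run date as the 8-digit YYYYMMDD stamp
#'
#' @param runDate a \code{Date}, or a string already in \code{YYYYMMDD} or
#'   \code{YYYY-MM-DD} form. Defaults to the current local date.
#' @return an 8-character string, zero padded, year-month-day order.
#' @keywords internal
renderDate <- function(runDate = Sys.Date()) {
  if (inherits(runDate, "Date")) {
    if (length(runDate) != 1L || is.na(runDate))
      stop("'runDate' must be a single non-missing date", call. = FALSE)
    return(format(runDate, "%Y%m%d"))
  }
  if (is.character(runDate) && length(runDate) == 1L && !is.na(runDate)) {
    s <- trimws(runDate)
    if (grepl("^\\d{8}$", s)) {
      ## validate round-trip so 20201399 is rejected
      d <- as.Date(s, format = "%Y%m%d")
      if (is.na(d) || format(d, "%Y%m%d") != s)
        stop("'", runDate, "' is not a valid YYYYMMDD date", call. = FALSE)
      return(s)
    }
    d <- tryCatch(as.Date(s), error = function(e) as.Date(NA))
    if (!is.na(d)) return(format(d, "%Y%m%d"))
  }
  stop("'runDate' must be a Date or a YYYYMMDD / YYYY-MM-DD string",
       call. = FALSE)
}

#' Render the output name for an operation
#'
#' Produces the exact file or folder name an operation emits:
#' \itemize{
#'   \item \code{target_file_list}: \code{"YYYYMMDD_target_file_list_TYP.txt"}
#'   \item \code{recursive_copy}: \code{"YYYYMMDD_recursive_copy_TYP"} (folder)
#'   \item \code{max_packs}: \code{"YYYYMMDD_max_packs_TYP_#"} (folder)
#'   \item \code{copy_by_list}: \code{"YYYYMMDD_copy_by_list"} (folder)
#'   \item sequence operations (\code{degap}, \code{rank_seq},
#'     \code{head_derep}, \code{seq_derep}, \code{multi_to_single_fasta}):
#'     \code{"YYYYMMDD_<op>.fas"}
#' }
#'
#' \code{renderName} is pure: identical arguments always give the identical
#' string, and the first eight characters always parse back to the run date.
#'
#' @param opName one of the nine operation tokens.
#' @param runDate run date (see \code{\link{renderDate}}); defaults to today.
#' @param fileType target file type; required for \code{target_file_list},
#'   \code{recursive_copy} and \code{max_packs}, forbidden otherwise.
#' @param index 1-based pack index; required for \code{max_packs},
#'   forbidden otherwise.
#' @return the rendered name, a character scalar.
#' @examples
#' renderName("degap", runDate = as.Date("2020-04-23"))
#' renderName("target_file_list", "2020-04-23", fileType = "JPG")
#' renderName("max_packs", "20200423", fileType = "AB1", index = 1)
#' @export
renderName <- function(opName, runDate = Sys.Date(), fileType = NULL,
                       index = NULL) {
  if (!is.character(opName) || length(opName) != 1L ||
      !opName %in% .OP_NAMES)
    stop("unknown operation '", paste(opName, collapse = ","),
         "'; expected one of: ", paste(.OP_NAMES, collapse = ", "),
         call. = FALSE)

  stamp <- renderDate(runDate)

  needsType <- opName %in% .OPS_NEEDING_TYPE
  if (needsType && is.null(fileType))
    stop("operation '", opName, "' requires a file type (JPG, AB1 or FAS)",
         call. = FALSE)
  if (!needsType && !is.null(fileType))
    stop("operation '", opName, "' does not take a file type", call. = FALSE)

  if (opName == "max_packs") {
    if (is.null(index))
      stop("operation 'max_packs' requires a folder index", call. = FALSE)
    if (!is.numeric(index) || length(index) != 1L || is.na(index) ||
        index < 1 || index != as.integer(index))
      stop("'index' must be a single integer >= 1", call. = FALSE)
  } else if (!is.null(index)) {
    stop("operation '", opName, "' does not take an index", call. = FALSE)
  }

  parts <- c(stamp, opName)
  if (needsType) parts <- c(parts, normalizeFileType(fileType))
  if (opName == "max_packs") parts <- c(parts, format(as.integer(index)))
  name <- paste(parts, collapse = "_")

  if (opName == "target_file_list") name <- paste0(name, ".txt")
  if (opName %in% .SEQ_OPS) name <- paste0(name, ".fas")
  name
}

#' Refuse to overwrite an existing output path
#'
#' Data-safety default: an operation whose rendered output name already
#' exists at its destination stops rather than overwriting.
#' @keywords internal
stopIfExists <- function(path) {
  if (file.exists(path))
    stop("output '", path, "' already exists; refusing to overwrite",
         call. = FALSE)
  invisible(path)
}
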