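#' Read a FASTA file
#'
#' Reads nucleotide or amino-acid FASTA. Record ids are the first
#' whitespace-delimited token of each header; sequences are uppercased.
#' Aligned protein input (with \code{-} gap characters) is accepted.
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns \code{id} and \code{sequence}, in file
#'   order.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">a", "acgt", ">b some description", "TTGA"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  nonempty <- which(nzchar(trimws(lines)))
  if (length(nonempty) > 0L && !startsWith(trimws(lines[nonempty[1L]]), ">")) {
    stop("malformed FASTA in ", path, ": sequence data before first header at line ",
         nonempty[1L])
  }
  set <- Biostrings::readBStringSet(path)
  ids <- vapply(strsplit(names(set), "[ \t]+"), `[`, character(1), 1L)
  data.frame(
    id = ids,
    sequence = toupper(as.character(set)),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Write records to a FASTA file
#'
#' @param records A data.frame with columns \code{id} and \code{sequence}
#'   (as returned by \code{\link{read_fasta}}), or a named character vector.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_fasta <- function(records, path) {
  if (is.character(records)) {
    records <- data.frame(id = names(records), sequence = unname(records),
                          stringsAsFactors = FALSE)
  }
  stopifnot(all(c("id", "sequence") %in% names(records)))
  if (anyDuplicated(records$id)) stop("duplicate sequence ids in FASTA output")
  set <- Biostrings::BStringSet(setNames(records$sequence, records$id))
  Biostrings::writeXStringSet(set, filepath = path)
  invisible(path)
}
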