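# Readers and writers for peptide record tables.

#' Read raw peptide entries from a FASTA file
#'
#' The sequence is taken from the record body; everything after the first
#' whitespace in the header line becomes the free-text annotation.
#'
#' @param path FASTA file path.
#' @param source Source tag attached to every entry (default "other").
#' @return data.frame with columns \code{sequence}, \code{annotation_text},
#'   \code{activity_value}, \code{activity_unit}, \code{source}.
#' @export
read_peptide_fasta <- function(path, source = "other") {
  fa <- seqinr::read.fasta(path, seqtype = "AA", as.string = TRUE,
                           forceDNAtolower = FALSE)
  headers <- vapply(fa, function(s) attr(s, "Annot"), character(1))
  headers <- sub("^>", "", headers)
  annot <- sub("^\\S+\\s*", "", headers)
  data.frame(sequence = toupper(unlist(fa)),
             annotation_text = annot,
             activity_value = NA_real_,
             activity_unit = NA_character_,
             source = source,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Read raw peptide entries from a CSV file
#'
#' Expects columns \code{sequence} and \code{annotation} (renamed to
#' \code{annotation_text}); \code{activity_value}, \code{activity_unit} and
#' \code{source} are optional.
#'
#' @param path CSV file path.
#' @return data.frame in the raw-entry layout accepted by [curate_entries()].
#' @export
read_peptide_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"sequence" %in% names(tab)) stop("CSV must have a 'sequence' column")
  if ("annotation" %in% names(tab) && !"annotation_text" %in% names(tab)) {
    names(tab)[names(tab) == "annotation"] <- "annotation_text"
  }
  if (!"annotation_text" %in% names(tab)) stop("CSV must have an 'annotation' column")
  for (col in c("activity_value", "activity_unit", "source")) {
    if (!col %in% names(tab)) {
      tab[[col]] <- if (col == "activity_value") NA_real_ else NA_character_
    }
  }
  tab$source[is.na(tab$source)] <- "other"
  tab[, c("sequence", "annotation_text", "activity_value", "activity_unit", "source")]
}

#' Write a curated dataset to CSV
#'
#' @param dataset An \code{acp_dataset}.
#' @param path Output CSV path.
#' @export
write_curated_csv <- function(dataset, path) {
  stopifnot(inherits(dataset, "acp_dataset"))
  utils::write.csv(dataset$records, path, row.names = FALSE)
  invisible(path)
}

#' Write a rejection log to CSV
#'
#' @param rejections data.frame with columns \code{sequence}, \code{reason}.
#' @param path Output CSV path.
#' @export
write_rejections_csv <- function(rejections, path) {
  utils::write.csv(rejections, path, row.names = FALSE)
  invisible(path)
}

#' Write the worked-example raw-entry table in canonical form
#'
#' Used to (re)generate \code{extdata/worked_example.csv}; the output is
#' byte-identical across calls.
#'
#' @param path Output CSV path.
#' @export
write_worked_example <- function(path) {
  utils::write.csv(make_worked_example(), path, row.names = FALSE, na = "")
  invisible(path)
}
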