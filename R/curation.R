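#' Validate and upper-case a raw peptide sequence
#'
#' Case-folds a raw sequence to upper case and checks that every character is
#' one of the 20 standard amino acids. Non-standard letters (B, J, O, U, X,
#' Z), gap characters, and internal whitespace are all rejected.
#'
#' @param raw Non-empty character scalar.
#' @return The validated upper-case sequence, or \code{NA_character_} with
#'   attribute \code{reason} naming the first offending character.
#' @examples
#' clean_sequence("klwKLW")   # "KLWKLW"
#' clean_sequence("ACXK")     # NA, rejected on 'X'
#' @export
clean_sequence <- function(raw) {
  stopifnot(is.character(raw), length(raw) == 1L)
  if (is.na(raw) || nchar(raw) == 0L) {
    return(structure(NA_character_, reason = "empty sequence"))
  }
  up <- toupper(raw)
  chars <- strsplit(up, "", fixed = TRUE)[[1L]]
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad)) {
    return(structure(NA_character_,
                     reason = sprintf("invalid character '%s'", chars[bad[1L]])))
  }
  up
}

#' Length-filter validated sequences
#'
#' Retains sequences whose length lies within the inclusive bounds and logs
#' each removal with its reason.
#'
#' @param sequences Character vector of alphabet-validated sequences.
#' @param min_len,max_len Inclusive length bounds (defaults 10 and 100).
#' @return List with \code{kept} (character vector) and \code{log}
#'   (data.frame with columns \code{sequence}, \code{reason}).
#' @export
filter_by_length <- function(sequences, min_len = 10L, max_len = 100L) {
  n <- nchar(sequences)
  too_short <- n < min_len
  too_long <- n > max_len
  log <- data.frame(
    sequence = c(sequences[too_short], sequences[too_long]),
    reason = c(rep_len("too short", sum(too_short)),
               rep_len("too long", sum(too_long))),
    stringsAsFactors = FALSE
  )
  list(kept = sequences[!too_short & !too_long], log = log)
}

#' Assign a tissue label from free-text annotation
#'
#' Performs case-insensitive substring matching of each tissue's keyword list
#' against the concatenated annotation text (cancer type, disease, cell line).
#' Entries matching two or more tissues are ambiguous and excluded downstream;
#' entries matching none are unmatched.
#'
#' @param annotation_text Character scalar of free-text annotation.
#' @param keyword_map Named list of keyword vectors per tissue, as returned by
#'   [load_keyword_map()].
#' @return One of the nine tissue names, or \code{"ambiguous"}, or
#'   \code{"unmatched"}.
#' @export
assign_tissue <- function(annotation_text, keyword_map = load_keyword_map()) {
  txt <- tolower(paste(annotation_text, collapse = " "))
  hit <- vapply(keyword_map, function(keys) {
    any(vapply(keys, function(k) grepl(k, txt, fixed = TRUE), logical(1)))
  }, logical(1))
  n_hit <- sum(hit)
  if (n_hit == 0L) return("unmatched")
  if (n_hit > 1L) return("ambiguous")
  names(keyword_map)[hit]
}

#' Standardize an activity value to micromolar
#'
#' Converts molar-concentration IC50 annotations to micromolar. Only molar
#' units are convertible; mass-concentration units (e.g. ug/mL) would require
#' a molecular weight and are reported as not convertible.
#'
#' @param value Positive numeric activity value.
#' @param unit Unit string; recognised molar units are uM (also the micro sign
#'   variant), nM, mM and M, case-insensitively.
#' @return The value in uM, or \code{NA_real_} with attribute \code{reason}.
#' @examples
#' standardize_activity(64, "uM")   # 64
#' standardize_activity(500, "nM")  # 0.5
#' @export
standardize_activity <- function(value, unit) {
  if (!is.numeric(value) || length(value) != 1L || is.na(value) || value <= 0) {
    return(structure(NA_real_, reason = "non-positive or missing value"))
  }
  u <- tolower(trimws(unit))
  u <- gsub("µ|μ", "u", u)  # micro sign / mu -> 'u'
  factor <- switch(u,
    "um" = 1,
    "nm" = 1e-3,
    "mm" = 1e3,
    "m"  = 1e6,
    NA_real_
  )
  if (is.na(factor)) {
    return(structure(NA_real_, reason = sprintf("unit '%s' not convertible", unit)))
  }
  value * factor
}

#' Construct a curated peptide dataset
#'
#' Wraps a record table in the curated-dataset container and checks the
#' record invariants (alphabet, length bounds, unique sequence-tissue pairs).
#'
#' @param records data.frame with columns \code{sequence}, \code{tissue},
#'   \code{ic50_uM}, \code{sources}.
#' @return An object of class \code{acp_dataset}: list with \code{records},
#'   \code{n_entries}, \code{n_unique_sequences}.
#' @export
curated_dataset <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("sequence", "tissue") %in% names(records)))
  if (!"ic50_uM" %in% names(records)) records$ic50_uM <- NA_real_
  if (!"sources" %in% names(records)) records$sources <- "other"
  if (nrow(records)) {
    lens <- nchar(records$sequence)
    ok_alpha <- vapply(strsplit(records$sequence, "", fixed = TRUE),
                       function(ch) all(ch %in% AA_ALPHABET), logical(1))
    if (!all(ok_alpha)) stop("record sequences contain non-standard characters")
    if (any(lens < 10L | lens > 100L)) stop("record lengths must be in [10, 100]")
    if (anyDuplicated(paste(records$sequence, records$tissue))) {
      stop("(sequence, tissue) pairs must be unique; run merge_and_deduplicate() first")
    }
    if (!all(records$tissue %in% TISSUES)) stop("unknown tissue label")
  }
  rownames(records) <- NULL
  structure(
    list(records = records,
         n_entries = nrow(records),
         n_unique_sequences = length(unique(records$sequence))),
    class = "acp_dataset"
  )
}

#' @export
print.acp_dataset <- function(x, ...) {
  cat("Curated peptide dataset:", x$n_entries, "entries,",
      x$n_unique_sequences, "unique sequences\n")
  tab <- table(factor(x$records$tissue, levels = TISSUES))
  print(tab)
  invisible(x)
}

#' Merge duplicate sequence-tissue entries
#'
#' Collapses a validated record table to exactly one record per
#' (sequence, tissue) pair. Sources are unioned. IC50 values follow a
#' completeness rule: a non-missing value beats a missing one; when two
#' non-missing values conflict, the minimum is kept and the conflict logged.
#' The same sequence may legitimately appear under several tissues — each
#' entry represents a unique sequence-tissue pair.
#'
#' @param entries data.frame with columns \code{sequence}, \code{tissue} and
#'   optionally \code{ic50_uM}, \code{sources} (comma-separated string or
#'   single source name).
#' @return An \code{acp_dataset}; attribute \code{conflicts} holds a
#'   data.frame of IC50 conflicts resolved by the minimum rule.
#' @export
merge_and_deduplicate <- function(entries) {
  stopifnot(is.data.frame(entries),
            all(c("sequence", "tissue") %in% names(entries)))
  if (!"ic50_uM" %in% names(entries)) entries$ic50_uM <- NA_real_
  if (!"sources" %in% names(entries)) entries$sources <- "other"
  key <- paste(entries$sequence, entries$tissue, sep = "\r")
  idx <- split(seq_len(nrow(entries)), key)
  # keep first-appearance order of pairs
  first <- vapply(idx, min, integer(1))
  idx <- idx[order(first)]
  conflicts <- list()
  rows <- lapply(idx, function(i) {
    ic <- entries$ic50_uM[i]
    ic <- ic[!is.na(ic)]
    ic50 <- if (length(ic) == 0L) NA_real_ else min(ic)
    if (length(unique(ic)) > 1L) {
      conflicts[[length(conflicts) + 1L]] <<- data.frame(
        sequence = entries$sequence[i[1L]], tissue = entries$tissue[i[1L]],
        kept_uM = ic50, stringsAsFactors = FALSE)
    }
    src <- sort(unique(unlist(strsplit(entries$sources[i], ",", fixed = TRUE))))
    data.frame(sequence = entries$sequence[i[1L]],
               tissue = entries$tissue[i[1L]],
               ic50_uM = ic50,
               sources = paste(src, collapse = ","),
               stringsAsFactors = FALSE)
  })
  records <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(records)) {
    records <- data.frame(sequence = character(), tissue = character(),
                          ic50_uM = numeric(), sources = character(),
                          stringsAsFactors = FALSE)
  }
  out <- curated_dataset(records)
  attr(out, "conflicts") <- if (length(conflicts)) do.call(rbind, conflicts) else NULL
  out
}

#' Run the full curation pipeline on raw entries
#'
#' Applies, in order: sequence validation and case folding, length filtering,
#' keyword-based tissue assignment (dropping ambiguous and unmatched entries),
#' IC50 standardisation to uM, and duplicate merging.
#'
#' @param raw data.frame with columns \code{sequence}, \code{annotation_text},
#'   and optionally \code{activity_value}, \code{activity_unit}, \code{source}.
#' @param keyword_map Tissue keyword dictionary; defaults to the shipped one.
#' @param min_len,max_len Inclusive length bounds.
#' @return List with \code{dataset} (an \code{acp_dataset}) and
#'   \code{rejections} (data.frame \code{sequence}, \code{reason}).
#' @export
curate_entries <- function(raw, keyword_map = load_keyword_map(),
                           min_len = 10L, max_len = 100L) {
  stopifnot(is.data.frame(raw),
            all(c("sequence", "annotation_text") %in% names(raw)))
  if (!"activity_value" %in% names(raw)) raw$activity_value <- NA_real_
  if (!"activity_unit" %in% names(raw)) raw$activity_unit <- NA_character_
  if (!"source" %in% names(raw)) raw$source <- "other"

  rejections <- data.frame(sequence = character(), reason = character(),
                           stringsAsFactors = FALSE)
  reject <- function(seqs, reasons) {
    rejections <<- rbind(rejections,
                         data.frame(sequence = seqs, reason = reasons,
                                    stringsAsFactors = FALSE))
  }

  cleaned <- lapply(raw$sequence, clean_sequence)
  ok <- !vapply(cleaned, is.na, logical(1))
  if (any(!ok)) {
    reject(raw$sequence[!ok],
           vapply(cleaned[!ok], function(x) attr(x, "reason"), character(1)))
  }
  raw <- raw[ok, , drop = FALSE]
  raw$sequence <- unlist(cleaned[ok])

  n <- nchar(raw$sequence)
  short <- n < min_len; long <- n > max_len
  if (any(short)) reject(raw$sequence[short], rep("too short", sum(short)))
  if (any(long)) reject(raw$sequence[long], rep("too long", sum(long)))
  raw <- raw[!short & !long, , drop = FALSE]

  tissue <- vapply(raw$annotation_text, assign_tissue, character(1),
                   keyword_map = keyword_map, USE.NAMES = FALSE)
  drop <- tissue %in% c("ambiguous", "unmatched")
  if (any(drop)) reject(raw$sequence[drop], paste("annotation", tissue[drop]))
  raw <- raw[!drop, , drop = FALSE]
  tissue <- tissue[!drop]

  ic50 <- rep(NA_real_, nrow(raw))
  has_act <- !is.na(raw$activity_value)
  if (any(has_act)) {
    ic50[has_act] <- mapply(function(v, u) as.numeric(standardize_activity(v, u)),
                            raw$activity_value[has_act], raw$activity_unit[has_act])
  }

  entries <- data.frame(sequence = raw$sequence, tissue = tissue,
                        ic50_uM = ic50, sources = raw$source,
                        stringsAsFactors = FALSE)
  list(dataset = merge_and_deduplicate(entries), rejections = rejections)
}

#' Build a one-versus-rest tissue task
#'
#' Labels every record of a curated dataset against one target tissue:
#' records annotated to the target tissue are positives (1), records from the
#' remaining tissues form the reference class (0). Record order is preserved.
#'
#' @param dataset An \code{acp_dataset}.
#' @param tissue One of the nine tissue names.
#' @return An object of class \code{acp_ovr_task}: list with \code{tissue},
#'   \code{records} and binary \code{labels}.
#' @export
build_ovr_task <- function(dataset, tissue) {
  stopifnot(inherits(dataset, "acp_dataset"), tissue %in% TISSUES)
  labels <- as.integer(dataset$records$tissue == tissue)
  if (sum(labels) == 0L) stop("no positive records for tissue ", tissue)
  if (sum(labels) == nrow(dataset$records)) {
    stop("no negative records: dataset contains only tissue ", tissue)
  }
  structure(list(tissue = tissue, records = dataset$records, labels = labels),
            class = "acp_ovr_task")
}

#' @export
print.acp_ovr_task <- function(x, ...) {
  cat(sprintf("One-vs-rest task '%s': %d positives / %d negatives\n",
              x$tissue, sum(x$labels), sum(1 - x$labels)))
  invisible(x)
}
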