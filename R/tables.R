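#' @keywords internal
"_PACKAGE"

#' The 20 standard amino acids
#'
#' One-letter codes in fixed alphabetical order. All descriptor blocks index
#' residues in this order.
#'
#' @export
AA_ALPHABET <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' The nine tissue categories
#'
#' Cancer-related tissue classes used for one-versus-rest task construction.
#'
#' @export
TISSUES <- c("Blood", "Brain", "Breast", "Cervix", "Colon",
             "Liver", "Lung", "Prostate", "Skin")

#' Amino-acid property scales for sequence-order descriptors
#'
#' Loads the hydrophobicity, hydrophilicity, and side-chain mass scales used
#' by the pseudo-amino-acid composition block, together with standardized
#' versions of each scale (zero mean, unit standard deviation across the 20
#' amino acids). The shipped values are Chou's original scales.
#'
#' @param path Path to a CSV with columns
#'   \code{amino_acid, hydrophobicity, hydrophilicity, mass}. Defaults to the
#'   table shipped with the package.
#' @return A list with elements \code{raw} and \code{normalized}, each a
#'   3-column matrix with one row per amino acid (rownames = one-letter code),
#'   columns \code{hydrophobicity}, \code{hydrophilicity}, \code{mass}.
#' @export
load_property_scales <- function(path = system.file("extdata", "property_scales.csv",
                                                    package = "tissueACP")) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot(all(c("amino_acid", "hydrophobicity", "hydrophilicity", "mass") %in% names(tab)))
  tab <- tab[match(AA_ALPHABET, tab$amino_acid), ]
  if (anyNA(tab$amino_acid)) {
    stop("property scale table must cover all 20 standard amino acids")
  }
  raw <- as.matrix(tab[, c("hydrophobicity", "hydrophilicity", "mass")])
  rownames(raw) <- tab$amino_acid
  # population standard deviation over the 20 values, per the standard
  # PseAAC normalization
  normalized <- apply(raw, 2, function(v) (v - mean(v)) / stats::sd(v))
  rownames(normalized) <- tab$amino_acid
  list(raw = raw, normalized = normalized)
}

#' Residue group table for physicochemical composition descriptors
#'
#' Loads the 20 named residue groups and the integer side-chain charge map
#' that drive the PCP descriptor block. The shipped defaults follow standard
#' biochemical classifications; any YAML file with the same structure can be
#' substituted.
#'
#' @param path Path to a YAML file with top-level keys \code{groups} (mapping
#'   group name to a list of one-letter codes) and \code{charge} (mapping
#'   amino acid to integer charge). Defaults to the shipped table.
#' @return A list with \code{groups} (named list of character vectors, in the
#'   fixed PCP group order) and \code{charge} (named numeric vector over all
#'   20 amino acids, zero where unlisted).
#' @export
load_group_table <- function(path = system.file("extdata", "residue_groups.yaml",
                                                package = "tissueACP")) {
  cfg <- yaml::read_yaml(path)
  expected <- c("Positive", "Negative", "Polar", "NonPolar", "Hydrophobic",
                "Hydrophilic", "Aromatic", "Aliphatic", "Sulfur", "Tiny",
                "Small", "Large", "Charged", "Neutral", "Flexible", "Rigid",
                "HelixFormer", "SheetFormer", "TurnFormer", "Intermediate")
  groups <- cfg$groups
  missing <- setdiff(expected, names(groups))
  if (length(missing)) {
    stop("group table is missing groups: ", paste(missing, collapse = ", "))
  }
  groups <- groups[expected]
  for (g in expected) {
    members <- unlist(groups[[g]])
    # YAML 1.1 reads bare Y/N as logicals; map them back to residue codes
    if (is.logical(members) || any(members %in% c("TRUE", "FALSE"))) {
      members <- ifelse(members == TRUE | members == "TRUE", "Y",
                        ifelse(members == FALSE | members == "FALSE", "N", members))
    }
    if (length(members) == 0 || !all(members %in% AA_ALPHABET)) {
      stop("group '", g, "' must be a non-empty subset of the 20-letter alphabet")
    }
    groups[[g]] <- members
  }
  charge <- stats::setNames(numeric(20), AA_ALPHABET)
  if (!is.null(cfg$charge)) {
    ch <- unlist(cfg$charge)
    if (!all(names(ch) %in% AA_ALPHABET)) stop("charge map keys must be amino acids")
    charge[names(ch)] <- ch
  }
  list(groups = groups, charge = charge)
}

#' Default tissue keyword dictionary
#'
#' Loads the keyword lists used for keyword-based tissue annotation. Matching
#' is case-insensitive substring matching over the concatenated annotation
#' text; see [assign_tissue()].
#'
#' @param path Path to a YAML file mapping each of the nine tissue names to a
#'   list of keywords. Defaults to the shipped dictionary.
#' @return Named list of lower-case character vectors, one per tissue.
#' @export
load_keyword_map <- function(path = system.file("extdata", "tissue_keywords.yaml",
                                                package = "tissueACP")) {
  km <- yaml::read_yaml(path)
  missing <- setdiff(TISSUES, names(km))
  if (length(missing)) {
    stop("keyword map must cover all nine tissues; missing: ",
         paste(missing, collapse = ", "))
  }
  lapply(km[TISSUES], function(x) tolower(unlist(x)))
}
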