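# Descriptor encoders: AAC (20) + DPC (400) + PCP (30) + PseAAC (23) = 473.

.pcp_extra_names <- c("Hydrophobic_Ratio", "Polar_Ratio", "Charged_Ratio",
                      "Net_Charge", "Avg_Hydrophobicity", "Aromatic_Ratio",
                      "Aliphatic_Ratio", "Helix_Ratio", "Sheet_Ratio",
                      "Turn_Ratio")

.seq_chars <- function(sequence) {
  stopifnot(is.character(sequence), length(sequence) == 1L, !is.na(sequence))
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  if (!length(chars)) stop("empty sequence")
  bad <- which(!(chars %in% AA_ALPHABET))
  if (length(bad)) {
    stop(sprintf("invalid character '%s' at position %d", chars[bad[1L]], bad[1L]))
  }
  chars
}

#' Feature schema for the 473-dimensional descriptor vector
#'
#' Fixed, ordered naming of all 473 features: the 20 amino-acid composition
#' features (\code{AAC_A} .. \code{AAC_Y}), the 400 dipeptide composition
#' features in row-major order (\code{DPC_AA}, \code{DPC_AC}, ...,
#' \code{DPC_YY}), the 30 physicochemical composition features
#' (\code{PCP_<Group>} for the 20 residue groups, then 10 ratio/statistic
#' descriptors), and the 23 pseudo-amino-acid composition features
#' (\code{PAAC_A} .. \code{PAAC_Y}, \code{PAAC_lam1..3}).
#'
#' @param group_table Residue group table; only the group names are used.
#' @return data.frame with columns \code{name} and \code{category}
#'   (\code{AAC}/\code{DPC}/\code{PCP}/\code{PAAC}), 473 rows.
#' @export
feature_schema <- function(group_table = load_group_table()) {
  aac <- paste0("AAC_", AA_ALPHABET)
  dpc <- paste0("DPC_", as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0))))
  pcp <- c(paste0("PCP_", names(group_table$groups)),
           paste0("PCP_", .pcp_extra_names))
  paac <- c(paste0("PAAC_", AA_ALPHABET), paste0("PAAC_lam", 1:3))
  data.frame(
    name = c(aac, dpc, pcp, paac),
    category = rep(c("AAC", "DPC", "PCP", "PAAC"), c(20L, 400L, 30L, 23L)),
    stringsAsFactors = FALSE
  )
}

#' Amino acid composition (20 features)
#'
#' Global frequency of each of the 20 standard amino acids:
#' \code{AAC_i = R_i / N} where \code{R_i} counts residues of type i and N is
#' the sequence length. The vector sums to 1.
#'
#' @param sequence Validated upper-case sequence, length >= 1.
#' @return Named numeric vector of 20 frequencies in fixed order A..Y.
#' @export
compute_aac <- function(sequence) {
  chars <- .seq_chars(sequence)
  counts <- table(factor(chars, levels = AA_ALPHABET))
  stats::setNames(as.numeric(counts) / length(chars), paste0("AAC_", AA_ALPHABET))
}

#' Dipeptide composition (400 features)
#'
#' Frequency of every adjacent (overlapping) residue pair:
#' \code{DPC_ij = N_ij / (N - 1)}. The 400 entries are ordered row-major
#' (AA, AC, ..., YY) and sum to 1 for any sequence of length >= 2.
#'
#' @param sequence Validated sequence, length >= 2.
#' @return Named numeric vector of 400 dipeptide frequencies.
#' @export
compute_dpc <- function(sequence) {
  chars <- .seq_chars(sequence)
  n <- length(chars)
  if (n < 2L) stop("dipeptide composition requires length >= 2")
  pairs <- paste0(chars[-n], chars[-1L])
  all_pairs <- as.vector(t(outer(AA_ALPHABET, AA_ALPHABET, paste0)))
  counts <- table(factor(pairs, levels = all_pairs))
  stats::setNames(as.numeric(counts) / (n - 1L), paste0("DPC_", all_pairs))
}

#' Physicochemical property composition (30 features)
#'
#' The first 20 entries are residue-group composition fractions
#' \code{PCP_g = P_g / N} over the 20 named groups of the shipped group
#' table. The remaining 10 descriptors are: hydrophobic, polar, charged,
#' aromatic, aliphatic, helix-forming, sheet-forming and turn-forming residue
#' ratios (re-using the corresponding group definitions), the net charge
#' (sum of integer side-chain charges, not length-normalised), and the mean
#' raw hydrophobicity over residues.
#'
#' @param sequence Validated sequence.
#' @param group_table Residue group table, see [load_group_table()].
#' @param scales Property scales, see [load_property_scales()].
#' @return Named numeric vector of 30 descriptors.
#' @export
compute_pcp <- function(sequence, group_table = load_group_table(),
                        scales = load_property_scales()) {
  chars <- .seq_chars(sequence)
  n <- length(chars)
  frac <- vapply(group_table$groups,
                 function(members) sum(chars %in% members) / n, numeric(1))
  names(frac) <- paste0("PCP_", names(group_table$groups))
  extras <- c(
    Hydrophobic_Ratio = unname(frac["PCP_Hydrophobic"]),
    Polar_Ratio = unname(frac["PCP_Polar"]),
    Charged_Ratio = unname(frac["PCP_Charged"]),
    Net_Charge = sum(group_table$charge[chars]),
    Avg_Hydrophobicity = mean(scales$raw[chars, "hydrophobicity"]),
    Aromatic_Ratio = unname(frac["PCP_Aromatic"]),
    Aliphatic_Ratio = unname(frac["PCP_Aliphatic"]),
    Helix_Ratio = unname(frac["PCP_HelixFormer"]),
    Sheet_Ratio = unname(frac["PCP_SheetFormer"]),
    Turn_Ratio = unname(frac["PCP_TurnFormer"])
  )
  names(extras) <- paste0("PCP_", .pcp_extra_names)
  c(frac, extras)
}

#' Pseudo-amino acid composition (23 features at lambda = 3)
#'
#' Chou's type-1 construction. Sequence-order correlation factors
#' \code{theta_k = mean over t of Theta(R_t, R_\{t+k\})} for lags k = 1..lambda,
#' where \code{Theta(a, b)} is the mean over the three standardized property
#' scales (hydrophobicity, hydrophilicity, side-chain mass) of
#' \code{(H(b) - H(a))^2}. Components are jointly normalized:
#' \code{x_u = f_u / (sum(f) + w * sum(theta))} for the 20 residue frequencies
#' and \code{x_\{20+k\} = w * theta_k / (same denominator)}, so the 23 values
#' sum to 1. A \code{mode = "raw"} variant skips the joint normalization and
#' returns plain frequencies alongside \code{w * theta_k}.
#'
#' @param sequence Validated sequence of length > lambda.
#' @param scales Property scales, see [load_property_scales()].
#' @param lambda Number of correlation lags (default 3).
#' @param w Sequence-order weight (default 0.05).
#' @param mode \code{"chou"} (default, jointly normalized) or \code{"raw"}.
#' @return Named numeric vector of \code{20 + lambda} features.
#' @export
compute_pseaac <- function(sequence, scales = load_property_scales(),
                           lambda = 3L, w = 0.05, mode = c("chou", "raw")) {
  mode <- match.arg(mode)
  chars <- .seq_chars(sequence)
  n <- length(chars)
  if (n <= lambda) stop("pseudo-AAC requires length > lambda")
  H <- scales$normalized[chars, , drop = FALSE]
  theta <- vapply(seq_len(lambda), function(k) {
    d <- H[seq_len(n - k) + k, , drop = FALSE] - H[seq_len(n - k), , drop = FALSE]
    mean(rowMeans(d^2))
  }, numeric(1))
  f <- as.numeric(table(factor(chars, levels = AA_ALPHABET))) / n
  denom <- if (mode == "chou") sum(f) + w * sum(theta) else 1
  out <- c(f / denom, w * theta / denom)
  names(out) <- c(paste0("PAAC_", AA_ALPHABET), paste0("PAAC_lam", seq_len(lambda)))
  out
}

#' Encode one peptide into the full 473-dimensional descriptor vector
#'
#' Concatenates the AAC, DPC, PCP and PseAAC blocks in schema order. The
#' encoding is deterministic: identical sequences give bitwise-identical
#' vectors.
#'
#' @param sequence Validated sequence, length 10..100.
#' @param group_table,scales Shipped descriptor tables by default.
#' @param lambda,w,paac_mode Passed to [compute_pseaac()].
#' @return Named numeric vector of length 473 aligned to [feature_schema()].
#' @export
encode_peptide <- function(sequence, group_table = load_group_table(),
                           scales = load_property_scales(),
                           lambda = 3L, w = 0.05, paac_mode = "chou") {
  n <- nchar(sequence)
  if (n < 10L || n > 100L) {
    stop("encode_peptide expects curated sequences of length 10..100, got ", n)
  }
  c(compute_aac(sequence),
    compute_dpc(sequence),
    compute_pcp(sequence, group_table, scales),
    compute_pseaac(sequence, scales, lambda, w, paac_mode))
}

#' Encode a set of records into a feature matrix
#'
#' One row per record in input order, columns in [feature_schema()] order.
#' Per-record failures are collected and reported together.
#'
#' @param records Character vector of sequences, or a data.frame with a
#'   \code{sequence} column (e.g. the \code{records} of an
#'   \code{acp_dataset}).
#' @inheritParams encode_peptide
#' @return Numeric matrix (n x 473) with schema column names; attribute
#'   \code{schema} holds the schema data.frame.
#' @export
encode_dataset <- function(records, group_table = load_group_table(),
                           scales = load_property_scales(),
                           lambda = 3L, w = 0.05, paac_mode = "chou") {
  seqs <- if (is.data.frame(records)) records$sequence else records
  schema <- feature_schema(group_table)
  mat <- matrix(NA_real_, nrow = length(seqs), ncol = nrow(schema),
                dimnames = list(NULL, schema$name))
  failures <- character()
  for (i in seq_along(seqs)) {
    v <- tryCatch(encode_peptide(seqs[i], group_table, scales, lambda, w, paac_mode),
                  error = function(e) conditionMessage(e))
    if (is.character(v)) {
      failures <- c(failures, sprintf("record %d: %s", i, v))
    } else {
      mat[i, ] <- v
    }
  }
  if (length(failures)) {
    stop("encoding failed for ", length(failures), " record(s):\n  ",
         paste(failures, collapse = "\n  "))
  }
  attr(mat, "schema") <- schema
  mat
}
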