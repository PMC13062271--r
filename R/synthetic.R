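# Synthetic peptide cohorts with controlled tissue structure, class
# imbalance, planted composition signals and cross-tissue duplicate
# sequences, so every pipeline stage is testable without external databases.

#' Default planted per-tissue sequence signals
#'
#' One distinct dipeptide motif per tissue: among that tissue's peptides the
#' transition probability into the motif's second residue (given its first)
#' is multiplied by \code{multiplier} at generation time.
#'
#' @param multiplier Effect multiplier (> 0); 1 means no signal (null cohort).
#' @return data.frame with columns \code{tissue}, \code{type}, \code{target},
#'   \code{multiplier}.
#' @export
default_planted_signals <- function(multiplier = 10) {
  data.frame(
    tissue = TISSUES,
    type = "dipeptide_motif",
    target = c("KW", "GP", "IA", "RF", "LP", "KF", "LI", "HT", "VY"),
    multiplier = multiplier,
    stringsAsFactors = FALSE
  )
}

#' Synthetic cohort configuration
#'
#' @param n_per_tissue Named integer vector of record counts per tissue. The
#'   default emulates a realistic unequal allocation: breast and lung most
#'   represented, brain smallest, liver and prostate also small.
#' @param length_median,length_sdlog Log-normal length distribution
#'   parameters; lengths are rounded and clipped to [10, 100]. Defaults give
#'   a median near 17 residues.
#' @param background Named residue sampling weights; \code{"uniform"}
#'   (default) or \code{"natural"} (approximate natural protein abundances),
#'   or a named numeric vector over the 20 amino acids.
#' @param planted_signals data.frame as in [default_planted_signals()]; types
#'   \code{dipeptide_motif}, \code{aa_enrichment}, \code{charge_shift}.
#' @param duplicate_rate Fraction of generated sequences re-emitted under a
#'   second tissue (exercises group-aware splitting); in [0, 1).
#' @param seed Integer seed.
#' @return List of class \code{acp_synth_config}.
#' @export
synthetic_config <- function(n_per_tissue = c(Blood = 120, Brain = 40,
                                              Breast = 180, Cervix = 90,
                                              Colon = 100, Liver = 70,
                                              Lung = 160, Prostate = 60,
                                              Skin = 90),
                             length_median = 17, length_sdlog = 0.35,
                             background = "uniform",
                             planted_signals = default_planted_signals(),
                             duplicate_rate = 0.1, seed = 42L) {
  stopifnot(all(names(n_per_tissue) %in% TISSUES), all(n_per_tissue >= 1),
            duplicate_rate >= 0, duplicate_rate < 1,
            all(planted_signals$multiplier > 0))
  if (identical(background, "uniform")) {
    background <- stats::setNames(rep(1, 20), AA_ALPHABET)
  } else if (identical(background, "natural")) {
    # approximate UniProt residue abundances (percent)
    background <- stats::setNames(
      c(8.3, 1.4, 5.5, 6.7, 3.9, 7.1, 2.3, 5.9, 5.8, 9.7,
        2.4, 4.1, 4.7, 3.9, 5.5, 6.6, 5.4, 6.9, 1.1, 2.9), AA_ALPHABET)
  } else {
    stopifnot(is.numeric(background), identical(sort(names(background)), AA_ALPHABET))
    background <- background[AA_ALPHABET]
  }
  bad <- planted_signals$type == "dipeptide_motif" &
    nchar(planted_signals$target) != 2L
  if (any(bad)) stop("dipeptide_motif targets must be length-2 strings")
  structure(list(n_per_tissue = n_per_tissue, length_median = length_median,
                 length_sdlog = length_sdlog, background = background,
                 planted_signals = planted_signals,
                 duplicate_rate = duplicate_rate, seed = seed),
            class = "acp_synth_config")
}

# Sample one sequence of the given length. Non-motif signals modify the
# residue weights globally. A dipeptide motif is planted by a generative
# emission process (biased sampling, never post-hoc editing): at each
# emission step the whole motif is emitted with probability
# q = base_insert_rate * (multiplier - 1), otherwise a single background
# residue is drawn. At multiplier 1 the insertion probability is zero, so
# positives and negatives are exchangeable and the cohort is a true null.
.sample_sequence <- function(len, weights, motif = NULL, multiplier = 1,
                             base_insert_rate = 0.02) {
  q <- if (is.null(motif)) 0 else min(0.9, base_insert_rate * (multiplier - 1))
  if (q == 0) {
    return(paste(sample(AA_ALPHABET, len, replace = TRUE, prob = weights),
                 collapse = ""))
  }
  chars <- character(0)
  while (length(chars) < len) {
    if (len - length(chars) >= 2L && stats::runif(1) < q) {
      chars <- c(chars, substr(motif, 1, 1), substr(motif, 2, 2))
    } else {
      chars <- c(chars, sample(AA_ALPHABET, 1L, prob = weights))
    }
  }
  paste(chars[seq_len(len)], collapse = "")
}

#' Generate a synthetic peptide cohort
#'
#' Draws residue-wise sequences from the background weights, applies each
#' tissue's planted signal at generation time, re-emits a
#' \code{duplicate_rate} fraction of sequences under a second tissue, and
#' returns a curated dataset plus the ground-truth signal manifest. Fully
#' reproducible under the config seed.
#'
#' @param config An [synthetic_config()] object.
#' @return List with \code{dataset} (an \code{acp_dataset}) and
#'   \code{manifest} (the planted-signal data.frame).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "acp_synth_config"))
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(config$seed)

  rows <- list()
  for (tissue in names(config$n_per_tissue)) {
    n <- config$n_per_tissue[[tissue]]
    sig <- config$planted_signals[config$planted_signals$tissue == tissue, , drop = FALSE]
    weights <- config$background
    motif <- NULL; mult <- 1
    for (si in seq_len(nrow(sig))) {
      s <- sig[si, ]
      if (s$type == "aa_enrichment") {
        weights[s$target] <- weights[s$target] * s$multiplier
      } else if (s$type == "charge_shift") {
        weights[c("K", "R")] <- weights[c("K", "R")] * s$multiplier
      } else if (s$type == "dipeptide_motif") {
        motif <- s$target; mult <- s$multiplier
      } else stop("unknown signal type: ", s$type)
    }
    lens <- pmin(100L, pmax(10L, as.integer(round(
      stats::rlnorm(n, meanlog = log(config$length_median),
                    sdlog = config$length_sdlog)))))
    if (!is.null(motif) && nchar(motif) > min(lens)) {
      stop("planted motif longer than the minimum sequence length")
    }
    seqs <- vapply(lens, .sample_sequence, character(1),
                   weights = weights, motif = motif, multiplier = mult)
    rows[[tissue]] <- data.frame(sequence = seqs, tissue = tissue,
                                 ic50_uM = NA_real_, sources = "synthetic",
                                 stringsAsFactors = FALSE)
  }
  records <- do.call(rbind, c(rows, list(make.row.names = FALSE)))

  n_dup <- floor(config$duplicate_rate * nrow(records))
  if (n_dup > 0) {
    pick <- sample(nrow(records), n_dup)
    extra <- lapply(pick, function(i) {
      other <- sample(setdiff(TISSUES, records$tissue[i]), 1L)
      data.frame(sequence = records$sequence[i], tissue = other,
                 ic50_uM = NA_real_, sources = "synthetic",
                 stringsAsFactors = FALSE)
    })
    records <- rbind(records, do.call(rbind, extra))
  }
  # duplicate re-emission may rarely collide with an existing pair
  records <- records[!duplicated(paste(records$sequence, records$tissue)), ]
  list(dataset = curated_dataset(records), manifest = config$planted_signals)
}

#' Tiny deterministic worked-example input
#'
#' A fixed table of ~40 raw entries over all nine tissues that exercises
#' every curation rule: an invalid-character entry, a too-short entry, an
#' ambiguous annotation, an unmatched annotation, a duplicated
#' sequence-tissue pair, and a cross-tissue duplicate sequence. The same
#' table is shipped as \code{extdata/worked_example.csv}; regeneration is
#' byte-identical.
#'
#' @return data.frame with columns \code{sequence}, \code{annotation_text},
#'   \code{activity_value}, \code{activity_unit}, \code{source}.
#' @export
make_worked_example <- function() {
  e <- function(seq, ann, val = NA_real_, unit = NA_character_, src = "synthetic") {
    data.frame(sequence = seq, annotation_text = ann, activity_value = val,
               activity_unit = unit, source = src, stringsAsFactors = FALSE)
  }
  rbind(
    # Blood
    e("KWKLFKKIGAVL", "acute myeloid leukemia, HL-60", 12, "uM"),
    e("FAKKLAKKLLKF", "T-cell leukemia, Jurkat", 800, "nM"),
    e("GLFDIIKKIAES", "lymphoma, U937"),
    # Brain
    e("ALWKTMLKKLGT", "glioblastoma multiforme, U87", 25, "uM"),
    e("KLAKLAKKLAKL", "neuroblastoma, SH-SY5Y"),
    e("GIGKFLHSAKKF", "astrocytoma"),
    # Breast
    e("KWKSFLKTFKSA", "breast adenocarcinoma, MCF-7", 64, "uM"),
    e("kwksflktfksa", "breast adenocarcinoma, MCF-7", 32, "uM"),  # duplicate pair
    e("FLPIIAKLLSGL", "breast carcinoma, MDA-MB-231", 5, "uM"),
    e("ILPWKWPWWPWR", "mammary carcinoma, T47D"),
    # Cervix
    e("SWLSKTAKKLEN", "cervical carcinoma, HeLa", 0.02, "mM"),
    e("FFGWLIKGAIHA", "cervical cancer, SiHa"),
    # Colon
    e("GWGSFFKKAAHV", "colorectal carcinoma, HT-29", 18, "uM"),
    e("VNWKKILGKIIK", "colon adenocarcinoma, HCT116"),
    e("KWKSFLKTFKSA", "colon carcinoma, SW480"),  # cross-tissue duplicate of a Breast peptide
    # Liver
    e("FLGALFKALSKL", "hepatocellular carcinoma, HepG2", 9, "uM"),
    e("GLWSKIKEVGKE", "hepatoma, SMMC-7721"),
    # Lung
    e("AFDIIKKIAESF", "lung adenocarcinoma, A549", 30, "uM"),
    e("RWKIFKKIEKVG", "non-small cell lung cancer, NCI-H460"),
    e("ILGKIWEGIKSL", "Lewis lung carcinoma"),
    # Prostate
    e("FAKLLAKLAKKL", "prostate carcinoma, PC-3", 14, "uM"),
    e("GLLDIVKKVVGA", "prostate cancer, DU145"),
    # Skin
    e("KIKWFKTMKSLR", "melanoma, A375", 7, "uM"),
    e("DSHAKRHHGYKR", "murine melanoma, B16"),
    e("GFKRIVQRIKDF", "skin squamous cell carcinoma"),
    # rejected entries
    e("ACXKLLKKWWRR", "breast adenocarcinoma, MCF-7"),            # invalid character
    e("KWKLFKK", "cervical carcinoma, HeLa"),                     # too short
    e("GLPALISWSKRK", "breast and lung carcinoma"),               # ambiguous
    e("RRWWRRWWRRWW", "osteosarcoma, MG-63"),                     # unmatched
    e("VDKPPYLPRPRP", "gastric carcinoma, AGS", 1, "ug/mL"),      # unmatched tissue
    # extra valid records so every tissue keeps at least two entries
    e("KKVVFKVKFKGG", "leukemia, K562"),
    e("PAWRKAFRWAWR", "glioma, U251"),
    e("GLFGVLAKVAAH", "cervical cancer, CaSki"),
    e("LLGDFFRKSKEK", "hepatocellular carcinoma, Huh-7"),
    e("SKITDILAKLGK", "prostate cancer, LNCaP"),
    e("WKLFKKILKVLG", "colon carcinoma, LoVo"),
    e("HGVSGHGQHGVH", "melanoma, SK-MEL-28"),
    e("TFFRLFNRSFTQ", "breast carcinoma, 4T1"),
    e("IDWKKLLDAAKQ", "lung carcinoma, Calu-3"),
    e("NGVQPKYKWWKW", "multiple myeloma")
  )
}
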