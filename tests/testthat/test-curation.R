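test_that("sequence cleaning case-folds, rejects non-standard characters, and is idempotent", {
  expect_identical(clean_sequence("klwKLW"), "KLWKLW")
  expect_identical(clean_sequence("ACDEFGHIKLMNPQRSTVWY"), "ACDEFGHIKLMNPQRSTVWY")
  for (bad in c("ACXK", "ACBK", "AC K", "AC-K", "ACUK", "ACOK")) {
    res <- clean_sequence(bad)
    expect_true(is.na(res))
    expect_match(attr(res, "reason"), "invalid character")
  }
  expect_true(is.na(clean_sequence("")))
  set.seed(5)
  for (s in rand_seqs(20)) {
    expect_identical(clean_sequence(clean_sequence(s)), clean_sequence(s))
  }
})

test_that("length filter is inclusive at both bounds and logs removals", {
  seqs <- vapply(c(9, 10, 50, 100, 101), function(n)
    paste(rep("A", n), collapse = ""), character(1))
  res <- filter_by_length(seqs)
  expect_identical(nchar(res$kept), c(10L, 50L, 100L))
  expect_setequal(res$log$reason, c("too short", "too long"))
  empty <- filter_by_length(character(0))
  expect_length(empty$kept, 0)
  expect_identical(nrow(empty$log), 0L)
})

test_that("keyword tissue assignment resolves unique matches and flags ambiguity", {
  expect_identical(assign_tissue("MCF-7 breast adenocarcinoma"), "Breast")
  expect_identical(assign_tissue("HeLa cervical carcinoma"), "Cervix")
  expect_identical(assign_tissue("breast and lung carcinoma"), "ambiguous")
  expect_identical(assign_tissue("osteosarcoma"), "unmatched")
  # case-insensitive substring matching
  expect_identical(assign_tissue("HEPG2 HEPATOMA"), "Liver")
})

test_that("activity standardisation converts molar units to uM and refuses mass units", {
  expect_equal(as.numeric(standardize_activity(64, "uM")), 64)
  expect_equal(as.numeric(standardize_activity(64, "μM")), 64)
  expect_equal(as.numeric(standardize_activity(500, "nM")), 0.5)
  expect_equal(as.numeric(standardize_activity(0.02, "mM")), 20)
  expect_equal(as.numeric(standardize_activity(1e-6, "M")), 1)
  expect_true(is.na(standardize_activity(1, "ug/mL")))
  expect_true(is.na(standardize_activity(-3, "uM")))
})

test_that("deduplication keeps one record per sequence-tissue pair and is idempotent", {
  entries <- data.frame(
    sequence = c("KWKSFLKTFKSA", "KWKSFLKTFKSA", "KWKSFLKTFKSA", "FLGALFKALSKL"),
    tissue = c("Breast", "Breast", "Lung", "Liver"),
    ic50_uM = c(64, 32, NA, 9),
    sources = c("cancerppd2", "dctpep", "dctpep", "cancerppd2"),
    stringsAsFactors = FALSE)
  ds <- merge_and_deduplicate(entries)
  expect_identical(ds$n_entries, 3L)
  expect_identical(ds$n_unique_sequences, 2L)
  breast <- ds$records[ds$records$tissue == "Breast", ]
  expect_equal(breast$ic50_uM, 32)  # conflicting values: minimum kept
  expect_identical(breast$sources, "cancerppd2,dctpep")
  expect_identical(nrow(attr(ds, "conflicts")), 1L)
  # same sequence under two tissues stays as two records
  expect_identical(sum(ds$records$sequence == "KWKSFLKTFKSA"), 2L)
  # idempotence
  ds2 <- merge_and_deduplicate(ds$records)
  expect_identical(ds2$records, ds$records)
})

test_that("the worked example survives curation with the documented rejection log", {
  we <- make_worked_example()
  cur <- curate_entries(we)
  expect_identical(sort(cur$rejections$reason),
                   sort(c("invalid character 'X'", "too short",
                          "annotation ambiguous", "annotation unmatched",
                          "annotation unmatched")))
  counts <- table(cur$dataset$records$tissue)
  expect_setequal(names(counts), TISSUES)
  expect_true(all(counts >= 2))
  # curated records satisfy the record invariants by construction
  lens <- nchar(cur$dataset$records$sequence)
  expect_true(all(lens >= 10 & lens <= 100))
  expect_false(anyDuplicated(paste(cur$dataset$records$sequence,
                                   cur$dataset$records$tissue)) > 0)
  # the fixture regenerates byte-identically
  fixture <- system.file("extdata", "worked_example.csv", package = "tissueACP")
  tmp <- tempfile(fileext = ".csv")
  write_worked_example(tmp)
  expect_identical(readBin(tmp, "raw", file.size(tmp)),
                   readBin(fixture, "raw", file.size(fixture)))
})

test_that("one-vs-rest tasks label per entry and positive counts sum to n_entries", {
  entries <- data.frame(
    sequence = rand_seqs(8), tissue = c(rep("Breast", 3), rep("Lung", 5)),
    stringsAsFactors = FALSE)
  ds <- merge_and_deduplicate(entries)
  task <- build_ovr_task(ds, "Breast")
  expect_identical(sum(task$labels), 3L)
  expect_identical(sum(task$labels == 0L), 5L)
  expect_error(build_ovr_task(ds, "Brain"), "no positive")
  only <- merge_and_deduplicate(entries[entries$tissue == "Breast", ])
  expect_error(build_ovr_task(only, "Breast"), "no negative")

  co <- small_cohort(15)
  pos_counts <- vapply(TISSUES, function(t)
    sum(build_ovr_task(co$dataset, t)$labels), integer(1))
  expect_identical(sum(pos_counts), co$dataset$n_entries)
})

test_that("FASTA and CSV readers feed the curation pipeline", {
  fa <- tempfile(fileext = ".fasta")
  writeLines(c(">p1 breast adenocarcinoma, MCF-7", "KWKSFLKTFKSA",
               ">p2 lung carcinoma, A549", "afdiikkiaesf"), fa)
  raw <- read_peptide_fasta(fa, source = "other")
  expect_identical(raw$sequence, c("KWKSFLKTFKSA", "AFDIIKKIAESF"))
  expect_identical(raw$annotation_text[1], "breast adenocarcinoma, MCF-7")
  cur <- curate_entries(raw)
  expect_identical(cur$dataset$n_entries, 2L)
  expect_setequal(cur$dataset$records$tissue, c("Breast", "Lung"))

  csvf <- tempfile(fileext = ".csv")
  write.csv(data.frame(sequence = "FLGALFKALSKL",
                       annotation = "hepatoma, HepG2",
                       activity_value = 9, activity_unit = "uM"),
            csvf, row.names = FALSE)
  raw2 <- read_peptide_csv(csvf)
  cur2 <- curate_entries(raw2)
  expect_identical(cur2$dataset$records$tissue, "Liver")
  expect_equal(cur2$dataset$records$ic50_uM, 9)
})
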