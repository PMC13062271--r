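test_that("the feature schema has 473 uniquely named features in fixed block order", {
  schema <- feature_schema()
  expect_identical(nrow(schema), 473L)
  expect_false(anyDuplicated(schema$name) > 0)
  expect_identical(as.vector(table(factor(schema$category,
                                          levels = c("AAC", "DPC", "PCP", "PAAC")))),
                   c(20L, 400L, 30L, 23L))
  expect_identical(rle(schema$category)$values, c("AAC", "DPC", "PCP", "PAAC"))
  expect_identical(schema$name[1], "AAC_A")
  expect_identical(schema$name[21], "DPC_AA")
  expect_identical(schema$name[420], "DPC_YY")
  expect_identical(schema$name[473], "PAAC_lam3")
})

test_that("amino acid composition matches direct counting", {
  aac <- compute_aac("ACDE")
  expect_equal(unname(aac[c("AAC_A", "AAC_C", "AAC_D", "AAC_E")]), rep(0.25, 4))
  expect_equal(sum(aac), 1)
  expect_equal(unname(compute_aac("AAAA")["AAC_A"]), 1)
  aac2 <- compute_aac("KLWKLWKLWK")
  expect_equal(unname(aac2[c("AAC_K", "AAC_L", "AAC_W")]), c(0.4, 0.3, 0.3))
  expect_error(compute_aac("ACXK"), "invalid character")
})

test_that("dipeptide composition uses overlapping counts over N-1 positions", {
  dpc <- compute_dpc("AAA")
  expect_equal(unname(dpc["DPC_AA"]), 1)
  expect_equal(sum(dpc), 1)
  dpc2 <- compute_dpc("ACAC")
  expect_equal(unname(dpc2["DPC_AC"]), 2 / 3)
  expect_equal(unname(dpc2["DPC_CA"]), 1 / 3)
  expect_length(dpc2, 400L)
  expect_error(compute_dpc("A"), "length >= 2")
})

test_that("AAC and DPC agree with a naive counting oracle on random sequences", {
  set.seed(101)
  seqs <- rand_seqs(200)
  for (s in seqs) {
    chars <- strsplit(s, "")[[1]]
    n <- length(chars)
    aac_oracle <- vapply(AA_ALPHABET, function(a) sum(chars == a) / n, numeric(1))
    expect_equal(unname(compute_aac(s)), unname(aac_oracle), tolerance = 1e-12)
    dpc <- compute_dpc(s)
    for (pair in sample(names(dpc), 5)) {
      ij <- sub("DPC_", "", pair)
      cnt <- 0L
      for (t in seq_len(n - 1)) {
        if (paste0(chars[t], chars[t + 1]) == ij) cnt <- cnt + 1L
      }
      expect_equal(unname(dpc[pair]), cnt / (n - 1))
    }
  }
})

test_that("physicochemical composition reflects group membership and charge", {
  gt <- load_group_table()
  pcp <- compute_pcp("KKKKKKKKKK")
  expect_equal(unname(pcp["PCP_Positive"]), 1)
  expect_equal(unname(pcp["PCP_Net_Charge"]), 10)
  pcp2 <- compute_pcp("KKKKKDDDDD")
  expect_equal(unname(pcp2["PCP_Net_Charge"]), 0)
  # Charged = Positive union Negative (disjoint) => fractions add
  set.seed(42)
  for (s in rand_seqs(50)) {
    p <- compute_pcp(s)
    expect_equal(unname(p["PCP_Charged"]),
                 unname(p["PCP_Positive"] + p["PCP_Negative"]), tolerance = 1e-12)
    chars <- strsplit(s, "")[[1]]
    expect_equal(unname(p["PCP_Net_Charge"]), sum(gt$charge[chars]))
    expect_true(all(p[1:20] >= 0 & p[1:20] <= 1))
  }
})

test_that("net charge and AAC respond monotonically to added lysines", {
  base <- "GAGAGAGAGAGAGAGAGAGA"
  prev_aac <- -1; prev_charge <- -Inf
  for (nk in 0:10) {
    s <- paste0(paste(rep("K", nk), collapse = ""),
                substr(base, 1, 20 - nk))
    aac_k <- unname(compute_aac(s)["AAC_K"])
    charge <- unname(compute_pcp(s)["PCP_Net_Charge"])
    expect_gt(aac_k, prev_aac)
    expect_gt(charge, prev_charge)
    prev_aac <- aac_k; prev_charge <- charge
  }
})

test_that("normalized property scales have mean 0 and unit sd over the 20 residues", {
  sc <- load_property_scales()
  expect_equal(unname(colMeans(sc$normalized)), rep(0, 3), tolerance = 1e-9)
  expect_equal(unname(apply(sc$normalized, 2, sd)), rep(1, 3), tolerance = 1e-9)
})

test_that("pseudo-AAC follows the type-1 construction and sums to one", {
  paac <- compute_pseaac("AAAAAAAAAA")
  expect_equal(unname(paac["PAAC_A"]), 1)
  expect_equal(sum(paac[-1]), 0)
  expect_length(compute_pseaac(rand_seqs(1, 23, 23)), 23L)
  # brute-force recomputation of the joint normalization on one sequence
  set.seed(7)
  s <- rand_seqs(1, 30, 30)
  chars <- strsplit(s, "")[[1]]
  sc <- load_property_scales()$normalized
  theta <- numeric(3)
  for (k in 1:3) {
    acc <- 0
    for (t in seq_len(30 - k)) {
      acc <- acc + mean((sc[chars[t + k], ] - sc[chars[t], ])^2)
    }
    theta[k] <- acc / (30 - k)
  }
  f <- vapply(AA_ALPHABET, function(a) sum(chars == a) / 30, numeric(1))
  denom <- sum(f) + 0.05 * sum(theta)
  expect_equal(unname(compute_pseaac(s)),
               unname(c(f / denom, 0.05 * theta / denom)), tolerance = 1e-12)
  expect_equal(sum(compute_pseaac(s)), 1, tolerance = 1e-9)
  expect_error(compute_pseaac("AAA"), "lambda")
  # raw mode keeps plain frequencies
  raw <- compute_pseaac(s, mode = "raw")
  expect_equal(unname(raw[1:20]), unname(f))
})

test_that("encode_peptide is deterministic and permutation changes only order-aware blocks", {
  set.seed(9)
  s <- rand_seqs(1, 20, 20)
  expect_identical(encode_peptide(s), encode_peptide(s))
  v <- encode_peptide(s)
  expect_length(v, 473L)
  chars <- strsplit(s, "")[[1]]
  shuffled <- paste(rev(chars), collapse = "")
  v2 <- encode_peptide(shuffled)
  expect_equal(v[1:20], v2[1:20])        # AAC invariant to order
  expect_equal(v[421:450], v2[421:450])  # PCP is order-free too
  expect_error(encode_peptide("KLWKLW"), "length 10..100")
})

test_that("encode_dataset returns one aligned row per record and an intact empty schema", {
  co <- small_cohort(5)
  X <- encode_dataset(co$dataset$records)
  expect_identical(dim(X), c(co$dataset$n_entries, 473L))
  expect_identical(colnames(X), feature_schema()$name)
  k <- 3L
  expect_equal(X[k, ], encode_peptide(co$dataset$records$sequence[k]))
  X0 <- encode_dataset(character(0))
  expect_identical(dim(X0), c(0L, 473L))
  expect_identical(colnames(X0), feature_schema()$name)
})

test_that("descriptor block sums are normalized for random valid sequences", {
  set.seed(2024)
  for (s in rand_seqs(300)) {
    expect_equal(sum(compute_aac(s)), 1, tolerance = 1e-9)
    expect_equal(sum(compute_dpc(s)), 1, tolerance = 1e-9)
    expect_equal(sum(compute_pseaac(s)), 1, tolerance = 1e-9)
  }
})
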