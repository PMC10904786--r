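layout4 <- read_layout(prefix_seq = "ACGTACGTAC", barcode_len = 8,
                       umi_len = 8, suffix_seq = "TTGGCCAA")

test_that("extract_barcode_umi slices at layout coordinates", {
  read <- paste0("ACGTACGTAC", "ACGTACGT", "TTTTCCCC", "TTGGCCAA")
  ex <- extract_barcode_umi(read, layout4)
  expect_equal(ex$status, "ok")
  expect_equal(ex$barcode, "ACGTACGT")
  expect_equal(ex$umi, "TTTTCCCC")

  # three prefix mismatches exceed the default anchor tolerance of 2
  bad <- paste0("TTTTACGTAC", "ACGTACGT", "TTTTCCCC", "TTGGCCAA")
  expect_equal(extract_barcode_umi(bad, layout4)$status, "anchor_fail")
  expect_equal(extract_barcode_umi(bad, layout4, anchor_max_mm = 3)$status,
               "ok")

  expect_equal(extract_barcode_umi("ACGTACG", layout4)$status, "anchor_fail")
  expect_equal(extract_barcode_umi(character(0), layout4)$status, character(0))
})

test_that("match_whitelist corrects within Hamming tolerance", {
  wl <- design_whitelist(n = 24, barcode_len = 8, min_dist = 3, seed = 5)
  truthv <- wl$sequence[3]
  mutated <- truthv
  substr(mutated, 4, 4) <- setdiff(c("A", "C", "G", "T"),
                                   substr(truthv, 4, 4))[1]
  res <- match_whitelist(c(truthv, mutated), wl, max_mm = 1)
  expect_equal(res$status, c("assigned", "assigned"))
  expect_equal(res$barcode_id, rep(wl$barcode_id[3], 2))
  # oracle: the corrected entry is the unique nearest neighbour
  dists <- vapply(wl$sequence, r_hamming, numeric(1), a = mutated)
  expect_equal(sum(dists <= 1), 1)
  expect_equal(wl$barcode_id[which.min(dists)], res$barcode_id[2])

  far <- paste(rep("A", 8), collapse = "")
  if (min(vapply(wl$sequence, r_hamming, numeric(1), a = far)) >= 2) {
    expect_equal(match_whitelist(far, wl, max_mm = 1)$status, "unmatched")
  }
})

test_that("equidistant matches in a degenerate whitelist are ambiguous", {
  wl <- data.frame(barcode_id = c("B1", "B2"),
                   sequence = c("AAAA", "AATT"),   # distance 2
                   lnp_name = c("L1", "L2"), stringsAsFactors = FALSE)
  expect_warning(res <- match_whitelist("AATA", wl, max_mm = 1),
                 "ambiguous")
  expect_equal(res$status, "ambiguous")
  expect_true(is.na(res$barcode_id))
})

test_that("directional collapse follows the 2c-1 rule", {
  expect_equal(collapse_umis(c(AAAA = 10, AAAT = 4, CCCC = 3)), 2)
  expect_equal(collapse_umis(c(AAAA = 5, AAAT = 5)), 2)  # 5 < 2*5-1: no edge
  expect_equal(collapse_umis(c(AAAA = 5, AAAT = 3)), 1)  # 5 >= 2*3-1
  expect_equal(collapse_umis(c(GGGG = 1)), 1)
  expect_equal(collapse_umis(stats::setNames(numeric(0), character(0))), 0)
  expect_equal(collapse_umis(c(AAAA = 10, AAAT = 4), method = "unique"), 2)
})

test_that("directional collapse equals the exhaustive oracle", {
  set.seed(11)
  for (i in 1:200) {
    inst <- random_umi_instance(n_max = 12, umi_len = 4)
    expect_equal(collapse_umis(inst), oracle_collapse_directional(inst),
                 info = paste(names(inst), inst, collapse = " "))
  }
})

test_that("dedup is invariant to read order and exact duplication", {
  wl <- design_whitelist(n = 6, barcode_len = 8, min_dist = 3, seed = 2)
  model <- biodistribution_model(wl, molecules_per_organ = 300,
                                 pcr_cycles = 2, pcr_efficiency = 0.6,
                                 seq_error_rate = 0.001,
                                 reads_per_sample = 800, seed = 9)
  screen <- simulate_screen(model, n_mice = 1, n_pool_replicates = 1)
  sheet <- screen$sample_sheet[1:2, ]
  reads <- screen$reads[sheet$sample_id]
  base <- build_count_table(reads, sheet, wl, screen$layout)

  shuffled <- lapply(reads, function(r) r[sample(length(r))])
  perm <- build_count_table(shuffled, sheet, wl, screen$layout)
  expect_identical(base$counts, perm$counts)

  # exact duplication of every read leaves the distinct-UMI count unchanged;
  # the directional count is NOT invariant by design (doubling all counts
  # turns borderline count(u) = 2*count(v) - 1 edges off), so idempotence
  # is asserted on the unique method
  doubled <- lapply(reads, function(r) rep(r, 2))
  dup <- build_count_table(doubled, sheet, wl, screen$layout)
  expect_identical(base$unique_counts, dup$unique_counts)
  expect_equal(dup$qc$reads_in, 2 * base$qc$reads_in)
})

test_that("read fates partition the input and directional <= unique", {
  wl <- design_whitelist(n = 12, barcode_len = 8, min_dist = 3, seed = 2)
  model <- biodistribution_model(wl, molecules_per_organ = 500,
                                 pcr_cycles = 3, pcr_efficiency = 0.7,
                                 seq_error_rate = 0.02,   # harsh error rate
                                 reads_per_sample = 2000, seed = 9)
  screen <- simulate_screen(model, n_mice = 1)
  counts <- build_count_table(screen$reads, screen$sample_sheet, wl,
                              screen$layout)
  qc <- counts$qc
  expect_equal(qc$assigned + qc$unmatched + qc$ambiguous + qc$anchor_fail,
               qc$reads_in)
  expect_true(all(counts$counts <= counts$unique_counts))
  expect_true(all(counts$unique_counts <= counts$read_counts))
})

test_that("noiseless end-to-end counts equal the truth table", {
  wl <- design_whitelist(n = 8, barcode_len = 8, min_dist = 3, seed = 4)
  model <- biodistribution_model(wl, mouse_sd = 0.2,
                                 molecules_per_organ = 400,
                                 pcr_cycles = 0, seq_error_rate = 0,
                                 reads_per_sample = NULL, seed = 21)
  # 16 nt UMIs make birthday collisions vanishingly unlikely, so the
  # deduplicated counts must reproduce the truth table exactly
  layout <- read_layout(umi_len = 16)
  screen <- simulate_screen(model, layout = layout, n_mice = 2)
  counts <- build_count_table(screen$reads, screen$sample_sheet, wl, layout)
  truth <- screen$truth
  for (i in which(screen$sample_sheet$role == "tissue")) {
    sid <- screen$sample_sheet$sample_id[i]
    sub <- truth[truth$mouse == screen$sample_sheet$mouse[i] &
                   truth$organ == screen$sample_sheet$organ[i], ]
    got <- counts$counts[sub$barcode_id, sid]
    expect_identical(unname(got), sub$molecules)
  }
})

test_that("assignment accuracy under realistic error rate is >= 99%", {
  wl <- design_whitelist(n = 24, barcode_len = 8, min_dist = 3, seed = 6)
  layout <- read_layout()
  model <- biodistribution_model(wl, seq_error_rate = 0.001, pcr_cycles = 0,
                                 reads_per_sample = NULL, seed = 13)
  mol_bc <- sample.int(nrow(wl), 5000, replace = TRUE)
  reads <- bdnascreen:::simulate_sample_reads(mol_bc, layout, wl, model,
                                              seed = 14)
  ex <- extract_barcode_umi(reads, layout)
  res <- match_whitelist(ex$barcode[ex$status == "ok"], wl, max_mm = 1)
  truth_ids <- wl$barcode_id[mol_bc[ex$status == "ok"]]
  assigned <- res$status == "assigned"
  accuracy <- mean(res$barcode_id[assigned] == truth_ids[assigned])
  expect_gte(accuracy, 0.99)
  expect_gte(mean(assigned), 0.99)
})

test_that("build_count_table I/O contracts hold", {
  wl <- design_whitelist(n = 4, barcode_len = 8, min_dist = 3, seed = 4)
  sheet <- data.frame(sample_id = "s1", mouse = 1, organ = "lung",
                      role = "tissue", stringsAsFactors = FALSE)
  empty <- build_count_table(list(s1 = character(0)), sheet, wl, read_layout())
  expect_true(all(empty$counts == 0))
  expect_equal(empty$qc$reads_in, 0)

  expect_error(build_count_table(list(other = character(0)), sheet, wl,
                                 read_layout()),
               "missing.*s1")
  expect_error(build_count_table(withr::local_tempdir(), sheet, wl,
                                 read_layout()),
               "no FASTQ found.*s1")
})

test_that("count table TSV round-trips through write/read", {
  wl <- design_whitelist(n = 5, barcode_len = 8, min_dist = 3, seed = 4)
  model <- biodistribution_model(wl, molecules_per_organ = 100,
                                 pcr_cycles = 0, seq_error_rate = 0,
                                 reads_per_sample = NULL, seed = 2)
  screen <- simulate_screen(model, n_mice = 1)
  counts <- build_count_table(screen$reads, screen$sample_sheet, wl,
                              screen$layout)
  dir <- withr::local_tempdir()
  write_count_table(counts, dir)
  back <- read_count_table(file.path(dir, "counts.tsv"), counts$samples)
  expect_identical(back$counts, counts$counts)
})
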