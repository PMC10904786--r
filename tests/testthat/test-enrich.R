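mk_counts <- function(m, roles, organs = NULL, mice = NULL) {
  ns <- ncol(m)
  sheet <- data.frame(
    sample_id = colnames(m),
    mouse = if (is.null(mice)) seq_len(ns) else mice,
    organ = if (is.null(organs)) rep("lung", ns) else organs,
    role = roles, stringsAsFactors = FALSE)
  structure(list(counts = m, samples = sheet, qc = NULL),
            class = "bdna_counts")
}

test_that("within-sample fractions match hand arithmetic", {
  m <- matrix(c(10L, 30L, 60L), ncol = 1,
              dimnames = list(c("b1", "b2", "b3"), "s1"))
  norm <- normalize_within_sample(mk_counts(m, "tissue"), pseudocount = 0)
  expect_equal(unname(norm$fractions[, 1]), c(0.1, 0.3, 0.6))

  m2 <- matrix(c(0L, 0L, 100L), ncol = 1,
               dimnames = list(c("b1", "b2", "b3"), "s1"))
  norm2 <- normalize_within_sample(mk_counts(m2, "tissue"), pseudocount = 0.5)
  expect_equal(unname(norm2$fractions[, 1]),
               c(0.5, 0.5, 100.5) / 101.5)

  single <- matrix(7L, ncol = 1, dimnames = list("b1", "s1"))
  expect_equal(unname(normalize_within_sample(
    mk_counts(single, "tissue"))$fractions[, 1]), 1)
})

test_that("fractions sum to one and zero samples are excluded", {
  set.seed(3)
  m <- matrix(rpois(40, 50), nrow = 8,
              dimnames = list(paste0("b", 1:8), paste0("s", 1:5)))
  m[, 3] <- 0L
  expect_warning(norm <- normalize_within_sample(mk_counts(m, rep("tissue", 5))),
                 "all-zero")
  expect_equal(ncol(norm$fractions), 4)
  expect_equal(unname(colSums(norm$fractions)), rep(1, 4), tolerance = 1e-9)
})

test_that("pool normalization is an elementwise ratio", {
  m <- matrix(c(10L, 30L, 60L, 20L, 20L, 60L), ncol = 2,
              dimnames = list(c("b1", "b2", "b3"), c("t1", "pool_1")))
  cc <- mk_counts(m, c("tissue", "pool"))
  norm <- normalize_to_pool(normalize_within_sample(cc, pseudocount = 0))
  expect_equal(unname(norm$norm[, "t1"]), c(0.5, 1.5, 1.0))

  # tissue identical to pool -> all ones, log2 fold-change zero
  m2 <- matrix(rep(c(10L, 30L, 60L), 2), ncol = 2,
               dimnames = list(c("b1", "b2", "b3"), c("t1", "pool_1")))
  norm2 <- normalize_to_pool(normalize_within_sample(
    mk_counts(m2, c("tissue", "pool")), pseudocount = 0))
  expect_equal(unname(norm2$norm[, "t1"]), rep(1, 3))
})

test_that("planted 8-fold lung barcode attains the closed-form accumulation", {
  # (8/103) / (1/96) = 768/103 ~ 7.456 at f = 1/96, mouse_sd = 0
  wl <- design_whitelist(n = 96, barcode_len = 8, min_dist = 3, seed = 7,
                         naked_control = FALSE)
  aff <- plant_tropism(wl, "BC001", "lung", 8)
  model <- biodistribution_model(wl, organ_affinity = aff, mouse_sd = 0,
                                 molecules_per_organ = 2e5, seed = 5)
  sq <- list(truth = simulate_biodistribution(model, n_mice = 5),
             pool_truth = bdnascreen:::simulate_pool_counts(model, 1),
             sample_sheet = NULL)
  counts <- counts_from_truth(sq)
  norm <- normalize_to_pool(normalize_within_sample(counts))
  lung_cols <- norm$samples$sample_id[norm$samples$organ == "lung"]
  med <- median(norm$norm["BC001", lung_cols])
  expect_equal(med, (8 / 103) / (1 / 96), tolerance = 0.05)
})

test_that("wilcoxon_rank_sum reproduces exact enumeration values", {
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6)), 0.1)
  expect_equal(wilcoxon_rank_sum(1:5, 6:10), 2 / 252, tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(1, 2), c(1, 2)), 1)
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("exact branch matches the enumeration oracle on random inputs", {
  set.seed(21)
  for (i in 1:40) {
    n <- sample(1:5, 1)
    m <- sample(1:5, 1)
    vals <- sample(1:50, n + m)  # tie-free
    x <- vals[seq_len(n)]
    y <- vals[-seq_len(n)]
    expect_equal(wilcoxon_rank_sum(x, y), oracle_wilcoxon_exact(x, y),
                 tolerance = 1e-12, info = paste(n, m))
  }
})

test_that("normal-approximation branch agrees with stats::wilcox.test", {
  set.seed(8)
  for (i in 1:20) {
    x <- rnorm(15)
    y <- rnorm(30, 0.4)
    ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
    expect_equal(wilcoxon_rank_sum(x, y), ref, tolerance = 1e-9)
  }
  # tie-corrected path
  x <- c(1, 1, 2, 2, 3, 5, 5, 7, 9, 9, 11)
  y <- c(2, 2, 3, 3, 5, 6, 8, 9, 9, 10, 12)
  ref <- stats::wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value
  expect_equal(wilcoxon_rank_sum(x, y), ref, tolerance = 1e-9)
})

test_that("bh_adjust implements the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.37), 0.37)
  expect_equal(bh_adjust(c(0.5, 1.0)), c(1.0, 1.0))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(4)
  for (i in 1:50) {
    p <- runif(sample(1:40, 1))
    q <- bh_adjust(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    expect_equal(q, stats::p.adjust(p, "BH"), tolerance = 1e-12)
    # monotone in sorted-p order, invariant under permutation
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    perm <- sample(length(p))
    expect_equal(bh_adjust(p[perm]), q[perm], tolerance = 1e-12)
  }
})

test_that("enrichment analysis recovers planted tropism at small scale", {
  w <- make_small_world(seed = 31)
  sq <- list(truth = simulate_biodistribution(w$model, n_mice = 5),
             pool_truth = bdnascreen:::simulate_pool_counts(w$model, 1),
             sample_sheet = NULL)
  counts <- counts_from_truth(sq)
  norm <- normalize_to_pool(normalize_within_sample(counts))
  rec <- enrichment_analysis(norm)
  expect_s3_class(rec, "bdna_enrichment")
  expect_true(all(rec$p_value >= 0 & rec$p_value <= 1, na.rm = TRUE))
  expect_true(all(rec$q_value >= rec$p_value - 1e-12, na.rm = TRUE))
  cand <- classify_tropism(rec)
  expect_setequal(cand, w$planted)
  # naked control carries no q-value and is never called
  expect_true(all(is.na(rec$q_value[rec$is_control])))
})

test_that("enrichment analysis enforces its preconditions", {
  w <- make_small_world(seed = 32)
  sq <- list(truth = simulate_biodistribution(w$model, n_mice = 1),
             pool_truth = bdnascreen:::simulate_pool_counts(w$model, 1),
             sample_sheet = NULL)
  norm <- normalize_to_pool(normalize_within_sample(counts_from_truth(sq)))
  expect_error(enrichment_analysis(norm), "fewer than 2 mice")

  sq5 <- list(truth = simulate_biodistribution(w$model, n_mice = 2),
              pool_truth = bdnascreen:::simulate_pool_counts(w$model, 1),
              sample_sheet = NULL)
  norm5 <- normalize_to_pool(normalize_within_sample(counts_from_truth(sq5)))
  expect_error(enrichment_analysis(norm5, comparison = "vs_pool_replicates"),
               "one_vs_rest")
})

test_that("classify_tropism applies the off-target exclusion", {
  rec <- data.frame(
    barcode_id = rep(c("b1", "b2", "b3"), each = 3),
    organ = rep(c("lung", "liver", "spleen"), 3),
    log2fc = c(2, -1, 0,   2, 2, 0,   0.5, 0, 0),
    q_value = c(0.01, 0.01, 0.5,  0.01, 0.01, 0.5,  0.01, 0.5, 0.5),
    is_control = FALSE, stringsAsFactors = FALSE)
  # b1: lung-only enrichment -> candidate; b2: also liver-enriched -> out;
  # b3: lung fold-change below threshold -> out
  expect_equal(classify_tropism(rec), "b1")
  expect_error(classify_tropism(rec, organ_of_interest = "kidney"),
               "missing")
  none <- rec
  none$q_value <- 1
  expect_equal(classify_tropism(none), character(0))
})

test_that("classify_tropism is monotone in its thresholds", {
  set.seed(9)
  rec <- expand.grid(barcode_id = paste0("b", 1:30),
                     organ = c("lung", "liver", "spleen"),
                     stringsAsFactors = FALSE)
  rec$log2fc <- rnorm(nrow(rec), 0, 2)
  rec$q_value <- runif(nrow(rec))
  rec$is_control <- FALSE
  # with no off-target exclusion, raising fc or lowering q never adds
  # candidates (the exclusion rule itself is deliberately anti-monotone:
  # a stricter threshold can release an off-target veto)
  prev <- classify_tropism(rec, off_targets = character(0),
                           fc_threshold = 0.5)
  for (fc in c(1, 1.5, 2, 3)) {
    cur <- classify_tropism(rec, off_targets = character(0),
                            fc_threshold = fc)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
  prev <- classify_tropism(rec, off_targets = character(0), q_threshold = 0.2)
  for (q in c(0.1, 0.05, 0.01)) {
    cur <- classify_tropism(rec, off_targets = character(0), q_threshold = q)
    expect_true(all(cur %in% prev))
    prev <- cur
  }
})

test_that("heatmap matrix is ordered, neutral-centered and scalable", {
  w <- make_small_world(seed = 33, planted = "BC001", affinity = 6,
                        mouse_sd = 0)
  sq <- list(truth = simulate_biodistribution(w$model, n_mice = 3),
             pool_truth = bdnascreen:::simulate_pool_counts(w$model, 1),
             sample_sheet = NULL)
  norm <- normalize_to_pool(normalize_within_sample(counts_from_truth(sq)))
  hm <- heatmap_matrix(norm)
  expect_equal(colnames(hm), bdna_organs())
  expect_equal(rownames(hm), w$wl$barcode_id)
  # neutral barcodes sit near 1 in non-target organs
  expect_equal(unname(hm["BC005", ]), rep(1, 5), tolerance = 0.15)
  # the planted barcode peaks in the lung column
  expect_equal(colnames(hm)[which.max(hm["BC001", ])], "lung")
  hr <- heatmap_matrix(norm, scale = "row")
  expect_equal(unname(apply(hr, 1, max)), rep(1, nrow(hr)))
})
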