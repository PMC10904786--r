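#' Read layout for b-DNA amplicons
#'
#' Positional contract for extracting barcode and UMI from a read. The
#' amplicon is `prefix + barcode + UMI + suffix`; coordinates are 0-based,
#' half-open, with the barcode region preceding the UMI. The default layout
#' (20 nt constant prefix, 8 nt barcode, 8 nt UMI, 20 nt constant suffix) is
#' a declared convention of this package, fully configurable and recorded in
#' run metadata.
#'
#' @param prefix_seq Constant 5' sequence (the extraction anchor).
#' @param barcode_len Barcode length, nt.
#' @param umi_len UMI length, nt.
#' @param suffix_seq Constant 3' sequence.
#' @return A list of class `bdna_layout` with the region coordinates.
#' @export
read_layout <- function(prefix_seq = "TCGGATCCTACGGTAACGCT",
                        barcode_len = 8L,
                        umi_len = 8L,
                        suffix_seq = "AGATCGGAAGAGCACACGTC") {
  stopifnot(barcode_len >= 1, umi_len >= 1)
  if (!grepl("^[ACGT]*$", prefix_seq) || !grepl("^[ACGT]*$", suffix_seq)) {
    stop("prefix/suffix must be ACGT strings")
  }
  layout <- list(
    prefix_seq = prefix_seq,
    suffix_seq = suffix_seq,
    prefix_len = nchar(prefix_seq),
    barcode_len = as.integer(barcode_len),
    umi_len = as.integer(umi_len),
    suffix_len = nchar(suffix_seq)
  )
  layout$total_len <- layout$prefix_len + layout$barcode_len +
    layout$umi_len + layout$suffix_len
  class(layout) <- "bdna_layout"
  layout
}

#' Generative model for a pooled biodistribution screen
#'
#' Describes how barcoded molecules distribute across organs and how they are
#' amplified and sequenced. Expected molecules for barcode b in organ o of
#' mouse m are
#' `molecules_per_organ * f_b * a_bo / sum_b'(f_b' * a_b'o) * exp(eps)`,
#' with `eps ~ Normal(0, mouse_sd^2)` independent per (mouse, barcode,
#' organ), realized as a Poisson draw. PCR is modelled as `pcr_cycles`
#' independent Bernoulli(`pcr_efficiency`) doubling rounds per molecule;
#' sequencing draws `reads_per_sample` reads from the amplified pool
#' (`NULL` emits every amplified copy) and applies i.i.d. per-base
#' substitution errors at `seq_error_rate`.
#'
#' @param whitelist Barcode whitelist (defines the barcode universe).
#' @param pool_fractions Named numeric simplex over `whitelist$barcode_id`
#'   (sums to 1); default uniform.
#' @param organ_affinity Barcode x organ matrix of multiplicative enrichment
#'   factors (1 = neutral); default all 1. Rownames = barcode_id, colnames =
#'   organs.
#' @param organs Organ panel; default heart, liver, spleen, lung, kidney.
#' @param mouse_sd SD of the log-normal per-(mouse, barcode, organ) noise.
#' @param molecules_per_organ Expected captured molecules per organ sample.
#' @param pcr_cycles,pcr_efficiency PCR doubling rounds and per-cycle
#'   duplication probability.
#' @param seq_error_rate Per-base substitution probability.
#' @param reads_per_sample Sequencing depth per sample; `NULL` = emit all
#'   amplified copies (only sensible for small `pcr_cycles`).
#' @param seed Root seed for the whole simulation.
#' @return A list of class `bdna_model`.
#' @export
biodistribution_model <- function(whitelist,
                                  pool_fractions = NULL,
                                  organ_affinity = NULL,
                                  organs = bdna_organs(),
                                  mouse_sd = 0.3,
                                  molecules_per_organ = 2e5,
                                  pcr_cycles = 16L,
                                  pcr_efficiency = 0.9,
                                  seq_error_rate = 1e-3,
                                  reads_per_sample = 2 * molecules_per_organ,
                                  seed = 1L) {
  ids <- whitelist$barcode_id
  if (is.null(pool_fractions)) {
    pool_fractions <- stats::setNames(rep(1 / length(ids), length(ids)), ids)
  }
  if (is.null(names(pool_fractions)) ||
      !setequal(names(pool_fractions), ids)) {
    stop("pool_fractions must be named by whitelist barcode_id")
  }
  pool_fractions <- pool_fractions[ids]
  if (abs(sum(pool_fractions) - 1) > 1e-9) {
    stop("pool_fractions must sum to 1 (got ", sum(pool_fractions), ")")
  }
  if (is.null(organ_affinity)) {
    organ_affinity <- matrix(1, nrow = length(ids), ncol = length(organs),
                             dimnames = list(ids, organs))
  }
  if (!all(ids %in% rownames(organ_affinity)) ||
      !all(organs %in% colnames(organ_affinity))) {
    stop("organ_affinity must cover all whitelist barcodes and organs")
  }
  organ_affinity <- organ_affinity[ids, organs, drop = FALSE]
  if (any(organ_affinity <= 0)) stop("all organ affinities must be > 0")
  stopifnot(mouse_sd >= 0, molecules_per_organ >= 0,
            pcr_cycles >= 0, pcr_efficiency >= 0, pcr_efficiency <= 1,
            seq_error_rate >= 0, seq_error_rate <= 1)
  structure(list(whitelist = wl_strip(whitelist),
                 pool_fractions = pool_fractions,
                 organ_affinity = organ_affinity,
                 organs = organs,
                 mouse_sd = mouse_sd,
                 molecules_per_organ = molecules_per_organ,
                 pcr_cycles = as.integer(pcr_cycles),
                 pcr_efficiency = pcr_efficiency,
                 seq_error_rate = seq_error_rate,
                 reads_per_sample = reads_per_sample,
                 seed = as.integer(seed)),
            class = "bdna_model")
}

wl_strip <- function(wl) {
  out <- as.data.frame(wl, stringsAsFactors = FALSE)
  attr(out, "barcode_len") <- attr(wl, "barcode_len")
  attr(out, "min_pairwise_hamming") <- attr(wl, "min_pairwise_hamming")
  out
}

#' Canonical organ panel
#'
#' Fixed order heart, liver, spleen, lung, kidney used for all tabular and
#' matrix output.
#' @return Character vector of organ names.
#' @export
bdna_organs <- function() c("heart", "liver", "spleen", "lung", "kidney")

#' Plant organ tropism into an affinity matrix
#'
#' Convenience builder: start from a neutral (all-1) matrix and set the
#' affinity of selected barcodes in one organ.
#'
#' @param whitelist Whitelist.
#' @param barcodes Barcode ids to modify.
#' @param organ Target organ.
#' @param affinity Multiplicative factor (> 1 enrichment, < 1 depletion).
#' @param base Optional existing matrix to modify.
#' @param organs Organ panel.
#' @return Barcode x organ affinity matrix.
#' @export
plant_tropism <- function(whitelist, barcodes, organ, affinity,
                          base = NULL, organs = bdna_organs()) {
  ids <- whitelist$barcode_id
  if (is.null(base)) {
    base <- matrix(1, nrow = length(ids), ncol = length(organs),
                   dimnames = list(ids, organs))
  }
  stopifnot(all(barcodes %in% ids), organ %in% colnames(base), affinity > 0)
  base[barcodes, organ] <- affinity
  base
}

#' Simulate ground-truth molecule counts per (mouse, organ, barcode)
#'
#' Draws the pre-PCR captured molecule counts for every tissue sample from
#' the biodistribution model (see [biodistribution_model()] for the
#' expectation formula). Deterministic given `model$seed`.
#'
#' @param model A `bdna_model`.
#' @param n_mice Number of mice (>= 1).
#' @param organs Organ list; defaults to the model's panel.
#' @return A data.frame (class `bdna_truth`) with columns `mouse`, `organ`,
#'   `barcode_id`, `molecules`, plus attribute `planted` (data.frame of
#'   non-neutral affinities: `barcode_id`, `organ`, `affinity`).
#' @export
simulate_biodistribution <- function(model, n_mice = 5L, organs = model$organs) {
  if (length(organs) == 0L) stop("organ list must be non-empty")
  stopifnot(n_mice >= 1)
  ids <- names(model$pool_fractions)
  nb <- length(ids)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  rows <- vector("list", n_mice * length(organs))
  k <- 0L
  for (m in seq_len(n_mice)) {
    for (o in organs) {
      k <- k + 1L
      set.seed(child_seed(model$seed, k))
      w <- model$pool_fractions * model$organ_affinity[, o]
      lambda <- model$molecules_per_organ * w / sum(w)
      if (model$mouse_sd > 0) {
        lambda <- lambda * exp(stats::rnorm(nb, 0, model$mouse_sd))
      }
      rows[[k]] <- data.frame(mouse = m, organ = o, barcode_id = ids,
                              molecules = stats::rpois(nb, lambda),
                              stringsAsFactors = FALSE)
    }
  }
  truth <- do.call(rbind, rows)
  aff <- model$organ_affinity
  nz <- which(aff != 1, arr.ind = TRUE)
  planted <- data.frame(barcode_id = rownames(aff)[nz[, 1]],
                        organ = colnames(aff)[nz[, 2]],
                        affinity = aff[nz],
                        stringsAsFactors = FALSE)
  attr(truth, "planted") <- planted
  class(truth) <- c("bdna_truth", "data.frame")
  truth
}

# Poisson draws of pool-reference molecule counts (uninjected pool aliquot).
simulate_pool_counts <- function(model, n_replicates = 1L) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  ids <- names(model$pool_fractions)
  rows <- lapply(seq_len(n_replicates), function(r) {
    set.seed(child_seed(model$seed, 100000L + r))
    data.frame(mouse = 0L, organ = "pool", replicate = r, barcode_id = ids,
               molecules = stats::rpois(length(ids),
                                        model$molecules_per_organ *
                                          model$pool_fractions),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Simulate the amplified, sequenced reads for one sample.
# mol_barcode_idx: 1-based whitelist row per captured molecule.
# Returns a character vector of read sequences; attribute "mol_of_read"
# gives the 1-based molecule index each read came from, "umi" the per-
# molecule UMI string.
# Exact distribution of the per-molecule copy number after `cycles` rounds
# of branching PCR (every copy duplicates independently with prob eff):
# P_{c+1}(y) = sum_x P_c(x) * dbinom(y - x, x, eff). Support is 1..2^cycles.
pcr_copy_distribution <- function(cycles, eff) {
  p <- c(1)  # P(X_0 = 1), index i = copy number i
  for (cy in seq_len(cycles)) {
    q <- numeric(2L * length(p))
    for (x in which(p > 0)) {
      q[x + 0:x] <- q[x + 0:x] + p[x] * stats::dbinom(0:x, x, eff)
    }
    p <- q
  }
  p
}

# Branching PCR copy numbers for n molecules: the first few cycles are
# drawn in one vectorized step from the exact DP distribution (the
# per-molecule trajectories are i.i.d. and Markov, so sampling the exact
# marginal and branching onward is distribution-identical), the remaining
# cycles run per molecule in C++.
draw_pcr_copies <- function(n_mol, cycles, eff) {
  if (cycles <= 0 || eff <= 0) return(rep(1, n_mol))
  if (eff >= 1) return(rep(2^cycles, n_mol))
  c0 <- min(cycles, 9L)
  dist <- pcr_copy_distribution(c0, eff)
  x0 <- sample.int(length(dist), n_mol, replace = TRUE, prob = dist)
  if (cycles == c0) return(as.numeric(x0))
  cpp_pcr_copies_from(x0, cycles - c0, eff)
}

simulate_sample_reads <- function(mol_barcode_idx, layout, whitelist, model,
                                  seed) {
  n_mol <- length(mol_barcode_idx)
  if (n_mol == 0L) {
    out <- character(0)
    attr(out, "mol_of_read") <- integer(0)
    attr(out, "umi") <- character(0)
    return(out)
  }
  rnd <- sample_read_randomness(n_mol, layout, model, seed)
  umi_str <- cpp_int_to_dna(rnd$umi_int, layout$umi_len)
  reads <- cpp_assemble_reads(layout$prefix_seq, whitelist$sequence,
                              as.integer(mol_barcode_idx), umi_str,
                              rnd$reads_per_mol, layout$suffix_seq,
                              rnd$eread, rnd$epos, rnd$eshift)
  attr(reads, "mol_of_read") <- rep.int(seq_len(n_mol), rnd$reads_per_mol)
  attr(reads, "umi") <- umi_str
  reads
}

# All stochastic draws for one sample, in a fixed order so that the
# FASTQ-producing and the fused in-memory paths are seed-identical:
# UMIs, PCR copy numbers, depth subsampling, substitution-error events.
sample_read_randomness <- function(n_mol, layout, model, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  umi_space <- 4^layout$umi_len
  umi_int <- if (umi_space <= .Machine$integer.max) {
    sample.int(umi_space, n_mol, replace = TRUE) - 1
  } else {
    floor(stats::runif(n_mol) * umi_space)
  }
  copies <- draw_pcr_copies(n_mol, model$pcr_cycles, model$pcr_efficiency)
  depth <- model$reads_per_sample
  if (is.null(depth)) {
    reads_per_mol <- as.integer(copies)
  } else {
    drawn <- sample.int(n_mol, size = depth, replace = TRUE, prob = copies)
    reads_per_mol <- tabulate(drawn, nbins = n_mol)
  }
  n_reads <- sum(reads_per_mol)
  eread <- integer(0)
  epos <- integer(0)
  eshift <- integer(0)
  if (model$seq_error_rate > 0 && n_reads > 0) {
    total_bases <- as.numeric(n_reads) * layout$total_len
    n_err <- stats::rbinom(1L, size = min(total_bases, .Machine$integer.max),
                           prob = model$seq_error_rate)
    if (n_err > 0) {
      eread <- sample.int(n_reads, n_err, replace = TRUE)
      epos <- sample.int(layout$total_len, n_err, replace = TRUE)
      eshift <- sample.int(3L, n_err, replace = TRUE)
      ord <- order(eread)
      eread <- eread[ord]
      epos <- epos[ord]
      eshift <- eshift[ord]
    }
  }
  list(umi_int = as.numeric(umi_int), reads_per_mol = reads_per_mol,
       eread = eread, epos = epos, eshift = eshift)
}

#' Simulate a full pooled screen
#'
#' Generates the complete stated experiment: per-(mouse, organ) tissue
#' samples plus uninjected-pool reference sample(s), each run through UMI
#' attachment, branching PCR and error-prone sequencing. Output is either
#' written as per-sample FASTQ files (when `out_dir` is given) or returned
#' as in-memory read vectors.
#'
#' @param model A `bdna_model`.
#' @param layout A `bdna_layout`.
#' @param n_mice Mice per organ panel.
#' @param n_pool_replicates Uninjected pool reference samples (>= 1).
#' @param out_dir Directory for FASTQ + TSV output, or `NULL` for in-memory.
#' @param gzip Write FASTQ gzip-compressed (only with `out_dir`).
#' @return A list of class `bdna_screen` with `sample_sheet` (columns
#'   `sample_id`, `mouse`, `organ`, `role`, `fastq`), `truth` (tissue truth
#'   table), `pool_truth`, `reads` (named list, `NULL` when written to disk),
#'   `model`, `layout`.
#' @export
simulate_screen <- function(model, layout = read_layout(), n_mice = 5L,
                            n_pool_replicates = 1L, out_dir = NULL,
                            gzip = FALSE) {
  if (n_mice < 1L) stop("validation error: n_mice must be >= 1")
  if (n_pool_replicates < 1L) stop("n_pool_replicates must be >= 1")
  if (attr(model$whitelist, "barcode_len") != layout$barcode_len) {
    stop("layout barcode_len does not match whitelist sequence length")
  }
  wl <- model$whitelist
  truth <- simulate_biodistribution(model, n_mice = n_mice)
  pool_truth <- simulate_pool_counts(model, n_pool_replicates)

  tissue_ids <- with(unique(truth[, c("mouse", "organ")]),
                     paste0("m", mouse, "_", organ))
  sheet <- unique(truth[, c("mouse", "organ")])
  sheet <- data.frame(sample_id = tissue_ids, mouse = sheet$mouse,
                      organ = sheet$organ, role = "tissue",
                      stringsAsFactors = FALSE)
  pool_sheet <- data.frame(sample_id = paste0("pool_", seq_len(n_pool_replicates)),
                           mouse = 0L, organ = "pool", role = "pool",
                           stringsAsFactors = FALSE)
  sheet <- rbind(sheet, pool_sheet)
  # relative file names keep the sample sheet portable across directories
  sheet$fastq <- if (is.null(out_dir)) NA_character_ else
    paste0(sheet$sample_id, ".fastq", if (gzip) ".gz")

  if (!is.null(out_dir) && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  reads_list <- if (is.null(out_dir)) vector("list", nrow(sheet)) else NULL
  bc_index <- stats::setNames(seq_len(nrow(wl)), wl$barcode_id)
  for (i in seq_len(nrow(sheet))) {
    sid <- sheet$sample_id[i]
    if (sheet$role[i] == "tissue") {
      sub <- truth[truth$mouse == sheet$mouse[i] & truth$organ == sheet$organ[i], ]
    } else {
      rep_i <- as.integer(sub("pool_", "", sid))
      sub <- pool_truth[pool_truth$replicate == rep_i, ]
    }
    mol_bc <- rep.int(unname(bc_index[sub$barcode_id]), sub$molecules)
    reads <- simulate_sample_reads(mol_bc, layout, wl, model,
                                   seed = child_seed(model$seed, 200000L + i))
    if (is.null(out_dir)) {
      attributes(reads) <- NULL
      reads_list[[i]] <- reads
    } else {
      write_fastq(reads, file.path(out_dir, sheet$fastq[i]), sid,
                  layout$total_len)
    }
  }
  if (is.null(out_dir)) names(reads_list) <- sheet$sample_id

  if (!is.null(out_dir)) {
    write_whitelist(wl, file.path(out_dir, "whitelist.tsv"))
    utils::write.table(sheet, file.path(out_dir, "sample_sheet.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(truth, file.path(out_dir, "truth_tissue.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(pool_truth, file.path(out_dir, "truth_pool.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  structure(list(sample_sheet = sheet, truth = truth, pool_truth = pool_truth,
                 reads = reads_list, model = model, layout = layout),
            class = "bdna_screen")
}

write_fastq <- function(reads, path, sample_id, read_len) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con), add = TRUE)
  n <- length(reads)
  if (n == 0L) return(invisible(path))
  qual <- strrep("I", read_len)
  block <- character(4L * n)
  block[seq(1L, 4L * n, 4L)] <- paste0("@", sample_id, ":", seq_len(n))
  block[seq(2L, 4L * n, 4L)] <- reads
  block[seq(3L, 4L * n, 4L)] <- "+"
  block[seq(4L, 4L * n, 4L)] <- qual
  writeLines(block, con)
  invisible(path)
}

#' Read sequences from a 4-line FASTQ file
#' @param path FASTQ path (`.gz` accepted).
#' @return Character vector of read sequences.
#' @export
read_fastq_seqs <- function(path) {
  con <- gzfile(path, "r")
  on.exit(close(con), add = TRUE)
  lines <- readLines(con)
  if (length(lines) %% 4L != 0L) {
    stop("malformed FASTQ (line count not a multiple of 4): ", path)
  }
  if (length(lines) == 0L) return(character(0))
  lines[seq(2L, length(lines), 4L)]
}

#' Simulate and quantify a screen sample-by-sample
#'
#' Fused driver for calibration studies: each sample's reads are simulated,
#' quantified and discarded before the next sample is touched, so memory
#' stays at one sample's reads. Statistically identical to
#' [simulate_screen()] followed by [build_count_table()] on the same seeds.
#'
#' @inheritParams simulate_screen
#' @param max_mm,anchor_max_mm,method Quantification settings, see
#'   [build_count_table()].
#' @return A list with `counts` (a `bdna_counts`), `truth`, `pool_truth`
#'   and `planted`.
#' @export
simulate_and_quantify <- function(model, layout = read_layout(), n_mice = 5L,
                                  n_pool_replicates = 1L, max_mm = 1L,
                                  anchor_max_mm = 2L,
                                  method = c("directional", "unique")) {
  method <- match.arg(method)
  wl <- model$whitelist
  truth <- simulate_biodistribution(model, n_mice = n_mice)
  pool_truth <- simulate_pool_counts(model, n_pool_replicates)
  tis <- unique(truth[, c("mouse", "organ")])
  sheet <- data.frame(sample_id = paste0("m", tis$mouse, "_", tis$organ),
                      mouse = tis$mouse, organ = tis$organ, role = "tissue",
                      stringsAsFactors = FALSE)
  sheet <- rbind(sheet, data.frame(
    sample_id = paste0("pool_", seq_len(n_pool_replicates)),
    mouse = 0L, organ = "pool", role = "pool", stringsAsFactors = FALSE))
  sheet$fastq <- NA_character_

  nb <- nrow(wl)
  ns <- nrow(sheet)
  counts <- matrix(0L, nb, ns, dimnames = list(wl$barcode_id, sheet$sample_id))
  ucounts <- counts
  rcounts <- counts
  qc <- data.frame(sample_id = sheet$sample_id, reads_in = 0, anchor_fail = 0,
                   unmatched = 0, ambiguous = 0, assigned = 0, molecules = 0,
                   dedup_ratio = NA_real_, stringsAsFactors = FALSE)
  bc_index <- stats::setNames(seq_len(nb), wl$barcode_id)
  for (i in seq_len(ns)) {
    if (sheet$role[i] == "tissue") {
      sub <- truth[truth$mouse == sheet$mouse[i] &
                     truth$organ == sheet$organ[i], ]
    } else {
      rep_i <- as.integer(sub("pool_", "", sheet$sample_id[i]))
      sub <- pool_truth[pool_truth$replicate == rep_i, ]
    }
    mol_bc <- rep.int(unname(bc_index[sub$barcode_id]), sub$molecules)
    rnd <- sample_read_randomness(length(mol_bc), layout, model,
                                  seed = child_seed(model$seed, 200000L + i))
    # byte-level fusion of read assembly and quantification; seed-identical
    # to simulate_sample_reads() + cpp_quantify_sample()
    dd <- cpp_sim_quant_sample(layout$prefix_seq, wl$sequence,
                               as.integer(mol_bc), rnd$umi_int,
                               rnd$reads_per_mol, layout$suffix_seq,
                               rnd$eread, rnd$epos, rnd$eshift,
                               layout$umi_len, as.integer(anchor_max_mm),
                               as.integer(max_mm))
    counts[, i] <- dd$directional
    ucounts[, i] <- dd$unique
    rcounts[, i] <- dd$reads
    qc$reads_in[i] <- dd$reads_in
    qc$anchor_fail[i] <- dd$anchor_fail
    qc$unmatched[i] <- dd$unmatched
    qc$ambiguous[i] <- dd$ambiguous
    qc$assigned[i] <- dd$assigned
    qc$molecules[i] <- sum(dd$directional)
    qc$dedup_ratio[i] <- if (dd$assigned > 0) sum(dd$directional) / dd$assigned
                         else NA_real_
  }
  if (method == "unique") counts <- ucounts
  cc <- structure(list(counts = counts, unique_counts = ucounts,
                       read_counts = rcounts, samples = sheet, qc = qc),
                  class = "bdna_counts")
  list(counts = cc, truth = truth, pool_truth = pool_truth,
       planted = attr(truth, "planted"))
}

#' Per-formulation dose in an evenly split pool
#'
#' Bookkeeping for pooled administration: a total nucleic-acid dose split
#' evenly across the pooled formulations. For the default 96-LNP pool at
#' 1.0 mg/kg total this is ~0.01 mg/kg per formulation.
#'
#' @param total_dose_mg_kg Total pooled dose (mg per kg body weight).
#' @param n_formulations Number of formulations in the pool.
#' @return Dose per formulation, mg/kg.
#' @export
pool_dose_per_formulation <- function(total_dose_mg_kg = 1.0,
                                      n_formulations = 96L) {
  stopifnot(total_dose_mg_kg > 0, n_formulations >= 1)
  total_dose_mg_kg / n_formulations
}
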