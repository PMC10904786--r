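#' Extract barcode and UMI regions from reads
#'
#' Positional extraction against a [read_layout()]: the observed prefix must
#' match the layout's constant prefix within `anchor_max_mm` mismatches
#' (an `N` counts as a mismatch), otherwise the read fails the anchor check.
#' Reads shorter than the layout also fail the anchor (counted, not fatal).
#'
#' @param reads Character vector of read sequences.
#' @param layout A `bdna_layout`.
#' @param anchor_max_mm Maximum prefix mismatches (default 2).
#' @return A list with `status` (`"ok"` or `"anchor_fail"` per read),
#'   `barcode` and `umi` (NA where the anchor failed).
#' @export
extract_barcode_umi <- function(reads, layout, anchor_max_mm = 2L) {
  n <- length(reads)
  status <- rep("ok", n)
  len_ok <- nchar(reads) >= layout$total_len
  status[!len_ok] <- "anchor_fail"
  prefix_obs <- substr(reads, 1L, layout$prefix_len)
  mm <- cpp_hamming_to(prefix_obs, layout$prefix_seq)
  status[len_ok & (is.na(mm) | mm > anchor_max_mm)] <- "anchor_fail"
  bc_start <- layout$prefix_len + 1L
  umi_start <- bc_start + layout$barcode_len
  barcode <- ifelse(status == "ok",
                    substr(reads, bc_start, umi_start - 1L), NA_character_)
  umi <- ifelse(status == "ok",
                substr(reads, umi_start, umi_start + layout$umi_len - 1L),
                NA_character_)
  list(status = status, barcode = barcode, umi = umi)
}

#' Assign barcode sequences to a whitelist with mismatch tolerance
#'
#' Exact matches win; otherwise the unique whitelist entry within Hamming
#' distance `max_mm` is assigned. Sequences with two or more entries at the
#' minimal distance are `ambiguous` (discarded downstream, never randomly
#' assigned); sequences farther than `max_mm` from every entry are
#' `unmatched`. Unambiguous correction requires a whitelist minimum pairwise
#' distance of at least `2 * max_mm + 1`; a warning is raised otherwise.
#'
#' @param barcode_seq Character vector of observed barcode sequences.
#' @param whitelist Whitelist data.frame.
#' @param max_mm Maximum mismatches for correction (default 1).
#' @return A list with `barcode_id` (NA when not assigned) and `status`
#'   (`assigned`, `unmatched`, `ambiguous` per sequence).
#' @export
match_whitelist <- function(barcode_seq, whitelist, max_mm = 1L) {
  min_d <- attr(whitelist, "min_pairwise_hamming")
  if (is.null(min_d) && nrow(whitelist) >= 2L) {
    min_d <- cpp_min_pairwise_hamming(whitelist$sequence)
  }
  if (!is.null(min_d) && !is.na(min_d) && min_d < 2L * max_mm + 1L) {
    warning("whitelist min pairwise distance ", min_d,
            " < 2*max_mm+1 = ", 2L * max_mm + 1L,
            "; correction may be ambiguous")
  }
  idx <- cpp_match_whitelist(barcode_seq, whitelist$sequence,
                             as.integer(max_mm))
  status <- rep("assigned", length(idx))
  status[idx == 0L] <- "unmatched"
  status[idx == -1L] <- "ambiguous"
  barcode_id <- rep(NA_character_, length(idx))
  barcode_id[idx > 0L] <- whitelist$barcode_id[idx[idx > 0L]]
  list(barcode_id = barcode_id, status = status)
}

#' Collapse UMIs into molecule counts
#'
#' `directional` (default) builds the adjacency network over distinct UMIs:
#' a directed edge u -> v exists iff Hamming(u, v) = 1 and
#' count(u) >= 2 * count(v) - 1. Nodes are visited by decreasing read count
#' (ties broken lexicographically); each unvisited node seeds one molecule
#' and absorbs everything reachable. `unique` simply counts distinct UMIs.
#'
#' @param umi_counts Named numeric vector: names are UMI sequences (equal
#'   length), values are read counts.
#' @param method `"directional"` or `"unique"`.
#' @return Integer molecule count (0 for empty input).
#' @export
#' @examples
#' collapse_umis(c(AAAA = 10, AAAT = 4, CCCC = 3))  # 2
collapse_umis <- function(umi_counts, method = c("directional", "unique")) {
  method <- match.arg(method)
  if (length(umi_counts) == 0L) return(0L)
  umis <- names(umi_counts)
  if (is.null(umis)) stop("umi_counts must be named by UMI sequence")
  if (length(unique(nchar(umis))) != 1L) stop("UMIs must have equal length")
  if (anyDuplicated(umis)) stop("duplicate UMIs in umi_counts")
  if (method == "unique") return(length(umis))
  cpp_collapse_directional(umis, as.numeric(umi_counts))
}

#' Quantify barcodes from FASTQ into a deduplicated count table
#'
#' Per sample: extract barcode/UMI positionally, assign barcodes to the
#' whitelist with mismatch tolerance, group assigned reads by barcode and
#' collapse UMIs (directional scheme) into molecule counts. UMIs containing
#' ambiguous bases are dropped before collapse. Processing is sequential per
#' sample, so memory scales with one sample's reads plus the distinct
#' (barcode, UMI) pairs.
#'
#' @param fastq Either a directory containing `<sample_id>.fastq[.gz]`
#'   files, a named character vector of file paths, or a named list of
#'   in-memory read vectors; names must cover `sample_sheet$sample_id`.
#' @param sample_sheet data.frame with columns `sample_id`, `mouse`,
#'   `organ`, `role`.
#' @param whitelist Whitelist data.frame.
#' @param layout A `bdna_layout`.
#' @param max_mm Barcode correction tolerance (default 1).
#' @param anchor_max_mm Prefix anchor tolerance (default 2).
#' @param method UMI collapse method for the `counts` matrix.
#' @param verbose Emit one log line per sample.
#' @return An object of class `bdna_counts`: list with `counts` (barcode x
#'   sample integer matrix of deduplicated molecules), `unique_counts`
#'   (distinct-UMI counts), `read_counts` (assigned reads), `samples`
#'   (sample sheet) and `qc` (per-sample reads_in, anchor_fail, unmatched,
#'   ambiguous, assigned, molecules, dedup_ratio).
#' @export
build_count_table <- function(fastq, sample_sheet, whitelist,
                              layout = read_layout(), max_mm = 1L,
                              anchor_max_mm = 2L,
                              method = c("directional", "unique"),
                              verbose = FALSE) {
  method <- match.arg(method)
  validate_whitelist(whitelist)
  required <- c("sample_id", "mouse", "organ", "role")
  missing <- setdiff(required, names(sample_sheet))
  if (length(missing) > 0L) {
    stop("sample sheet missing columns: ", paste(missing, collapse = ", "))
  }
  samples <- sample_sheet$sample_id
  get_reads <- resolve_fastq_source(fastq, samples)

  nb <- nrow(whitelist)
  ns <- length(samples)
  counts <- matrix(0L, nb, ns, dimnames = list(whitelist$barcode_id, samples))
  ucounts <- counts
  rcounts <- counts
  qc <- data.frame(sample_id = samples, reads_in = 0L, anchor_fail = 0L,
                   unmatched = 0L, ambiguous = 0L, assigned = 0L,
                   molecules = 0L, dedup_ratio = NA_real_,
                   stringsAsFactors = FALSE)
  min_d <- attr(whitelist, "min_pairwise_hamming")
  if (!is.null(min_d) && !is.na(min_d) && min_d < 2L * max_mm + 1L) {
    warning("whitelist min pairwise distance ", min_d,
            " < 2*max_mm+1; barcode correction may be ambiguous")
  }
  for (j in seq_len(ns)) {
    reads <- get_reads(samples[j])
    dd <- cpp_quantify_sample(reads, layout$prefix_seq,
                              as.integer(anchor_max_mm),
                              whitelist$sequence, as.integer(max_mm),
                              layout$barcode_len, layout$umi_len,
                              layout$total_len)
    qc$reads_in[j] <- dd$reads_in
    qc$anchor_fail[j] <- dd$anchor_fail
    qc$unmatched[j] <- dd$unmatched
    qc$ambiguous[j] <- dd$ambiguous
    qc$assigned[j] <- dd$assigned
    counts[, j] <- dd$directional
    ucounts[, j] <- dd$unique
    rcounts[, j] <- dd$reads
    qc$molecules[j] <- sum(dd$directional)
    qc$dedup_ratio[j] <- if (qc$assigned[j] > 0)
      qc$molecules[j] / qc$assigned[j] else NA_real_
    if (verbose) {
      message(sprintf("quantify sample=%s reads_in=%d assigned=%d molecules=%d",
                      samples[j], qc$reads_in[j], qc$assigned[j],
                      qc$molecules[j]))
    }
  }
  if (method == "unique") counts <- ucounts
  structure(list(counts = counts, unique_counts = ucounts,
                 read_counts = rcounts, samples = sample_sheet, qc = qc),
            class = "bdna_counts")
}

resolve_fastq_source <- function(fastq, samples) {
  if (is.list(fastq)) {
    missing <- setdiff(samples, names(fastq))
    if (length(missing) > 0L) {
      stop("samples missing from in-memory FASTQ set: ",
           paste(missing, collapse = ", "))
    }
    return(function(sid) fastq[[sid]])
  }
  if (is.character(fastq) && length(fastq) == 1L && dir.exists(fastq)) {
    paths <- stats::setNames(rep(NA_character_, length(samples)), samples)
    for (sid in samples) {
      cand <- file.path(fastq, paste0(sid, c(".fastq", ".fastq.gz")))
      hit <- cand[file.exists(cand)]
      if (length(hit) > 0L) paths[sid] <- hit[1]
    }
    if (anyNA(paths)) {
      stop("no FASTQ found for sample(s): ",
           paste(names(paths)[is.na(paths)], collapse = ", "))
    }
    return(function(sid) read_fastq_seqs(paths[[sid]]))
  }
  if (is.character(fastq)) {
    missing <- setdiff(samples, names(fastq))
    if (length(missing) > 0L) {
      stop("samples missing from FASTQ path set: ",
           paste(missing, collapse = ", "))
    }
    absent <- fastq[samples][!file.exists(fastq[samples])]
    if (length(absent) > 0L) {
      stop("FASTQ file(s) do not exist: ", paste(absent, collapse = ", "))
    }
    return(function(sid) read_fastq_seqs(fastq[[sid]]))
  }
  stop("fastq must be a directory, named file paths, or named read vectors")
}

#' Write a count table and its QC to TSV
#' @param counts A `bdna_counts` object.
#' @param dir Output directory.
#' @param prefix File-name prefix.
#' @return Paths written, invisibly.
#' @export
write_count_table <- function(counts, dir, prefix = "counts") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  cpath <- file.path(dir, paste0(prefix, ".tsv"))
  qpath <- file.path(dir, paste0(prefix, "_qc.tsv"))
  tab <- data.frame(barcode_id = rownames(counts$counts), counts$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, cpath, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(counts$qc, qpath, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(cpath, qpath))
}

#' Read a count table TSV (plus sample sheet) back into a `bdna_counts`
#' @param path Count TSV (first column `barcode_id`).
#' @param sample_sheet Sample sheet data.frame or TSV path.
#' @return A `bdna_counts` object (QC absent).
#' @export
read_count_table <- function(path, sample_sheet) {
  tab <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(tab)[1] != "barcode_id") stop("first column must be barcode_id")
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab$barcode_id
  storage.mode(m) <- "integer"
  if (is.character(sample_sheet)) {
    sample_sheet <- utils::read.delim(sample_sheet, stringsAsFactors = FALSE)
  }
  missing <- setdiff(sample_sheet$sample_id, colnames(m))
  if (length(missing) > 0L) {
    stop("count table missing sample column(s): ",
         paste(missing, collapse = ", "))
  }
  m <- m[, sample_sheet$sample_id, drop = FALSE]
  structure(list(counts = m, unique_counts = NULL, read_counts = NULL,
                 samples = sample_sheet, qc = NULL),
            class = "bdna_counts")
}

#' Build a `bdna_counts` object directly from simulated truth
#'
#' Skips the read level entirely: the pre-PCR molecule counts of a
#' simulated screen become the deduplicated counts. Useful for fast
#' statistical calibration studies where sequencing noise is not the object
#' under test.
#'
#' @param screen A `bdna_screen` (or a list with `truth` and `pool_truth`).
#' @return A `bdna_counts` object.
#' @export
counts_from_truth <- function(screen) {
  truth <- screen$truth
  pool <- screen$pool_truth
  ids <- unique(truth$barcode_id)
  sheet <- screen$sample_sheet
  if (is.null(sheet)) {
    tis <- unique(truth[, c("mouse", "organ")])
    sheet <- data.frame(sample_id = paste0("m", tis$mouse, "_", tis$organ),
                        mouse = tis$mouse, organ = tis$organ, role = "tissue",
                        stringsAsFactors = FALSE)
    if (!is.null(pool)) {
      sheet <- rbind(sheet, data.frame(
        sample_id = paste0("pool_", unique(pool$replicate)), mouse = 0L,
        organ = "pool", role = "pool", stringsAsFactors = FALSE))
    }
    sheet$fastq <- NA_character_
  }
  m <- matrix(0L, length(ids), nrow(sheet),
              dimnames = list(ids, sheet$sample_id))
  for (j in seq_len(nrow(sheet))) {
    if (sheet$role[j] == "tissue") {
      sub <- truth[truth$mouse == sheet$mouse[j] &
                     truth$organ == sheet$organ[j], ]
    } else {
      rep_i <- as.integer(sub("pool_", "", sheet$sample_id[j]))
      sub <- pool[pool$replicate == rep_i, ]
    }
    m[sub$barcode_id, j] <- as.integer(sub$molecules)
  }
  structure(list(counts = m, unique_counts = NULL, read_counts = NULL,
                 samples = sheet, qc = NULL),
            class = "bdna_counts")
}
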