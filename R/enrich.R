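#' Within-sample barcode fractions
#'
#' Converts deduplicated counts into pseudocount-stabilized per-sample
#' fractions: `fraction(b, s) = (count + pseudocount) / sum_b(count +
#' pseudocount)`. Samples whose raw column total is zero are excluded with a
#' warning. Control barcodes (naked b-DNA) stay in the denominator but are
#' flagged for downstream reporting.
#'
#' @param counts A `bdna_counts` object (or a bare barcode x sample matrix
#'   plus `sample_sheet`).
#' @param pseudocount Non-negative stabilizer added to every count
#'   (default 0.5).
#' @param control_barcodes Barcode ids of spiked controls; defaults to ids
#'   matching `"naked"` (case-insensitive).
#' @param sample_sheet Required when `counts` is a bare matrix.
#' @return An object of class `bdna_norm` with `fractions` (barcode x
#'   sample), `samples`, `control_barcodes`, `pseudocount`. Pool
#'   normalization fields are added by [normalize_to_pool()].
#' @export
normalize_within_sample <- function(counts, pseudocount = 0.5,
                                    control_barcodes = NULL,
                                    sample_sheet = NULL) {
  if (inherits(counts, "bdna_counts")) {
    m <- counts$counts
    sheet <- counts$samples
  } else {
    m <- counts
    sheet <- sample_sheet
    if (is.null(sheet)) stop("sample_sheet required with a bare matrix")
  }
  stopifnot(pseudocount >= 0)
  if (any(m < 0)) stop("counts must be non-negative")
  keep <- colSums(m) > 0
  if (!all(keep)) {
    warning("excluding all-zero sample(s): ",
            paste(colnames(m)[!keep], collapse = ", "))
    m <- m[, keep, drop = FALSE]
    sheet <- sheet[sheet$sample_id %in% colnames(m), , drop = FALSE]
  }
  if (ncol(m) == 0L) stop("no usable samples (all columns zero)")
  if (is.null(control_barcodes)) {
    control_barcodes <- rownames(m)[grepl("naked", rownames(m),
                                          ignore.case = TRUE)]
  }
  mm <- m + pseudocount
  fractions <- sweep(mm, 2L, colSums(mm), "/")
  structure(list(fractions = fractions, samples = sheet,
                 control_barcodes = control_barcodes,
                 pseudocount = pseudocount,
                 pool_fractions = NULL, norm = NULL, n_pool = 0L),
            class = "bdna_norm")
}

#' Pool ("basemean") normalization
#'
#' Divides each barcode's within-tissue fraction by its fraction in the
#' uninjected LNP pool reference (averaged over pool replicates), yielding
#' the normalized accumulation used for heatmaps, volcano plots and tropism
#' calls. Values > 1 mean over-representation relative to the injected pool.
#'
#' @param norm A `bdna_norm` from [normalize_within_sample()].
#' @param pool_fractions Optional externally supplied pool fraction vector
#'   (named by barcode); by default computed from samples with
#'   `role == "pool"`.
#' @return The `bdna_norm` with `pool_fractions`, `n_pool` and `norm`
#'   (barcode x tissue-sample normalized accumulation matrix) filled in.
#' @export
normalize_to_pool <- function(norm, pool_fractions = NULL) {
  stopifnot(inherits(norm, "bdna_norm"))
  sheet <- norm$samples
  pool_cols <- sheet$sample_id[sheet$role == "pool"]
  if (is.null(pool_fractions)) {
    if (length(pool_cols) < 1L) {
      stop("no pool sample in sheet and no pool_fractions supplied")
    }
    pool_fractions <- rowMeans(norm$fractions[, pool_cols, drop = FALSE])
  } else {
    missing <- setdiff(rownames(norm$fractions), names(pool_fractions))
    if (length(missing) > 0L) {
      stop("pool_fractions missing barcode(s): ",
           paste(utils::head(missing, 5), collapse = ", "))
    }
    pool_fractions <- pool_fractions[rownames(norm$fractions)]
  }
  tissue_cols <- sheet$sample_id[sheet$role == "tissue"]
  tissue_cols <- intersect(tissue_cols, colnames(norm$fractions))
  norm$pool_fractions <- pool_fractions
  norm$n_pool <- length(pool_cols)
  norm$norm <- norm$fractions[, tissue_cols, drop = FALSE] / pool_fractions
  norm
}

#' Two-sided Wilcoxon rank-sum test
#'
#' Exact permutation p-value (via the null rank-sum distribution) when
#' `length(x) + length(y) <= 20` and there are no ties, two-sided by
#' doubling the smaller tail (capped at 1). Otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param x,y Numeric samples (each non-empty).
#' @return Two-sided p-value in (0, 1].
#' @export
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))  # 0.1
wilcoxon_rank_sum <- function(x, y) {
  if (length(x) < 1L || length(y) < 1L) stop("both samples must be non-empty")
  if (any(!is.finite(c(x, y)))) stop("samples must be finite")
  n <- length(x)
  m <- length(y)
  ties <- anyDuplicated(c(x, y)) > 0L
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n)])
  if (!ties && n + m <= 20L) {
    u <- w - n * (n + 1) / 2
    lower <- stats::pwilcox(u, n, m)
    upper <- 1 - stats::pwilcox(u - 1, n, m)
    return(min(1, 2 * min(lower, upper)))
  }
  N <- n + m
  mu <- n * (N + 1) / 2
  tie_tab <- table(c(x, y))
  sigma2 <- n * m / 12 * ((N + 1) - sum(tie_tab^3 - tie_tab) / (N * (N - 1)))
  if (sigma2 <= 0) return(1)
  d <- w - mu
  z <- (d - sign(d) * 0.5) / sqrt(sigma2)
  min(1, 2 * stats::pnorm(-abs(z)))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: on sorted p-values, `q_(i) = min_{j >= i} min(1,
#' p_(j) * m / j)`, mapped back to the input order.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(is.na(p)) || any(p < 0) || any(p > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  m <- length(p)
  ord <- order(p)
  qs <- p[ord] * m / seq_len(m)
  qs <- rev(cummin(rev(qs)))
  qs <- pmin(qs, 1)
  out <- numeric(m)
  out[ord] <- qs
  out
}

#' Per-(barcode, organ) enrichment analysis
#'
#' For each organ, tests every barcode's per-mouse normalized accumulation
#' for enrichment. The default `one_vs_rest` comparison tests barcode b's n
#' per-mouse values against the pooled per-mouse values of all other
#' (non-control) barcodes in that organ; `vs_pool_replicates` tests b's
#' tissue fractions against its pool-replicate fractions and requires at
#' least 3 pool replicates. The Benjamini-Hochberg adjustment is applied per
#' organ across (non-control) barcodes. The log2 fold-change is the median
#' over mice of log2 normalized accumulation.
#'
#' @param norm A pool-normalized `bdna_norm` (see [normalize_to_pool()]).
#' @param comparison `"one_vs_rest"` (default) or `"vs_pool_replicates"`.
#' @param fc_threshold log2 fold-change call threshold (default 1).
#' @param q_threshold FDR call threshold (default 0.05).
#' @param bh_scope `"per_organ"` (default) or `"global"` BH adjustment.
#' @return data.frame of class `bdna_enrichment`: `barcode_id`, `organ`,
#'   `log2fc`, `p_value`, `q_value`, `call` (`enriched` / `depleted` /
#'   `neutral`), `is_control`.
#' @export
enrichment_analysis <- function(norm,
                                comparison = c("one_vs_rest",
                                               "vs_pool_replicates"),
                                fc_threshold = 1, q_threshold = 0.05,
                                bh_scope = c("per_organ", "global")) {
  comparison <- match.arg(comparison)
  bh_scope <- match.arg(bh_scope)
  stopifnot(inherits(norm, "bdna_norm"))
  if (is.null(norm$norm)) stop("run normalize_to_pool() first")
  sheet <- norm$samples
  tissue <- sheet[sheet$role == "tissue", , drop = FALSE]
  organs <- unique(tissue$organ)
  ids <- rownames(norm$norm)
  ctrl <- ids %in% norm$control_barcodes
  if (comparison == "vs_pool_replicates" && norm$n_pool < 3L) {
    stop("vs_pool_replicates needs >= 3 pool replicates (have ",
         norm$n_pool, "); use comparison = 'one_vs_rest'")
  }
  pool_cols <- sheet$sample_id[sheet$role == "pool"]
  records <- vector("list", length(organs))
  for (oi in seq_along(organs)) {
    o <- organs[oi]
    cols <- tissue$sample_id[tissue$organ == o]
    if (length(cols) < 2L) {
      stop("organ '", o, "' has fewer than 2 mice")
    }
    mat <- norm$norm[, cols, drop = FALSE]
    log2fc <- apply(mat, 1L, function(v) stats::median(log2(v)))
    pv <- rep(NA_real_, length(ids))
    for (b in seq_along(ids)) {
      x <- mat[b, ]
      if (comparison == "one_vs_rest") {
        rest <- which(!ctrl & seq_along(ids) != b)
        y <- as.vector(mat[rest, , drop = FALSE])
      } else {
        y <- as.numeric(norm$fractions[b, pool_cols] / norm$pool_fractions[b])
        x <- as.numeric(norm$fractions[b, cols] / norm$pool_fractions[b])
      }
      pv[b] <- wilcoxon_rank_sum(x, y)
    }
    qv <- rep(NA_real_, length(ids))
    qv[!ctrl] <- bh_adjust(pv[!ctrl])
    records[[oi]] <- data.frame(barcode_id = ids, organ = o, log2fc = log2fc,
                                p_value = pv, q_value = qv,
                                is_control = ctrl, stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, records)
  if (bh_scope == "global") {
    ok <- !rec$is_control
    rec$q_value[ok] <- bh_adjust(rec$p_value[ok])
  }
  rec$call <- "neutral"
  sig <- !is.na(rec$q_value) & rec$q_value <= q_threshold
  rec$call[sig & rec$log2fc >= fc_threshold] <- "enriched"
  rec$call[sig & rec$log2fc <= -fc_threshold] <- "depleted"
  rownames(rec) <- NULL
  class(rec) <- c("bdna_enrichment", "data.frame")
  attr(rec, "comparison") <- comparison
  attr(rec, "fc_threshold") <- fc_threshold
  attr(rec, "q_threshold") <- q_threshold
  rec
}

#' Call organ-tropic candidate formulations
#'
#' A barcode is a candidate for the organ of interest iff it is enriched
#' there (log2 FC >= `fc_threshold` and q <= `q_threshold`) and NOT enriched
#' in every off-target organ (log2 FC < `fc_threshold` or q >
#' `q_threshold`). Control barcodes are never candidates.
#'
#' @param records A `bdna_enrichment` data.frame.
#' @param organ_of_interest Target organ (default `"lung"`).
#' @param off_targets Organs that must not be enriched (default liver and
#'   spleen).
#' @param fc_threshold,q_threshold Call thresholds (log2 scale, FDR).
#' @return Character vector of candidate barcode ids (possibly empty).
#' @export
classify_tropism <- function(records, organ_of_interest = "lung",
                             off_targets = c("liver", "spleen"),
                             fc_threshold = 1, q_threshold = 0.05) {
  needed <- c(organ_of_interest, off_targets)
  have <- unique(records$organ)
  missing <- setdiff(needed, have)
  if (length(missing) > 0L) {
    stop("organ(s) missing from records: ", paste(missing, collapse = ", "))
  }
  enriched_in <- function(o) {
    r <- records[records$organ == o & !records$is_control, ]
    r$barcode_id[!is.na(r$q_value) & r$q_value <= q_threshold &
                   r$log2fc >= fc_threshold]
  }
  cand <- enriched_in(organ_of_interest)
  for (o in off_targets) cand <- setdiff(cand, enriched_in(o))
  cand
}

#' Barcode x organ accumulation matrix for heatmaps
#'
#' Mouse-median normalized accumulation per (barcode, organ), rows in the
#' whitelist/count order, columns in the fixed organ order (heart, liver,
#' spleen, lung, kidney; organs absent from the data are dropped).
#'
#' @param norm A pool-normalized `bdna_norm`.
#' @param scale `"none"` (default), `"row"` (each row divided by its max,
#'   mapping the row max to 1) or `"column"`.
#' @return Numeric matrix.
#' @export
heatmap_matrix <- function(norm, scale = c("none", "row", "column")) {
  scale <- match.arg(scale)
  stopifnot(inherits(norm, "bdna_norm"))
  if (is.null(norm$norm)) stop("run normalize_to_pool() first")
  sheet <- norm$samples
  tissue <- sheet[sheet$role == "tissue", , drop = FALSE]
  organs <- intersect(bdna_organs(), unique(tissue$organ))
  if (length(organs) == 0L) organs <- unique(tissue$organ)
  out <- sapply(organs, function(o) {
    cols <- tissue$sample_id[tissue$organ == o]
    apply(norm$norm[, cols, drop = FALSE], 1L, stats::median)
  })
  out <- matrix(out, nrow = nrow(norm$norm),
                dimnames = list(rownames(norm$norm), organs))
  if (scale == "row") {
    mx <- apply(out, 1L, max)
    out <- out / ifelse(mx > 0, mx, 1)
  } else if (scale == "column") {
    mx <- apply(out, 2L, max)
    out <- sweep(out, 2L, ifelse(mx > 0, mx, 1), "/")
  }
  out
}
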