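#' Design a barcode whitelist by rejection sampling
#'
#' Samples random DNA barcodes of fixed length and accepts a candidate only
#' if (i) it contains no homopolymer run longer than 3 nt and (ii) its
#' Hamming distance to every already-accepted barcode is at least `min_dist`.
#' A minimum pairwise distance of `2 * max_mm + 1` guarantees unambiguous
#' single-pass error correction at `max_mm` mismatches downstream.
#'
#' @param n Number of barcodes (>= 1).
#' @param barcode_len Barcode length in nt.
#' @param min_dist Minimum pairwise Hamming distance (>= 1).
#' @param seed Integer seed; the design is deterministic given the seed.
#' @param lnp_names Optional character vector of length `n` assigning a
#'   formulation name to each barcode; defaults to `LNP-CAD1 ... LNP-CADn`.
#' @param naked_control If `TRUE` (default) an extra barcode named
#'   `"naked_control"` is appended (unencapsulated b-DNA spiked into the
#'   injection as a negative control), also honouring `min_dist`.
#' @param max_attempts Attempt budget per barcode before a capacity error.
#' @return A data.frame (class `bdna_whitelist`) with columns `barcode_id`,
#'   `sequence`, `lnp_name`, and attributes `barcode_len` and
#'   `min_pairwise_hamming`.
#' @export
#' @examples
#' wl <- design_whitelist(n = 8, barcode_len = 8, min_dist = 3, seed = 1)
design_whitelist <- function(n, barcode_len = 8L, min_dist = 3L, seed = 1L,
                             lnp_names = NULL, naked_control = TRUE,
                             max_attempts = 10000L) {
  stopifnot(n >= 1, min_dist >= 1, barcode_len >= 1)
  if (min_dist > barcode_len) {
    stop("capacity error: min_dist (", min_dist,
         ") cannot exceed barcode_len (", barcode_len, ")")
  }
  if (4^barcode_len < 4 * n) {
    stop("capacity error: 4^", barcode_len,
         " sequences cannot comfortably host ", n, " barcodes")
  }
  n_total <- n + as.integer(naked_control)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  bases <- c("A", "C", "G", "T")
  accepted <- character(0)
  while (length(accepted) < n_total) {
    placed <- FALSE
    for (attempt in seq_len(max_attempts)) {
      cand <- paste(sample(bases, barcode_len, replace = TRUE), collapse = "")
      if (has_long_homopolymer(cand, max_run = 3L)) next
      if (length(accepted) == 0L ||
          cpp_all_at_distance(cand, accepted, as.integer(min_dist))) {
        accepted <- c(accepted, cand)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("capacity error: could not place barcode ", length(accepted) + 1L,
           " of ", n_total, " within ", max_attempts, " attempts ",
           "(len = ", barcode_len, ", min_dist = ", min_dist, ")")
    }
  }
  if (is.null(lnp_names)) lnp_names <- paste0("LNP-CAD", seq_len(n))
  stopifnot(length(lnp_names) == n)
  wl <- data.frame(
    barcode_id = c(sprintf("BC%03d", seq_len(n)),
                   if (naked_control) "BC_naked"),
    sequence = accepted,
    lnp_name = c(lnp_names, if (naked_control) "naked_control"),
    stringsAsFactors = FALSE
  )
  attr(wl, "barcode_len") <- as.integer(barcode_len)
  attr(wl, "min_pairwise_hamming") <- as.integer(min_dist)
  class(wl) <- c("bdna_whitelist", "data.frame")
  validate_whitelist(wl)
  wl
}

has_long_homopolymer <- function(seq, max_run = 3L) {
  grepl(sprintf("A{%d}|C{%d}|G{%d}|T{%d}",
                max_run + 1L, max_run + 1L, max_run + 1L, max_run + 1L), seq)
}

#' Validate a barcode whitelist
#'
#' Checks column presence, sequence uniqueness and the minimum pairwise
#' Hamming distance (recomputed exhaustively).
#' @param wl Whitelist data.frame.
#' @return The whitelist, invisibly; errors on violation.
#' @export
validate_whitelist <- function(wl) {
  required <- c("barcode_id", "sequence", "lnp_name")
  missing <- setdiff(required, names(wl))
  if (length(missing) > 0L) {
    stop("whitelist missing columns: ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(wl$sequence)) stop("whitelist sequences are not unique")
  if (anyDuplicated(wl$barcode_id)) stop("whitelist barcode_ids are not unique")
  lens <- unique(nchar(wl$sequence))
  if (length(lens) != 1L) stop("whitelist sequences have unequal lengths")
  if (nrow(wl) >= 2L) {
    d <- cpp_min_pairwise_hamming(wl$sequence)
    declared <- attr(wl, "min_pairwise_hamming")
    if (!is.null(declared) && d < declared) {
      stop("whitelist min pairwise Hamming distance ", d,
           " below declared ", declared)
    }
    attr(wl, "min_pairwise_hamming") <- d
  }
  attr(wl, "barcode_len") <- lens
  invisible(wl)
}

#' Write / read a whitelist TSV (`barcode_id, sequence, lnp_name`)
#' @param wl Whitelist data.frame.
#' @param path Output path.
#' @export
write_whitelist <- function(wl, path) {
  utils::write.table(wl, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_whitelist
#' @export
read_whitelist <- function(path) {
  wl <- utils::read.delim(path, stringsAsFactors = FALSE)
  wl <- validate_whitelist(wl)
  d <- if (nrow(wl) >= 2L) cpp_min_pairwise_hamming(wl$sequence) else NA_integer_
  attr(wl, "min_pairwise_hamming") <- d
  attr(wl, "barcode_len") <- unique(nchar(wl$sequence))
  class(wl) <- c("bdna_whitelist", "data.frame")
  wl
}

# Save / restore .Random.seed so seeded helpers do not disturb the caller's
# RNG stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Deterministic child-seed scheme: child k of root r is
# (r * 48271 + k * 9349 + 7) mod 2147483647, kept in [1, 2^31 - 2].
child_seed <- function(root, counter) {
  r <- as.double(root) %% 2147483647
  s <- (r * 48271 + as.double(counter) * 9349 + 7) %% 2147483647
  as.integer(s + 1)
}
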