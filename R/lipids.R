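#' Default amine core registry
#'
#' The combinatorial cationic degradable (CAD) lipid library is built from 12
#' polyamine cores. Each core carries an annotation of how many secondary
#' amines the final (reduced) lipid presents; this covariate drives the
#' structure--activity hit-rate tabulation. The counts shipped here are a
#' synthetic, editable annotation table: they are registry data, not values
#' computed from chemistry, and any user registry with the same columns can be
#' substituted.
#'
#' @return A data.frame with columns `core_id` (integer, unique),
#'   `name` (character), `secondary_amine_count` (integer >= 1) and `note`.
#' @export
#' @examples
#' cores <- amine_core_registry()
#' nrow(cores)  # 12
amine_core_registry <- function() {
  reg <- data.frame(
    core_id = 1:12,
    name = paste0("amine core ", 1:12),
    secondary_amine_count = c(1L, 1L, 2L, 2L, 2L, 2L, 2L, 3L, 2L, 3L, 4L, 4L),
    note = "synthetic default annotation; replace with measured registry",
    stringsAsFactors = FALSE
  )
  validate_core_registry(reg)
  reg
}

validate_core_registry <- function(cores) {
  required <- c("core_id", "secondary_amine_count")
  missing <- setdiff(required, names(cores))
  if (length(missing) > 0L) {
    stop("core registry missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(cores) == 0L) stop("core registry is empty")
  if (anyDuplicated(cores$core_id)) {
    stop("duplicate core_id in registry: ",
         paste(unique(cores$core_id[duplicated(cores$core_id)]), collapse = ", "))
  }
  if (any(cores$secondary_amine_count < 1L)) {
    stop("secondary_amine_count must be >= 1")
  }
  invisible(cores)
}

#' Default aldehyde tail registry
#'
#' The 15 degradable aldehyde ester tails used to assemble the CAD library.
#' Tail codes follow the `A<y>-<Z>[b|b2]` grammar: `y` is the number of tails
#' installed per amine reaction site (2 or 3), `Z` the carbon count per tail,
#' and an optional `b`/`b2` suffix marks branched architectures.
#'
#' @return A data.frame with columns `tail_code`, `tail_number`, `tail_length`
#'   and `branch_class` (one of `"linear"`, `"branched_b"`, `"branched_b2"`),
#'   in synthesis order.
#' @export
aldehyde_tail_registry <- function() {
  codes <- c("A2-6", "A2-6b", "A2-7", "A2-7b", "A2-7b2",
             "A2-8", "A2-8b", "A2-9", "A2-9b", "A2-9b2",
             "A3-6b", "A3-7b", "A3-7b2", "A3-8b", "A3-9b2")
  parsed <- do.call(rbind, lapply(codes, function(x) {
    p <- parse_tail_code(x)
    data.frame(tail_code = x, tail_number = p$tail_number,
               tail_length = p$tail_length, branch_class = p$branch_class,
               stringsAsFactors = FALSE)
  }))
  validate_tail_registry(parsed)
  parsed
}

validate_tail_registry <- function(tails) {
  required <- c("tail_code", "tail_number", "tail_length", "branch_class")
  missing <- setdiff(required, names(tails))
  if (length(missing) > 0L) {
    stop("tail registry missing columns: ", paste(missing, collapse = ", "))
  }
  if (nrow(tails) == 0L) stop("tail registry is empty")
  if (anyDuplicated(tails$tail_code)) {
    stop("duplicate tail_code in registry: ",
         paste(unique(tails$tail_code[duplicated(tails$tail_code)]), collapse = ", "))
  }
  invisible(tails)
}

#' Parse an aldehyde tail code
#'
#' @param code Tail code such as `"A2-7b2"`.
#' @return A list with `tail_number`, `tail_length`, `branch_class`.
#' @export
parse_tail_code <- function(code) {
  stopifnot(is.character(code), length(code) == 1L)
  m <- regmatches(code, regexec("^A([23])-([0-9]+)(b2|b)?$", code))[[1]]
  if (length(m) == 0L) {
    stop("malformed tail code: '", code, "'")
  }
  suffix <- m[4]
  branch <- if (is.na(suffix) || suffix == "") "linear"
            else if (suffix == "b") "branched_b"
            else "branched_b2"
  list(tail_number = as.integer(m[2]),
       tail_length = as.integer(m[3]),
       branch_class = branch)
}

#' Parse a CAD lipid name
#'
#' Lipid names follow the `X-Ay-Z` nomenclature where `X` is the amine core
#' id, `y` the tail number and `Z` the carbon number per tail, with an
#' optional branching suffix (`b`, `b2`).
#'
#' @param name Lipid name such as `"5-A2-7b2"`.
#' @return A list with `core_id`, `tail_code`, `tail_number`, `tail_length`
#'   and `branch_class`.
#' @export
#' @examples
#' parse_lipid_name("5-A2-7b2")
parse_lipid_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- regmatches(name, regexec("^([0-9]+)-(A[23]-[0-9]+(?:b2|b)?)$", name))[[1]]
  if (length(m) == 0L) {
    stop("malformed lipid name: '", name,
         "' (expected <core_id>-A<2|3>-<carbons>[b|b2])")
  }
  tail <- parse_tail_code(m[3])
  list(core_id = as.integer(m[2]),
       tail_code = m[3],
       tail_number = tail$tail_number,
       tail_length = tail$tail_length,
       branch_class = tail$branch_class)
}

#' Enumerate the combinatorial lipid library
#'
#' Builds the full cross product of an amine core registry and an aldehyde
#' tail registry, in deterministic core-major order (tails in registered
#' order within each core). With the default registries this yields the
#' 180-lipid CAD library.
#'
#' @param cores Core registry, see [amine_core_registry()].
#' @param tails Tail registry, see [aldehyde_tail_registry()].
#' @return A data.frame of lipid descriptors with columns `name`, `core_id`,
#'   `secondary_amine_count`, `tail_code`, `tail_number`, `tail_length`,
#'   `branch_class`.
#' @export
#' @examples
#' lib <- enumerate_library()
#' nrow(lib)  # 180
enumerate_library <- function(cores = amine_core_registry(),
                              tails = aldehyde_tail_registry()) {
  validate_core_registry(cores)
  validate_tail_registry(tails)
  idx <- expand.grid(tail = seq_len(nrow(tails)), core = seq_len(nrow(cores)))
  # expand.grid varies the first factor fastest; we want core-major order,
  # i.e. all tails of core 1, then core 2, ...
  lib <- data.frame(
    name = paste0(cores$core_id[idx$core], "-", tails$tail_code[idx$tail]),
    core_id = cores$core_id[idx$core],
    secondary_amine_count = cores$secondary_amine_count[idx$core],
    tail_code = tails$tail_code[idx$tail],
    tail_number = tails$tail_number[idx$tail],
    tail_length = tails$tail_length[idx$tail],
    branch_class = tails$branch_class[idx$tail],
    stringsAsFactors = FALSE
  )
  stopifnot(!anyDuplicated(lib$name))
  lib
}

#' Call in vitro hits from a replicate RLU table
#'
#' Relative luminescence (RLU) readouts, normalized to PBS-treated cells, are
#' aggregated per lipid across replicates and compared against a strict
#' threshold: a lipid is a hit iff its aggregate RLU is strictly greater than
#' `threshold` (default 100).
#'
#' @param rlu Long-format data.frame with columns `lipid_name`, `replicate`,
#'   `rlu` (all RLU >= 0, >= 1 replicate per lipid).
#' @param threshold Positive hit threshold on the aggregated RLU.
#' @param aggregate Replicate aggregation statistic, `"mean"` (default) or
#'   `"median"`.
#' @return data.frame with columns `lipid_name`, `rlu_aggregate`, `hit`
#'   (logical), one row per lipid, in first-appearance order.
#' @export
classify_hits <- function(rlu, threshold = 100, aggregate = c("mean", "median")) {
  aggregate <- match.arg(aggregate)
  required <- c("lipid_name", "rlu")
  missing <- setdiff(required, names(rlu))
  if (length(missing) > 0L) {
    stop("RLU table missing columns: ", paste(missing, collapse = ", "))
  }
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0) {
    stop("threshold must be a single positive number")
  }
  if (nrow(rlu) == 0L) stop("RLU table has no rows")
  if (any(!is.finite(rlu$rlu)) || any(rlu$rlu < 0)) {
    stop("all RLU values must be finite and >= 0")
  }
  fun <- if (aggregate == "mean") mean else stats::median
  lipids <- unique(rlu$lipid_name)
  agg <- vapply(lipids, function(l) fun(rlu$rlu[rlu$lipid_name == l]),
                numeric(1))
  data.frame(lipid_name = lipids,
             rlu_aggregate = unname(agg),
             hit = unname(agg) > threshold,
             stringsAsFactors = FALSE)
}

#' Hit rate by structural feature
#'
#' Tabulates the relative hit rate of a library against one structural
#' feature. The default denominator is the whole library (rate at a level =
#' hits at that level / total library size, as a percentage), so rates across
#' the levels of one feature sum to the overall hit rate. A within-group
#' denominator (hits at level / lipids at level) is available.
#'
#' @param hits data.frame as returned by [classify_hits()] (columns
#'   `lipid_name`, `hit`), or a character vector of hit lipid names.
#' @param library Lipid library from [enumerate_library()].
#' @param feature One of `"secondary_amine_count"`, `"branch_class"`,
#'   `"tail_number"`, `"tail_length"`.
#' @param denominator `"library"` (default) or `"within"`.
#' @return data.frame with columns `feature`, `level`, `n_lipids`, `n_hits`,
#'   `hit_rate_pct`.
#' @export
hit_rate_by_feature <- function(hits, library,
                                feature = c("secondary_amine_count",
                                            "branch_class", "tail_number",
                                            "tail_length"),
                                denominator = c("library", "within")) {
  feature <- match.arg(feature)
  denominator <- match.arg(denominator)
  hit_names <- if (is.character(hits)) hits else hits$lipid_name[hits$hit]
  unknown <- setdiff(hit_names, library$name)
  if (length(unknown) > 0L) {
    stop("hit lipids not present in library: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  levels_ <- sort(unique(library[[feature]]))
  is_hit <- library$name %in% hit_names
  out <- do.call(rbind, lapply(levels_, function(lv) {
    in_level <- library[[feature]] == lv
    n_hits <- sum(is_hit & in_level)
    denom <- if (denominator == "library") nrow(library) else sum(in_level)
    data.frame(feature = feature, level = as.character(lv),
               n_lipids = sum(in_level), n_hits = n_hits,
               hit_rate_pct = 100 * n_hits / denom,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Read an RLU replicate table from TSV
#'
#' Expected columns: `lipid_name`, `replicate`, `rlu`.
#' @param path Path to a tab-delimited file with a header row.
#' @return data.frame.
#' @export
read_rlu_table <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("lipid_name", "replicate", "rlu")
  missing <- setdiff(required, names(tab))
  if (length(missing) > 0L) {
    stop("RLU table ", path, " missing columns: ",
         paste(missing, collapse = ", "))
  }
  tab
}
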