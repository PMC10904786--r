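#' Default run configuration
#'
#' Key-value configuration covering every pipeline stage. All keys can be
#' supplied in a config file (one `key = value` per line, `#` comments) or
#' overridden on the command line. List-valued keys (`off_targets`,
#' `planted_barcodes`) are comma-separated.
#'
#' @return Named list of defaults.
#' @export
default_config <- function() {
  list(
    out_dir = "bdna_out",
    fastq_dir = NA_character_,        # defaults to <out_dir>/fastq
    whitelist = NA_character_,        # defaults to <fastq_dir>/whitelist.tsv
    sample_sheet = NA_character_,     # defaults to <fastq_dir>/sample_sheet.tsv
    rlu_table = NA_character_,        # optional; enables the sar stage
    seed = 1L,
    # whitelist design
    n_barcodes = 96L,
    barcode_len = 8L,
    min_dist = 3L,
    naked_control = TRUE,
    # read layout
    prefix_seq = "TCGGATCCTACGGTAACGCT",
    suffix_seq = "AGATCGGAAGAGCACACGTC",
    umi_len = 8L,
    # simulator
    n_mice = 5L,
    n_pool_replicates = 1L,
    mouse_sd = 0.3,
    molecules_per_organ = 2e5,
    pcr_cycles = 16L,
    pcr_efficiency = 0.9,
    seq_error_rate = 1e-3,
    reads_per_sample = 4e5,
    planted_barcodes = character(0),
    planted_organ = "lung",
    planted_affinity = 8,
    gzip_fastq = FALSE,
    # quantification
    max_mm = 1L,
    anchor_max_mm = 2L,
    dedup_method = "directional",
    # enrichment
    pseudocount = 0.5,
    comparison = "one_vs_rest",
    fc_threshold = 1,
    q_threshold = 0.05,
    organ_of_interest = "lung",
    off_targets = c("liver", "spleen"),
    # sar
    rlu_threshold = 100,
    rlu_aggregate = "mean",
    hit_denominator = "library",
    force = FALSE,
    verbose = 1L
  )
}

list_keys <- function() c("off_targets", "planted_barcodes")

#' Read a run configuration file
#'
#' Parses `key = value` lines (`#` starts a comment), coerces values to the
#' type of the corresponding default, and overlays them on
#' [default_config()]. Unknown keys are an error.
#'
#' @param path Config file path, or `NULL` for pure defaults.
#' @param overrides Named list applied on top of the file (logged).
#' @return Named configuration list (class `bdna_config`).
#' @export
read_config <- function(path = NULL, overrides = list()) {
  cfg <- default_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    lines <- readLines(path)
    lines <- sub("#.*$", "", lines)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    for (ln in lines) {
      eq <- regexpr("=", ln, fixed = TRUE)
      if (eq < 0) stop("malformed config line (no '='): ", ln)
      key <- trimws(substr(ln, 1L, eq - 1L))
      val <- trimws(substr(ln, eq + 1L, nchar(ln)))
      cfg <- set_config_value(cfg, key, val)
    }
  }
  for (key in names(overrides)) {
    cfg <- set_config_value(cfg, key, overrides[[key]])
  }
  class(cfg) <- c("bdna_config", "list")
  cfg
}

set_config_value <- function(cfg, key, val) {
  if (!key %in% names(cfg)) stop("unknown config key: ", key)
  proto <- default_config()[[key]]
  if (is.character(val) && length(val) == 1L &&
      (val == "NA" || val == "") && !key %in% list_keys()) {
    cfg[key] <- list(proto[NA][1])  # typed NA
    return(cfg)
  }
  if (key %in% list_keys()) {
    if (is.character(val) && length(val) == 1L) {
      val <- trimws(strsplit(val, ",", fixed = TRUE)[[1]])
      val <- val[nzchar(val)]
    }
    cfg[[key]] <- as.character(val)
  } else if (is.logical(proto)) {
    cfg[[key]] <- as.logical(val)
  } else if (is.integer(proto)) {
    cfg[[key]] <- as.integer(val)
  } else if (is.numeric(proto)) {
    cfg[[key]] <- as.numeric(val)
  } else {
    cfg[[key]] <- as.character(val)
  }
  cfg
}

#' Serialize a configuration to `key = value` lines
#' @param cfg Configuration list.
#' @param path Optional output path; when `NULL` the lines are returned.
#' @return Character vector of lines (invisibly when written).
#' @export
write_config <- function(cfg, path = NULL) {
  keys <- sort(names(cfg))
  fmt <- vapply(keys, function(k) {
    v <- cfg[[k]]
    v <- if (length(v) == 0L) "" else paste(format(v, scientific = FALSE,
                                                   trim = TRUE),
                                            collapse = ",")
    paste0(k, " = ", v)
  }, character(1))
  if (!is.null(path)) {
    writeLines(fmt, path)
    return(invisible(fmt))
  }
  fmt
}

#' Short provenance hash of a configuration
#'
#' Polynomial rolling hash (mod 2^31 - 1) over the sorted serialized
#' config; a provenance tag, not a cryptographic digest.
#' @param cfg Configuration list.
#' @return 8-character hex string.
#' @export
config_hash <- function(cfg) {
  txt <- paste(write_config(cfg), collapse = "\n")
  bytes <- utf8ToInt(txt)
  h <- 17
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", as.integer(h))
}

resolve_paths <- function(cfg) {
  if (is.na(cfg$fastq_dir)) cfg$fastq_dir <- file.path(cfg$out_dir, "fastq")
  if (is.na(cfg$whitelist)) {
    cfg$whitelist <- file.path(cfg$fastq_dir, "whitelist.tsv")
  }
  if (is.na(cfg$sample_sheet)) {
    cfg$sample_sheet <- file.path(cfg$fastq_dir, "sample_sheet.tsv")
  }
  cfg
}

validate_config <- function(cfg, stage) {
  problems <- character(0)
  if (cfg$n_mice < 1L) problems <- c(problems, "n_mice must be >= 1")
  if (cfg$n_barcodes < 1L) problems <- c(problems, "n_barcodes must be >= 1")
  if (cfg$pcr_efficiency < 0 || cfg$pcr_efficiency > 1) {
    problems <- c(problems, "pcr_efficiency must be in [0, 1]")
  }
  if (cfg$seq_error_rate < 0 || cfg$seq_error_rate > 1) {
    problems <- c(problems, "seq_error_rate must be in [0, 1]")
  }
  if (stage %in% c("quantify", "run-all")) {
    for (key in c("whitelist", "sample_sheet")) {
      if (!file.exists(cfg[[key]])) {
        problems <- c(problems, paste0(key, " file not found: ", cfg[[key]]))
      }
    }
  }
  if (length(problems) > 0L) {
    stop("config validation failed for stage '", stage, "':\n  ",
         paste(problems, collapse = "\n  "))
  }
  invisible(cfg)
}

prov_header <- function(cfg) {
  sprintf("# bdnascreen %s config %s",
          as.character(utils::packageVersion("bdnascreen")),
          config_hash(cfg))
}

write_tsv_prov <- function(df, path, cfg) {
  con <- file(path, "w")
  on.exit(close(con), add = TRUE)
  writeLines(prov_header(cfg), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by the pipeline (provenance comments ignored)
#' @param path TSV path.
#' @return data.frame.
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, comment.char = "#", check.names = FALSE,
                    stringsAsFactors = FALSE)
}
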