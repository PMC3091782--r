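#' Write a pipeline table as TSV with a provenance header
#'
#' Tables are plain tab-separated files with a mandatory column header,
#' preceded by `#`-comment lines recording the package version and the
#' simulation seed, so every output can be traced to the run that made it.
#'
#' @param x Data.frame to write.
#' @param path Output file path.
#' @param seed Optional integer seed recorded in the header.
#' @return `path`, invisibly.
#' @export
write_fsv_tsv <- function(x, path, seed = NULL) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(sprintf("# fsvkit %s",
                     as.character(utils::packageVersion("fsvkit"))), con)
  if (!is.null(seed)) writeLines(sprintf("# seed %d", as.integer(seed)), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' Read a pipeline TSV written by [write_fsv_tsv()]
#'
#' @param path File path.
#' @return Data.frame (comment lines skipped).
#' @export
read_fsv_tsv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Column schemas for the pipeline interchange tables
#'
#' Each schema names the required columns with their types, the key columns
#' that must be unique, the columns that must be non-negative, and whether
#' positions must be sorted within chromosome.
#'
#' @param name One of `"pileup"`, `"calls"`, `"chip_summary"`, `"fsv"`.
#' @return A schema list understood by [validate_table()].
#' @export
table_schema <- function(name = c("pileup", "calls", "chip_summary", "fsv")) {
  name <- match.arg(name)
  switch(name,
    pileup = list(
      cols = c(chrom = "character", pos = "integer", line = "character",
               ref_reads = "integer", nonref_reads = "integer"),
      key = c("chrom", "pos", "line"),
      nonneg = c("ref_reads", "nonref_reads"),
      sorted = TRUE
    ),
    calls = list(
      cols = c(chrom = "character", pos = "integer",
               detected_high = "logical", detected_low = "logical",
               S_high = "numeric", S_low = "numeric",
               depth_high = "integer", depth_low = "integer",
               variation_class = "character", excluded = "logical"),
      key = c("chrom", "pos"),
      nonneg = c("depth_high", "depth_low"),
      sorted = TRUE
    ),
    chip_summary = list(
      cols = c(chrom = "character", pos = "integer", freq_high = "numeric",
               freq_low = "numeric", call_freq = "numeric",
               polymorphic = "logical", delta_p = "numeric",
               usable = "logical"),
      key = c("chrom", "pos"),
      nonneg = character(0),
      sorted = TRUE
    ),
    fsv = list(
      cols = c(chrom = "character", pos = "integer", window_total = "integer",
               N_H = "integer", N_L = "integer", fsv = "numeric",
               defined = "logical", density_pass = "logical"),
      key = c("chrom", "pos", "window_total"),
      nonneg = c("N_H", "N_L"),
      sorted = FALSE
    )
  )
}

#' Read and validate a pipeline table against a schema
#'
#' @param path TSV file path.
#' @param schema A schema from [table_schema()].
#' @param sort If `TRUE` (default) an unsorted table is sorted by chromosome
#'   and position with a note; if `FALSE` unsorted input is an error.
#' @return The validated (and possibly sorted) data.frame.
#' @export
validate_table <- function(path, schema, sort = TRUE) {
  df <- read_fsv_tsv(path)
  miss <- setdiff(names(schema$cols), names(df))
  if (length(miss) > 0) {
    stop("table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in names(schema$cols)) {
    want <- schema$cols[[col]]
    v <- df[[col]]
    ok <- nrow(df) == 0 || switch(want,
      character = is.character(v) | all(is.na(v)),
      integer = is.numeric(v) && all(is.na(v) | v == floor(v)),
      numeric = is.numeric(v) || is.logical(v),
      logical = is.logical(v) ||
        all(is.na(v) | v %in% c("TRUE", "FALSE", 0, 1))
    )
    if (!isTRUE(all(ok))) {
      bad <- which(!ok)[1]
      stop(sprintf("column '%s' of %s fails type '%s' (data row %d)",
                   col, path, want, bad), call. = FALSE)
    }
    if (want == "logical" && !is.logical(v)) df[[col]] <- as.logical(v)
    if (want == "integer") df[[col]] <- as.integer(v)
    if (want == "character" && !is.character(v)) df[[col]] <- as.character(v)
  }
  for (col in schema$nonneg) {
    bad <- which(!is.na(df[[col]]) & df[[col]] < 0)
    if (length(bad) > 0) {
      stop(sprintf("negative value in column '%s' of %s (data row %d)",
                   col, path, bad[1]), call. = FALSE)
    }
  }
  if (length(schema$key) > 0 && nrow(df) > 0) {
    key <- do.call(paste, df[schema$key])
    if (anyDuplicated(key)) {
      stop(sprintf("duplicated key (%s) in %s (data row %d)",
                   paste(schema$key, collapse = ","), path,
                   which(duplicated(key))[1]), call. = FALSE)
    }
  }
  if (isTRUE(schema$sorted) && nrow(df) > 1) {
    ord <- order(df$chrom, df$pos)
    if (!identical(ord, seq_len(nrow(df)))) {
      if (!sort) stop("table ", path, " is not sorted by (chrom, pos)",
                      call. = FALSE)
      message("note: sorting ", path, " by (chrom, pos)")
      df <- df[ord, , drop = FALSE]
      rownames(df) <- NULL
    }
  }
  df
}

#' Write / read a simulation configuration as a YAML file
#'
#' @param config An [sim_config()] object.
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns the validated `fsv_sim_config`.
#' @export
write_sim_config <- function(config, path) {
  validate_sim_config(config)
  x <- unclass(config)
  x$chromosome_classes <- as.list(x$chromosome_classes)
  x$chromosome_lengths <- as.list(x$chromosome_lengths)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  sim_config(
    chromosome_lengths = unlist(x$chromosome_lengths),
    chromosome_classes = unlist(x$chromosome_classes),
    snp_density = x$snp_density,
    chip_fraction = x$chip_fraction,
    n_individuals_chip = x$n_individuals_chip,
    pool_males = x$pool_males,
    pool_females = x$pool_females,
    mean_depth_high = x$mean_depth_high,
    mean_depth_low = x$mean_depth_low,
    fst_within_block = x$fst_within_block,
    block_length_mean = x$block_length_mean,
    ancestral_freq_shape = unlist(x$ancestral_freq_shape),
    snp_jitter = x$snp_jitter,
    seq_error_rate = x$seq_error_rate,
    missing_rate = x$missing_rate,
    rng_seed = x$rng_seed
  )
}
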