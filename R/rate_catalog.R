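#' Baltimore classification groups covered by the rate catalog
#'
#' The six genome-type groups for which both short-term and long-term
#' substitution-rate estimates exist (group III dsRNA viruses lack published
#' long-term rates and are therefore absent from the catalog schema).
#'
#' @format Character vector of group labels.
#' @export
baltimore_groups <- c("I", "II", "IV", "V", "VI", "VII")

catalog_columns <- c("record_id", "virus_name", "baltimore_group", "genus",
                     "rate", "timescale", "block_id", "alternative_id",
                     "source_id")

#' Construct a validated rate-estimate catalog
#'
#' A `rate_dataset` holds one row per published substitution-rate estimate:
#' the virus it was measured on, its Baltimore group and (optionally) genus,
#' the estimate in substitutions/site/year, the timescale of measurement in
#' years, and phylogenetic-independence annotations. Records sharing a
#' `block_id` are phylogenetically nested; within a block, `alternative_id`
#' labels mutually exclusive groupings of viruses of which at most one may
#' enter any phylogenetically independent subset (see
#' [sample_pseudoreplicate()]).
#'
#' @param records Data frame with columns `record_id`, `virus_name`,
#'   `baltimore_group`, `genus`, `rate`, `timescale`, `block_id`,
#'   `alternative_id`, `source_id`. `genus` may be empty (`""`).
#' @param label Free-text label for the dataset.
#' @return An object of class `rate_dataset`: the records (row order
#'   preserved) plus the label.
#' @examples
#' rec <- data.frame(record_id = "r1", virus_name = "TMV",
#'                   baltimore_group = "IV", genus = "Tobamovirus",
#'                   rate = 1e-4, timescale = 50, block_id = "b1",
#'                   alternative_id = "a1", source_id = "s1")
#' rate_dataset(rec, label = "toy")
#' @export
rate_dataset <- function(records, label = "") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  validate_rate_records(records)
  structure(list(records = records, label = as.character(label)[1]),
            class = "rate_dataset")
}

validate_rate_records <- function(records) {
  missing_cols <- setdiff(catalog_columns, names(records))
  if (length(missing_cols) > 0L) {
    tdrp_error("tdrp_parse_error",
               paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  for (col in c("record_id", "virus_name", "baltimore_group", "genus",
                "block_id", "alternative_id", "source_id")) {
    records[[col]] <- as.character(records[[col]])
  }
  bad <- function(cond, what) {
    i <- which(cond)
    if (length(i) > 0L) {
      tdrp_error("tdrp_parse_error",
                 sprintf("%s in row(s): %s", what,
                         paste(utils::head(i, 5L), collapse = ", ")))
    }
  }
  bad(!is.finite(records$rate) | records$rate <= 0, "non-positive rate")
  bad(!is.finite(records$timescale) | records$timescale <= 0,
      "non-positive timescale")
  bad(!(records$baltimore_group %in% baltimore_groups),
      "unknown Baltimore group")
  bad(duplicated(records$record_id), "duplicate record_id")
  bad(is.na(records$record_id) | records$record_id == "", "empty record_id")
  # a virus must sit in exactly one alternative of any block it occurs in
  key <- unique(records[, c("block_id", "virus_name", "alternative_id")])
  dup <- duplicated(key[, c("block_id", "virus_name")])
  if (any(dup)) {
    v <- key$virus_name[dup][1]
    tdrp_error("tdrp_parse_error",
               sprintf("virus '%s' appears in more than one alternative of block '%s'",
                       v, key$block_id[dup][1]))
  }
  invisible(records)
}

#' @export
print.rate_dataset <- function(x, ...) {
  rec <- x$records
  cat(sprintf("rate_dataset '%s': %d rate estimates, %d viruses, %d blocks\n",
              x$label, nrow(rec), length(unique(rec$virus_name)),
              length(unique(rec$block_id))))
  tab <- table(factor(rec$baltimore_group, levels = baltimore_groups),
               term_class(rec$timescale))
  print(tab)
  invisible(x)
}

#' @export
as.data.frame.rate_dataset <- function(x, ...) x$records

#' Number of rate estimates in a catalog
#' @param x A [rate_dataset()].
#' @export
n_records <- function(x) nrow(x$records)

#' Classify a measurement timescale as short- or long-term
#'
#' Rates estimated over timescales shorter than 1,000 years (typically from
#' heterochronous sequence data) are "short"; rates estimated over 1,000
#' years or more (typically from cospeciation or geographic-separation
#' calibrations) are "long". The cutoff sits inside a gap in observed
#' measurement timescales (roughly 760 to 6,600 years), so the boundary case
#' does not arise in real catalogs; exactly 1,000 years classifies as long.
#'
#' @param timescale Numeric vector of timescales in years, all positive.
#' @return Character vector of `"short"`/`"long"`.
#' @examples
#' term_class(c(760, 6600, 1000))
#' @export
term_class <- function(timescale) {
  if (any(!is.finite(timescale) | timescale <= 0)) {
    tdrp_error("tdrp_domain_error", "timescale must be positive and finite")
  }
  ifelse(timescale < 1000, "short", "long")
}

#' Read a rate catalog from a delimited table
#'
#' Expects a UTF-8, comma-separated table with one header row naming the
#' columns of the catalog schema (`record_id, virus_name, baltimore_group,
#' genus, rate, timescale, block_id, alternative_id, source_id`). Rates may
#' use scientific notation. All dataset invariants are checked; violations
#' raise a parse error naming the offending rows.
#'
#' @param path Path to the CSV file.
#' @param sep Field separator, `","` by default.
#' @param label Dataset label; defaults to the file name.
#' @return A [rate_dataset()].
#' @seealso [write_rate_table()]
#' @export
read_rate_table <- function(path, sep = ",", label = basename(path)) {
  if (!file.exists(path)) {
    tdrp_error("tdrp_parse_error", paste0("file not found: ", path))
  }
  records <- utils::read.table(path, header = TRUE, sep = sep,
                               colClasses = "character",
                               stringsAsFactors = FALSE, quote = "\"",
                               fileEncoding = "UTF-8")
  missing_cols <- setdiff(catalog_columns, names(records))
  if (length(missing_cols) > 0L) {
    tdrp_error("tdrp_parse_error",
               paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  records <- records[, catalog_columns]
  records$rate <- as.numeric(records$rate)
  records$timescale <- as.numeric(records$timescale)
  rate_dataset(records, label = label)
}

#' Write a rate catalog as a delimited table
#'
#' @param x A [rate_dataset()].
#' @param path Output file path.
#' @param sep Field separator, `","` by default.
#' @return Invisibly, `path`.
#' @seealso [read_rate_table()]
#' @export
write_rate_table <- function(x, path, sep = ",") {
  stopifnot(inherits(x, "rate_dataset"))
  utils::write.table(x$records[, catalog_columns], path, sep = sep,
                     row.names = FALSE, quote = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}
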