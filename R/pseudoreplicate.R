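#' Sample one phylogenetically independent data subset
#'
#' Draws a subset of the catalog approximating phylogenetic independence:
#' within each independence block exactly one alternative grouping is chosen
#' uniformly at random, and for each virus in the chosen alternative exactly
#' one of its rate records is chosen uniformly. The draw is accepted only if
#' every Baltimore group present in the parent catalog retains at least one
#' short-term and (when `require_long = TRUE`) one long-term record, the
#' condition under which a rate-decay slope is estimable per group;
#' otherwise the draw is rejected and retried.
#'
#' @param dataset A [rate_dataset()].
#' @param require_short,require_long Per-group term constraints applied to
#'   the accepted subset. `require_long = FALSE` is used for short-term-only
#'   catalogs.
#' @param max_attempts Rejection-sampling budget before failing with an
#'   error naming the group that lacks short or long records.
#' @param replicate_index Integer recorded on the result for pairing with
#'   downstream per-replicate statistics.
#' @return A `pseudoreplicate`: list with `record_ids`, `replicate_index`
#'   and `attempts` (number of rejection-sampling draws used).
#' @seealso [generate_pseudoreplicates()]
#' @export
sample_pseudoreplicate <- function(dataset, require_short = TRUE,
                                   require_long = TRUE,
                                   max_attempts = 10000L,
                                   replicate_index = 1L) {
  stopifnot(inherits(dataset, "rate_dataset"))
  rec <- dataset$records
  rec$term <- term_class(rec$timescale)
  groups <- unique(rec$baltimore_group)
  blocks <- split(seq_len(nrow(rec)), rec$block_id)
  last_missing <- NULL
  for (attempt in seq_len(max_attempts)) {
    chosen <- unlist(lapply(blocks, function(idx) {
      alts <- unique(rec$alternative_id[idx])
      a <- if (length(alts) == 1L) alts else sample(alts, 1L)
      idx <- idx[rec$alternative_id[idx] == a]
      # one record per virus, uniformly among that virus's records
      unlist(lapply(split(idx, rec$virus_name[idx]), function(vi) {
        if (length(vi) == 1L) vi else sample(vi, 1L)
      }), use.names = FALSE)
    }), use.names = FALSE)
    sub <- rec[chosen, ]
    ok <- TRUE
    for (g in groups) {
      terms <- sub$term[sub$baltimore_group == g]
      miss_s <- require_short && !any(terms == "short")
      miss_l <- require_long && !any(terms == "long")
      if (miss_s || miss_l) {
        ok <- FALSE
        last_missing <- sprintf("group %s lacks a %s-term record", g,
                                if (miss_s) "short" else "long")
        break
      }
    }
    if (ok) {
      return(structure(list(record_ids = rec$record_id[sort(chosen)],
                            replicate_index = as.integer(replicate_index),
                            attempts = attempt),
                       class = "pseudoreplicate"))
    }
  }
  tdrp_error("tdrp_sampling_error",
             sprintf("no subset satisfying the term constraint in %d attempts (%s)",
                     max_attempts, last_missing))
}

#' Generate a sequence of pseudoreplicated data subsets
#'
#' Repeatedly applies [sample_pseudoreplicate()] to build independently
#' sampled subsets (the published analysis used 1,000). Reproducible under a
#' fixed seed.
#'
#' @inheritParams sample_pseudoreplicate
#' @param n Number of subsets (>= 1).
#' @param seed Optional integer seed.
#' @return List of `pseudoreplicate` objects with `replicate_index` 1..n.
#' @examples
#' cat <- generate_synthetic_catalog(table1_config(seed = 1))
#' reps <- generate_pseudoreplicates(cat, n = 5, seed = 2)
#' sapply(reps, function(r) length(r$record_ids))
#' @export
generate_pseudoreplicates <- function(dataset, n, seed = NULL,
                                      require_short = TRUE,
                                      require_long = TRUE,
                                      max_attempts = 10000L) {
  stopifnot(n >= 1L)
  with_seed(seed, {
    lapply(seq_len(n), function(i) {
      sample_pseudoreplicate(dataset, require_short = require_short,
                             require_long = require_long,
                             max_attempts = max_attempts,
                             replicate_index = i)
    })
  })
}

#' Extract the records of a pseudoreplicate
#'
#' @param dataset The parent [rate_dataset()].
#' @param replicate A `pseudoreplicate` from [sample_pseudoreplicate()].
#' @return Data frame of the subset's records (catalog schema).
#' @export
replicate_records <- function(dataset, replicate) {
  stopifnot(inherits(dataset, "rate_dataset"),
            inherits(replicate, "pseudoreplicate"))
  rec <- dataset$records
  rec[match(replicate$record_ids, rec$record_id), , drop = FALSE]
}

#' Export pseudoreplicate membership as a long table
#'
#' @param replicates List of `pseudoreplicate` objects.
#' @return Data frame with columns `replicate_index`, `record_id`.
#' @export
replicates_as_table <- function(replicates) {
  do.call(rbind, lapply(replicates, function(r) {
    data.frame(replicate_index = r$replicate_index, record_id = r$record_ids,
               stringsAsFactors = FALSE)
  }))
}
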