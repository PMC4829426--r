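#' Subsample reads without replacement
#'
#' Uniform random subsample of size `min(n, length(read_ids))`,
#' deterministic for a given seed. Samples with fewer than `n` reads are
#' kept whole (no discard, no up-sampling); a message notes when this
#' happens. The default of 40,000 tags per sample keeps large amplicon
#' runs computationally tractable without biasing composition.
#'
#' @param read_ids Character vector of read identifiers.
#' @param n Target sample size. Default 40000.
#' @param seed Integer seed; the draw is reproducible per seed.
#' @return Character vector of sampled read ids.
#' @export
subsample_reads <- function(read_ids, n = 40000, seed = 1) {
  if (n < 0) abort("n must be non-negative")
  if (length(read_ids) <= n) {
    if (length(read_ids) < n) {
      rlang::inform(paste0("sample has only ", length(read_ids),
                           " reads (< ", n, "); kept whole"))
    }
    return(read_ids)
  }
  withr::with_seed(seed, sample(read_ids, n))
}

#' OTU classification acceptance rule
#'
#' An OTU's best database match is accepted when the mean of its sequence
#' identity and alignment coverage reaches the threshold:
#' `(identity + coverage) / 2 >= threshold` (all in percent, boundary
#' inclusive). OTUs failing the rule are treated as unclassified.
#'
#' @param identity,coverage Percent values in \[0, 100\]; vectorised.
#' @param threshold Acceptance threshold in percent. Default 93.
#' @return Logical vector.
#' @export
#' @examples
#' passes_similarity(93, 93)   # TRUE
#' passes_similarity(98, 86)   # FALSE: mean is 92
passes_similarity <- function(identity, coverage, threshold = 93) {
  if (any(identity < 0 | identity > 100, na.rm = TRUE) ||
      any(coverage < 0 | coverage > 100, na.rm = TRUE)) {
    abort("identity and coverage must be in [0, 100]")
  }
  (identity + coverage) / 2 >= threshold
}

#' Collapse an OTU table on shared taxonomy, no deeper than genus
#'
#' Sums read counts over OTUs whose lineages agree after truncation at the
#' genus level; OTUs classified only to a shallower rank collapse at their
#' deepest assigned rank, and OTUs with empty taxonomy (those failing the
#' acceptance rule) aggregate into an `"unclassified"` row. Returns a
#' taxa-by-samples abundance table.
#'
#' @param otus Data frame with `otu_id`, `sample_id`, `read_count`,
#'   `lineage` (semicolon-joined names; `""` or `NA` for unclassified).
#' @return Tibble with `taxon` (the collapsed lineage string) and one
#'   column per sample holding summed read counts.
#' @export
collapse_to_genus <- function(otus) {
  otus <- as_tibble(otus)
  genus_ord <- match("genus", tax_ranks())
  key <- vapply(as.character(otus$lineage), function(s) {
    if (is.na(s) || s == "") return("unclassified")
    parts <- strsplit(s, ";", fixed = TRUE)[[1]]
    paste(parts[seq_len(min(length(parts), genus_ord))], collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  otus |>
    mutate(taxon = key) |>
    group_by(.data$taxon, .data$sample_id) |>
    summarise(read_count = sum(.data$read_count), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "sample_id",
                       values_from = "read_count", values_fill = 0) |>
    arrange(.data$taxon)
}
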