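#' Per-family E-value cutoff table
#'
#' CAZyme families differ widely in HMM/alignment statistics, so each
#' family can carry its own E-value cutoff; families without an entry fall
#' back to `default_cutoff`. Ships as a template: the default is 1e-5
#' everywhere and any family can be overridden.
#'
#' @param ... Named per-family cutoffs, e.g. `GH16 = 1e-18`, or a single
#'   named numeric vector / list.
#' @param default_cutoff Fallback cutoff for families without an entry.
#'   Default `1e-5`.
#' @return Object of class `cutoff_table`.
#' @export
#' @examples
#' cutoff_table(GH16 = 1e-18, CBM50 = 1e-8)
cutoff_table <- function(..., default_cutoff = 1e-5) {
  vals <- unlist(list(...))
  if (is.null(vals)) vals <- numeric(0)
  if (length(vals) > 0 && (is.null(names(vals)) || any(names(vals) == ""))) {
    abort("per-family cutoffs must be named")
  }
  if (any(c(vals, default_cutoff) <= 0)) abort("cutoffs must be positive")
  structure(list(cutoffs = vals, default_cutoff = default_cutoff),
            class = "cutoff_table")
}

#' Read a per-family cutoff table from TSV
#'
#' Reads a two-column tab-separated file (`family`, `cutoff`) into a
#' [cutoff_table()]. A template listing common families at the default
#' cutoff ships with the package:
#' `system.file("extdata", "cazyme_cutoffs_template.tsv",
#' package = "bloombin")`. Curated per-family values are user data and can
#' be dropped in by editing the file.
#'
#' @param path TSV path with a header row.
#' @param default_cutoff Fallback for families not listed. Default `1e-5`.
#' @return A `cutoff_table`.
#' @export
read_cutoff_table <- function(path, default_cutoff = 1e-5) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(
                         family = readr::col_character(),
                         cutoff = readr::col_double()))
  cutoff_table(setNames(x$cutoff, x$family),
               default_cutoff = default_cutoff)
}

cutoff_for <- function(table, family) {
  stopifnot(inherits(table, "cutoff_table"))
  out <- unname(table$cutoffs[family])
  out[is.na(out)] <- table$default_cutoff
  out
}

#' Filter HMM/BLAST family hits by per-family E-value cutoffs
#'
#' Keeps hits with `e_value <= cutoff(family)` (boundary inclusive), where
#' the cutoff comes from a [cutoff_table()].
#'
#' @param hits Data frame with `gene_id`, `family`, `e_value`, `source`.
#' @param cutoffs A `cutoff_table`.
#' @return Tibble of surviving hits.
#' @export
apply_cutoffs <- function(hits, cutoffs = cutoff_table()) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) return(hits)
  filter(hits, .data$e_value <= cutoff_for(cutoffs, .data$family))
}

#' Consensus CAZyme calls (two-of-three rule)
#'
#' A gene is annotated with a CAZyme family only when at least two distinct
#' evidence sources (of `cazy_blast`, `dbcan`, `pfam`) have a surviving hit
#' for the same family label, and the gene's contig is at least
#' `min_contig_len` bp long (boundary inclusive; short contigs carry
#' unreliable gene models). One gene may carry several families
#' (multi-domain proteins).
#'
#' @param filtered Data frame of hits surviving [apply_cutoffs()], with
#'   `gene_id`, `family`, `source`.
#' @param genes Data frame mapping `gene_id` to `contig_id`.
#' @param contigs Data frame with `contig_id`, `length`.
#' @param min_contig_len Minimum contig length in bp. Default 500.
#' @return Tibble with `gene_id`, `family`, `n_sources`, `sources`
#'   (comma-joined, sorted source labels).
#' @export
consensus_cazymes <- function(filtered, genes, contigs,
                              min_contig_len = 500) {
  filtered <- as_tibble(filtered)
  genes <- as_tibble(genes)
  contigs <- as_tibble(contigs)
  if (nrow(filtered) == 0) {
    return(tibble(gene_id = character(), family = character(),
                  n_sources = integer(), sources = character()))
  }
  valid_sources <- c("cazy_blast", "dbcan", "pfam")
  bad <- setdiff(unique(as.character(filtered$source)), valid_sources)
  if (length(bad) > 0) {
    abort(paste0("unknown evidence source(s): ", paste(bad, collapse = ", ")))
  }
  no_contig <- setdiff(unique(as.character(filtered$gene_id)),
                       as.character(genes$gene_id))
  if (length(no_contig) > 0) {
    abort(paste0("gene(s) without contig: ",
                 paste(no_contig, collapse = ", ")))
  }
  no_len <- setdiff(unique(as.character(genes$contig_id)),
                    as.character(contigs$contig_id[!is.na(contigs$length)]))
  if (length(no_len) > 0) {
    abort(paste0("contig(s) without length: ",
                 paste(no_len, collapse = ", ")))
  }
  filtered |>
    distinct(.data$gene_id, .data$family, .data$source) |>
    group_by(.data$gene_id, .data$family) |>
    summarise(n_sources = dplyr::n_distinct(.data$source),
              sources = paste(sort(unique(.data$source)), collapse = ","),
              .groups = "drop") |>
    filter(.data$n_sources >= 2) |>
    inner_join(select(genes, "gene_id", "contig_id"), by = "gene_id") |>
    inner_join(select(contigs, "contig_id", "length"), by = "contig_id") |>
    filter(.data$length >= min_contig_len) |>
    select("gene_id", "family", "n_sources", "sources") |>
    arrange(.data$gene_id, .data$family)
}

#' Single-source Pfam family calls (sulfatases and transporters)
#'
#' Non-CAZyme functional families — sulfatases, TonB-dependent transporters
#' (TBDT) and TRAP transporters — are called from Pfam evidence alone at a
#' flat E-value cutoff (default 1e-5).
#'
#' @param hits Data frame with `gene_id`, `family`, `e_value`, `source`;
#'   only rows with `source == "pfam"` are considered.
#' @param families_of_interest Character vector of family labels to call.
#' @param max_e E-value cutoff, inclusive. Default `1e-5`.
#' @return Tibble with `gene_id`, `family`.
#' @export
pfam_family_calls <- function(hits,
                              families_of_interest = c("sulfatase", "TBDT",
                                                       "TRAP"),
                              max_e = 1e-5) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0 || length(families_of_interest) == 0) {
    return(tibble(gene_id = character(), family = character()))
  }
  hits |>
    filter(.data$source == "pfam",
           .data$family %in% families_of_interest,
           .data$e_value <= max_e) |>
    distinct(.data$gene_id, .data$family) |>
    arrange(.data$gene_id, .data$family)
}
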