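#' Filter read mappings by percent identity
#'
#' Keeps read-to-reference mappings with `identity >= min_identity`
#' (boundary inclusive). The default of 95 reflects mapping against a
#' habitat-specific reference set, where only near-identical placements are
#' trustworthy taxonomic evidence.
#'
#' @param mappings Data frame with at least `read_id`, `reference_taxon`,
#'   `identity` (percent in \[0, 100\]).
#' @param min_identity Minimum percent identity, inclusive. Default 95.
#' @return Tibble of retained mappings.
#' @export
filter_mappings <- function(mappings, min_identity = 95) {
  mappings <- as_tibble(mappings)
  if (nrow(mappings) == 0) return(mappings)
  idt <- as.numeric(mappings$identity)
  bad <- is.na(idt) | idt < 0 | idt > 100
  if (any(bad)) {
    abort(paste0("identity outside [0, 100] for read_id(s): ",
                 paste(utils::head(mappings$read_id[bad], 10), collapse = ", ")))
  }
  filter(mappings, idt >= min_identity)
}

#' Per-contig taxonomic path evidence from back-mapped reads
#'
#' Reads mapped to references are carried back to the contigs they
#' assembled into; each contig thus accumulates read support for one or
#' more taxonomic paths (the reference taxa's lineages). Paths supported by
#' fewer than `min_fraction` of a contig's mapped reads are discarded; the
#' denominator is the contig's total mapped reads counted before any path
#' is dropped. Reads without a back-mapping entry are ignored.
#'
#' @param mappings Data frame with `read_id`, `reference_taxon` (already
#'   identity-filtered, see [filter_mappings()]).
#' @param backmap Data frame with `read_id`, `contig_id`.
#' @param tree A `taxonomy`; reference taxa must resolve in it.
#' @param min_fraction Minimum supporting fraction per path. Default 0.01.
#' @return Tibble with `contig_id`, `lineage` (semicolon-joined names),
#'   `n_reads`; one row per retained (contig, path).
#' @export
contig_paths <- function(mappings, backmap, tree, min_fraction = 0.01) {
  stopifnot(inherits(tree, "taxonomy"))
  mappings <- as_tibble(mappings)
  backmap <- as_tibble(backmap)
  if (nrow(mappings) == 0) {
    return(tibble(contig_id = character(), lineage = character(),
                  n_reads = integer()))
  }
  unknown <- setdiff(unique(as.character(mappings$reference_taxon)),
                     rownames(tree$ancestors))
  if (length(unknown) > 0) {
    abort(paste0("unknown reference taxa: ", paste(unknown, collapse = ", ")))
  }
  lin_of <- vapply(
    unique(as.character(mappings$reference_taxon)),
    function(tx) lineage_string(tree, lineage_of(tree, tx)),
    character(1)
  )
  tallied <- mappings |>
    mutate(reference_taxon = as.character(.data$reference_taxon)) |>
    inner_join(backmap, by = "read_id") |>
    mutate(lineage = unname(lin_of[.data$reference_taxon])) |>
    count(.data$contig_id, .data$lineage, name = "n_reads")

  tallied |>
    group_by(.data$contig_id) |>
    # the 1% denominator is the pre-filter mapped-read total of the contig
    filter(.data$n_reads >= min_fraction * sum(.data$n_reads)) |>
    ungroup() |>
    arrange(.data$contig_id, desc(.data$n_reads))
}

#' Merge path evidence from two mapping sources
#'
#' Concatenates per-contig path evidence derived from two reference sets
#' (e.g. curated genomes and a habitat-specific protein database) by
#' summing read counts per (contig, path). The minimum-fraction rule is
#' applied per source before merging and is not re-applied afterwards.
#'
#' @param genome_paths,nr_paths Tibbles as returned by [contig_paths()].
#' @return Tibble with `contig_id`, `lineage`, `n_reads` summed per path.
#' @export
merge_path_sources <- function(genome_paths, nr_paths) {
  bind_rows(as_tibble(genome_paths), as_tibble(nr_paths)) |>
    group_by(.data$contig_id, .data$lineage) |>
    summarise(n_reads = sum(.data$n_reads), .groups = "drop") |>
    arrange(.data$contig_id, desc(.data$n_reads))
}
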