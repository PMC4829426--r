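#' Read the package's tab-separated input tables
#'
#' Thin readr wrappers for the pipeline's TSV dialects. Each returns a
#' tibble with typed columns; extra columns pass through untouched.
#'
#' * `read_hit_table()`: BLAST-tabular-like hits extended with a subject
#'   taxon column (`gene_id`, `subject_taxon`, `bit_score`, `e_value`).
#' * `read_family_hits()`: domtblout-style family hits (`gene_id`,
#'   `family`, `e_value`, `score`, `source`).
#' * `read_mapping_table()`: read mappings (`read_id`, `reference_id`,
#'   `reference_taxon`, `identity`).
#' * `read_backmap()`: read-to-contig back-map (`read_id`, `contig_id`).
#' * `read_contig_table()`: contigs (`contig_id`, `length`, `gc`,
#'   `coverage`, `platform`).
#' * `read_gene_table()`: gene coordinates (`gene_id`, `contig_id`,
#'   `start`, `end`, `strand`).
#' * `read_otu_table()`: OTU records (`otu_id`, `sample_id`, `read_count`,
#'   `best_ref_identity`, `best_ref_coverage`, `lineage`).
#'
#' @param path File path of a tab-separated file with a header row.
#' @return A tibble.
#' @name read_tables
NULL

read_tsv_typed <- function(path, numeric_cols = character(),
                           integer_cols = character()) {
  x <- readr::read_tsv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  for (cc in intersect(numeric_cols, names(x))) x[[cc]] <- as.numeric(x[[cc]])
  for (cc in intersect(integer_cols, names(x))) x[[cc]] <- as.integer(x[[cc]])
  x
}

#' @rdname read_tables
#' @export
read_hit_table <- function(path) {
  read_tsv_typed(path, numeric_cols = c("bit_score", "e_value", "pident"))
}

#' @rdname read_tables
#' @export
read_family_hits <- function(path) {
  read_tsv_typed(path, numeric_cols = c("e_value", "score"))
}

#' @rdname read_tables
#' @export
read_mapping_table <- function(path) {
  read_tsv_typed(path, numeric_cols = "identity")
}

#' @rdname read_tables
#' @export
read_backmap <- function(path) read_tsv_typed(path)

#' @rdname read_tables
#' @export
read_contig_table <- function(path) {
  read_tsv_typed(path, numeric_cols = c("gc", "coverage"),
                 integer_cols = "length")
}

#' @rdname read_tables
#' @export
read_gene_table <- function(path) {
  read_tsv_typed(path, integer_cols = c("start", "end"))
}

#' @rdname read_tables
#' @export
read_otu_table <- function(path) {
  x <- read_tsv_typed(path,
                      numeric_cols = c("best_ref_identity",
                                       "best_ref_coverage"),
                      integer_cols = "read_count")
  if ("lineage" %in% names(x)) x$lineage[is.na(x$lineage)] <- ""
  x
}

#' Write a simulated dataset to a directory
#'
#' Serialises every table of a [simulate_metagenome()] result as TSV, the
#' contigs additionally as FASTA (sequences drawn to match each contig's
#' length and GC content), and the ground truth alongside. Files
#' round-trip through the `read_*` table readers.
#'
#' @param sim Result of [simulate_metagenome()].
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths written.
#' @export
write_simulation <- function(sim, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  wr <- function(x, name) {
    p <- file.path(dir, paste0(name, ".tsv"))
    readr::write_tsv(x, p)
    paths <<- c(paths, p)
  }
  wr(sim$contigs, "contigs")
  wr(sim$genes, "genes")
  wr(sim$protein_hits, "protein_hits")
  wr(sim$cazyme_hits, "cazyme_hits")
  wr(sim$pfam_hits, "pfam_hits")
  wr(sim$mappings, "mappings")
  wr(sim$backmap, "backmap")
  wr(sim$bins, "bins")
  wr(sim$truth$genes, "truth_genes")
  wr(sim$truth$contigs, "truth_contigs")

  fa <- file.path(dir, "contigs.fasta")
  seqs <- withr::with_seed(sim$truth$config$seed, {
    purrr::map2_chr(sim$contigs$length, sim$contigs$gc, function(len, gc) {
      p_gc <- gc / 100
      paste(sample(c("G", "C", "A", "T"), len, replace = TRUE,
                   prob = c(p_gc / 2, p_gc / 2, (1 - p_gc) / 2,
                            (1 - p_gc) / 2)),
            collapse = "")
    })
  })
  writeLines(paste0(">", sim$contigs$contig_id, "\n", seqs), fa)
  paths <- c(paths, fa)
  invisible(paths)
}
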