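#' Coverage-weighted gene frequency
#'
#' Frequency (in percent) of a set of target genes among all genes,
#' weighting each gene by its average read coverage:
#' `100 * sum(coverage over targets) / sum(coverage over all genes)`.
#' A gene's average coverage is taken as its contig's mean coverage unless
#' per-gene depths are supplied.
#'
#' @param target_genes Character vector of target gene ids (subset of
#'   `all_genes`).
#' @param all_genes Character vector of all gene ids in scope.
#' @param gene_coverage Named numeric vector of per-gene coverages
#'   (non-negative), covering `all_genes`.
#' @return Frequency in percent.
#' @export
#' @examples
#' gene_frequency(c("g1", "g2"), c("g1", "g2", "g3"),
#'                c(g1 = 10, g2 = 30, g3 = 60))  # 40
gene_frequency <- function(target_genes, all_genes, gene_coverage) {
  target_genes <- as.character(target_genes)
  all_genes <- as.character(all_genes)
  if (length(setdiff(target_genes, all_genes)) > 0) {
    abort("target genes must be a subset of all genes")
  }
  cov_all <- gene_coverage[all_genes]
  if (anyNA(cov_all)) abort("missing coverage for some genes")
  if (any(cov_all < 0)) abort("coverages must be non-negative")
  total <- sum(cov_all)
  if (total <= 0) abort("no covered genes")
  if (length(target_genes) == 0) return(0)
  100 * sum(gene_coverage[target_genes]) / total
}

#' Per-family gene-frequency profiles, community-wide or per taxobin
#'
#' For each scope (the whole community, or each taxonomic bin of contigs)
#' and each annotated family, computes the coverage-weighted gene frequency
#' of that family's genes among all genes in the scope. Per-bin profiles
#' restrict numerator and denominator to the bin's own genes, so they read
#' as within-clade gene repertoires. Genes carrying several family calls
#' count in each family's numerator.
#'
#' @param calls Data frame with `gene_id`, `family` (e.g. from
#'   [consensus_cazymes()] or [pfam_family_calls()]).
#' @param genes Data frame with `gene_id`, `contig_id` and optionally
#'   `coverage` (per-gene depth; defaults to the contig's coverage).
#' @param contigs Data frame with `contig_id`, `coverage`.
#' @param scope_assignments Optional data frame with `contig_id`, `taxobin`
#'   assigning contigs to bins; `NULL` gives only the community scope.
#' @param sample_id Label stored in the output. Default `"sample"`.
#' @return Tibble of class `frequency_profile`: `sample_id`, `scope`,
#'   `family`, `frequency` (percent). Scopes with zero genes are omitted
#'   with a warning.
#' @export
family_profile <- function(calls, genes, contigs, scope_assignments = NULL,
                           sample_id = "sample") {
  calls <- as_tibble(calls)
  genes <- as_tibble(genes)
  contigs <- as_tibble(contigs)
  if (!("coverage" %in% names(genes))) {
    genes <- left_join(genes,
                       select(contigs, "contig_id", "coverage"),
                       by = "contig_id")
  }
  if (anyNA(genes$coverage)) abort("gene(s) on contigs without coverage")
  cov <- setNames(as.numeric(genes$coverage), as.character(genes$gene_id))

  scopes <- list(community = as.character(genes$gene_id))
  if (!is.null(scope_assignments)) {
    scope_assignments <- as_tibble(scope_assignments)
    gb <- left_join(genes,
                    select(scope_assignments, "contig_id", "taxobin"),
                    by = "contig_id")
    for (b in unique(stats::na.omit(gb$taxobin))) {
      scopes[[b]] <- as.character(gb$gene_id[!is.na(gb$taxobin) &
                                               gb$taxobin == b])
    }
  }

  fams <- sort(unique(as.character(calls$family)))
  out <- purrr::imap(scopes, function(gene_set, scope_name) {
    if (length(gene_set) == 0 || sum(cov[gene_set]) <= 0) {
      warn(paste0("scope '", scope_name, "' has no covered genes; omitted"))
      return(NULL)
    }
    tibble(
      sample_id = sample_id, scope = scope_name, family = fams,
      frequency = vapply(fams, function(f) {
        tg <- intersect(unique(calls$gene_id[calls$family == f]), gene_set)
        gene_frequency(tg, gene_set, cov)
      }, numeric(1), USE.NAMES = FALSE)
    )
  }) |> bind_rows()
  class(out) <- c("frequency_profile", class(out))
  out
}

#' GC-coverage contig filter for bin visualisation
#'
#' Selects contigs suitable for a GC-content versus coverage bubble plot:
#' platform-specific length floors (pyrosequencing assemblies yield shorter
#' trustworthy contigs than Illumina ones), a GC window, and exclusion of
#' sparse very-high-coverage contigs via an empirical coverage quantile.
#' All boundaries are inclusive.
#'
#' @param contigs Data frame with `contig_id`, `length`, `gc`, `coverage`,
#'   `platform` (`"454"` or `"illumina"`) and optionally `taxobin`.
#' @param min_len_454 Length floor for 454 contigs (bp). Default 2750.
#' @param min_len_illumina Length floor for Illumina contigs (bp).
#'   Default 15000.
#' @param gc_lo,gc_hi GC window in percent. Defaults 20 and 60.
#' @param cov_hi_quantile Coverage quantile above which contigs are
#'   excluded. Default 0.99.
#' @return Tibble of passing contigs with an added `radius` column
#'   proportional to contig length (suitable as a bubble radius).
#' @export
gc_coverage_filter <- function(contigs, min_len_454 = 2750,
                               min_len_illumina = 15000,
                               gc_lo = 20, gc_hi = 60,
                               cov_hi_quantile = 0.99) {
  contigs <- as_tibble(contigs)
  if (nrow(contigs) == 0) return(mutate(contigs, radius = numeric(0)))
  cov_cap <- quantile(contigs$coverage, cov_hi_quantile, names = FALSE)
  min_len <- ifelse(contigs$platform == "454", min_len_454,
                    min_len_illumina)
  out <- contigs[contigs$length >= min_len &
                   contigs$gc >= gc_lo & contigs$gc <= gc_hi &
                   contigs$coverage <= cov_cap, , drop = FALSE]
  mutate(out, radius = .data$length / max(contigs$length))
}
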