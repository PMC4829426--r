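#' Default per-rank vote thresholds
#'
#' The rank-progressive classifiers accept a rank when the winning taxon's
#' share of the bit-score (or predictor-weight) vote reaches the rank's
#' threshold. Thresholds must be in (0, 1] and non-decreasing from
#' superkingdom to species — the vote becomes stricter as it descends. The
#' defaults (0.50 to 0.90) are package defaults; every value is a knob.
#'
#' @param superkingdom,phylum,class,order,family,genus,species Per-rank
#'   thresholds in (0, 1], non-decreasing.
#' @return Named numeric vector of length 7 in rank order.
#' @export
#' @examples
#' kirsten_thresholds()
#' kirsten_thresholds(species = 0.95)
kirsten_thresholds <- function(superkingdom = 0.50, phylum = 0.55,
                               class = 0.60, order = 0.65, family = 0.70,
                               genus = 0.80, species = 0.90) {
  t <- c(superkingdom = superkingdom, phylum = phylum, class = class,
         order = order, family = family, genus = genus, species = species)
  if (any(t <= 0) || any(t > 1)) abort("thresholds must be in (0, 1]")
  if (is.unsorted(t)) {
    abort("thresholds must be non-decreasing from superkingdom to species")
  }
  t
}

#' Filter a protein hit table by E-value and hit count
#'
#' Keeps hits with `e_value <= max_e`, sorts by descending bit score and
#' truncates to the `max_hits` best per gene. Defaults mirror the UBLAST
#' post-processing used upstream of the classifier: E-value cutoff 1e-10
#' and a maximum of 500 hits.
#'
#' @param hits Data frame with at least `bit_score` and `e_value`; a
#'   `gene_id` column, if present, scopes the truncation per gene.
#' @param max_e E-value cutoff (inclusive). Default `1e-10`.
#' @param max_hits Maximum retained hits per gene. Default `500`.
#' @return Tibble of surviving hits, bit score descending within gene.
#' @export
filter_hits <- function(hits, max_e = 1e-10, max_hits = 500) {
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) return(hits)
  out <- filter(hits, .data$e_value <= max_e)
  out <- arrange(out, desc(.data$bit_score))
  if ("gene_id" %in% names(out)) {
    out <- out |>
      group_by(.data$gene_id) |>
      slice_head(n = max_hits) |>
      ungroup()
  } else {
    out <- slice_head(out, n = max_hits)
  }
  out
}

# core rank-progressive weighted vote over one gene's hits.
# taxa: character vector of subject taxon ids; weights: bit scores.
# Returns lineage as character vector of taxon ids.
vote_lineage <- function(taxa, weights, tree, thresholds) {
  if (length(taxa) == 0) return(character(0))
  unknown <- setdiff(unique(taxa), rownames(tree$ancestors))
  if (length(unknown) > 0) {
    abort(paste0("unknown subject taxa: ", paste(unknown, collapse = ", ")))
  }
  anc <- tree$ancestors[taxa, , drop = FALSE]
  keep <- rep(TRUE, length(taxa))
  lineage <- character(0)
  for (r in 1:7) {
    a <- anc[keep, r]
    w <- weights[keep]
    ok <- !is.na(a)
    if (!any(ok)) break                      # no hit resolves this rank
    tot <- sum(w[ok])
    ws <- rowsum(w[ok], a[ok])
    mx <- max(ws)
    if (sum(ws == mx) > 1) break             # tie: stop at previous rank
    if (mx / tot < thresholds[r]) break
    win <- rownames(ws)[which.max(ws)]
    lineage <- c(lineage, win)
    # restrict to the winner's subtree; rank-deficient hits stay
    keep <- keep & (is.na(anc[, r]) | anc[, r] == win)
  }
  lineage
}

#' Classify one gene from its protein hits (rank-progressive weighted vote)
#'
#' Walks the seven ranks from superkingdom to species. At each rank the
#' surviving hits are grouped by their ancestor taxon at that rank and each
#' taxon is weighted by the sum of its hits' bit scores. If the heaviest
#' taxon's share of the vote reaches the rank's threshold, it is fixed,
#' hits outside its subtree are discarded, and the walk continues; else it
#' stops. Hits whose reference lineage does not reach the current rank
#' abstain from that vote (they neither support nor veto) but remain
#' available at no deeper rank than they resolve. A tie for the maximum
#' stops the walk; threshold equality passes.
#'
#' @param hits Data frame with `subject_taxon` and `bit_score` (already
#'   filtered, e.g. by [filter_hits()]).
#' @param tree A `taxonomy`.
#' @param thresholds Per-rank thresholds, see [kirsten_thresholds()].
#' @return Lineage: character vector of taxon ids, length 0-7.
#' @export
#' @examples
#' nodes <- data.frame(taxon_id = c("r", "b", "p", "c", "o", "f", "g", "s"),
#'                     parent_id = c("r", "r", "b", "p", "c", "o", "f", "g"),
#'                     rank = c("root", tax_ranks()))
#' tree <- load_taxonomy(nodes)
#' classify_gene(data.frame(subject_taxon = "s", bit_score = 100), tree)
classify_gene <- function(hits, tree, thresholds = kirsten_thresholds()) {
  stopifnot(inherits(tree, "taxonomy"))
  hits <- as_tibble(hits)
  if (nrow(hits) == 0) return(character(0))
  vote_lineage(as.character(hits$subject_taxon), as.numeric(hits$bit_score),
               tree, thresholds)
}

#' Classify all genes of a hit table
#'
#' Applies [classify_gene()] to each `gene_id` group of a (filtered) hit
#' table and returns one row per gene with the assigned lineage, its depth,
#' and the taxon id fixed at each rank (`NA` beyond the assignment depth).
#'
#' @param hit_table Data frame with `gene_id`, `subject_taxon`, `bit_score`.
#' @param tree A `taxonomy`.
#' @param thresholds Per-rank thresholds, see [kirsten_thresholds()].
#' @param gene_ids Optional character vector of genes that must appear in
#'   the output even if they have no surviving hits (e.g. every predicted
#'   gene, when the hit table was E-value filtered).
#' @return Tibble with columns `gene_id`, `depth`, `lineage`
#'   (semicolon-joined taxon names) and one column per rank holding taxon
#'   ids. Genes with zero hits are reported with an empty lineage.
#' @export
classify_genes <- function(hit_table, tree,
                           thresholds = kirsten_thresholds(),
                           gene_ids = NULL) {
  stopifnot(inherits(tree, "taxonomy"))
  hit_table <- as_tibble(hit_table)
  unknown <- setdiff(unique(as.character(hit_table$subject_taxon)),
                     rownames(tree$ancestors))
  if (length(unknown) > 0) {
    abort(paste0("unknown subject taxa: ", paste(unknown, collapse = ", ")))
  }
  genes <- union(unique(as.character(hit_table$gene_id)),
                 as.character(gene_ids %||% character(0)))
  rows <- lapply(genes, function(g) {
    sub <- hit_table[hit_table$gene_id == g, , drop = FALSE]
    lin <- classify_gene(sub, tree, thresholds)
    c(list(gene_id = g, depth = length(lin),
           lineage = lineage_string(tree, lin)),
      as.list(setNames(lineage_pad(lin), tax_ranks())))
  })
  out <- bind_rows(rows)
  if (nrow(out) == 0) {
    out <- tibble(gene_id = character(), depth = integer(),
                  lineage = character())
  }
  out
}
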