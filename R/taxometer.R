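#' Consensus taxonomy for one contig from multiple predictors
#'
#' Consolidates per-gene lineage predictions from several classifiers plus
#' read-mapping path evidence into one lineage per contig by a weighted
#' per-rank vote over the seven ranks. Each gene-based predictor speaks
#' with one voice per contig: at each rank its vote goes to the taxon named
#' by the plurality of its genes (among genes consistent with the lineage
#' fixed so far); an internal tie makes it abstain. The mapping evidence
#' enters as one pseudo-predictor whose weight is split over taxa in
#' proportion to path read counts. At each rank, if the heaviest taxon's
#' share of the cast weight reaches the rank threshold it is fixed with
#' that share recorded as support; otherwise (or on a tie for the maximum)
#' the walk stops. Evidence contradicting an already-fixed ancestor
#' abstains at deeper ranks.
#'
#' @param gene_preds Data frame with `gene_id`, `predictor_id`, `lineage`
#'   (semicolon-joined taxon names) for this contig's genes. May have zero
#'   rows.
#' @param path_evidence Data frame with `lineage`, `n_reads` for this
#'   contig (e.g. one contig's rows of [contig_paths()]), or `NULL`.
#' @param tree A `taxonomy`.
#' @param weights Named numeric vector of positive predictor weights;
#'   unnamed predictors (and the mapping pseudo-predictor `"mapping"`)
#'   default to 1.
#' @param thresholds Per-rank thresholds, see [kirsten_thresholds()].
#' @return List with `lineage` (character vector of taxon ids) and
#'   `support` (numeric vector, one value per assigned rank).
#' @export
consensus_contig <- function(gene_preds, path_evidence = NULL, tree,
                             weights = NULL,
                             thresholds = kirsten_thresholds()) {
  stopifnot(inherits(tree, "taxonomy"))
  gene_preds <- as_tibble(gene_preds)
  if (!is.null(weights) && any(weights <= 0)) {
    abort("predictor weights must be positive")
  }
  wt <- function(p) {
    if (!is.null(weights) && p %in% names(weights)) weights[[p]] else 1
  }

  # per-predictor matrices of padded lineages (genes x 7 ranks)
  pred_ids <- unique(as.character(gene_preds$predictor_id))
  pred_mats <- lapply(pred_ids, function(p) {
    lins <- gene_preds$lineage[gene_preds$predictor_id == p]
    t(vapply(lins, function(s) lineage_pad(parse_lineage(tree, s)),
             character(7)))
  })
  names(pred_mats) <- pred_ids

  path_mat <- NULL
  path_counts <- NULL
  if (!is.null(path_evidence) && nrow(as_tibble(path_evidence)) > 0) {
    path_evidence <- as_tibble(path_evidence)
    path_mat <- t(vapply(path_evidence$lineage,
                         function(s) lineage_pad(parse_lineage(tree, s)),
                         character(7)))
    path_counts <- as.numeric(path_evidence$n_reads)
  }

  consistent <- function(mat, fixed, r) {
    # rows whose entries at ranks 1..r-1 match the fixed lineage and that
    # resolve rank r
    if (nrow(mat) == 0) return(logical(0))
    ok <- !is.na(mat[, r])
    if (r > 1) {
      for (k in seq_len(r - 1)) {
        ok <- ok & !is.na(mat[, k]) & mat[, k] == fixed[k]
      }
    }
    ok
  }

  lineage <- character(0)
  support <- numeric(0)
  for (r in 1:7) {
    cast_taxon <- character(0)
    cast_weight <- numeric(0)
    for (p in pred_ids) {
      mat <- pred_mats[[p]]
      ok <- consistent(mat, lineage, r)
      if (!any(ok)) next
      votes <- table(mat[ok, r])
      top <- votes == max(votes)
      if (sum(top) > 1) next                # internal tie: abstain
      cast_taxon <- c(cast_taxon, names(votes)[which.max(votes)])
      cast_weight <- c(cast_weight, wt(p))
    }
    if (!is.null(path_mat)) {
      ok <- consistent(path_mat, lineage, r)
      if (any(ok)) {
        share <- rowsum(path_counts[ok], path_mat[ok, r])
        share <- share / sum(share) * wt("mapping")
        cast_taxon <- c(cast_taxon, rownames(share))
        cast_weight <- c(cast_weight, as.numeric(share))
      }
    }
    if (length(cast_taxon) == 0) break
    ws <- rowsum(cast_weight, cast_taxon)
    mx <- max(ws)
    if (sum(ws == mx) > 1) break            # cross-predictor tie: stop
    f <- mx / sum(ws)
    if (f < thresholds[r]) break
    lineage <- c(lineage, rownames(ws)[which.max(ws)])
    support <- c(support, f)
  }
  list(lineage = lineage, support = support)
}

#' Consensus taxonomy for every contig
#'
#' Runs [consensus_contig()] per contig over a gene-prediction table and a
#' path-evidence table and returns a long tibble of per-rank assignments.
#' The result carries a `taxometer_consensus` class whose [glance()] method
#' reports the fraction of contigs (at or above a length floor, when contig
#' lengths are supplied) that received a non-empty lineage.
#'
#' @param gene_preds Data frame with `contig_id`, `gene_id`,
#'   `predictor_id`, `lineage` (semicolon-joined names).
#' @param paths Data frame with `contig_id`, `lineage`, `n_reads`
#'   (see [contig_paths()]), or `NULL`.
#' @param tree A `taxonomy`.
#' @param weights,thresholds Passed to [consensus_contig()].
#' @param contigs Optional contig table with `contig_id`, `length`, used by
#'   [glance()] to restrict the classified-fraction summary.
#' @param min_len Length floor (bp) for the classified-fraction summary.
#'   Default 1000.
#' @return Tibble of class `taxometer_consensus` with columns `contig_id`,
#'   `rank`, `taxon_id`, `taxon`, `support`; contigs left unclassified
#'   appear with `rank = NA`.
#' @export
consensus_all <- function(gene_preds, paths = NULL, tree, weights = NULL,
                          thresholds = kirsten_thresholds(),
                          contigs = NULL, min_len = 1000) {
  stopifnot(inherits(tree, "taxonomy"))
  gene_preds <- as_tibble(gene_preds)
  paths <- if (is.null(paths)) {
    tibble(contig_id = character(), lineage = character(),
           n_reads = integer())
  } else {
    as_tibble(paths)
  }
  ids <- union(unique(as.character(gene_preds$contig_id)),
               unique(as.character(paths$contig_id)))
  rows <- lapply(ids, function(cid) {
    res <- consensus_contig(
      gene_preds[gene_preds$contig_id == cid, , drop = FALSE],
      paths[paths$contig_id == cid, , drop = FALSE],
      tree, weights, thresholds
    )
    d <- length(res$lineage)
    if (d == 0) {
      tibble(contig_id = cid, rank = NA_character_,
             taxon_id = NA_character_, taxon = NA_character_,
             support = NA_real_)
    } else {
      tibble(contig_id = cid, rank = tax_ranks()[seq_len(d)],
             taxon_id = res$lineage,
             taxon = lineage_names(tree, res$lineage),
             support = res$support)
    }
  })
  out <- bind_rows(rows)
  classified <- vapply(split(out$rank, out$contig_id),
                       function(r) any(!is.na(r)), logical(1))
  eligible <- names(classified)
  if (!is.null(contigs)) {
    contigs <- as_tibble(contigs)
    eligible <- intersect(
      eligible,
      as.character(contigs$contig_id[contigs$length >= min_len]))
  }
  attr(out, "n_contigs") <- length(ids)
  attr(out, "n_eligible") <- length(eligible)
  attr(out, "frac_classified") <-
    if (length(eligible) > 0) mean(classified[eligible]) else NA_real_
  attr(out, "min_len") <- min_len
  class(out) <- c("taxometer_consensus", class(out))
  out
}

#' Summarise a contig consensus run
#'
#' @param x A `taxometer_consensus` from [consensus_all()].
#' @param ... Unused.
#' @return One-row tibble: number of contigs, number at or above the length
#'   floor, and the fraction of those with a non-empty consensus lineage.
#' @exportS3Method generics::glance
glance.taxometer_consensus <- function(x, ...) {
  tibble(
    n_contigs = attr(x, "n_contigs"),
    n_eligible = attr(x, "n_eligible"),
    min_len = attr(x, "min_len"),
    frac_classified = attr(x, "frac_classified")
  )
}

#' Deepest consensus assignment per contig
#'
#' Convenience accessor: one row per contig with the deepest assigned rank,
#' taxon, and the full lineage string.
#'
#' @param x A `taxometer_consensus` from [consensus_all()].
#' @param tree The `taxonomy` the consensus was computed against.
#' @return Tibble with `contig_id`, `depth`, `rank`, `taxon`, `lineage`.
#' @export
consensus_lineages <- function(x, tree) {
  stopifnot(inherits(x, "taxometer_consensus"))
  split(as_tibble(x), x$contig_id) |>
    purrr::map(function(d) {
      if (all(is.na(d$rank))) {
        tibble(contig_id = d$contig_id[1], depth = 0L,
               rank = NA_character_, taxon = NA_character_, lineage = "")
      } else {
        tibble(contig_id = d$contig_id[1], depth = nrow(d),
               rank = d$rank[nrow(d)], taxon = d$taxon[nrow(d)],
               lineage = paste(d$taxon, collapse = ";"))
      }
    }) |>
    bind_rows()
}
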