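# Independent reference implementations used as test oracles. These are
# deliberately written against the rule statements, not against the package
# internals: they materialise full per-rank vote tables from lineage_of()
# and aggregate with base R.

`%||%` <- function(a, b) if (is.null(a)) b else a

# Rank-by-rank weighted-vote classifier over explicit lineage rows.
oracle_classify <- function(hits, tree, thresholds) {
  if (nrow(hits) == 0) return(character(0))
  lin <- lapply(as.character(hits$subject_taxon),
                function(tx) lineage_of(tree, tx))
  w <- as.numeric(hits$bit_score)
  alive <- seq_along(lin)
  out <- character(0)
  for (r in 1:7) {
    votes <- list()
    for (i in alive) {
      if (length(lin[[i]]) >= r) {
        tx <- lin[[i]][r]
        votes[[tx]] <- (votes[[tx]] %||% 0) + w[i]
      }
    }
    if (length(votes) == 0) break
    vv <- unlist(votes)
    winners <- names(vv)[vv == max(vv)]
    if (length(winners) > 1) break
    if (max(vv) / sum(vv) < thresholds[r]) break
    out <- c(out, winners)
    alive <- alive[vapply(alive, function(i) {
      length(lin[[i]]) < r || lin[[i]][r] == winners
    }, logical(1))]
  }
  out
}

# Spearman rho via the rank formula (average ranks) and, for small tie-free
# samples, the exact two-sided p from the full permutation distribution of
# the sum of squared rank differences.
oracle_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  rho <- 1 - 6 * sum((rx - ry)^2) / (n * (n^2 - 1))
  list(rho = rho, p = oracle_spearman_p(x, y))
}

oracle_spearman_p <- function(x, y) {
  n <- length(x)
  stopifnot(n <= 7, !anyDuplicated(x), !anyDuplicated(y))
  rx <- rank(x); ry <- rank(y)
  s_obs <- sum((rx - ry)^2)
  perms <- permutations_of(n)
  s_all <- apply(perms, 1, function(p) sum((rx - ry[p])^2))
  mid <- (n^3 - n) / 6
  p1 <- if (s_obs > mid) mean(s_all >= s_obs) else mean(s_all <= s_obs)
  min(2 * p1, 1)
}

permutations_of <- function(n) {
  if (n == 1) return(matrix(1, 1, 1))
  sub <- permutations_of(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    cbind(k, sub + (sub >= k))
  }))
}

# Direct per-contig path tally from pooled loops.
oracle_contig_tally <- function(mappings, backmap, tree) {
  cid <- setNames(as.character(backmap$contig_id),
                  as.character(backmap$read_id))
  rec <- list()
  for (i in seq_len(nrow(mappings))) {
    rd <- as.character(mappings$read_id[i])
    if (!(rd %in% names(cid))) next
    path <- lineage_string(tree,
                           lineage_of(tree,
                                      as.character(mappings$reference_taxon[i])))
    key <- paste(cid[[rd]], path, sep = "\r")
    rec[[key]] <- (rec[[key]] %||% 0L) + 1L
  }
  if (length(rec) == 0) {
    return(tibble::tibble(contig_id = character(), lineage = character(),
                          n_reads = integer()))
  }
  parts <- strsplit(names(rec), "\r", fixed = TRUE)
  tibble::tibble(
    contig_id = vapply(parts, `[`, "", 1),
    lineage = vapply(parts, function(p) if (length(p) > 1) p[2] else "", ""),
    n_reads = as.integer(unlist(rec))
  )
}

# Base-R group-by tally of an OTU table collapsed at genus depth.
oracle_collapse <- function(otus) {
  genus_depth <- 6
  key <- vapply(as.character(otus$lineage), function(s) {
    if (is.na(s) || s == "") return("unclassified")
    p <- strsplit(s, ";", fixed = TRUE)[[1]]
    paste(p[seq_len(min(length(p), genus_depth))], collapse = ";")
  }, character(1), USE.NAMES = FALSE)
  stats::aggregate(read_count ~ taxon + sample_id,
                   data = data.frame(taxon = key,
                                     sample_id = otus$sample_id,
                                     read_count = otus$read_count),
                   FUN = sum)
}
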