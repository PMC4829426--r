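flat60 <- setNames(rep(0.6, 7), tax_ranks())

pred_row <- function(tree, gene, pred, taxon) {
  tibble::tibble(gene_id = gene, predictor_id = pred,
                 lineage = lineage_string(tree, lineage_of(tree, taxon)))
}

test_that("unanimous predictors yield their lineage with full support", {
  tree <- toy_tree()
  preds <- dplyr::bind_rows(
    pred_row(tree, "g1", "kirsten", "s1"),
    pred_row(tree, "g1", "carma_pfam", "s1"),
    pred_row(tree, "g1", "other", "s1")
  )
  res <- consensus_contig(preds, NULL, tree, thresholds = flat60)
  expect_equal(res$lineage, lineage_of(tree, "s1"))
  expect_equal(res$support, rep(1, 7))
})

test_that("no evidence at all gives an empty lineage", {
  tree <- toy_tree()
  res <- consensus_contig(tibble::tibble(gene_id = character(),
                                         predictor_id = character(),
                                         lineage = character()),
                          NULL, tree)
  expect_length(res$lineage, 0)
})

test_that("a 2-of-3 class vote fixes the class with support 2/3", {
  tree <- toy_tree()
  preds <- dplyr::bind_rows(
    pred_row(tree, "g1", "A", "s1"),   # class Flavobacteriia
    pred_row(tree, "g2", "B", "s2"),   # class Flavobacteriia
    pred_row(tree, "g3", "C", "s4")    # class Gammaproteobacteria
  )
  res <- consensus_contig(preds, NULL, tree, thresholds = flat60)
  d <- length(res$lineage)
  expect_gte(d, 3)
  expect_equal(res$lineage[3], "flavo")
  expect_equal(res$support[3], 2 / 3)
  # C contradicts the fixed class, so it abstains below: the order vote is
  # A vs B (s1 vs s2, distinct orders), a 50:50 tie -> stop at class? No:
  # a tie among taxa stops the walk, so depth is exactly 3
  expect_equal(d, 3)
})

test_that("contradicting evidence abstains below the fixed rank", {
  tree <- toy_tree()
  preds <- dplyr::bind_rows(
    pred_row(tree, "g1", "A", "s1"),
    pred_row(tree, "g2", "B", "s1"),
    pred_row(tree, "g3", "C", "s4")
  )
  res <- consensus_contig(preds, NULL, tree, thresholds = flat60)
  # below class only A and B vote; they agree down to species s1
  expect_equal(res$lineage, lineage_of(tree, "s1"))
  expect_equal(res$support[4:7], rep(1, 4))
})

test_that("mapping evidence votes proportionally to path read counts", {
  tree <- toy_tree()
  paths <- tibble::tibble(
    lineage = c(lineage_string(tree, lineage_of(tree, "s1")),
                lineage_string(tree, lineage_of(tree, "s4"))),
    n_reads = c(90, 10)
  )
  res <- consensus_contig(tibble::tibble(gene_id = character(),
                                         predictor_id = character(),
                                         lineage = character()),
                          paths, tree, thresholds = flat60)
  # class vote: 0.9 vs 0.1 of the mapping weight -> Flavobacteriia
  expect_equal(res$lineage, lineage_of(tree, "s1"))
  expect_equal(res$support[3], 0.9)
})

test_that("consensus is invariant to rescaling all predictor weights", {
  tree <- toy_tree()
  preds <- dplyr::bind_rows(
    pred_row(tree, "g1", "A", "s1"),
    pred_row(tree, "g2", "B", "s2"),
    pred_row(tree, "g3", "C", "s4")
  )
  paths <- tibble::tibble(
    lineage = lineage_string(tree, lineage_of(tree, "s2")),
    n_reads = 40
  )
  w1 <- c(A = 1, B = 2, C = 0.5, mapping = 1.5)
  w2 <- w1 * 11
  r1 <- consensus_contig(preds, paths, tree, weights = w1,
                         thresholds = flat60)
  r2 <- consensus_contig(preds, paths, tree, weights = w2,
                         thresholds = flat60)
  expect_equal(r1, r2)
  expect_error(consensus_contig(preds, NULL, tree, weights = c(A = -1)),
               "positive")
})

test_that("randomised consensus respects unanimity and prefix structure", {
  for (seed in 1:40) {
    tree <- random_tree(seed %% 6 + 1, max_children = 2)
    taxa <- setdiff(rownames(tree$ancestors), tree$root_id)
    preds <- withr::with_seed(seed + 300, {
      dplyr::bind_rows(lapply(1:3, function(k) {
        pred_row(tree, paste0("g", k), paste0("P", k), sample(taxa, 1))
      }))
    })
    sched <- random_schedule(seed + 400)
    res <- consensus_contig(preds, NULL, tree, thresholds = sched)
    lins <- lapply(preds$lineage, function(s) parse_lineage(tree, s))
    # structural check: the consensus is a prefix of some evidence lineage
    # (possibly through their LCA)
    if (length(res$lineage) > 0) {
      is_prefix <- vapply(lins, function(l) {
        length(l) >= length(res$lineage) &&
          all(l[seq_along(res$lineage)] == res$lineage)
      }, logical(1))
      expect_true(any(is_prefix) ||
                    identical(res$lineage, lca(lins)))
    }
    # unanimity property on the same tree
    uni <- dplyr::mutate(preds, lineage = preds$lineage[1])
    res_u <- consensus_contig(uni, NULL, tree, thresholds = sched)
    expect_equal(res_u$lineage, lins[[1]])
    expect_equal(res_u$support, rep(1, length(lins[[1]])))
  }
})

test_that("removing an agreeing predictor never lengthens the lineage beyond it", {
  for (seed in 1:25) {
    tree <- random_tree(seed %% 6 + 1, max_children = 2)
    taxa <- setdiff(rownames(tree$ancestors), tree$root_id)
    preds <- withr::with_seed(seed + 500, {
      dplyr::bind_rows(lapply(1:4, function(k) {
        pred_row(tree, paste0("g", k), paste0("P", k), sample(taxa, 1))
      }))
    })
    res <- consensus_contig(preds, NULL, tree, thresholds = flat60)
    if (length(res$lineage) == 0) next
    # drop a predictor whose lineage is exactly the consensus: it agreed at
    # every fixed rank and abstained below, so its removal cannot open a
    # deeper vote it was blocking
    agree <- vapply(seq_len(nrow(preds)), function(i) {
      l <- parse_lineage(tree, preds$lineage[i])
      identical(l, res$lineage)
    }, logical(1))
    if (!any(agree)) next
    drop <- which(agree)[1]
    res2 <- consensus_contig(preds[-drop, ], NULL, tree,
                             thresholds = flat60)
    k <- min(length(res2$lineage), length(res$lineage))
    if (k > 0) expect_equal(res2$lineage[seq_len(k)], res$lineage[seq_len(k)])
    expect_lte(length(res2$lineage), length(res$lineage))
  }
})

test_that("the batch driver matches per-contig runs and summarises coverage", {
  tree <- toy_tree()
  preds <- dplyr::bind_rows(
    dplyr::mutate(pred_row(tree, "g1", "A", "s1"), contig_id = "c1"),
    dplyr::mutate(pred_row(tree, "g2", "B", "s1"), contig_id = "c1"),
    dplyr::mutate(pred_row(tree, "g3", "A", "s4"), contig_id = "c2")
  )
  res <- consensus_all(preds, NULL, tree,
                       contigs = tibble::tibble(contig_id = c("c1", "c2"),
                                                length = c(2000, 800)))
  single <- consensus_contig(preds[preds$contig_id == "c1", ], NULL, tree)
  expect_equal(res$taxon_id[res$contig_id == "c1"], single$lineage)
  g <- glance(res)
  expect_equal(g$n_contigs, 2)
  expect_equal(g$n_eligible, 1)                 # only c1 passes 1 kbp
  expect_equal(g$frac_classified, 1)
  lin <- consensus_lineages(res, tree)
  expect_equal(nrow(lin), 2)
  expect_equal(lin$depth[lin$contig_id == "c2"], 7)
})
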