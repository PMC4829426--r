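flat60 <- setNames(rep(0.6, 7), tax_ranks())

test_that("hit filtering applies the E-value cutoff and hit cap", {
  hits <- tibble::tibble(gene_id = "g",
                         subject_taxon = "s1",
                         bit_score = c(50, 60, 70),
                         e_value = c(1e-20, 1e-9, 1e-11))
  expect_equal(nrow(filter_hits(hits)), 2)       # 1e-9 fails the 1e-10 cutoff
  expect_setequal(filter_hits(hits)$e_value, c(1e-20, 1e-11))

  many <- tibble::tibble(gene_id = "g", subject_taxon = "s1",
                         bit_score = sample(1:600), e_value = 1e-30)
  kept <- filter_hits(many)
  expect_equal(nrow(kept), 500)
  expect_setequal(kept$bit_score, 101:600)       # the 500 highest bit scores

  empty <- tibble::tibble(gene_id = character(), subject_taxon = character(),
                          bit_score = numeric(), e_value = numeric())
  expect_equal(nrow(filter_hits(empty)), 0)
})

test_that("a single hit yields the full lineage of its species", {
  tree <- toy_tree()
  hits <- tibble::tibble(subject_taxon = "s1", bit_score = 100)
  expect_equal(classify_gene(hits, tree, kirsten_thresholds(0.5, 0.5, 0.5,
                                                            0.5, 0.5, 0.5,
                                                            0.5)),
               lineage_of(tree, "s1"))
})

test_that("the class vote follows the bit-score fractions rank by rank", {
  tree <- toy_tree()
  # 200+150+100 bits to three Flavobacteriia species (distinct orders),
  # 120 bits to one Gammaproteobacteria species; class vote 450/570
  hits <- tibble::tibble(subject_taxon = c("s1", "s2", "s3", "s4"),
                         bit_score = c(200, 150, 100, 120))
  sched <- flat60
  sched["class"] <- 0.6
  got <- classify_gene(hits, tree, sched)
  # 450/570 = 0.789 passes 0.6 at class; orders then split 200/150/100,
  # max 200/450 = 0.444 < 0.6, so the walk stops below class
  expect_equal(got, c("bact", "phyX", "flavo"))
  # the 120-bit hit is outside the winning subtree: with it gone, the
  # order vote is unchanged, confirming the discard
  expect_equal(classify_gene(hits[1:3, ], tree, sched)[-(1:3)],
               got[-(1:3)])

  sched["class"] <- 0.9                          # 0.789 < 0.9
  expect_equal(classify_gene(hits, tree, sched), c("bact", "phyX"))
})

test_that("a tie at the top weight stops at the previous rank", {
  tree <- toy_tree()
  hits <- tibble::tibble(subject_taxon = c("s1", "s4"),
                         bit_score = c(100, 100))
  # classes tie 100:100 at class; sk and phylum are unanimous
  expect_equal(classify_gene(hits, tree, flat60), c("bact", "phyX"))
})

test_that("rank-deficient hits abstain without vetoing deeper ranks", {
  tree <- toy_tree()
  # one deep hit plus a class-level hit: the class-level hit supports the
  # path down to class and abstains below, so the species is still reached
  hits <- tibble::tibble(subject_taxon = c("s1", "flavo"),
                         bit_score = c(100, 400))
  expect_equal(classify_gene(hits, tree, flat60), lineage_of(tree, "s1"))
})

test_that("batch classification composes and reports hit-less genes", {
  tree <- toy_tree()
  tbl <- tibble::tibble(
    gene_id = c("a", "a", "b"),
    subject_taxon = c("s1", "s2", "s4"),
    bit_score = c(100, 30, 80),
    e_value = 1e-30
  )
  out <- classify_genes(tbl, tree, flat60, gene_ids = c("a", "b", "c"))
  expect_setequal(out$gene_id, c("a", "b", "c"))
  for (g in c("a", "b")) {
    sub <- tbl[tbl$gene_id == g, ]
    expect_equal(out$depth[out$gene_id == g],
                 length(classify_gene(sub, tree, flat60)))
  }
  expect_equal(out$depth[out$gene_id == "c"], 0)
  expect_equal(out$lineage[out$gene_id == "c"], "")
  expect_error(classify_genes(tibble::tibble(gene_id = "g",
                                             subject_taxon = "zzz",
                                             bit_score = 1),
                              tree),
               "unknown subject taxa.*zzz")
})

test_that("classification matches the exhaustive vote-table oracle", {
  for (seed in 1:150) {
    tree <- random_tree(seed %% 7 + 1, max_children = 2)
    hits <- random_hits(tree, n_hits = seed %% 10 + 1, seed = seed + 1000)
    sched <- random_schedule(seed + 2000)
    expect_equal(classify_gene(hits, tree, sched),
                 oracle_classify(hits, tree, sched),
                 info = paste("seed", seed))
  }
})

test_that("raising any threshold never deepens the result", {
  for (seed in 1:60) {
    tree <- random_tree(seed %% 5 + 1, max_children = 2)
    hits <- random_hits(tree, n_hits = 8, seed = seed + 3000)
    sched <- random_schedule(seed + 4000)
    base <- classify_gene(hits, tree, sched)
    bumped <- sched
    r <- seed %% 7 + 1
    bumped[r:7] <- pmax(bumped[r:7], min(1, sched[r] + 0.2))
    expect_lte(length(classify_gene(hits, tree, bumped)), length(base))
  }
})

test_that("reinforcing the returned lineage never shortens it", {
  for (seed in 1:60) {
    tree <- random_tree(seed %% 5 + 1, max_children = 2)
    hits <- random_hits(tree, n_hits = 6, seed = seed + 5000)
    sched <- random_schedule(seed + 6000)
    base <- classify_gene(hits, tree, sched)
    if (length(base) == 0) next
    # add a strong hit to a species descending through the current result
    species <- rownames(tree$ancestors)[tree$depth == 7]
    ok <- species[tree$ancestors[species, length(base)] ==
                    base[length(base)]]
    extra <- tibble::tibble(gene_id = "g", subject_taxon = ok[1],
                            bit_score = 500, e_value = 1e-40)
    longer <- classify_gene(dplyr::bind_rows(hits, extra), tree, sched)
    expect_gte(length(longer), length(base))
    expect_equal(longer[seq_along(base)], base)
  }
})

test_that("the vote is invariant to rescaling all bit scores", {
  for (seed in 1:30) {
    tree <- random_tree(seed %% 5 + 1, max_children = 2)
    hits <- random_hits(tree, n_hits = 7, seed = seed + 7000)
    sched <- random_schedule(seed + 8000)
    scaled <- dplyr::mutate(hits, bit_score = bit_score * 7.3)
    expect_equal(classify_gene(scaled, tree, sched),
                 classify_gene(hits, tree, sched))
  }
})
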