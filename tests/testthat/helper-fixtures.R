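# Hand-built taxonomy fixtures used across the suite.

# Two classes under one phylum: Flavobacteriia with three species that
# diverge at order, and Gammaproteobacteria with a single deep chain.
toy_tree <- function() {
  rows <- list(
    c("root", "root", "root"),
    c("bact", "root", "superkingdom"),
    c("phyX", "bact", "phylum"),
    c("flavo", "phyX", "class"),
    c("gamma", "phyX", "class"),
    c("o1", "flavo", "order"), c("o2", "flavo", "order"),
    c("o3", "flavo", "order"), c("o4", "gamma", "order"),
    c("f1", "o1", "family"), c("f2", "o2", "family"),
    c("f3", "o3", "family"), c("f4", "o4", "family"),
    c("g1", "f1", "genus"), c("g2", "f2", "genus"),
    c("g3", "f3", "genus"), c("g4", "f4", "genus"),
    c("s1", "g1", "species"), c("s2", "g2", "species"),
    c("s3", "g3", "species"), c("s4", "g4", "species")
  )
  nodes <- do.call(rbind, rows)
  nodes <- data.frame(taxon_id = nodes[, 1], parent_id = nodes[, 2],
                      rank = nodes[, 3])
  nms <- data.frame(
    taxon_id = c("bact", "phyX", "flavo", "gamma"),
    name = c("Bacteria", "PhylumX", "Flavobacteriia", "Gammaproteobacteria")
  )
  load_taxonomy(nodes, nms)
}

# Random full-depth taxonomy with bounded size, deterministic per seed.
random_tree <- function(seed, max_children = 2) {
  withr::with_seed(seed, {
    ids <- "root"; parents <- "root"; ranks <- "root"
    prev <- "root"
    for (r in 1:7) {
      kids <- unlist(lapply(prev, function(p) {
        paste0("r", r, "n", seq_len(sample.int(max_children, 1)), "_", p)
      }))
      ids <- c(ids, kids)
      parents <- c(parents, sub("^r[0-9]+n[0-9]+_", "", kids))
      ranks <- c(ranks, rep(tax_ranks()[r], length(kids)))
      prev <- kids
    }
    load_taxonomy(data.frame(taxon_id = ids, parent_id = parents,
                             rank = ranks))
  })
}

# Random hit table over a tree's taxa; integer bit scores keep vote sums
# exact.
random_hits <- function(tree, n_hits, seed) {
  withr::with_seed(seed, {
    taxa <- setdiff(rownames(tree$ancestors), tree$root_id)
    tibble::tibble(
      gene_id = "g",
      subject_taxon = sample(taxa, n_hits, replace = TRUE),
      bit_score = sample(30:300, n_hits, replace = TRUE),
      e_value = 1e-30
    )
  })
}

random_schedule <- function(seed) {
  withr::with_seed(seed, {
    t <- sort(runif(7, 0.3, 0.95))
    names(t) <- tax_ranks()
    t
  })
}
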