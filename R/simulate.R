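#' Configuration for the synthetic-data generator
#'
#' Collects every tunable of the generator in one validated list. Defaults
#' describe a small bloom-like community: a balanced seven-rank taxonomy,
#' a handful of genus-level taxon bins with distinct GC means and
#' abundances, genes whose protein hits point to the true lineage with
#' probability `1 - p_err`, three partially concordant CAZyme evidence
#' sources, read mappings with identity noise, and clade-abundance time
#' series with planted monotone environmental effects at signal-to-noise
#' `effect_size / noise_sd`.
#'
#' @param seed Integer seed; every draw derives from it.
#' @param n_per_rank Children per node at each of the seven ranks
#'   (scalar or length-7).
#' @param n_bins Number of genus-level taxon bins.
#' @param n_contigs,genes_per_contig Community size.
#' @param hits_per_gene Protein hits simulated per gene.
#' @param p_err Probability a protein hit (or a read mapping) points to a
#'   random wrong taxon instead of the true lineage.
#' @param bit_true_mean,bit_false_mean,bit_sd Bit-score model: true hits
#'   draw from the higher-mean normal.
#' @param cazyme_families Family label pool.
#' @param p_cazyme Probability a gene carries a (single) true CAZyme
#'   family.
#' @param sensitivity Named per-source detection probability for a true
#'   family (`cazy_blast`, `dbcan`, `pfam`).
#' @param fp_rate Per-gene, per-source false-positive family rate.
#' @param reads_per_contig Mean mapped reads per contig (scaled by
#'   coverage).
#' @param identity_mean,identity_sd Read-mapping identity noise (percent).
#' @param n_samples Time-series length.
#' @param effect_size,noise_sd Planted log-scale effect of each clade's
#'   driver and the lognormal noise; their ratio is the signal-to-noise.
#' @param n_otus OTUs in the synthetic tag table.
#' @param p_fail Fraction of OTUs constructed to fail the
#'   `(identity + coverage)/2 >= 93` rule.
#' @return Object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1, n_per_rank = 2, n_bins = 4,
                       n_contigs = 50, genes_per_contig = 10,
                       hits_per_gene = 8, p_err = 0.1,
                       bit_true_mean = 150, bit_false_mean = 80,
                       bit_sd = 15,
                       cazyme_families = c("GH16", "GH17", "GH30", "GH92",
                                           "GH13", "GH3", "CBM50", "PL7",
                                           "CE4", "GH29"),
                       p_cazyme = 0.3,
                       sensitivity = c(cazy_blast = 0.9, dbcan = 0.9,
                                       pfam = 0.7),
                       fp_rate = 0.02,
                       reads_per_contig = 60,
                       identity_mean = 97, identity_sd = 1.5,
                       n_samples = 30, effect_size = 1, noise_sd = 0.5,
                       n_otus = 40, p_fail = 0.2) {
  if (length(n_per_rank) == 1) n_per_rank <- rep(n_per_rank, 7)
  stopifnot(length(n_per_rank) == 7, all(n_per_rank >= 1))
  probs <- c(p_err = p_err, p_cazyme = p_cazyme, fp_rate = fp_rate,
             p_fail = p_fail, sensitivity)
  if (any(probs < 0) || any(probs > 1)) {
    abort("all probabilities must be in [0, 1]")
  }
  stopifnot(n_bins >= 1, n_contigs >= 1, genes_per_contig >= 1,
            n_samples >= 10, noise_sd >= 0)
  structure(as.list(environment()), class = "sim_config")
}

# friendly genus labels echoing recurrent bloom responders
.bin_labels <- c("Polaribacter_like", "Formosa_like", "Reinekea_like",
                 "Ulvibacter_like", "NS5_like", "SAR92_like",
                 "Cryomorphaceae_like", "NS3a_like")

#' Generate a balanced seven-rank taxonomy
#'
#' Builds a rooted tree with `n_per_rank[r]` children per node at rank r.
#' The first superkingdom is named `Bacteria`, the first phyla
#' `Bacteroidetes_like` / `Proteobacteria_like`, and the first genus nodes
#' carry labels echoing recurrent bloom-responder clades
#' (`Polaribacter_like`, `Formosa_like`, `Reinekea_like`, ...), purely for
#' readable fixtures. Deterministic given the config.
#'
#' @param config A [sim_config()].
#' @return A `taxonomy`.
#' @export
make_taxonomy <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  npr <- config$n_per_rank
  ranks <- tax_ranks()
  ids <- "root"
  parents <- "root"
  rank_col <- "root"
  prev <- "root"
  prefix <- c("sk", "p", "c", "o", "f", "g", "s")
  for (r in 1:7) {
    kids <- unlist(lapply(prev, function(p) {
      paste0(prefix[r], seq_len(npr[r]), "_", p)
    }))
    ids <- c(ids, kids)
    parents <- c(parents, rep(prev, each = npr[r]))
    rank_col <- c(rank_col, rep(ranks[r], length(kids)))
    prev <- kids
  }
  nodes <- tibble(taxon_id = ids, parent_id = parents, rank = rank_col)
  # readable names for a few marquee nodes
  nm <- ids
  sk <- ids[rank_col == "superkingdom"]
  nm[match(sk, ids)] <- c("Bacteria", "Archaea",
                          paste0("Superkingdom", seq_along(sk)))[seq_along(sk)]
  ph <- ids[rank_col == "phylum"]
  nm[match(utils::head(ph, 2), ids)] <-
    utils::head(c("Bacteroidetes_like", "Proteobacteria_like"), length(ph))
  gn <- ids[rank_col == "genus"]
  k <- min(length(gn), length(.bin_labels))
  nm[match(gn[seq_len(k)], ids)] <- .bin_labels[seq_len(k)]
  load_taxonomy(nodes, tibble(taxon_id = ids, name = nm))
}

#' Simulate a ground-truthed metagenome
#'
#' Draws a bloom-like community over a taxonomy: genus-level taxon bins
#' with planted abundances and distinct GC means; contigs whose coverage is
#' proportional to their bin's abundance (with multiplicative noise) and
#' whose GC clusters by bin; genes tiled along contigs; protein hits that
#' point to the gene's true species with probability `1 - p_err` (and then
#' carry higher bit scores) or to a random other species; three CAZyme
#' evidence tables with per-source sensitivity, false positives, and some
#' hits too weak to pass cutoffs; Pfam hits for sulfatase/TBDT/TRAP genes;
#' and read mappings with identity noise plus their contig back-map.
#'
#' @param tree A `taxonomy` from [make_taxonomy()].
#' @param config A [sim_config()].
#' @return List of tibbles: `bins`, `contigs`, `genes`, `protein_hits`,
#'   `cazyme_hits`, `pfam_hits`, `mappings`, `backmap`, and `truth`
#'   (list with `genes`, `contigs`, and the `config`).
#' @export
simulate_metagenome <- function(tree, config = sim_config()) {
  stopifnot(inherits(tree, "taxonomy"), inherits(config, "sim_config"))
  withr::with_seed(config$seed, {
    nodes <- tree$nodes
    genera <- nodes$taxon_id[nodes$rank == "genus"]
    species <- nodes$taxon_id[nodes$rank == "species"]
    n_bins <- min(config$n_bins, length(genera))
    bin_genera <- genera[seq_len(n_bins)]

    bins <- tibble(
      taxobin = lineage_names(tree, bin_genera),
      genus_id = bin_genera,
      abundance = exp(seq(log(8), log(1), length.out = n_bins)),
      gc_mean = seq(30, 52, length.out = n_bins)
    )

    species_of <- lapply(bin_genera, function(g) {
      species[tree$ancestors[species, "genus"] == g]
    })

    n <- config$n_contigs
    bin_idx <- sample(n_bins, n, replace = TRUE, prob = bins$abundance)
    true_species <- vapply(bin_idx, function(b) {
      sp <- species_of[[b]]
      sp[sample.int(length(sp), 1)]
    }, character(1))

    contigs <- tibble(
      contig_id = sprintf("contig_%03d", seq_len(n)),
      length = pmax(600L, as.integer(round(rlnorm(n, log(3000), 0.5)))),
      gc = pmin(100, pmax(0, rnorm(n, bins$gc_mean[bin_idx], 2))),
      coverage = bins$abundance[bin_idx] * rlnorm(n, 0, 0.3) * 10,
      platform = "illumina"
    )

    g_per <- config$genes_per_contig
    genes <- purrr::map2(contigs$contig_id, contigs$length, function(cid, len) {
      bounds <- unique(as.integer(round(seq(1, len + 1,
                                            length.out = g_per + 1))))
      k <- length(bounds) - 1L
      tibble(
        gene_id = paste0(cid, "_g", seq_len(k)),
        contig_id = cid,
        start = bounds[seq_len(k)],
        end = bounds[-1] - 1L,
        strand = sample(c("+", "-"), k, replace = TRUE)
      )
    }) |> bind_rows()
    gene_bin <- bin_idx[match(genes$contig_id, contigs$contig_id)]
    gene_species <- true_species[match(genes$contig_id, contigs$contig_id)]
    ng <- nrow(genes)

    # protein hits: two-component bit-score model
    h <- config$hits_per_gene
    hit_gene <- rep(genes$gene_id, each = h)
    hit_true_sp <- rep(gene_species, each = h)
    is_true <- runif(ng * h) >= config$p_err
    draw_other <- function(sp) {
      # a decoy taxon differing from the truth (unless the tree has only
      # one species, in which case errors are unrepresentable)
      if (length(species) == 1) return(sp)
      repeat {
        cand <- species[sample.int(length(species), 1)]
        if (cand != sp) return(cand)
      }
    }
    wrong <- vapply(hit_true_sp, draw_other, character(1))
    bit <- round(rnorm(ng * h,
                       ifelse(is_true, config$bit_true_mean,
                              config$bit_false_mean),
                       config$bit_sd), 1)
    bit <- pmax(bit, 30)
    protein_hits <- tibble(
      gene_id = hit_gene,
      subject_taxon = ifelse(is_true, hit_true_sp, wrong),
      bit_score = bit,
      e_value = 10^(-bit / 4)
    )

    # CAZyme truth and three evidence sources
    fams <- config$cazyme_families
    has_caz <- runif(ng) < config$p_cazyme
    true_fam <- ifelse(has_caz, sample(fams, ng, replace = TRUE),
                       NA_character_)
    srcs <- names(config$sensitivity)
    cazyme_hits <- purrr::map(srcs, function(s) {
      det <- has_caz & runif(ng) < config$sensitivity[[s]]
      tp <- tibble(gene_id = genes$gene_id[det], family = true_fam[det],
                   e_value = 10^(-runif(sum(det), 8, 60)), source = s)
      fp_sel <- runif(ng) < config$fp_rate
      fp <- tibble(gene_id = genes$gene_id[fp_sel],
                   family = sample(fams, sum(fp_sel), replace = TRUE),
                   e_value = 10^(-runif(sum(fp_sel), 8, 60)), source = s)
      # weak hits that must not survive the cutoffs
      wk_sel <- runif(ng) < 0.05
      wk <- tibble(gene_id = genes$gene_id[wk_sel],
                   family = sample(fams, sum(wk_sel), replace = TRUE),
                   e_value = 10^(-runif(sum(wk_sel), 0.2, 4)), source = s)
      bind_rows(tp, fp, wk)
    }) |> bind_rows() |> mutate(score = -log10(.data$e_value))

    func_pool <- c("sulfatase", "TBDT", "TRAP")
    has_func <- runif(ng) < 0.1
    func_fam <- ifelse(has_func, sample(func_pool, ng, replace = TRUE),
                       NA_character_)
    pfam_hits <- tibble(
      gene_id = genes$gene_id[has_func],
      family = func_fam[has_func],
      e_value = 10^(-runif(sum(has_func), 6, 40)),
      score = 50, source = "pfam"
    )

    # read mappings with identity noise, back-mapped to contigs
    n_reads <- pmax(5L, as.integer(round(
      config$reads_per_contig * contigs$coverage /
        mean(contigs$coverage))))
    read_contig <- rep(contigs$contig_id, n_reads)
    read_sp <- rep(true_species, n_reads)
    nr <- length(read_contig)
    m_true <- runif(nr) >= config$p_err
    m_wrong <- vapply(read_sp, draw_other, character(1))
    mappings <- tibble(
      read_id = sprintf("read_%06d", seq_len(nr)),
      reference_id = paste0("ref_", ifelse(m_true, read_sp, m_wrong)),
      reference_taxon = ifelse(m_true, read_sp, m_wrong),
      identity = pmin(100, pmax(60, rnorm(nr, config$identity_mean,
                                          config$identity_sd)))
    )
    backmap <- tibble(read_id = mappings$read_id, contig_id = read_contig)

    truth_genes <- tibble(
      gene_id = genes$gene_id,
      contig_id = genes$contig_id,
      species_id = gene_species,
      lineage = vapply(gene_species, function(sp) {
        lineage_string(tree, lineage_of(tree, sp))
      }, character(1), USE.NAMES = FALSE),
      cazyme_family = true_fam,
      functional_family = func_fam
    )
    truth_contigs <- tibble(
      contig_id = contigs$contig_id,
      species_id = true_species,
      taxobin = bins$taxobin[bin_idx],
      genus_id = bins$genus_id[bin_idx],
      lineage = vapply(true_species, function(sp) {
        lineage_string(tree, lineage_of(tree, sp))
      }, character(1), USE.NAMES = FALSE)
    )

    list(bins = bins, contigs = contigs, genes = genes,
         protein_hits = protein_hits, cazyme_hits = cazyme_hits,
         pfam_hits = pfam_hits, mappings = mappings, backmap = backmap,
         truth = list(genes = truth_genes, contigs = truth_contigs,
                      config = config))
  })
}

#' Simulate clade-abundance time series with planted environmental effects
#'
#' Builds an environmental table over a bloom (seasonal temperature ramp,
#' declining nutrients, a bloom-shaped chlorophyll a curve), then plants a
#' monotone log-scale effect of one driver variable per clade: clade
#' abundance is `exp(base + effect_size * sign * scale(driver) + noise)`
#' with lognormal noise of standard deviation `noise_sd` on the log scale.
#' Also draws a synthetic OTU tag table in which a known fraction of OTUs
#' fails the `(identity + coverage)/2 >= 93` acceptance rule.
#'
#' @param config A [sim_config()].
#' @return List: `env` (tibble of environmental variables), `clades`
#'   (tibble of clade abundance columns), `otus` (OTU record table), and
#'   `truth` (tibble of planted clade-driver effects plus the config).
#' @export
simulate_timeseries <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$seed + 1L, {
    n <- config$n_samples
    t01 <- seq(0, 1, length.out = n)
    env <- tibble(
      sample_id = sprintf("s%02d", seq_len(n)),
      temperature = 4 + 12 * t01 + rnorm(n, 0, 0.4),
      salinity = 33 - 1.5 * t01 + rnorm(n, 0, 0.15),
      silicate = 12 * exp(-3 * t01) + rnorm(n, 0, 0.3),
      phosphate = 0.8 * exp(-2 * t01) + rnorm(n, 0, 0.03),
      nitrate = 25 * exp(-2.5 * t01) + rnorm(n, 0, 0.5),
      nitrite = 0.5 * exp(-2 * t01) + rnorm(n, 0, 0.02),
      ammonium = 1.5 - t01 + rnorm(n, 0, 0.08),
      chlorophyll_a = 1 + 14 * exp(-((t01 - 0.45) / 0.15)^2) +
        rnorm(n, 0, 0.3)
    )
    drivers <- c("chlorophyll_a", "temperature", "nitrate", "silicate",
                 "salinity", "phosphate")
    clade_names <- .bin_labels[seq_len(min(6, length(.bin_labels)))]
    truth <- tibble(
      clade = clade_names,
      variable = drivers[seq_along(clade_names)],
      sign = rep(c(1, -1), length.out = length(clade_names)),
      effect_size = config$effect_size
    )
    clades <- purrr::pmap(truth, function(clade, variable, sign,
                                          effect_size) {
      z <- as.numeric(scale(env[[variable]]))
      exp(log(1e4) + effect_size * sign * z + rnorm(n, 0, config$noise_sd))
    })
    names(clades) <- clade_names
    clades <- as_tibble(clades)

    tag_tree <- make_taxonomy(sim_config(seed = config$seed))
    genera <- tag_tree$nodes$taxon_id[tag_tree$nodes$rank == "genus"]
    n_otu <- config$n_otus
    fails <- runif(n_otu) < config$p_fail
    otu_genus <- genera[sample.int(length(genera), n_otu, replace = TRUE)]
    otu_depth <- sample(4:6, n_otu, replace = TRUE)  # order..genus depth
    lineages <- vapply(seq_len(n_otu), function(i) {
      if (fails[i]) return("")
      lin <- lineage_of(tag_tree, otu_genus[i])[seq_len(otu_depth[i])]
      lineage_string(tag_tree, lin)
    }, character(1))
    otus <- tidyr::expand_grid(otu = seq_len(n_otu),
                               sample_id = env$sample_id) |>
      mutate(
        otu_id = sprintf("otu_%03d", .data$otu),
        read_count = stats::rnbinom(dplyr::n(), mu = 50, size = 2),
        best_ref_identity = rep(ifelse(fails, runif(n_otu, 78, 88),
                                       runif(n_otu, 95, 100)),
                                each = n),
        best_ref_coverage = rep(ifelse(fails, runif(n_otu, 78, 88),
                                       runif(n_otu, 93, 100)),
                                each = n),
        lineage = rep(lineages, each = n)
      ) |>
      select("otu_id", "sample_id", "read_count", "best_ref_identity",
             "best_ref_coverage", "lineage")
    list(env = env, clades = clades, otus = otus,
         truth = list(effects = truth, otu_fails = fails, config = config))
  })
}
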