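# Shared helpers for the test suite.

# random stop-free codon-index vector at the process equilibrium
random_codons <- function(n, omega = 0.2, kappa = 2) {
  tab <- paleoploid:::codon_tables()
  raw <- sample(which(!tab$is_stop), n, replace = TRUE)
  paleoploid:::evolve_codons(raw, 2, omega, kappa)$codons
}

# simulate one diverged codon pair and return its CDS strings
sim_cds_pair <- function(d, n = 120, omega = 0.2, kappa = 2) {
  anc <- random_codons(n, omega, kappa)
  a <- paleoploid:::evolve_codons(anc, d / 2, omega, kappa)$codons
  b <- paleoploid:::evolve_codons(anc, d / 2, omega, kappa)$codons
  list(a = paleoploid:::codons_to_dna(a), b = paleoploid:::codons_to_dna(b))
}

# random protein sequence
random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

# a small annotation tibble from a list of chromosome gene-id vectors
toy_annotation <- function(chroms, gene_len = 300L, spacer = 200L) {
  purrr::imap_dfr(chroms, function(ids, cn) {
    rank <- seq_along(ids) - 1L
    start <- rank * (gene_len + spacer) + 1L
    tibble::tibble(chrom = cn, gene_id = ids, start = start,
                   end = start + gene_len - 1L, strand = "+")
  })
}

# minimal anchor tibble on one chromosome pair
mk_anchors <- function(r1, r2, chrom1 = "c1", chrom2 = "c2", score = 50) {
  tibble::tibble(
    gene1 = paste0("a", seq_along(r1)), gene2 = paste0("b", seq_along(r1)),
    chrom1 = chrom1, chrom2 = chrom2,
    rank1 = as.integer(r1), rank2 = as.integer(r2), score = score
  )
}

# exhaustive optimal monotone chain: max over all anchor subsets that form a
# strictly monotone chain (both orientations) with per-side rank steps in
# [1, max_gap + 1], scored as n * anchor_score - gap_penalty * gap units
chain_oracle <- function(r1, r2, max_gap, gap_penalty = 1, anchor_score = 50) {
  n <- length(r1)
  best <- -Inf
  bits <- 2^(0:(n - 1))
  for (mask in seq_len(2^n - 1)) {
    idx <- which(bitwAnd(mask, bits) > 0)
    if (length(idx) < 2) next
    o <- idx[order(r1[idx])]
    d1 <- diff(r1[o])
    if (any(d1 <= 0 | d1 > max_gap + 1)) next
    d2 <- diff(r2[o])
    ok <- all(d2 >= 1 & d2 <= max_gap + 1) ||
      all(-d2 >= 1 & -d2 <= max_gap + 1)
    if (!ok) next
    sc <- length(o) * anchor_score -
      gap_penalty * sum((d1 - 1) + (abs(d2) - 1))
    best <- max(best, sc)
  }
  best
}

# A medium-scale simulated genome with derived homology/synteny objects,
# shared by the synteny and duplicate-classification tests.
medium_env <- new.env(parent = emptyenv())
medium_scenario <- function() {
  if (!is.null(medium_env$sim)) return(as.list(medium_env))
  sim <- simulate_genome(sim_config(n_chromosomes = 4, genes_per_chromosome = 40,
                                    cds_length_codons = 200, tandem_rate = 0.05,
                                    seed = 99L))
  ann <- add_ranks(sim$species$A$annotation)
  hits <- filter_hits(blast_hits(sim$species$A$protein))
  anchors <- build_anchors(hits, ann)
  blocks <- detect_blocks(anchors)
  medium_env$sim <- sim
  medium_env$ann <- ann
  medium_env$hits <- hits
  medium_env$anchors <- anchors
  medium_env$blocks <- blocks
  as.list(medium_env)
}

# The default-scenario dataset and its derived objects are expensive (minutes),
# and several acceptance tests share them; compute once per test run.
heavy_env <- new.env(parent = emptyenv())
heavy_scenario <- function() {
  if (!is.null(heavy_env$sim)) return(as.list(heavy_env))
  sim <- simulate_genome(sim_config(seed = 20260101L))
  pa <- sim$truth$ohnolog_pairs[sim$truth$ohnolog_pairs$species == "A",
                                c("gene1", "gene2")]
  pb <- sim$truth$ohnolog_pairs[sim$truth$ohnolog_pairs$species == "B",
                                c("gene1", "gene2")]
  heavy_env$sim <- sim
  heavy_env$ann_a <- add_ranks(sim$species$A$annotation)
  heavy_env$hits_a <- filter_hits(blast_hits(sim$species$A$protein))
  heavy_env$ks_a <- pairs_ks(pa, sim$species$A$cds)
  heavy_env$ks_b <- pairs_ks(pb, sim$species$B$cds)
  hits <- filter_hits(blast_hits(sim$species$A$protein,
                                 sim$species$B$protein))
  best_ab <- hits |>
    dplyr::group_by(query) |>
    dplyr::slice_max(bitscore, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  best_ba <- hits |>
    dplyr::group_by(subject) |>
    dplyr::slice_max(bitscore, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
  rbh <- dplyr::inner_join(best_ab[, c("query", "subject")],
                           best_ba[, c("query", "subject")],
                           by = c("query", "subject"))
  heavy_env$ks_ortho <- pairs_ks(
    dplyr::rename(rbh, gene1 = "query", gene2 = "subject"),
    sim$species$A$cds, sim$species$B$cds
  )
  as.list(heavy_env)
}
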