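#' Configuration for the forward genome-evolution simulator
#'
#' Builds the parameter set for [simulate_genome()]. The default scenario
#' (`"barnacle"`) encodes one whole-genome duplication (WGD) shared by two
#' descendant species: paralog (ohnolog) divergence 0.8 synonymous
#' substitutions per synonymous site in species A, 1.0 in species B (which
#' carries `second_lineage_extra_ks` additional divergence on the duplicated
#' copy), and ortholog divergence 0.6 between the species — so the WGD
#' predates the lineage split.
#'
#' @param n_chromosomes Number of ancestral chromosomes (doubled by the WGD).
#' @param genes_per_chromosome Genes per ancestral chromosome.
#' @param cds_length_codons Codons per coding sequence (>= 10).
#' @param wgd_ks Expected synonymous substitutions per synonymous site
#'   separating the two members of a retained ohnolog pair in species A.
#' @param speciation_ks Expected synonymous divergence between orthologs of
#'   the two descendant species.
#' @param second_lineage_extra_ks Additional divergence applied to the
#'   duplicated copy in species B only, so its paralog peak sits at
#'   `wgd_ks + second_lineage_extra_ks`.
#' @param retention_prob Probability that the duplicated copy of a gene
#'   survives post-WGD gene loss.
#' @param tandem_rate Per-gene probability of spawning a tandem duplicate
#'   after the lineage split.
#' @param tandem_ks Synonymous divergence of a tandem duplicate from its
#'   parent gene.
#' @param n_inversions,n_translocations Rearrangement counts applied to each
#'   species after the split.
#' @param kappa HKY transition/transversion rate ratio (> 0).
#' @param omega Nonsynonymous/synonymous rate ratio.
#' @param prop_nonfunctionalized Fraction of ohnolog genes labelled
#'   nonfunctionalized (silenced) in the expression truth.
#' @param prop_neo_sub Fraction of ohnolog genes labelled as the
#'   differentially-expressed member of a neo-/subfunctionalized pair.
#' @param seed Random seed; a fixed seed makes every output byte-identical.
#'
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_chromosomes = 8,
                       genes_per_chromosome = 100,
                       cds_length_codons = 200,
                       wgd_ks = 0.8,
                       speciation_ks = 0.6,
                       second_lineage_extra_ks = 0.2,
                       retention_prob = 0.8,
                       tandem_rate = 0.02,
                       tandem_ks = 0.05,
                       n_inversions = 4,
                       n_translocations = 2,
                       kappa = 2,
                       omega = 0.2,
                       prop_nonfunctionalized = 0.0716,
                       prop_neo_sub = 0.0836,
                       seed = 1L) {
  if (kappa <= 0) stop("kappa must be > 0", call. = FALSE)
  if (cds_length_codons < 10) stop("cds_length_codons must be >= 10", call. = FALSE)
  if (retention_prob < 0 || retention_prob > 1) {
    stop("retention_prob must be in [0, 1]", call. = FALSE)
  }
  if (tandem_rate < 0 || tandem_rate > 1) stop("tandem_rate must be in [0, 1]", call. = FALSE)
  if (wgd_ks < 0 || speciation_ks < 0 || second_lineage_extra_ks < 0) {
    stop("divergence parameters must be >= 0", call. = FALSE)
  }
  if (wgd_ks < speciation_ks) {
    warning("wgd_ks < speciation_ks: the duplication postdates the lineage split")
  }
  if (omega < 0) stop("omega must be >= 0", call. = FALSE)
  if (prop_nonfunctionalized + 2 * prop_neo_sub > 1) {
    stop("fate fractions exceed the available ohnolog genes", call. = FALSE)
  }
  structure(list(
    n_chromosomes = as.integer(n_chromosomes),
    genes_per_chromosome = as.integer(genes_per_chromosome),
    cds_length_codons = as.integer(cds_length_codons),
    wgd_ks = wgd_ks, speciation_ks = speciation_ks,
    second_lineage_extra_ks = second_lineage_extra_ks,
    retention_prob = retention_prob,
    tandem_rate = tandem_rate, tandem_ks = tandem_ks,
    n_inversions = as.integer(n_inversions),
    n_translocations = as.integer(n_translocations),
    kappa = kappa, omega = omega,
    prop_nonfunctionalized = prop_nonfunctionalized,
    prop_neo_sub = prop_neo_sub,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

# Evolve a codon vector along one branch. The number of synonymous events is
# Poisson with mean d_syn * S0 (S0 = NG86 synonymous sites of the starting
# sequence), so d_syn is, by construction, the expected number of synonymous
# substitutions per synonymous site. Nonsynonymous events are omega-scaled.
# Events are placed sequentially with HKY weights (kappa for transitions);
# changes creating stop codons are never proposed.
evolve_codons <- function(cod, d_syn, omega, kappa) {
  tab <- codon_tables()
  S0 <- sum(tab$syn_sites[cod])
  N0 <- sum(tab$nonsyn_sites[cod])
  n_s <- stats::rpois(1L, d_syn * S0)
  n_n <- stats::rpois(1L, omega * d_syn * N0)
  if (n_s + n_n == 0L) {
    return(list(codons = cod, n_syn = 0L, n_nonsyn = 0L, syn_sites0 = S0))
  }
  types <- sample(rep(c(TRUE, FALSE), c(n_s, n_n)))
  ws <- kappa * tab$syn_ts[cod] + tab$syn_tv[cod]
  wn <- kappa * tab$non_ts[cod] + tab$non_tv[cod]
  done_s <- 0L; done_n <- 0L
  for (syn in types) {
    w <- if (syn) ws else wn
    tot <- sum(w)
    if (tot <= 0) next
    pos <- sample.int(length(cod), 1L, prob = w)
    nb <- tab$neigh[[cod[pos]]]
    nb <- nb[!nb$stop & (if (syn) nb$syn else !nb$syn), , drop = FALSE]
    wt <- ifelse(nb$ts, kappa, 1)
    k <- if (nrow(nb) == 1L) 1L else sample.int(nrow(nb), 1L, prob = wt)
    cod[pos] <- nb$to[k]
    ws[pos] <- kappa * tab$syn_ts[cod[pos]] + tab$syn_tv[cod[pos]]
    wn[pos] <- kappa * tab$non_ts[cod[pos]] + tab$non_tv[cod[pos]]
    if (syn) done_s <- done_s + 1L else done_n <- done_n + 1L
  }
  list(codons = cod, n_syn = done_s, n_nonsyn = done_n, syn_sites0 = S0)
}

#' Simulate two post-WGD genomes with truth labels
#'
#' Builds a random stop-free ancestor genome, duplicates every chromosome in
#' one WGD, loses each duplicated copy independently with probability
#' `1 - retention_prob`, evolves sequences under an HKY codon process (kappa
#' for transitions, omega-scaled nonsynonymous rate), splits the lineage into
#' species A and B, adds tandem duplicates and rank-based rearrangements, and
#' records the full ground truth (ohnolog pairs with true Ks and realized
#' synonymous event counts, paralogous chromosome pairs, expression fate
#' labels, tandem gene ids).
#'
#' @param config A [sim_config()].
#' @return A `sim_dataset` list with elements `config`, `species` (each with
#'   `annotation`, `cds`, `protein`) and `truth`.
#' @export
simulate_genome <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  tab <- codon_tables()
  nonstop <- which(!tab$is_stop)

  n_chr <- config$n_chromosomes
  n_anc <- n_chr * config$genes_per_chromosome
  anc_chrom <- rep(seq_len(n_chr), each = config$genes_per_chromosome)
  anc_seq <- lapply(seq_len(n_anc), function(i) {
    # random stop-free codons, then a burn-in so the ancestor sits at the
    # compositional equilibrium of the substitution process
    raw <- sample(nonstop, config$cds_length_codons, replace = TRUE)
    evolve_codons(raw, 2, config$omega, config$kappa)$codons
  })
  retained <- stats::runif(n_anc) < config$retention_prob
  if (!any(retained)) {
    warning("no duplicated copies retained: the dataset contains no ohnolog pairs")
  }

  d_pre <- max(config$wgd_ks - config$speciation_ks, 0) / 2
  d_sp <- config$speciation_ks / 2
  d_extra <- config$second_lineage_extra_ks

  gene_id <- function(i, copy) sprintf("g%04d.%d", i, copy)

  seqs <- list(A = list(), B = list())
  events <- list(A = numeric(n_anc), B = numeric(n_anc))
  expected <- list(A = numeric(n_anc), B = numeric(n_anc))
  anc_sites <- numeric(n_anc)
  for (i in seq_len(n_anc)) {
    anc_sites[i] <- sum(tab$syn_sites[anc_seq[[i]]])
    pre1 <- evolve_codons(anc_seq[[i]], d_pre, config$omega, config$kappa)
    a1 <- evolve_codons(pre1$codons, d_sp, config$omega, config$kappa)
    b1 <- evolve_codons(pre1$codons, d_sp, config$omega, config$kappa)
    seqs$A[[gene_id(i, 1)]] <- a1$codons
    seqs$B[[gene_id(i, 1)]] <- b1$codons
    if (retained[i]) {
      pre2 <- evolve_codons(anc_seq[[i]], d_pre, config$omega, config$kappa)
      a2 <- evolve_codons(pre2$codons, d_sp, config$omega, config$kappa)
      b2 <- evolve_codons(pre2$codons, d_sp + d_extra, config$omega, config$kappa)
      seqs$A[[gene_id(i, 2)]] <- a2$codons
      seqs$B[[gene_id(i, 2)]] <- b2$codons
      events$A[i] <- pre1$n_syn + pre2$n_syn + a1$n_syn + a2$n_syn
      events$B[i] <- pre1$n_syn + pre2$n_syn + b1$n_syn + b2$n_syn
      # Poisson expectation of the implemented process, segment by segment
      expected$A[i] <- 2 * d_pre * anc_sites[i] +
        d_sp * (a1$syn_sites0 + a2$syn_sites0)
      expected$B[i] <- 2 * d_pre * anc_sites[i] +
        d_sp * b1$syn_sites0 + (d_sp + d_extra) * b2$syn_sites0
    }
  }

  ohno <- dplyr::bind_rows(
    tibble::tibble(
      species = "A",
      gene1 = gene_id(which(retained), 1), gene2 = gene_id(which(retained), 2),
      true_ks = config$wgd_ks,
      anc_syn_sites = anc_sites[retained],
      n_syn_events = events$A[retained],
      expected_syn_events = expected$A[retained]
    ),
    tibble::tibble(
      species = "B",
      gene1 = gene_id(which(retained), 1), gene2 = gene_id(which(retained), 2),
      true_ks = config$wgd_ks + d_extra,
      anc_syn_sites = anc_sites[retained],
      n_syn_events = events$B[retained],
      expected_syn_events = expected$B[retained]
    )
  )

  chrom_name <- function(i) sprintf("chr%02d", i)
  chrom_pairs <- tibble::tibble(
    chrom1 = chrom_name(seq_len(n_chr)),
    chrom2 = chrom_name(seq_len(n_chr) + n_chr)
  )

  # per-species chromosome gene orders (copy 1 on chr i, copy 2 on chr i+n)
  build_species <- function(sp) {
    chroms <- vector("list", 2L * n_chr)
    for (c in seq_len(n_chr)) {
      ids <- which(anc_chrom == c)
      chroms[[c]] <- gene_id(ids, 1)
      chroms[[c + n_chr]] <- gene_id(ids[retained[ids]], 2)
    }
    names(chroms) <- chrom_name(seq_len(2L * n_chr))
    chroms
  }

  species <- list(A = build_species("A"), B = build_species("B"))
  strands <- list(
    A = stats::setNames(sample(c("+", "-"), length(seqs$A), replace = TRUE), names(seqs$A)),
    B = stats::setNames(sample(c("+", "-"), length(seqs$B), replace = TRUE), names(seqs$B))
  )
  tandems <- list()

  for (sp in c("A", "B")) {
    # tandem duplications after the split
    base_ids <- unlist(species[[sp]], use.names = FALSE)
    is_tandem <- stats::runif(length(base_ids)) < config$tandem_rate
    new_tandems <- character(0)
    if (any(is_tandem)) {
      for (pid in base_ids[is_tandem]) {
        tid <- paste0(pid, "t")
        ev <- evolve_codons(seqs[[sp]][[pid]], config$tandem_ks,
                            config$omega, config$kappa)
        seqs[[sp]][[tid]] <- ev$codons
        strands[[sp]][tid] <- strands[[sp]][pid]
        # insert immediately after the parent
        for (cn in names(species[[sp]])) {
          at <- match(pid, species[[sp]][[cn]])
          if (!is.na(at)) {
            species[[sp]][[cn]] <- append(species[[sp]][[cn]], tid, after = at)
            break
          }
        }
        new_tandems <- c(new_tandems, tid)
      }
      tandems[[sp]] <- tibble::tibble(
        species = sp, gene_id = new_tandems,
        parent_id = base_ids[is_tandem]
      )
    }

    # inversions: reverse a rank interval and flip strands
    for (k in seq_len(config$n_inversions)) {
      cn <- sample(names(species[[sp]]), 1L)
      g <- species[[sp]][[cn]]
      if (length(g) < 2L) next
      ij <- sort(sample.int(length(g), 2L))
      seg <- g[ij[1]:ij[2]]
      species[[sp]][[cn]] <- c(
        g[seq_len(ij[1] - 1L)], rev(seg),
        if (ij[2] < length(g)) g[(ij[2] + 1L):length(g)] else character(0)
      )
      strands[[sp]][seg] <- ifelse(strands[[sp]][seg] == "+", "-", "+")
    }

    # translocations: move a short interval to another chromosome
    for (k in seq_len(config$n_translocations)) {
      from <- sample(names(species[[sp]]), 1L)
      g <- species[[sp]][[from]]
      if (length(g) < 6L) next
      len <- sample.int(5L, 1L)
      i0 <- sample.int(length(g) - len + 1L, 1L)
      seg <- g[i0:(i0 + len - 1L)]
      species[[sp]][[from]] <- g[-(i0:(i0 + len - 1L))]
      to <- sample(setdiff(names(species[[sp]]), from), 1L)
      h <- species[[sp]][[to]]
      at <- sample.int(length(h) + 1L, 1L) - 1L
      species[[sp]][[to]] <- append(h, seg, after = at)
    }
  }

  gene_len <- 3L * config$cds_length_codons
  make_annotation <- function(chroms, strand) {
    purrr::imap_dfr(chroms, function(ids, cn) {
      if (length(ids) == 0) return(tibble::tibble())
      rank <- seq_along(ids) - 1L
      start <- rank * (gene_len + 500L) + 1L
      tibble::tibble(
        chrom = cn, gene_id = ids, start = start,
        end = start + gene_len - 1L,
        strand = unname(strand[ids]), rank = rank
      )
    })
  }

  out_species <- lapply(c(A = "A", B = "B"), function(sp) {
    cds <- vapply(seqs[[sp]], codons_to_dna, character(1))
    prot <- vapply(seqs[[sp]], translate_codons, character(1))
    list(
      annotation = make_annotation(species[[sp]], strands[[sp]]),
      cds = cds, protein = prot
    )
  })

  fate <- assign_fates(
    ohno[ohno$species == "A", ],
    names(seqs$A),
    config$prop_nonfunctionalized, config$prop_neo_sub
  )

  structure(list(
    config = config,
    species = out_species,
    truth = list(
      ohnolog_pairs = ohno,
      chromosome_pairs = chrom_pairs,
      fate_labels = fate,
      tandem_ids = if (length(tandems)) dplyr::bind_rows(tandems) else
        tibble::tibble(species = character(), gene_id = character(),
                       parent_id = character())
    )
  ), class = "sim_dataset")
}

# Assign expression-fate labels to species-A genes. Nonfunctionalized genes
# and neo-/subfunctionalized pairs are drawn from the ohnolog set at the
# configured fractions of ohnolog GENES (the analysis denominator); one
# member per selected pair carries the neo_sub label.
assign_fates <- function(pairs_a, all_genes, prop_nonf, prop_neo) {
  ohno_genes <- c(pairs_a$gene1, pairs_a$gene2)
  n <- length(ohno_genes)
  fate <- stats::setNames(rep("functional", length(all_genes)), all_genes)
  if (n > 0) {
    n_neo_pairs <- round(prop_neo * n)
    n_nonf <- round(prop_nonf * n)
    neo_rows <- sample.int(nrow(pairs_a), min(n_neo_pairs, nrow(pairs_a)))
    neo_member <- ifelse(stats::runif(length(neo_rows)) < 0.5, 1L, 2L)
    neo_genes <- ifelse(neo_member == 1L,
                        pairs_a$gene1[neo_rows], pairs_a$gene2[neo_rows])
    fate[neo_genes] <- "neo_sub"
    in_neo_pair <- c(pairs_a$gene1[neo_rows], pairs_a$gene2[neo_rows])
    pool <- setdiff(ohno_genes, in_neo_pair)
    nonf <- sample(pool, min(n_nonf, length(pool)))
    fate[nonf] <- "nonfunctionalized"
  }
  tibble::tibble(gene_id = names(fate), fate = unname(fate))
}

#' @export
print.sim_dataset <- function(x, ...) {
  nA <- nrow(x$species$A$annotation)
  nB <- nrow(x$species$B$annotation)
  cat(sprintf(
    "<sim_dataset> %d + %d genes on %d chromosomes each; %d ohnolog pairs/species\n",
    nA, nB, 2L * x$config$n_chromosomes,
    sum(x$truth$ohnolog_pairs$species == "A")
  ))
  invisible(x)
}
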