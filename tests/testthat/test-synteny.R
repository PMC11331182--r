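# minimal 12-column hit row(s)
mk_hits <- function(query, subject, bitscore = 100, pident = 90) {
  h <- tibble::tibble(
    query = query, subject = subject, pident = pident, length = 100,
    mismatch = 0, gapopen = 0, qstart = 1, qend = 100, sstart = 1, send = 100,
    evalue = 1e-30, bitscore = bitscore
  )
  attr(h, "search_space") <- c(m = 1, n = 1)
  h
}

test_that("add_ranks orders by start within chromosome, 0-based", {
  ann <- tibble::tibble(
    chrom = c("c2", "c1", "c1", "c2"),
    gene_id = c("g4", "g2", "g1", "g3"),
    start = c(500L, 900L, 100L, 100L), end = c(700L, 1100L, 300L, 300L)
  )
  r <- add_ranks(ann)
  expect_equal(r$rank[r$gene_id == "g1"], 0L)
  expect_equal(r$rank[r$gene_id == "g2"], 1L)
  expect_equal(r$rank[r$gene_id == "g3"], 0L)
  expect_equal(r$rank[r$gene_id == "g4"], 1L)
  expect_error(add_ranks(dplyr::mutate(ann, gene_id = "x")), "unique")
  expect_error(add_ranks(dplyr::mutate(ann, start = end + 1L)), "start > end")
})

test_that("build_anchors places hits on rank coordinates", {
  ann_a <- toy_annotation(list(c1 = c("a1", "a2", "a3")))
  ann_b <- toy_annotation(list(c9 = c("b1", "b2")))
  h <- mk_hits(c("a1", "a3"), c("b2", "b1"))
  an <- build_anchors(h, ann_a, ann_b)
  expect_equal(an$rank1, c(0L, 2L))
  expect_equal(an$rank2, c(1L, 0L))
  expect_equal(an$chrom1, c("c1", "c1"))
  expect_equal(an$chrom2, c("c9", "c9"))
  expect_equal(attr(an, "n_dropped"), 0L)
  # unknown genes are dropped with a warning and counted
  h2 <- mk_hits(c("a1", "a3"), c("b2", "nope"))
  expect_warning(an2 <- build_anchors(h2, ann_a, ann_b), "not in annotation")
  expect_equal(nrow(an2), 1)
  expect_equal(attr(an2, "n_dropped"), 1L)
})

test_that("intra-genome anchors are canonical and deduplicated", {
  ann <- toy_annotation(list(c1 = c("g1", "g2"), c2 = c("g3", "g4")))
  # both directions of the same unordered pair, plus a self-hit
  h <- mk_hits(c("g3", "g1", "g1"), c("g1", "g3", "g1"),
               bitscore = c(80, 120, 500))
  an <- build_anchors(h, ann)
  expect_equal(nrow(an), 1)
  expect_equal(an$gene1, "g1")   # lower chromosome on side 1
  expect_equal(an$gene2, "g3")
  expect_equal(an$score, 120)    # best bit score kept
})

test_that("four collinear anchors yield no block; five yield one", {
  expect_equal(nrow(detect_blocks(mk_anchors(1:4, 1:4))), 0)
  b <- detect_blocks(mk_anchors(c(1, 3, 5, 9, 12), c(2, 4, 7, 8, 15)))
  expect_equal(nrow(b), 1)
  expect_equal(b$n_anchors, 5L)
  expect_equal(b$orientation, "same")
  # 5 anchors at 50 each minus (1+1+3+2) + (1+2+0+6) gap units
  expect_equal(b$score, 5 * 50 - 16)
  # anchors come back ordered along the chain
  expect_equal(b$anchors[[1]]$rank1, c(1L, 3L, 5L, 9L, 12L))
})

test_that("a descending run is reported as an inverted block", {
  b <- detect_blocks(mk_anchors(1:6, 12:7))
  expect_equal(nrow(b), 1)
  expect_equal(b$orientation, "inverted")
  expect_equal(b$n_anchors, 6L)
})

test_that("runs separated by more than max_gap split into separate blocks", {
  an <- mk_anchors(c(1:5, 40:44), c(1:5, 40:44))
  b <- detect_blocks(an, max_gap = 25)
  expect_equal(nrow(b), 2)
  expect_equal(sort(b$n_anchors), c(5L, 5L))
  # every anchor is used at most once
  used <- dplyr::bind_rows(b$anchors)
  expect_equal(anyDuplicated(paste(used$gene1, used$gene2)), 0L)
})

test_that("top chain equals the brute-force oracle on random instances", {
  set.seed(11)
  for (trial in 1:100) {
    n <- sample(4:12, 1)
    r1 <- sample.int(20, n)
    r2 <- sample.int(20, n)
    mg <- sample(2:8, 1)
    want <- chain_oracle(r1, r2, max_gap = mg)
    got <- detect_blocks(mk_anchors(r1, r2), min_genes = 2, max_gap = mg)
    if (is.infinite(want)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_gt(nrow(got), 0)
      expect_equal(got$score[1], want)
    }
  }
})

test_that("simulated WGD blocks are found and shuffling ranks destroys them", {
  ms <- medium_scenario()
  b <- ms$blocks
  expect_gt(nrow(b), 0)
  expect_true(all(b$n_anchors >= 5))
  # every block satisfies its monotonicity and gap invariants
  for (i in seq_len(nrow(b))) {
    a <- b$anchors[[i]]
    d1 <- diff(a$rank1)
    d2 <- diff(a$rank2)
    expect_true(all(d1 >= 1 & d1 <= 26))
    if (b$orientation[i] == "same") {
      expect_true(all(d2 >= 1 & d2 <= 26))
    } else {
      expect_true(all(d2 <= -1 & d2 >= -26))
    }
  }
  # shuffle gene ranks genome-wide and re-run
  set.seed(12)
  shuffled <- ms$ann |>
    dplyr::mutate(gene_id = sample(gene_id)) |>
    dplyr::select(-rank) |>
    add_ranks()
  b2 <- detect_blocks(build_anchors(ms$hits, shuffled))
  expect_lte(sum(b2$n_anchors), 0.1 * sum(b$n_anchors))
})

test_that("pair_chromosomes declares only mutually enriched pairs", {
  ann <- toy_annotation(list(
    c1 = paste0("x", 1:7), c2 = paste0("y", 1:6), c3 = paste0("z", 1:2)
  ))
  h <- mk_hits(c(paste0("x", 1:6), "x7"),
               c(paste0("y", 1:6), "z1"))
  cp <- pair_chromosomes(h, ann)
  expect_s3_class(cp, "chrom_pairing")
  expect_true(isSymmetric(cp$counts))
  expect_equal(unname(diag(cp$counts)), rep(0, 3))
  expect_equal(nrow(cp$pairs), 1)
  expect_equal(sort(c(cp$pairs$chrom1, cp$pairs$chrom2)), c("c1", "c2"))
  # only intrachromosomal hits: nothing to count
  h_same <- mk_hits("x1", "x2")
  cp0 <- pair_chromosomes(h_same, ann)
  expect_equal(sum(cp0$counts), 0)
  expect_equal(nrow(cp0$pairs), 0)
})

test_that("pair_chromosomes recovers the simulated chromosome pairing", {
  ms <- medium_scenario()
  cp <- pair_chromosomes(ms$hits, ms$ann)
  truth <- ms$sim$truth$chromosome_pairs
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  # restrict to truth pairs with enough surviving anchors to be detectable
  n_anch <- ms$anchors |>
    dplyr::count(pair = key(chrom1, chrom2))
  strong <- truth[key(truth$chrom1, truth$chrom2) %in%
                    n_anch$pair[n_anch$n >= 20], ]
  declared <- key(cp$pairs$chrom1, cp$pairs$chrom2)
  expect_setequal(declared, key(strong$chrom1, strong$chrom2))
})

test_that("classify_duplicates applies the rank-distance rules", {
  ann <- toy_annotation(list(c1 = paste0("g", 1:15), c2 = paste0("h", 1:3)))
  no_blocks <- detect_blocks(mk_anchors(integer(0), integer(0)))
  h <- mk_hits(c("g1", "g3", "g12"), c("g2", "g8", "h1"))
  cls <- classify_duplicates(h, ann, no_blocks)
  lab <- stats::setNames(cls$class, cls$gene_id)
  expect_equal(lab[["g1"]], "tandem")      # adjacent ranks
  expect_equal(lab[["g3"]], "proximal")    # 5 ranks apart
  expect_equal(lab[["g12"]], "dispersed")  # different chromosome
  expect_equal(lab[["g15"]], "singleton")  # no paralog hit
  # block anchors take precedence
  blk <- detect_blocks(mk_anchors(0:4, 0:4, chrom1 = "c1", chrom2 = "c2"))
  blk$anchors[[1]]$gene1 <- paste0("g", 1:5)
  blk$anchors[[1]]$gene2 <- c(paste0("h", 1:3), "g14", "g15")
  cls2 <- classify_duplicates(h, ann, blk)
  lab2 <- stats::setNames(cls2$class, cls2$gene_id)
  expect_equal(unname(lab2[c("g1", "h1", "g15")]),
               rep("wgd_segmental", 3))
})

test_that("simulated tandem and ohnolog genes are classified correctly", {
  ms <- medium_scenario()
  cls <- classify_duplicates(ms$hits, ms$ann, ms$blocks)
  lab <- stats::setNames(cls$class, cls$gene_id)
  td <- ms$sim$truth$tandem_ids
  td <- td[td$species == "A", ]
  expect_gt(nrow(td), 3)
  # recall per tandem event: the duplicate or its parent is labeled tandem.
  # The duplicate itself can legitimately end up wgd_segmental when it stands
  # in for its (near-indistinguishable) parent as a block anchor, and a pair
  # split apart by a later rearrangement is not positionally tandem at all.
  found <- lab[td$gene_id] == "tandem" | lab[td$parent_id] == "tandem"
  expect_gte(mean(found), 0.9)
  # most duplicates are still recognized directly
  expect_gte(mean(lab[td$gene_id] == "tandem"), 0.7)
  # every retained ohnolog gene that anchors a block is wgd_segmental
  ba <- block_anchors(ms$blocks)
  ohno <- ms$sim$truth$ohnolog_pairs
  ohno_genes <- c(ohno$gene1[ohno$species == "A"], ohno$gene2[ohno$species == "A"])
  hit_genes <- intersect(ohno_genes, unique(c(ba$gene1, ba$gene2)))
  expect_gt(length(hit_genes), 50)
  expect_true(all(lab[hit_genes] == "wgd_segmental"))
})

test_that("shared_blocks links intra-genome blocks through orthologs", {
  blk <- function(c1, c2) tibble::tibble(
    block_id = seq_along(c1), chrom1 = c1, chrom2 = c2,
    orientation = "same", n_anchors = 5L, score = 250,
    anchors = replicate(length(c1), tibble::tibble(), simplify = FALSE)
  )
  intra_a <- blk("a1", "a2")
  intra_b <- blk("b1", "b2")
  ortho <- blk(c("a1", "a2"), c("b1", "b2"))
  sb <- shared_blocks(intra_a, intra_b, ortho)
  expect_equal(nrow(sb$quartets), 1)
  expect_equal(sb$quartets$n_shared, 1L)
  expect_equal(unlist(sb$quartets[1, 1:4], use.names = FALSE),
               c("a1", "a2", "b1", "b2"))
  expect_true(sb$a_blocks$matched)
  # crossed ortholog links resolve to the same quartet
  sb2 <- shared_blocks(intra_a, intra_b, blk(c("a1", "a2"), c("b2", "b1")))
  expect_equal(sb2$quartets, sb$quartets)
  # no ortholog blocks: warning and empty result
  expect_warning(sb0 <- shared_blocks(intra_a, intra_b, ortho[0, ]), "empty")
  expect_equal(nrow(sb0$quartets), 0)
  expect_false(any(sb0$a_blocks$matched))
})
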