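# enumerate every global alignment of two short peptides and return the best
# score under the affine convention used by the package (a gap of length L
# costs open + L * ext, end gaps penalized)
nw_oracle <- function(p1, p2, open = 11, ext = 1) {
  mat <- paleoploid:::blosum62()
  a <- strsplit(p1, "")[[1]]
  b <- strsplit(p2, "")[[1]]
  paths <- function(i, j) {
    if (i == 0 && j == 0) return(list(character(0)))
    out <- list()
    if (i > 0 && j > 0) {
      out <- c(out, lapply(paths(i - 1, j - 1), function(p) c(p, "M")))
    }
    if (i > 0) out <- c(out, lapply(paths(i - 1, j), function(p) c(p, "D")))
    if (j > 0) out <- c(out, lapply(paths(i, j - 1), function(p) c(p, "I")))
    out
  }
  score_path <- function(mv) {
    s <- 0; i <- 0; j <- 0
    r <- rle(mv)
    for (k in seq_along(r$values)) {
      if (r$values[k] == "M") {
        for (u in seq_len(r$lengths[k])) {
          i <- i + 1; j <- j + 1
          s <- s + mat[a[i], b[j]]
        }
      } else {
        if (r$values[k] == "D") i <- i + r$lengths[k] else j <- j + r$lengths[k]
        s <- s - open - ext * r$lengths[k]
      }
    }
    s
  }
  max(vapply(paths(length(a), length(b)), score_path, numeric(1)))
}

# score the alignment implied by a codon_alignment object, same convention
aln_score <- function(aln, open = 11, ext = 1) {
  mat <- paleoploid:::blosum62()
  aa <- function(cod) {
    out <- rep(NA_character_, length(cod))
    out[!is.na(cod)] <- strsplit(
      paleoploid:::translate_codons(cod[!is.na(cod)]), "")[[1]]
    out
  }
  a <- aa(aln$codons_a); b <- aa(aln$codons_b)
  s <- sum(mat[cbind(a[aln$counted], b[aln$counted])])
  for (g in list(is.na(a), is.na(b))) {
    r <- rle(g)
    s <- s - sum(open + ext * r$lengths[r$values])
  }
  s
}

test_that("identical CDS align with zero gaps, all columns counted", {
  set.seed(21)
  cds <- paleoploid:::codons_to_dna(random_codons(40))
  aln <- codon_align(cds, cds)
  expect_true(all(aln$counted))
  expect_false(anyNA(aln$codons_a))
  # ungapping reproduces the input
  expect_equal(aln$codons_a[!is.na(aln$codons_a)],
               paleoploid:::dna_to_codons(cds))
})

test_that("one inserted codon produces exactly one one-codon gap", {
  set.seed(22)
  cod <- random_codons(30)
  extra <- random_codons(1)
  cds_a <- paleoploid:::codons_to_dna(cod)
  cds_b <- paleoploid:::codons_to_dna(append(cod, extra, after = 10))
  aln <- codon_align(cds_a, cds_b)
  expect_equal(length(aln$codons_a), 31)
  expect_equal(sum(is.na(aln$codons_a)), 1)
  expect_false(anyNA(aln$codons_b))
  expect_equal(sum(aln$counted), 30)
})

test_that("toy alignments equal the exhaustive protein-NW oracle", {
  set.seed(23)
  for (trial in 1:15) {
    ca <- random_codons(sample(3:5, 1))
    cb <- random_codons(sample(3:5, 1))
    aln <- codon_align(paleoploid:::codons_to_dna(ca),
                       paleoploid:::codons_to_dna(cb))
    want <- nw_oracle(paleoploid:::translate_codons(ca),
                      paleoploid:::translate_codons(cb))
    expect_equal(aln_score(aln), want)
  }
})

test_that("codon_align rejects bad input with the offending gene id", {
  ok <- "ATGGGGTTT"
  expect_error(codon_align("ATGG", ok, id_a = "geneX"), "geneX.*multiple of 3")
  expect_error(codon_align(ok, "ATGTAAGGG", id_b = "geneY"),
               "geneY.*internal stop")
  expect_error(codon_align("ATGNNNGGG", ok, id_a = "geneZ"), "geneZ.*non-ACGT")
})

test_that("identical sequences give Ks = 0 with zero differences", {
  set.seed(24)
  cds <- paleoploid:::codons_to_dna(random_codons(60))
  e <- estimate_ks(codon_align(cds, cds))
  expect_equal(e$ks, 0)
  expect_equal(e$ka, 0)
  expect_equal(e$Sd, 0)
  expect_false(e$saturated)
})

test_that("estimate_ks is exactly symmetric in pair order", {
  set.seed(25)
  for (trial in 1:10) {
    p <- sim_cds_pair(runif(1, 0.1, 1.2), n = 90)
    # include an indel so the alignment itself must be symmetric too
    if (trial %% 2 == 0) {
      cod <- paleoploid:::dna_to_codons(p$b)
      p$b <- paleoploid:::codons_to_dna(append(cod, random_codons(1), after = 5))
    }
    e1 <- estimate_ks(codon_align(p$a, p$b))
    e2 <- estimate_ks(codon_align(p$b, p$a))
    expect_identical(
      unclass(e1)[c("S", "N", "Sd", "Sd_ts", "Sd_tv", "Nd", "ks", "ka",
                    "kappa", "omega")],
      unclass(e2)[c("S", "N", "Sd", "Sd_ts", "Sd_tv", "Nd", "ks", "ka",
                    "kappa", "omega")]
    )
  }
})

test_that("one synonymous transversion matches the hand-computed correction", {
  # 100 Gly codons; one fourfold-degenerate third position G -> C
  cds_a <- strrep("GGG", 100)
  cds_b <- paste0("GGC", strrep("GGG", 99))
  e <- estimate_ks(codon_align(cds_a, cds_b), method = "k2p")
  # S = 100 synonymous sites, P = 0, Q = 1/100; K2P formula chain by hand
  expect_equal(e$S, 100)
  expect_equal(e$Sd_tv, 1)
  q <- 0.01
  d_hand <- -0.5 * log(1 - q) - 0.25 * log(1 - 2 * q)
  expect_equal(e$ks, d_hand)
  # at small divergence the codon-process inversion agrees with Sd/S
  e2 <- estimate_ks(codon_align(cds_a, cds_b), method = "codon")
  expect_lt(abs(e2$ks - 0.01), 0.001)
})

test_that("saturation is flagged instead of extrapolated", {
  cds_a <- strrep("GGG", 60)
  cds_b <- strrep("GGC", 60)  # every synonymous site hit by a transversion
  for (m in c("codon", "k2p")) {
    e <- estimate_ks(codon_align(cds_a, cds_b), method = m)
    expect_true(e$saturated)
    expect_true(is.na(e$ks))
  }
})

test_that("degenerate inputs are rejected or flagged", {
  # Met/Trp only: no synonymous sites at all
  cds <- strrep("ATGTGG", 20)
  expect_error(estimate_ks(codon_align(cds, cds)), "zero synonymous sites")
  # short alignments carry the low-confidence flag
  set.seed(26)
  cds2 <- paleoploid:::codons_to_dna(random_codons(20))
  expect_true(estimate_ks(codon_align(cds2, cds2))$low_confidence)
})

test_that("Ks is monotone in simulated divergence (Spearman > 0.95)", {
  set.seed(27)
  d <- seq(0.05, 1.5, length.out = 200)
  est <- vapply(d, function(di) {
    p <- sim_cds_pair(di, n = 200)
    estimate_ks(codon_align(p$a, p$b))$ks
  }, numeric(1))
  expect_lt(mean(is.na(est)), 0.02)
  ok <- !is.na(est)
  expect_gt(cor(d[ok], est[ok], method = "spearman"), 0.95)
})

test_that("pairs_ks carries input columns and skips missing CDS", {
  set.seed(28)
  store <- c(
    g1 = paleoploid:::codons_to_dna(random_codons(50)),
    g2 = paleoploid:::codons_to_dna(random_codons(50))
  )
  pairs <- tibble::tibble(gene1 = c("g1", "g1"), gene2 = c("g2", "missing"),
                          tag = c("a", "b"))
  expect_warning(out <- pairs_ks(pairs, store), "1 pair.*missing CDS")
  expect_equal(nrow(out), 1)
  expect_equal(out$tag, "a")
  expect_true(all(c("S", "Sd", "kappa", "ks", "ka", "saturated") %in% names(out)))
})

test_that("block medians exclude saturated pairs", {
  set.seed(29)
  store <- character(0)
  mk <- function(id, d) {
    p <- sim_cds_pair(d, n = 400)
    store[[paste0(id, "_1")]] <<- p$a
    store[[paste0(id, "_2")]] <<- p$b
  }
  mk("p1", 0.2); mk("p2", 0.4); mk("p3", 0.6)
  store[["p4_1"]] <- strrep("GGG", 60)
  store[["p4_2"]] <- strrep("GGC", 60)
  blocks <- tibble::tibble(
    block_id = 1L, chrom1 = "c1", chrom2 = "c2", orientation = "same",
    n_anchors = 4L, score = 200,
    anchors = list(tibble::tibble(gene1 = paste0("p", 1:4, "_1"),
                                  gene2 = paste0("p", 1:4, "_2")))
  )
  out <- block_ks(blocks, store)
  expect_equal(nrow(out), 4)
  expect_equal(sum(out$saturated), 1)
  valid <- out$ks[!out$saturated]
  expect_equal(unique(out$block_median_ks), stats::median(valid))
  # with these divergences the median is the middle (0.4) pair
  expect_equal(unique(out$block_median_ks), sort(valid)[2])
  # identical-gene block: median exactly 0
  same <- paleoploid:::codons_to_dna(random_codons(60))
  store2 <- stats::setNames(rep(same, 2), c("x_1", "x_2"))
  blocks2 <- dplyr::mutate(blocks, anchors = list(
    tibble::tibble(gene1 = rep("x_1", 5), gene2 = rep("x_2", 5))
  ))
  expect_equal(unique(block_ks(blocks2, store2)$block_median_ks), 0)
})

test_that("ks_peaks finds constructed modes", {
  set.seed(30)
  x <- rnorm(300, 0.5, 0.01)
  pk <- ks_peaks(x)
  expect_equal(nrow(pk$peaks), 1)
  expect_lt(abs(ks_mode(pk) - 0.5), 0.02)
  expect_false(pk$low_confidence)

  y <- c(rnorm(300, 0.3, 0.05), rnorm(300, 1.2, 0.1))
  y <- y[y >= 0.01 & y <= 5]
  pk2 <- ks_peaks(y)
  expect_gte(nrow(pk2$peaks), 2)
  top2 <- sort(pk2$peaks$ks[1:2])
  expect_lt(abs(top2[1] - 0.3), 0.08)
  expect_lt(abs(top2[2] - 1.2), 0.15)
  # mixture mode recovers the same structure on log-Ks
  pk3 <- ks_peaks(y, method = "gmm")
  expect_gte(nrow(pk3$peaks), 2)
  expect_lt(min(abs(pk3$peaks$ks - 0.3)), 0.1)
  expect_lt(min(abs(pk3$peaks$ks - 1.2)), 0.2)
})

test_that("ks_peaks windows its input and flags small samples", {
  set.seed(31)
  x <- c(rnorm(100, 0.5, 0.01), 0.005, 5.5, NA)
  pk <- ks_peaks(x)
  expect_equal(pk$n, 100)
  expect_warning(pk2 <- ks_peaks(rnorm(20, 0.5, 0.01)), "low-confidence")
  expect_true(pk2$low_confidence)
  expect_equal(nrow(pk2$peaks), 1)
})

test_that("order_events reproduces the reference orderings", {
  r <- order_events(c(0.8, 1.0), 0.6)
  expect_equal(r$order, "WGD_BEFORE_DIVERGENCE")
  expect_equal(r$margin, 0.2)

  expect_equal(order_events(0.3, 0.6)$order, "WGD_AFTER_DIVERGENCE")

  a <- order_events(0.61, 0.6, delta = 0.05)
  expect_equal(a$order, "AMBIGUOUS")
  expect_equal(a$margin, 0.01)

  m <- order_events(c(0.8, NA), 0.6)
  expect_equal(m$order, "AMBIGUOUS")
  expect_match(m$reason, "missing")
})
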