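# one expression tibble builder: genes x (C_1..C_k, L_1..L_k, ...) from a
# per-gene list of group -> replicate FPKM vectors
mk_expr <- function(rows, n_reps = 3, groups = c("C", "L")) {
  samples <- tibble::tibble(
    sample = paste0(rep(groups, each = n_reps), "_", rep(seq_len(n_reps), length(groups))),
    group = rep(groups, each = n_reps)
  )
  expr <- purrr::imap_dfr(rows, function(vals, id) {
    v <- unlist(vals[groups], use.names = FALSE)
    stats::setNames(tibble::as_tibble(as.list(c(list(id), v)),
                                      .name_repair = "minimal"),
                    c("gene_id", samples$sample))
  })
  list(expr = expr, samples = samples)
}

test_that("expression_state applies the strict floor per sample", {
  expr <- tibble::tibble(
    gene_id = c("silent", "faint", "at_floor", "above_floor"),
    s1 = c(0, 0.1, 0.5, 0.6),
    s2 = c(0, 0, 0.5, 0.2)
  )
  st <- expression_state(expr)
  expect_equal(st$expressed, c(FALSE, TRUE, TRUE, TRUE))
  # a value exactly at the floor does not count as expression
  st2 <- expression_state(expr, expr_floor = 0.5)
  expect_equal(st2$expressed[st2$gene_id == "at_floor"], FALSE)
  expect_equal(st2$expressed[st2$gene_id == "above_floor"], TRUE)
  expect_error(expression_state(dplyr::mutate(expr, s1 = c(-1, 0, 0, 0))),
               "negative FPKM")
})

test_that("unexpressed counts follow the binomial at the reported rate", {
  set.seed(101)
  n <- 1675
  pi0 <- 0.0716
  fate <- tibble::tibble(
    gene_id = sprintf("g%04d", seq_len(n)),
    fate = ifelse(stats::runif(n) < pi0, "nonfunctionalized", "functional")
  )
  ds <- simulate_expression(list(fate_labels = fate), seed = 102L)
  st <- expression_state(ds$expr)
  n_unexpressed <- sum(!st$expressed)
  # the simulator silences exactly the nonfunctionalized genes
  expect_equal(n_unexpressed, sum(fate$fate == "nonfunctionalized"))
  sd3 <- 3 * sqrt(n * pi0 * (1 - pi0))
  expect_lt(abs(n_unexpressed - n * pi0), sd3)
})

test_that("differential_expression matches stats::t.test on log2(FPKM+1)", {
  lc <- c(1, 2, 3); ll <- c(4, 5, 6)
  d <- mk_expr(list(g1 = list(C = 2^lc - 1, L = 2^ll - 1)))
  de <- differential_expression(d$expr, d$samples)
  want <- stats::t.test(ll, lc, var.equal = TRUE)
  expect_equal(de$p, want$p.value)
  expect_equal(de$log2fc, mean(ll) - mean(lc))
  expect_equal(de$direction, "up")
  de_w <- differential_expression(d$expr, d$samples, var_equal = FALSE)
  expect_equal(de_w$p, stats::t.test(ll, lc, var.equal = FALSE)$p.value)
})

test_that("degenerate variance rules give p = 1 and p = 0", {
  d <- mk_expr(list(
    same = list(C = c(7, 7, 7), L = c(7, 7, 7)),       # identical constants
    shift = list(C = c(1, 1, 1), L = c(63, 63, 63)),   # zero variance, shifted
    silent = list(C = c(0, 0, 0), L = c(0, 0, 0))      # no expression at all
  ))
  de <- differential_expression(d$expr, d$samples)
  p <- stats::setNames(de$p, de$gene_id)
  expect_equal(unname(p["same"]), 1)
  expect_equal(unname(p["shift"]), 0)
  expect_equal(unname(p["silent"]), 1)
  expect_equal(de$direction[de$gene_id == "shift"], "up")
})

test_that("a strong mean shift with tiny variance is significant and up", {
  set.seed(103)
  d <- mk_expr(list(g1 = list(C = 2 + rnorm(3, 0, 0.01),
                              L = 10 + rnorm(3, 0, 0.01))))
  de <- differential_expression(d$expr, d$samples)
  expect_true(de$significant)
  expect_equal(de$direction, "up")
})

test_that("replicate and control-group validation works", {
  d <- mk_expr(list(g1 = list(C = c(1, 2, 3), L = c(2, 3, 4))))
  expect_error(differential_expression(d$expr, d$samples, control = "Z"),
               "control group not found")
  # one group with a single replicate is skipped with a warning
  expr2 <- dplyr::mutate(d$expr, X_1 = 5)
  samp2 <- dplyr::bind_rows(d$samples, tibble::tibble(sample = "X_1", group = "X"))
  expect_warning(de <- differential_expression(expr2, samp2),
                 "< 2 replicates skipped: X")
  expect_false("X" %in% de$group)
  expect_true("L" %in% de$group)
  # a one-replicate control is fatal
  samp3 <- dplyr::filter(samp2, sample != "C_2" & sample != "C_3")
  expect_error(suppressWarnings(differential_expression(expr2, samp3)),
               "control group has < 2 replicates")
})

test_that("the fdr flag switches significance to BH-adjusted p-values", {
  set.seed(104)
  rows <- c(
    list(hit = list(C = c(1, 1, 1), L = c(9, 9.1, 8.9))),
    stats::setNames(
      lapply(1:30, function(i) list(C = 2^rnorm(3, 3, 0.5), L = 2^rnorm(3, 3, 0.5))),
      paste0("null", 1:30)
    )
  )
  d <- mk_expr(rows)
  de <- differential_expression(d$expr, d$samples, fdr = TRUE)
  expect_true("p_adj" %in% names(de))
  expect_equal(de$p_adj, stats::p.adjust(de$p, method = "BH"))
  expect_equal(de$significant, de$p_adj < 0.05)
  # without the flag there is no adjusted column
  expect_false("p_adj" %in% names(differential_expression(d$expr, d$samples)))
})

test_that("classify_fates applies the fate precedence per pair", {
  d <- mk_expr(list(
    a1 = list(C = c(0, 0, 0), L = c(0, 0, 0)),      # unexpressed member
    a2 = list(C = c(0, 0, 0), L = c(63, 63, 63)),   # DE, but pair is nonf
    b1 = list(C = c(1, 1, 1), L = c(63, 63, 63)),   # DE
    b2 = list(C = c(10, 10, 10), L = c(10, 10, 10)),
    c1 = list(C = c(1, 1, 1), L = c(63, 63, 63)),   # both DE
    c2 = list(C = c(63, 63, 63), L = c(1, 1, 1)),
    d1 = list(C = c(10, 10, 10), L = c(10, 10, 10)),
    d2 = list(C = c(5, 5, 5), L = c(5, 5, 5))
  ))
  pairs <- tibble::tibble(gene1 = c("a1", "b1", "c1", "d1"),
                          gene2 = c("a2", "b2", "c2", "d2"))
  ft <- classify_fates(pairs, d$expr, d$samples)
  expect_equal(ft$fate, c("nonfunctionalized_member", "neo_sub",
                          "both_responsive", "conserved"))
  s <- fate_summary(ft)
  expect_equal(s$n_ohnolog_genes, 8)
  expect_equal(s$n_pairs, 4)
  expect_equal(s$n_nonfunctionalized, 1)
  # DE genes: a2, b1, c1, c2 (a2 is expressed — only a1 is silent)
  expect_equal(s$n_de_genes, 4)
  expect_equal(s$n_neo_sub_genes, 1)
  expect_equal(s$pct_nonfunctionalized, 100 / 8)
  expect_equal(s$pct_neo_sub, 100 / 8)
})

test_that("120 and 140 of 1675 ohnolog genes give 7.16% and 8.36%", {
  n <- 1675
  ids <- sprintf("g%04d", seq_len(n))
  # 838 pairs over 1675 genes: consecutive pairs plus one pair sharing g1674
  pairs <- tibble::tibble(
    gene1 = c(ids[seq(1, 1673, by = 2)], ids[1674]),
    gene2 = c(ids[seq(2, 1674, by = 2)], ids[1675])
  )
  mat <- matrix(10, n, 6)
  nonf_rows <- 2 * (1:120) - 1          # gene1 of pairs 1..120: silent
  de_rows <- 2 * (121:260) - 1          # gene1 of pairs 121..260: responsive
  mat[nonf_rows, ] <- 0
  mat[de_rows, 1:3] <- 0
  mat[de_rows, 4:6] <- 63
  d <- mk_expr(list())
  samples <- tibble::tibble(
    sample = c(paste0("C_", 1:3), paste0("L_", 1:3)),
    group = rep(c("C", "L"), each = 3)
  )
  expr <- dplyr::bind_cols(
    tibble::tibble(gene_id = ids),
    stats::setNames(tibble::as_tibble(as.data.frame(mat)), samples$sample)
  )
  ft <- classify_fates(pairs, expr, samples)
  expect_equal(sum(ft$fate == "nonfunctionalized_member"), 120)
  expect_equal(sum(ft$fate == "neo_sub"), 140)
  expect_equal(sum(ft$fate == "conserved"), 838 - 260)
  s <- fate_summary(ft)
  expect_equal(s$n_ohnolog_genes, 1675)
  expect_equal(s$n_nonfunctionalized, 120)
  expect_equal(s$n_de_genes, 140)
  expect_equal(s$pct_nonfunctionalized, 100 * 120 / 1675)
  expect_equal(s$pct_neo_sub, 100 * 140 / 1675)
  expect_equal(round(s$pct_nonfunctionalized, 2), 7.16)
  expect_equal(round(s$pct_neo_sub, 2), 8.36)
})

test_that("all-expressed, no-DE input gives 0% and 0%", {
  d <- mk_expr(list(g1 = list(C = c(5, 5, 5), L = c(5, 5, 5)),
                    g2 = list(C = c(7, 7, 7), L = c(7, 7, 7))))
  ft <- classify_fates(tibble::tibble(gene1 = "g1", gene2 = "g2"),
                       d$expr, d$samples)
  s <- fate_summary(ft)
  expect_equal(s$pct_nonfunctionalized, 0)
  expect_equal(s$pct_neo_sub, 0)
  expect_equal(ft$fate, "conserved")
})

test_that("pairs with members missing from the matrix are excluded", {
  d <- mk_expr(list(g1 = list(C = c(5, 5, 5), L = c(5, 5, 5)),
                    g2 = list(C = c(7, 7, 7), L = c(7, 7, 7))))
  pairs <- tibble::tibble(gene1 = c("g1", "g1"), gene2 = c("g2", "absent"))
  expect_warning(ft <- classify_fates(pairs, d$expr, d$samples),
                 "1 pair\\(s\\) with member\\(s\\) missing")
  expect_equal(nrow(ft), 1)
  # the denominator only counts genes from the retained pairs
  expect_equal(fate_summary(ft)$n_ohnolog_genes, 2)
})

test_that("fates are deterministic and invariant to row/column order", {
  set.seed(105)
  rows <- stats::setNames(
    lapply(1:12, function(i) list(C = 2^rnorm(3, 3, 1), L = 2^rnorm(3, 3 + (i %% 2) * 4, 0.2))),
    paste0("g", 1:12)
  )
  d <- mk_expr(rows)
  pairs <- tibble::tibble(gene1 = paste0("g", seq(1, 11, 2)),
                          gene2 = paste0("g", seq(2, 12, 2)))
  ft1 <- classify_fates(pairs, d$expr, d$samples)
  expect_identical(ft1, classify_fates(pairs, d$expr, d$samples))
  # shuffle gene rows and sample order; the summary must not move
  set.seed(106)
  expr2 <- d$expr[sample.int(nrow(d$expr)), ]
  samp2 <- d$samples[sample.int(nrow(d$samples)), ]
  ft2 <- classify_fates(pairs, expr2, samp2)
  expect_identical(fate_summary(ft1), fate_summary(ft2))
  expect_identical(ft1$fate, ft2$fate)
})

test_that("simulated neo_sub pairs are recovered with few false calls", {
  sim <- simulate_genome(sim_config(n_chromosomes = 2, genes_per_chromosome = 40,
                                    cds_length_codons = 10, seed = 41L))
  pairs <- sim$truth$ohnolog_pairs[sim$truth$ohnolog_pairs$species == "A",
                                   c("gene1", "gene2")]
  fate_of <- stats::setNames(sim$truth$fate_labels$fate,
                             sim$truth$fate_labels$gene_id)
  truth_neo <- xor(fate_of[pairs$gene1] == "neo_sub",
                   fate_of[pairs$gene2] == "neo_sub")
  expect_gt(sum(truth_neo), 5)

  # recall is assessed under the default (uncorrected p < 0.05) pipeline;
  # three uncorrected contrasts per gene make its single-member false-call
  # rate ~2q(1-q) with q = 1 - 0.95^3, so the false-positive bound is
  # assessed under the BH-FDR option instead
  recall <- fp_bh <- numeric(20)
  for (s in 1:20) {
    ds <- simulate_expression(sim, seed = s)
    called <- classify_fates(pairs, ds$expr, ds$samples)$fate == "neo_sub"
    called_bh <- classify_fates(pairs, ds$expr, ds$samples,
                                fdr = TRUE)$fate == "neo_sub"
    recall[s] <- mean(called[truth_neo])
    fp_bh[s] <- mean(called_bh[!truth_neo])
  }
  expect_gte(mean(recall), 0.8)
  expect_lte(mean(fp_bh), 0.1)
})

test_that("up_trend reports counts, monotonicity and the sign statistic", {
  mk_de <- function(n_up) {
    purrr::imap_dfr(n_up, function(k, g) {
      tibble::tibble(
        gene_id = paste0(g, "_", seq_len(k + 2)),
        group = g,
        significant = c(rep(TRUE, k), TRUE, FALSE),
        direction = c(rep("up", k), "down", "up")
      )
    })
  }
  r <- up_trend(mk_de(c(L = 10, M = 20, H = 30)))
  expect_equal(r$counts$n_up, c(10, 20, 30))
  expect_true(r$monotone_increasing)
  expect_equal(r$kendall_s, 3L)
  expect_true(r$complete)

  r2 <- up_trend(mk_de(c(L = 30, M = 20, H = 10)))
  expect_false(r2$monotone_increasing)
  expect_equal(r2$kendall_s, -3L)

  # ties break strict monotonicity
  expect_false(up_trend(mk_de(c(L = 10, M = 10, H = 30)))$monotone_increasing)

  expect_warning(r3 <- up_trend(mk_de(c(L = 5, M = 9))),
                 "missing group\\(s\\): H")
  expect_false(r3$complete)
  expect_equal(r3$counts$group, c("L", "M"))
  expect_equal(r3$kendall_s, 1L)
})

test_that("simulated exposure responses trend upward along the gradient", {
  fate <- tibble::tibble(
    gene_id = sprintf("g%03d", 1:300),
    fate = c(rep("neo_sub", 60), rep("functional", 240))
  )
  ds <- simulate_expression(list(fate_labels = fate), seed = 107L)
  de <- differential_expression(ds$expr, ds$samples)
  r <- up_trend(de)
  expect_true(r$monotone_increasing)
  expect_equal(r$kendall_s, 3L)
})
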