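#' Per-gene expression state
#'
#' A gene is unexpressed when its FPKM is at or below `expr_floor` in every
#' sample — the operational definition of nonfunctionalization for a retained
#' duplicate.
#'
#' @param expr Expression tibble: gene_id column plus one numeric column per
#'   sample (FPKM).
#' @param expr_floor Expression floor (default 0).
#' @return Tibble: gene_id, expressed.
#' @export
expression_state <- function(expr, expr_floor = 0) {
  stopifnot("gene_id" %in% names(expr))
  mat <- as.matrix(expr[, setdiff(names(expr), "gene_id")])
  if (any(mat < 0)) stop("negative FPKM values", call. = FALSE)
  tibble::tibble(
    gene_id = expr$gene_id,
    expressed = apply(mat, 1, function(v) any(v > expr_floor))
  )
}

# vectorized two-sample t on rows of two matrices; Student (pooled) by
# default, Welch optional. Degenerate cases: identical constant rows give
# p = 1, zero variance with differing means gives p = 0.
row_t_test <- function(x, y, var_equal = TRUE) {
  nx <- ncol(x); ny <- ncol(y)
  mx <- rowMeans(x); my <- rowMeans(y)
  vx <- apply(x, 1, stats::var); vy <- apply(y, 1, stats::var)
  diff <- mx - my
  if (var_equal) {
    sp <- ((nx - 1) * vx + (ny - 1) * vy) / (nx + ny - 2)
    se <- sqrt(sp * (1 / nx + 1 / ny))
    df <- rep(nx + ny - 2, length(mx))
  } else {
    se <- sqrt(vx / nx + vy / ny)
    df <- (vx / nx + vy / ny)^2 /
      ((vx / nx)^2 / (nx - 1) + (vy / ny)^2 / (ny - 1))
  }
  p <- 2 * stats::pt(abs(diff / se), df, lower.tail = FALSE)
  p[se == 0 & diff == 0] <- 1
  p[se == 0 & diff != 0] <- 0
  list(p = p, diff = diff)
}

#' Differential expression of each exposure group against the control
#'
#' Two-sided Student t-test (Welch optional) on log2(FPKM + 1) replicate
#' values, each non-control group against the control group. Genes
#' unexpressed in both compared groups get p = 1. No multiple-testing
#' correction is applied by default, matching the plain p < 0.05 convention;
#' `fdr = TRUE` switches the significance flag to Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param expr Expression tibble (gene_id + sample columns).
#' @param samples Sample sheet tibble: sample, group.
#' @param control Control group label (default "C").
#' @param alpha Significance level on the (adjusted) p-value.
#' @param var_equal Student (TRUE, default) or Welch (FALSE) t-test.
#' @param fdr Apply Benjamini-Hochberg adjustment per contrast.
#' @return Tibble: gene_id, group, log2fc, p (and p_adj if `fdr`),
#'   significant, direction.
#' @export
differential_expression <- function(expr, samples, control = "C",
                                    alpha = 0.05, var_equal = TRUE,
                                    fdr = FALSE) {
  stopifnot("gene_id" %in% names(expr),
            all(c("sample", "group") %in% names(samples)))
  if (!control %in% samples$group) stop("control group not found", call. = FALSE)
  groups <- setdiff(unique(samples$group), control)
  reps <- table(samples$group)
  if (any(reps < 2)) {
    skip <- names(reps)[reps < 2]
    warning(sprintf("group(s) with < 2 replicates skipped: %s",
                    paste(skip, collapse = ", ")))
    groups <- setdiff(groups, skip)
    if (control %in% skip) stop("control group has < 2 replicates", call. = FALSE)
  }
  mat <- as.matrix(expr[, samples$sample])
  if (any(mat < 0)) stop("negative FPKM values", call. = FALSE)
  lmat <- log2(mat + 1)
  ctrl_cols <- samples$sample[samples$group == control]

  out <- purrr::map_dfr(groups, function(g) {
    gc <- samples$sample[samples$group == g]
    tt <- row_t_test(lmat[, gc, drop = FALSE], lmat[, ctrl_cols, drop = FALSE],
                     var_equal = var_equal)
    p <- tt$p
    # genes silent in both compared groups carry no evidence
    silent <- rowSums(mat[, c(gc, ctrl_cols), drop = FALSE]) == 0
    p[silent] <- 1
    tibble::tibble(
      gene_id = expr$gene_id, group = g,
      log2fc = tt$diff, p = p,
      direction = dplyr::if_else(tt$diff >= 0, "up", "down")
    )
  })
  if (fdr) {
    out <- out |>
      dplyr::group_by(.data$group) |>
      dplyr::mutate(p_adj = stats::p.adjust(.data$p, method = "BH")) |>
      dplyr::ungroup() |>
      dplyr::mutate(significant = .data$p_adj < alpha)
  } else {
    out <- dplyr::mutate(out, significant = .data$p < alpha)
  }
  out
}

#' Classify ohnolog pairs into expression fates
#'
#' Gene-level nonfunctionalization = unexpressed in every sample. Pair-level
#' neo-/subfunctionalization = significant differential expression (any
#' group) in exactly one member. Pair fates are exhaustive and mutually
#' exclusive with precedence nonfunctionalized_member > neo_sub >
#' both_responsive > conserved. Summary percentages are computed over the
#' ohnolog genes present in the matrix (the syntenic-block ohnolog
#' denominator).
#'
#' @param pairs Ohnolog pair tibble: gene1, gene2 (e.g. block anchors).
#' @param expr,samples Expression matrix and sample sheet.
#' @param control,alpha,var_equal,fdr Passed to [differential_expression()].
#' @param expr_floor Passed to [expression_state()].
#' @return A `fate_table`: tibble of pairs with member states and fate, with
#'   a `summary` attribute (counts, denominator and percentages; see
#'   [fate_summary()]).
#' @export
classify_fates <- function(pairs, expr, samples, control = "C", alpha = 0.05,
                           var_equal = TRUE, fdr = FALSE, expr_floor = 0) {
  stopifnot(all(c("gene1", "gene2") %in% names(pairs)))
  present <- pairs$gene1 %in% expr$gene_id & pairs$gene2 %in% expr$gene_id
  if (!all(present)) {
    warning(sprintf("%d pair(s) with member(s) missing from the matrix excluded",
                    sum(!present)))
    pairs <- pairs[present, ]
  }
  st <- expression_state(expr, expr_floor)
  de <- differential_expression(expr, samples, control = control, alpha = alpha,
                                var_equal = var_equal, fdr = fdr)
  de_any <- de |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(de = any(.data$significant), .groups = "drop")
  lookup_expr <- stats::setNames(st$expressed, st$gene_id)
  lookup_de <- stats::setNames(de_any$de, de_any$gene_id)

  out <- pairs |>
    dplyr::mutate(
      expressed1 = unname(lookup_expr[.data$gene1]),
      expressed2 = unname(lookup_expr[.data$gene2]),
      de1 = unname(lookup_de[.data$gene1]) & .data$expressed1,
      de2 = unname(lookup_de[.data$gene2]) & .data$expressed2,
      fate = dplyr::case_when(
        !expressed1 | !expressed2 ~ "nonfunctionalized_member",
        xor(de1, de2) ~ "neo_sub",
        de1 & de2 ~ "both_responsive",
        TRUE ~ "conserved"
      )
    )

  genes <- unique(c(pairs$gene1, pairs$gene2))
  n_genes <- length(genes)
  n_nonfunctionalized <- sum(!lookup_expr[genes])
  n_de_genes <- sum(lookup_de[genes] & lookup_expr[genes])
  n_neo_sub <- sum(out$fate == "neo_sub")
  summary <- list(
    n_ohnolog_genes = n_genes,
    n_pairs = nrow(out),
    n_nonfunctionalized = n_nonfunctionalized,
    n_de_genes = n_de_genes,
    n_neo_sub_genes = n_neo_sub,
    pct_nonfunctionalized = 100 * n_nonfunctionalized / n_genes,
    pct_neo_sub = 100 * n_neo_sub / n_genes
  )
  attr(out, "summary") <- summary
  class(out) <- c("fate_table", class(out))
  out
}

#' Fate summary of a classified ohnolog set
#'
#' Counts and percentages over the ohnolog-gene denominator: unexpressed
#' (nonfunctionalized) genes and genes differentially expressed in exactly
#' one member of their pair (neo-/subfunctionalized), as percentages of all
#' ohnolog genes.
#'
#' @param fates A `fate_table` from [classify_fates()].
#' @return A one-row tibble: n_ohnolog_genes, n_pairs, n_nonfunctionalized,
#'   n_de_genes, n_neo_sub_genes, pct_nonfunctionalized, pct_neo_sub.
#' @export
fate_summary <- function(fates) {
  s <- attr(fates, "summary")
  stopifnot(!is.null(s))
  tibble::as_tibble(s)
}

#' Up-regulation trend along the exposure gradient
#'
#' Counts significantly up-regulated genes per exposure group in elevation
#' order and reports whether the counts increase monotonically, plus a
#' Mann-Kendall-style sign statistic (number of increasing minus decreasing
#' ordered pairs).
#'
#' @param de A [differential_expression()] table.
#' @param groups Exposure groups in increasing order (default L, M, H).
#' @return List: `counts` (tibble group, n_up), `monotone_increasing`,
#'   `kendall_s`, and `complete` (FALSE when a requested group is absent).
#' @export
up_trend <- function(de, groups = c("L", "M", "H")) {
  have <- intersect(groups, unique(de$group))
  if (!setequal(have, groups)) {
    warning(sprintf("missing group(s): %s — partial trend report",
                    paste(setdiff(groups, have), collapse = ", ")))
  }
  counts <- purrr::map_dfr(have, function(g) {
    tibble::tibble(
      group = g,
      n_up = sum(de$group == g & de$significant & de$direction == "up")
    )
  })
  n <- counts$n_up
  s <- 0L
  if (length(n) >= 2) {
    for (i in seq_len(length(n) - 1)) {
      for (j in (i + 1):length(n)) s <- s + sign(n[j] - n[i])
    }
  }
  list(
    counts = counts,
    monotone_increasing = length(n) >= 2 && all(diff(n) > 0),
    kendall_s = as.integer(s),
    complete = setequal(have, groups)
  )
}
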