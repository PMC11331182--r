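#' Derive 0-based gene ranks within chromosomes
#'
#' Orders genes by start coordinate within each chromosome and attaches the
#' 0-based `rank` column all synteny logic runs on.
#'
#' @param ann Tibble with columns chrom, gene_id, start, end (strand optional).
#' @export
add_ranks <- function(ann) {
  stopifnot(all(c("chrom", "gene_id", "start", "end") %in% names(ann)))
  if (anyDuplicated(ann$gene_id)) stop("gene ids must be unique", call. = FALSE)
  if (any(ann$start > ann$end)) stop("start > end in annotation", call. = FALSE)
  ann |>
    dplyr::arrange(.data$chrom, .data$start) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(rank = dplyr::row_number() - 1L) |>
    dplyr::ungroup()
}

#' Build positional anchors from homology hits
#'
#' Places each retained hit on chromosome/rank coordinates. In intra-genome
#' mode (`ann_b = NULL`) self-pairs are dropped and each unordered gene pair
#' is kept once (best bit score). Hits whose genes are absent from the
#' annotation are dropped with a warning; the count is attached as attribute
#' `n_dropped`.
#'
#' @param hits Filtered hit tibble (see [filter_hits()]).
#' @param ann_a,ann_b Ranked annotations ([add_ranks()]); `ann_b = NULL` for
#'   paralog anchors.
#' @param collapse_tandem In intra-genome mode, paralog pairs this close in
#'   rank on one chromosome (default 1, i.e. adjacent) are treated as tandem
#'   arrays: the pair anchors themselves are removed (a string of tandem
#'   pairs would otherwise chain into a fake intrachromosomal block) and all
#'   other anchors of array members are remapped onto the array's first gene,
#'   so a tandem duplicate never stands in for its parent inside a syntenic
#'   block. Set to a negative value to disable.
#' @return Anchor tibble: gene1, gene2, chrom1, chrom2, rank1, rank2, score.
#' @export
build_anchors <- function(hits, ann_a, ann_b = NULL, collapse_tandem = 1) {
  intra <- is.null(ann_b)
  if (intra) ann_b <- ann_a
  if (!"rank" %in% names(ann_a)) ann_a <- add_ranks(ann_a)
  if (!"rank" %in% names(ann_b)) ann_b <- add_ranks(ann_b)
  ga <- ann_a[, c("gene_id", "chrom", "rank")]
  gb <- ann_b[, c("gene_id", "chrom", "rank")]

  x <- hits |>
    dplyr::left_join(ga, by = c(query = "gene_id")) |>
    dplyr::rename(chrom1 = "chrom", rank1 = "rank") |>
    dplyr::left_join(gb, by = c(subject = "gene_id")) |>
    dplyr::rename(chrom2 = "chrom", rank2 = "rank")
  unresolved <- is.na(x$chrom1) | is.na(x$chrom2)
  if (any(unresolved)) {
    warning(sprintf("%d hit(s) dropped: gene id not in annotation", sum(unresolved)))
  }
  x <- x[!unresolved, ]
  if (intra) {
    x <- dplyr::filter(x, .data$query != .data$subject)
    # canonical orientation: lower chromosome (then rank) on side 1, so each
    # unordered pair lands in one chromosome-pair group
    flip <- x$chrom1 > x$chrom2 |
      (x$chrom1 == x$chrom2 & x$rank1 > x$rank2)
    x[flip, c("query", "subject", "chrom1", "chrom2", "rank1", "rank2")] <-
      x[flip, c("subject", "query", "chrom2", "chrom1", "rank2", "rank1")]
    x <- x |>
      dplyr::group_by(.data$query, .data$subject) |>
      dplyr::slice_max(.data$bitscore, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
  }
  out <- x |>
    dplyr::transmute(
      gene1 = .data$query, gene2 = .data$subject,
      chrom1 = .data$chrom1, chrom2 = .data$chrom2,
      rank1 = .data$rank1, rank2 = .data$rank2,
      score = .data$bitscore
    )
  if (intra && collapse_tandem >= 0) {
    out <- remap_tandem_arrays(out, collapse_tandem)
  }
  attr(out, "n_dropped") <- sum(unresolved)
  out
}

# Collapse tandem arrays in intra-genome anchors. Pair anchors joining genes
# within `gap` ranks on the same chromosome define arrays (connected
# components); those anchors are dropped and every other anchor of an array
# member is remapped onto the array representative, deduplicating remapped
# anchors by best score. The representative is the member with the strongest
# outside-of-array homology (ties by rank): a tandem duplicate carries extra
# divergence relative to its parent, so the parent, not the copy, should
# stand in syntenic chains.
remap_tandem_arrays <- function(anchors, gap) {
  is_pair <- anchors$chrom1 == anchors$chrom2 &
    abs(anchors$rank1 - anchors$rank2) <= gap
  if (!any(is_pair)) return(anchors)
  e <- anchors[is_pair, ]
  rank <- c(stats::setNames(e$rank1, e$gene1), stats::setNames(e$rank2, e$gene2))
  genes <- unique(c(e$gene1, e$gene2))
  comp <- stats::setNames(seq_along(genes), genes)
  repeat {
    changed <- FALSE
    for (i in seq_len(nrow(e))) {
      m <- min(comp[[e$gene1[i]]], comp[[e$gene2[i]]])
      if (comp[[e$gene1[i]]] != m || comp[[e$gene2[i]]] != m) {
        comp[[e$gene1[i]]] <- m
        comp[[e$gene2[i]]] <- m
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  non_pair <- anchors[!is_pair, ]
  outside <- stats::setNames(rep(0, length(genes)), genes)
  for (side in c("gene1", "gene2")) {
    s <- tapply(non_pair$score, factor(non_pair[[side]], levels = genes), sum)
    outside <- outside + ifelse(is.na(s), 0, s)
  }
  rep_of <- vapply(split(genes, comp[genes]), function(g) {
    g <- g[order(-outside[g], rank[g])]
    g[1]
  }, character(1))
  map <- stats::setNames(rep_of[as.character(comp[genes])], genes)

  out <- non_pair
  for (side in 1:2) {
    gcol <- paste0("gene", side); rcol <- paste0("rank", side)
    m <- map[out[[gcol]]]
    sel <- !is.na(m)
    out[[gcol]][sel] <- m[sel]
    out[[rcol]][sel] <- as.integer(rank[m[sel]])
  }
  out |>
    dplyr::filter(.data$gene1 != .data$gene2) |>
    dplyr::group_by(.data$gene1, .data$gene2, .data$chrom1, .data$chrom2) |>
    dplyr::slice_max(.data$score, n = 1, with_ties = FALSE) |>
    dplyr::ungroup()
}

# Collapse tandem-redundant anchors: among anchors on one chromosome pair
# that share the gene in `shared`, keep only those whose `rank_col` rank
# differs by more than `gap` from every kept one. The kept representative is
# the first gene of the array (lowest rank; ties by hit score), so a tandem
# duplicate never displaces its parent from a chain.
collapse_tandem_anchors <- function(anchors, shared, rank_col, gap) {
  key <- paste(anchors$chrom1, anchors$chrom2, anchors[[shared]], sep = "\r")
  keep <- rep(TRUE, nrow(anchors))
  for (g in split(seq_len(nrow(anchors)), key)) {
    if (length(g) < 2L) next
    g <- g[order(anchors[[rank_col]][g], -anchors$score[g])]
    kept_ranks <- integer(0)
    for (i in g) {
      r <- anchors[[rank_col]][i]
      if (length(kept_ranks) && any(abs(kept_ranks - r) <= gap)) {
        keep[i] <- FALSE
      } else {
        kept_ranks <- c(kept_ranks, r)
      }
    }
  }
  anchors[keep, ]
}

# single best chain over one chromosome pair and orientation; anchors given
# as integer ranks r1, r2 (r2 already negated for the inverted orientation)
# and per-anchor scores. Returns indices of the chain and its score.
chain_dp <- function(r1, r2, score, max_gap, gap_penalty) {
  ord <- order(r1, r2)
  r1 <- r1[ord]; r2 <- r2[ord]; sc <- score[ord]
  n <- length(r1)
  dp <- sc
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    if (i == 1L) next
    j <- seq_len(i - 1L)
    d1 <- r1[i] - r1[j]
    d2 <- r2[i] - r2[j]
    ok <- d1 > 0 & d2 > 0 & d1 <= max_gap + 1 & d2 <= max_gap + 1
    if (any(ok)) {
      cand <- dp[j][ok] - gap_penalty * ((d1[ok] - 1) + (d2[ok] - 1))
      b <- which.max(cand)
      if (cand[b] > 0) {
        dp[i] <- sc[i] + cand[b]
        prev[i] <- j[ok][b]
      }
    }
  }
  end <- which.max(dp)
  chain <- integer(0)
  i <- end
  while (i != 0L) { chain <- c(i, chain); i <- prev[i] }
  list(idx = ord[chain], score = dp[end])
}

#' Detect collinear (syntenic) blocks by dynamic-programming chaining
#'
#' Per chromosome pair, repeatedly extracts the highest-scoring strictly
#' monotone anchor chain (both orientations tried: rank2 increasing = `same`,
#' decreasing = `inverted`), maximizing `sum(anchor score) - gap_penalty *
#' gap units` where a step contributes `(delta_rank - 1)` gap units per side
#' and steps are bounded by `max_gap` unmatched ranks. Used anchors are
#' removed so no anchor is reported twice; chains with fewer than `min_genes`
#' anchors are discarded (the conventional "at least five collinear genes"
#' rule).
#'
#' @param anchors Anchor tibble from [build_anchors()].
#' @param min_genes Minimum anchors per reported block (default 5).
#' @param max_gap Maximum unmatched gene ranks between consecutive anchors
#'   on either side (default 25).
#' @param gap_penalty Penalty per gap unit (default 1).
#' @param anchor_score Constant score per anchor (default 50, the MCScanX
#'   match-score convention); set `use_hit_score = TRUE` to use hit bit
#'   scores instead.
#' @param use_hit_score Score chains by hit bit score.
#' @param collapse_gap Redundancy cleanup before chaining (default 1):
#'   anchors sharing a gene whose other-side ranks fall within this distance
#'   compete for the same chain slot (typically a tandem array hitting one
#'   partner) and are collapsed to the lowest-rank one. Set to a negative
#'   value to disable. See also the tandem-array remapping in
#'   [build_anchors()].
#' @return Block tibble: block_id, chrom1, chrom2, orientation, n_anchors,
#'   score, and a list-column `anchors` of per-block anchor tibbles ordered
#'   along the chain.
#' @export
detect_blocks <- function(anchors, min_genes = 5, max_gap = 25, gap_penalty = 1,
                          anchor_score = 50, use_hit_score = FALSE,
                          collapse_gap = 1) {
  empty <- tibble::tibble(
    block_id = integer(0), chrom1 = character(0), chrom2 = character(0),
    orientation = character(0), n_anchors = integer(0), score = numeric(0),
    anchors = list()
  )
  if (nrow(anchors) == 0) return(empty)
  if (collapse_gap >= 0) {
    anchors <- collapse_tandem_anchors(anchors, "gene2", "rank1", collapse_gap)
    anchors <- collapse_tandem_anchors(anchors, "gene1", "rank2", collapse_gap)
    if (nrow(anchors) == 0) return(empty)
  }
  anchors <- dplyr::mutate(
    anchors,
    .score = if (use_hit_score) .data$score else anchor_score
  )
  blocks <- list()
  groups <- split(anchors, paste(anchors$chrom1, anchors$chrom2, sep = "\r"))
  for (g in groups) {
    rem <- g
    repeat {
      if (nrow(rem) < 2L) break
      best <- NULL
      for (orient in c("same", "inverted")) {
        r2 <- if (orient == "same") rem$rank2 else -rem$rank2
        ch <- chain_dp(rem$rank1, r2, rem$.score, max_gap, gap_penalty)
        if (is.null(best) || ch$score > best$score) {
          best <- ch; best$orientation <- orient
        }
      }
      if (length(best$idx) < 2L) break
      if (length(best$idx) >= min_genes) {
        blk <- rem[best$idx, ]
        blocks[[length(blocks) + 1L]] <- tibble::tibble(
          chrom1 = blk$chrom1[1], chrom2 = blk$chrom2[1],
          orientation = best$orientation,
          n_anchors = nrow(blk), score = best$score,
          anchors = list(dplyr::select(blk, -".score"))
        )
      }
      rem <- rem[-best$idx, ]
    }
  }
  if (length(blocks) == 0) return(empty)
  out <- dplyr::bind_rows(blocks) |>
    dplyr::arrange(dplyr::desc(.data$score)) |>
    dplyr::mutate(block_id = dplyr::row_number(), .before = 1)
  out
}

#' Flatten block anchors to one row per anchor pair
#' @param blocks Block tibble from [detect_blocks()].
#' @export
block_anchors <- function(blocks) {
  if (nrow(blocks) == 0) {
    return(tibble::tibble(block_id = integer(0), gene1 = character(0),
                          gene2 = character(0)))
  }
  blocks |>
    dplyr::select("block_id", "anchors") |>
    tidyr::unnest("anchors")
}

#' Classify genes by duplication mode
#'
#' MCScanX-style precedence: a gene in any syntenic block anchor is
#' `wgd_segmental`; otherwise a gene whose best surviving paralog sits within
#' `tandem_gap` ranks on the same chromosome is `tandem`, within
#' `proximal_gap` ranks `proximal`; any other gene with a surviving paralog
#' hit is `dispersed`; the rest are `singleton`.
#'
#' @param hits Filtered paralog hits.
#' @param ann Ranked annotation.
#' @param blocks Block tibble from [detect_blocks()].
#' @param tandem_gap,proximal_gap Rank-distance cutoffs (defaults 1 and 10).
#' @return Tibble: gene_id, class.
#' @export
classify_duplicates <- function(hits, ann, blocks,
                                tandem_gap = 1, proximal_gap = 10) {
  if (!"rank" %in% names(ann)) ann <- add_ranks(ann)
  cls <- stats::setNames(rep("singleton", nrow(ann)), ann$gene_id)

  h <- hits |>
    dplyr::filter(.data$query != .data$subject,
                  .data$query %in% ann$gene_id,
                  .data$subject %in% ann$gene_id)
  # make the hit list symmetric so every gene has its best partner
  h2 <- dplyr::bind_rows(
    h,
    dplyr::rename(h, query = "subject", subject = "query",
                  qstart = "sstart", qend = "send",
                  sstart = "qstart", send = "qend")
  )
  best <- h2 |>
    dplyr::arrange(.data$query, dplyr::desc(.data$bitscore),
                   dplyr::desc(.data$pident), .data$subject) |>
    dplyr::distinct(.data$query, .keep_all = TRUE) |>
    dplyr::left_join(ann[, c("gene_id", "chrom", "rank")],
                     by = c(query = "gene_id")) |>
    dplyr::left_join(ann[, c("gene_id", "chrom", "rank")],
                     by = c(subject = "gene_id"), suffix = c("", "_s"))

  cls[best$query] <- "dispersed"
  same <- best$chrom == best$chrom_s
  dist <- abs(best$rank - best$rank_s)
  cls[best$query[same & dist <= proximal_gap]] <- "proximal"
  cls[best$query[same & dist <= tandem_gap]] <- "tandem"

  ba <- block_anchors(blocks)
  cls[unique(c(ba$gene1, ba$gene2))] <- "wgd_segmental"

  tibble::tibble(gene_id = ann$gene_id, class = unname(cls[ann$gene_id]))
}

#' Identify paralogous chromosome pairs from interchromosomal best hits
#'
#' For each gene, its single best interchromosomal paralog (bit score, ties
#' by identity then subject id) increments the cell of the corresponding
#' chromosome pair; the matrix is symmetrized by summation. A pair (i, j) is
#' declared paralogous when its count is the row maximum for both i and j and
#' exceeds the uniform-assignment expectation by at least `enrich_min`.
#'
#' @param hits Filtered paralog hits.
#' @param ann Ranked annotation.
#' @param enrich_min Minimum fold enrichment over the uniform expectation.
#' @return An object of class `chrom_pairing`: list with `counts` (symmetric
#'   matrix), `pairs` (tibble: chrom1, chrom2, count, enrichment) and
#'   `expected` (uniform expectation per unordered pair).
#' @export
pair_chromosomes <- function(hits, ann, enrich_min = 2) {
  if (!"rank" %in% names(ann)) ann <- add_ranks(ann)
  chroms <- sort(unique(ann$chrom))
  K <- length(chroms)
  counts <- matrix(0, K, K, dimnames = list(chroms, chroms))
  empty <- structure(list(
    counts = counts, expected = NA_real_,
    pairs = tibble::tibble(chrom1 = character(0), chrom2 = character(0),
                           count = numeric(0), enrichment = numeric(0))
  ), class = "chrom_pairing")
  if (K < 2 || nrow(hits) == 0) return(empty)

  h <- hits |>
    dplyr::filter(.data$query != .data$subject) |>
    dplyr::left_join(ann[, c("gene_id", "chrom")], by = c(query = "gene_id")) |>
    dplyr::rename(chrom_q = "chrom") |>
    dplyr::left_join(ann[, c("gene_id", "chrom")], by = c(subject = "gene_id")) |>
    dplyr::rename(chrom_s = "chrom") |>
    dplyr::filter(!is.na(.data$chrom_q), !is.na(.data$chrom_s),
                  .data$chrom_q != .data$chrom_s)
  # symmetric view so both genes of a hit get a candidate partner
  h <- dplyr::bind_rows(
    h,
    dplyr::rename(h, query = "subject", subject = "query",
                  chrom_q = "chrom_s", chrom_s = "chrom_q",
                  qstart = "sstart", qend = "send",
                  sstart = "qstart", send = "qend")
  )
  if (nrow(h) == 0) return(empty)
  best <- h |>
    dplyr::arrange(.data$query, dplyr::desc(.data$bitscore),
                   dplyr::desc(.data$pident), .data$subject) |>
    dplyr::distinct(.data$query, .keep_all = TRUE)
  tabbed <- table(factor(best$chrom_q, chroms), factor(best$chrom_s, chroms))
  counts <- unclass(tabbed) + t(unclass(tabbed))
  diag(counts) <- 0

  expected <- sum(counts) / 2 / (K * (K - 1) / 2)
  pairs <- list()
  rowmax <- apply(counts, 1, max)
  for (i in seq_len(K - 1)) {
    for (j in (i + 1):K) {
      cnt <- counts[i, j]
      if (cnt > 0 && cnt == rowmax[i] && cnt == rowmax[j] &&
          cnt >= enrich_min * expected) {
        pairs[[length(pairs) + 1L]] <- tibble::tibble(
          chrom1 = chroms[i], chrom2 = chroms[j],
          count = cnt, enrichment = cnt / expected
        )
      }
    }
  }
  structure(list(
    counts = counts, expected = expected,
    pairs = if (length(pairs)) dplyr::bind_rows(pairs) else empty$pairs
  ), class = "chrom_pairing")
}

#' @export
print.chrom_pairing <- function(x, ...) {
  cat(sprintf("<chrom_pairing> %d chromosomes, %d declared pair(s)\n",
              nrow(x$counts), nrow(x$pairs)))
  if (nrow(x$pairs) > 0) print(x$pairs)
  invisible(x)
}

#' Shared syntenic blocks across two descendant species
#'
#' Connects intra-genome paralog blocks of species A to those of species B
#' through ortholog blocks: a quartet (two A chromosomes, two B chromosomes)
#' is shared when ortholog links join each A chromosome of an intra-A block
#' to a distinct chromosome of an intra-B block. The count of connected
#' (A block, B block) combinations is reported per quartet.
#'
#' @param intra_a,intra_b Intra-genome block tibbles.
#' @param ortho Ortholog (A vs B) block tibble; chrom1 must be the A side.
#' @return List with `quartets` (tibble: chrom_a1, chrom_a2, chrom_b1,
#'   chrom_b2, n_shared) and `a_blocks` (tibble: block_id, matched flag).
#' @export
shared_blocks <- function(intra_a, intra_b, ortho) {
  if (nrow(ortho) == 0) {
    warning("no ortholog blocks: shared synteny is empty")
    return(list(
      quartets = tibble::tibble(chrom_a1 = character(0), chrom_a2 = character(0),
                                chrom_b1 = character(0), chrom_b2 = character(0),
                                n_shared = integer(0)),
      a_blocks = tibble::tibble(block_id = intra_a$block_id,
                                matched = rep(FALSE, nrow(intra_a)))
    ))
  }
  links <- unique(paste(ortho$chrom1, ortho$chrom2, sep = "\r"))
  linked <- function(ca, cb) paste(ca, cb, sep = "\r") %in% links

  quartets <- list()
  matched <- rep(FALSE, nrow(intra_a))
  for (i in seq_len(nrow(intra_a))) {
    a1 <- intra_a$chrom1[i]; a2 <- intra_a$chrom2[i]
    for (j in seq_len(nrow(intra_b))) {
      b1 <- intra_b$chrom1[j]; b2 <- intra_b$chrom2[j]
      hit <- (linked(a1, b1) && linked(a2, b2)) ||
        (linked(a1, b2) && linked(a2, b1))
      if (hit) {
        matched[i] <- TRUE
        quartets[[length(quartets) + 1L]] <- tibble::tibble(
          chrom_a1 = a1, chrom_a2 = a2,
          chrom_b1 = min(b1, b2), chrom_b2 = max(b1, b2)
        )
      }
    }
  }
  q <- if (length(quartets)) {
    dplyr::bind_rows(quartets) |>
      dplyr::count(.data$chrom_a1, .data$chrom_a2, .data$chrom_b1,
                   .data$chrom_b2, name = "n_shared")
  } else {
    tibble::tibble(chrom_a1 = character(0), chrom_a2 = character(0),
                   chrom_b1 = character(0), chrom_b2 = character(0),
                   n_shared = integer(0))
  }
  list(
    quartets = q,
    a_blocks = tibble::tibble(block_id = intra_a$block_id, matched = matched)
  )
}
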