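#' Single-copy / duplicated / missing fractions per genome
#'
#' Summarizes a reference family table (BUSCO-style: near-universal
#' single-copy ortholog families scored by copy number per genome). An
#' elevated duplicated fraction is a classic whole-genome-duplication
#' signature.
#'
#' @param families Tidy tibble: genome, family, copies (integer >= 0).
#' @return Tibble per genome: n_families, frac_single, frac_duplicated,
#'   frac_missing (fractions sum to 1).
#' @export
duplication_fraction <- function(families) {
  stopifnot(all(c("genome", "family", "copies") %in% names(families)))
  if (nrow(families) == 0) stop("empty family table", call. = FALSE)
  if (any(families$copies < 0) || any(families$copies != round(families$copies))) {
    stop("copy numbers must be non-negative integers", call. = FALSE)
  }
  families |>
    dplyr::group_by(.data$genome) |>
    dplyr::summarise(
      n_families = dplyr::n(),
      frac_single = mean(.data$copies == 1),
      frac_duplicated = mean(.data$copies >= 2),
      frac_missing = mean(.data$copies == 0),
      .groups = "drop"
    )
}

#' Compare duplicated fractions between two genome groups
#'
#' Two-sided Welch t-test plus a permutation test on the group-mean
#' difference; the permutation p-value is exact (full enumeration of label
#' assignments) when the total sample size is at most `exact_max`, otherwise
#' Monte-Carlo with `nperm` draws. For tiny groups the permutation test is
#' the primary result.
#'
#' @param group_a,group_b Numeric vectors of duplicated fractions (or a
#'   `duplication_fraction` tibble's `frac_duplicated` column).
#' @param nperm Monte-Carlo permutations when enumeration is infeasible.
#' @param exact_max Enumerate exactly when `length(a) + length(b)` is at most
#'   this (default 12).
#' @return List: mean_a, mean_b, mean_diff, t_statistic, p_t (NA if either
#'   group has < 2 values), p_perm, n_perm, exact.
#' @export
compare_groups <- function(group_a, group_b, nperm = 10000, exact_max = 12) {
  a <- as.numeric(group_a); b <- as.numeric(group_b)
  if (length(a) == 0 || length(b) == 0) stop("empty group", call. = FALSE)
  obs <- mean(a) - mean(b)

  welch <- if (length(a) >= 2 && length(b) >= 2 &&
               (stats::sd(a) > 0 || stats::sd(b) > 0)) {
    stats::t.test(a, b)
  } else NULL

  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  exact <- n <= exact_max
  if (exact) {
    idx <- utils::combn(n, na)
    diffs <- apply(idx, 2, function(i) mean(pool[i]) - mean(pool[-i]))
    p_perm <- mean(abs(diffs) >= abs(obs) - 1e-12)
    n_used <- ncol(idx)
  } else {
    diffs <- replicate(nperm, {
      i <- sample.int(n, na)
      mean(pool[i]) - mean(pool[-i])
    })
    # add the identity permutation so p >= 1/(nperm + 1)
    p_perm <- (sum(abs(diffs) >= abs(obs) - 1e-12) + 1) / (nperm + 1)
    n_used <- nperm
  }
  list(
    mean_a = mean(a), mean_b = mean(b), mean_diff = obs,
    t_statistic = if (is.null(welch)) NA_real_ else unname(welch$statistic),
    p_t = if (is.null(welch)) NA_real_ else welch$p.value,
    p_perm = p_perm, n_perm = n_used, exact = exact
  )
}

#' Scan chromosomes for conserved marker-gene clusters
#'
#' Finds maximal runs of marker-family genes (e.g. the Hox families lab, pb,
#' Dfd, Scr, ftz, Antp, Ubx, Abd-B and associated miRNAs) whose internal rank
#' gaps are at most `max_gap`. The largest run is the principal cluster (ties
#' broken by lowest chromosome id); markers outside it are extra copies, and
#' extra copies co-located within `max_gap` form extra clusters — the
#' signature of a duplicated cluster retained after WGD.
#'
#' @param ann Ranked annotation ([add_ranks()]).
#' @param markers Tibble: gene_id, family.
#' @param max_gap Maximum unmatched ranks inside a run (default 5).
#' @param reference_families Optional family universe; families absent from
#'   `markers` are reported missing.
#' @return List: `clusters` (tibble: cluster_id, chrom, n, rank_start,
#'   rank_end, families list-column, principal flag), `missing_families`.
#' @export
scan_clusters <- function(ann, markers, max_gap = 5, reference_families = NULL) {
  if (!"rank" %in% names(ann)) ann <- add_ranks(ann)
  m <- dplyr::inner_join(markers, ann, by = "gene_id")
  missing <- setdiff(reference_families %||% character(0), markers$family)
  if (nrow(m) == 0) {
    warning("no marker genes found in the annotation")
    return(list(
      clusters = tibble::tibble(cluster_id = integer(0), chrom = character(0),
                                n = integer(0), rank_start = integer(0),
                                rank_end = integer(0), families = list(),
                                principal = logical(0)),
      missing_families = missing
    ))
  }
  runs <- m |>
    dplyr::arrange(.data$chrom, .data$rank) |>
    dplyr::group_by(.data$chrom) |>
    dplyr::mutate(run = cumsum(c(1, diff(.data$rank) > max_gap + 1))) |>
    dplyr::group_by(.data$chrom, .data$run) |>
    dplyr::summarise(
      n = dplyr::n(), rank_start = min(.data$rank), rank_end = max(.data$rank),
      families = list(.data$family[order(.data$rank)]),
      .groups = "drop"
    )
  principal_at <- order(-runs$n, runs$chrom)[1]
  runs$principal <- seq_len(nrow(runs)) == principal_at
  runs <- runs |>
    dplyr::arrange(dplyr::desc(.data$principal), dplyr::desc(.data$n), .data$chrom) |>
    dplyr::mutate(cluster_id = dplyr::row_number(), .before = 1) |>
    dplyr::select(-"run")
  list(clusters = runs, missing_families = missing)
}

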