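#' Protein-guided codon alignment of two coding sequences
#'
#' Globally aligns the translated proteins (BLOSUM62, affine gaps) and
#' back-translates the alignment to codons. Columns with a gap on either side
#' are excluded from substitution counting.
#'
#' @param cds_a,cds_b Coding sequences (A/C/G/T, length a multiple of 3, no
#'   internal stop codons).
#' @param id_a,id_b Optional gene ids used in error messages.
#' @return A `codon_alignment`: integer codon index vectors (NA at gaps) and
#'   a `counted` column mask.
#' @export
codon_align <- function(cds_a, cds_b, id_a = "cds_a", id_b = "cds_b") {
  tab <- codon_tables()
  check <- function(cds, id) {
    cod <- tryCatch(dna_to_codons(cds),
                    error = function(e) stop(sprintf("%s: %s", id, conditionMessage(e)),
                                             call. = FALSE))
    if (any(tab$is_stop[cod])) {
      stop(sprintf("%s: internal stop codon", id), call. = FALSE)
    }
    cod
  }
  # canonical input order, so the alignment (and hence every downstream
  # count) is exactly symmetric in pair order despite traceback tie-breaking
  swapped <- cds_b < cds_a
  if (swapped) {
    tmp <- cds_a; cds_a <- cds_b; cds_b <- tmp
    tmp <- id_a; id_a <- id_b; id_b <- tmp
  }
  ca <- check(cds_a, id_a)
  cb <- check(cds_b, id_b)
  pa <- translate_codons(ca)
  pb <- translate_codons(cb)
  aln <- Biostrings::pairwiseAlignment(
    pattern = Biostrings::AAString(pa), subject = Biostrings::AAString(pb),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 11, gapExtension = 1
  )
  ga <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  gb <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  out_a <- rep(NA_integer_, length(ga))
  out_b <- rep(NA_integer_, length(gb))
  out_a[ga != "-"] <- ca
  out_b[gb != "-"] <- cb
  if (swapped) {
    tmp <- out_a; out_a <- out_b; out_b <- tmp
  }
  structure(list(
    codons_a = out_a, codons_b = out_b,
    counted = !is.na(out_a) & !is.na(out_b)
  ), class = "codon_alignment")
}

# HKY codon-process machinery for the exact expected-count inversion.
# The rate matrix on the 61 sense codons has q_ij = kappa^[transition] *
# omega^[nonsynonymous] for single-nucleotide neighbors (stops excluded),
# which is symmetric, so the stationary distribution is uniform and P(t)
# comes from one eigendecomposition. Memoized on a rounded (kappa, omega)
# grid so pairs with similar parameter estimates share the decomposition.
codon_process <- function(kappa, omega) {
  key <- sprintf("Q_%.2f_%.3f", kappa, omega)
  hit <- .paleo_cache[[key]]
  if (!is.null(hit)) return(hit)
  tab <- codon_tables()
  sense <- which(!tab$is_stop)
  n <- length(sense)
  pos <- stats::setNames(seq_len(n), sense)
  Q <- matrix(0, n, n)
  for (a in seq_len(n)) {
    nb <- tab$neigh[[sense[a]]]
    nb <- nb[!nb$stop, , drop = FALSE]
    w <- ifelse(nb$ts, kappa, 1) * ifelse(nb$syn, 1, omega)
    Q[a, pos[as.character(nb$to)]] <- w
  }
  diag(Q) <- -rowSums(Q)
  eg <- eigen(Q, symmetric = TRUE)

  pt <- codon_pair_tables()
  sdts <- pt$sd_ts[sense, sense]
  sdtv <- pt$sd_tv[sense, sense]
  sdmat <- sdts + sdtv
  ndmat <- (pt$nd_ts + pt$nd_tv)[sense, sense]
  ssites <- tab$syn_sites[sense]
  nsites <- tab$nonsyn_sites[sense]
  smean <- outer(ssites, ssites, function(a, b) (a + b) / 2)
  nmean <- outer(nsites, nsites, function(a, b) (a + b) / 2)
  # per-codon synonymous / nonsynonymous flux at rate 1 (uniform pi)
  syn_rate <- numeric(n); non_rate <- numeric(n)
  for (a in seq_len(n)) {
    nb <- tab$neigh[[sense[a]]]
    nb <- nb[!nb$stop, , drop = FALSE]
    w <- ifelse(nb$ts, kappa, 1) * ifelse(nb$syn, 1, omega)
    syn_rate[a] <- sum(w[nb$syn])
    non_rate[a] <- sum(w[!nb$syn])
  }
  obj <- list(
    vectors = eg$vectors, values = eg$values, n = n,
    sdmat = sdmat, sdts = sdts, sdtv = sdtv,
    ndmat = ndmat, smean = smean, nmean = nmean,
    # synonymous events per synonymous site per unit time (the Ks clock)
    c_syn = mean(syn_rate) / mean(ssites),
    c_non = mean(non_rate) / mean(nsites)
  )
  .paleo_cache[[key]] <- obj
  obj
}

# expected observed proportions (path-counted differences per site) after
# total divergence time t between two equilibrium sequences
codon_expected <- function(proc, t) {
  P <- proc$vectors %*% (exp(proc$values * t) * t(proc$vectors))
  c(
    p_syn = sum(P * proc$sdmat) / sum(P * proc$smean),
    p_non = sum(P * proc$ndmat) / sum(P * proc$nmean)
  )
}

# invert an observed difference proportion to a distance on the Ks (or Ka)
# scale; returns NA when the proportion is at or beyond the saturation level
invert_codon <- function(proc, obs, what = c("p_syn", "p_non"), t_max = 60) {
  what <- match.arg(what)
  clock <- if (what == "p_syn") proc$c_syn else proc$c_non
  if (obs <= 0) return(0)
  sat <- codon_expected(proc, t_max)[[what]]
  if (obs >= sat) return(NA_real_)
  f <- function(t) codon_expected(proc, t)[[what]] - obs
  t_hat <- stats::uniroot(f, c(0, t_max), tol = 1e-8)$root
  clock * t_hat
}

# raw divergence time matching an observed synonymous difference proportion
# (NA when saturated)
codon_time <- function(proc, p_syn, t_max = 60) {
  if (p_syn <= 0) return(0)
  if (p_syn >= codon_expected(proc, t_max)[["p_syn"]]) return(NA_real_)
  f <- function(t) codon_expected(proc, t)[["p_syn"]] - p_syn
  stats::uniroot(f, c(0, t_max), tol = 1e-8)$root
}

# Solve for the underlying nucleotide kappa: the transition share of counted
# synonymous differences depends on kappa, but structurally exceeds the
# nucleotide ratio because two-fold degenerate sites admit only synonymous
# transitions — so kappa is found by matching the observed share to its
# expectation under the codon process at the divergence implied by p_syn.
# Returns the boundary value when the observed share falls outside the
# attainable range.
solve_kappa <- function(p_syn, ts_share, omega, k_range = c(0.5, 15)) {
  kgrid <- function(k) round(k, 1)
  mismatch <- function(k) {
    proc <- codon_process(kgrid(k), omega)
    t_hat <- codon_time(proc, p_syn)
    if (is.na(t_hat)) return(NA_real_)
    P <- proc$vectors %*% (exp(proc$values * t_hat) * t(proc$vectors))
    e_ts <- sum(P * proc$sdts); e_tv <- sum(P * proc$sdtv)
    e_ts / (e_ts + e_tv) - ts_share
  }
  lo <- mismatch(k_range[1]); hi <- mismatch(k_range[2])
  if (is.na(lo) || is.na(hi)) return(NA_real_)
  if (lo >= 0) return(k_range[1])
  if (hi <= 0) return(k_range[2])
  kgrid(stats::uniroot(mismatch, k_range, tol = 0.05)$root)
}

# Kimura-two-parameter closed form on one site partition: the HKY family
# collapses to a single transition/transversion ratio under the near-uniform
# base composition this estimator assumes.
k2p_distance <- function(P, Q) {
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    return(list(d = NA_real_, kappa = NA_real_, saturated = TRUE))
  }
  at <- -0.5 * log(w1) + 0.25 * log(w2)
  bt <- -0.25 * log(w2)
  list(
    d = -0.5 * log(w1) - 0.25 * log(w2),
    kappa = if (bt > 0) at / bt else Inf,
    saturated = FALSE
  )
}

#' Estimate synonymous and nonsynonymous distances for a codon alignment
#'
#' Site and difference counts follow the NG86 recipe: per-codon synonymous
#' site fractions (stop-codon mutations excluded, positions renormalized) and
#' minimal-mutation-path averaged difference counts, split into transitions
#' and transversions.
#'
#' Multiple-hit correction (the default, `method = "codon"`) inverts the
#' expected counted-difference proportion under the HKY codon process itself:
#' kappa comes from the synonymous transition/transversion split (closed-form
#' two-parameter estimate), omega from the partition distance ratio, and the
#' observed Sd/S (resp. Nd/N) is mapped back to a distance through the exact
#' transition probabilities of the 61-codon rate matrix. This accounts for
#' the mixed saturation behavior of two-fold and four-fold degenerate sites
#' and for path misattribution at high divergence, which a single pooled
#' nucleotide-style curve over-corrects.
#'
#' `method = "k2p"` instead applies the closed-form Kimura two-parameter
#' correction per partition (the textbook NG86-style recipe); with `kappa`
#' supplied it uses the kappa-constrained transversion-only inversion.
#' Observed proportions at or beyond the saturation level of the correction
#' flag the pair as saturated (Ks undefined, NA).
#'
#' @param aln A [codon_align()] result.
#' @param kappa Optional fixed transition/transversion ratio.
#' @param method Multiple-hit correction: `"codon"` (exact HKY codon-process
#'   inversion, default) or `"k2p"` (closed-form two-parameter per partition).
#' @return A `ks_estimate` list: S, N (site counts), Sd, Nd (differences,
#'   with the transition/transversion split), ks, ka, kappa, omega,
#'   saturated, low_confidence (fewer than 30 counted codons), n_codons.
#' @export
estimate_ks <- function(aln, kappa = NULL, method = c("codon", "k2p")) {
  method <- match.arg(method)
  stopifnot(inherits(aln, "codon_alignment"))
  tab <- codon_tables()
  pt <- codon_pair_tables()
  ca <- aln$codons_a[aln$counted]
  cb <- aln$codons_b[aln$counted]
  n_codons <- length(ca)
  S <- (sum(tab$syn_sites[ca]) + sum(tab$syn_sites[cb])) / 2
  N <- (sum(tab$nonsyn_sites[ca]) + sum(tab$nonsyn_sites[cb])) / 2
  if (S <= 0) stop("zero synonymous sites", call. = FALSE)
  ij <- cbind(ca, cb)
  sd_ts <- sum(pt$sd_ts[ij]); sd_tv <- sum(pt$sd_tv[ij])
  nd_ts <- sum(pt$nd_ts[ij]); nd_tv <- sum(pt$nd_tv[ij])

  k2p_correct <- function(dts, dtv, sites) {
    P <- dts / sites; Q <- dtv / sites
    if (is.null(kappa)) {
      k2p_distance(P, Q)
    } else {
      # kappa fixed: invert the transversion component only
      w2 <- 1 - 2 * Q
      if (w2 <= 0) return(list(d = NA_real_, kappa = kappa, saturated = TRUE))
      bt <- -0.25 * log(w2)
      list(d = (kappa + 2) * bt, kappa = kappa, saturated = FALSE)
    }
  }
  syn_k2p <- k2p_correct(sd_ts, sd_tv, S)
  non_k2p <- k2p_correct(nd_ts, nd_tv, N)

  if (method == "k2p") {
    ks <- syn_k2p$d; ka <- non_k2p$d
    kap <- syn_k2p$kappa; om <- if (is.finite(ks) && ks > 0) ka / ks else NA_real_
    saturated <- syn_k2p$saturated
  } else {
    # parameter plug-ins, rounded so pairs share the memoized
    # eigendecomposition: omega starts from the corrected partition distance
    # ratio (raw proportion ratio as fallback); kappa is solved within the
    # codon process itself (see solve_kappa) because the synonymous-partition
    # ts/tv ratio structurally overstates the nucleotide kappa
    ps <- (sd_ts + sd_tv) / S
    pn <- (nd_ts + nd_tv) / N
    om <- if (is.finite(syn_k2p$d) && syn_k2p$d > 0 && is.finite(non_k2p$d)) {
      non_k2p$d / syn_k2p$d
    } else if (ps > 0) pn / ps else 1
    om <- round(min(max(om, 0.02), 5), 2)
    solve_kap <- is.null(kappa)
    share <- if (sd_ts + sd_tv > 0) sd_ts / (sd_ts + sd_tv) else NA_real_
    if (solve_kap) {
      kap <- if (is.finite(share)) solve_kappa(ps, share, om) else 2
      if (is.na(kap)) kap <- 2  # share unresolvable (saturation): nominal kappa
    } else {
      kap <- round(min(max(kappa, 0.5), 20), 1)
    }
    proc <- codon_process(kap, om)
    ks <- invert_codon(proc, ps, "p_syn")
    ka <- invert_codon(proc, pn, "p_non")
    # one refinement pass on omega once both distances are on a common scale
    if (is.finite(ks) && ks > 0 && is.finite(ka)) {
      om2 <- round(min(max(ka / ks, 0.02), 5), 2)
      if (abs(om2 - om) > 0.01) {
        om <- om2
        if (solve_kap && is.finite(share)) {
          k2 <- solve_kappa(ps, share, om)
          if (!is.na(k2)) kap <- k2
        }
        proc <- codon_process(kap, om)
        ks <- invert_codon(proc, ps, "p_syn")
        ka <- invert_codon(proc, pn, "p_non")
      }
    }
    saturated <- is.na(ks)
  }

  structure(list(
    S = S, N = N,
    Sd = sd_ts + sd_tv, Sd_ts = sd_ts, Sd_tv = sd_tv,
    Nd = nd_ts + nd_tv,
    ks = ks, ka = ka, kappa = kap, omega = om,
    saturated = saturated,
    low_confidence = n_codons < 30,
    n_codons = n_codons,
    method = method
  ), class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat(sprintf("<ks_estimate> Ks = %s (S = %.1f, Sd = %.1f)%s\n",
              ifelse(x$saturated, "saturated", sprintf("%.4f", x$ks)),
              x$S, x$Sd,
              ifelse(x$low_confidence, " [low confidence]", "")))
  invisible(x)
}

#' Ks for a table of gene pairs
#'
#' Runs [codon_align()] + [estimate_ks()] for each pair; pairs with a missing
#' CDS are skipped with a warning. With `pool_kappa = TRUE` (the default for
#' the codon method) the transition/transversion ratio is solved once from
#' the pooled synonymous counts of all pairs and held fixed, which removes
#' the per-pair kappa noise that otherwise inflates high-divergence
#' estimates.
#'
#' @param pairs Tibble with columns gene1, gene2 (extra columns carried over).
#' @param cds_a Named character vector of coding sequences for gene1.
#' @param cds_b Sequences for gene2 (defaults to `cds_a` for paralog pairs).
#' @param kappa,method Passed to [estimate_ks()].
#' @param pool_kappa Share one kappa solved from pooled counts across pairs
#'   (codon method with `kappa = NULL` only).
#' @return Tibble: the input columns plus S, Sd, kappa, ks, ka, saturated,
#'   low_confidence.
#' @export
pairs_ks <- function(pairs, cds_a, cds_b = cds_a, kappa = NULL,
                     method = c("codon", "k2p"), pool_kappa = TRUE) {
  method <- match.arg(method)
  stopifnot(all(c("gene1", "gene2") %in% names(pairs)))
  missing <- !(pairs$gene1 %in% names(cds_a)) | !(pairs$gene2 %in% names(cds_b))
  if (any(missing)) {
    warning(sprintf("%d pair(s) skipped: missing CDS", sum(missing)))
    pairs <- pairs[!missing, ]
  }
  alns <- purrr::map2(pairs$gene1, pairs$gene2, function(g1, g2) {
    codon_align(cds_a[[g1]], cds_b[[g2]], g1, g2)
  })
  if (pool_kappa && is.null(kappa) && method == "codon" && length(alns) > 0) {
    counts <- purrr::map(alns, estimate_ks, method = "k2p")
    sts <- sum(purrr::map_dbl(counts, "Sd_ts"))
    stv <- sum(purrr::map_dbl(counts, "Sd_tv"))
    S <- sum(purrr::map_dbl(counts, "S"))
    nd <- sum(purrr::map_dbl(counts, "Nd"))
    N <- sum(purrr::map_dbl(counts, "N"))
    if (sts + stv > 0 && S > 0) {
      om0 <- round(min(max((nd / N) / ((sts + stv) / S), 0.02), 5), 2)
      kappa <- solve_kappa((sts + stv) / S, sts / (sts + stv), om0)
      if (is.na(kappa)) kappa <- NULL  # pooled counts saturated: per-pair kappa
    }
  }
  est <- purrr::map(alns, function(aln) {
    e <- estimate_ks(aln, kappa = kappa, method = method)
    tibble::tibble(S = e$S, Sd = e$Sd, kappa = e$kappa, ks = e$ks, ka = e$ka,
                   saturated = e$saturated, low_confidence = e$low_confidence)
  })
  dplyr::bind_cols(pairs, dplyr::bind_rows(est))
}

#' Ks for every anchor pair of a block set
#'
#' @param blocks Block tibble from [detect_blocks()].
#' @param cds_a,cds_b CDS stores (side 2 defaults to side 1 for paralog
#'   blocks).
#' @param kappa,method Passed to [estimate_ks()].
#' @return Tibble with one row per anchor (block_id attached) plus the
#'   per-block median Ks over unsaturated pairs (`block_median_ks`).
#' @export
block_ks <- function(blocks, cds_a, cds_b = cds_a, kappa = NULL,
                     method = c("codon", "k2p")) {
  ba <- block_anchors(blocks)
  if (nrow(ba) == 0) {
    return(tibble::tibble(block_id = integer(0), gene1 = character(0),
                          gene2 = character(0), ks = numeric(0)))
  }
  out <- pairs_ks(ba[, c("block_id", "gene1", "gene2")], cds_a, cds_b,
                  kappa = kappa, method = method)
  out |>
    dplyr::group_by(.data$block_id) |>
    dplyr::mutate(block_median_ks = stats::median(.data$ks[!.data$saturated])) |>
    dplyr::ungroup()
}

#' Detect peaks in a Ks distribution
#'
#' Gaussian kernel density (Silverman bandwidth scaled by `bw_adjust`) on Ks
#' values within the analysis window, evaluated on a regular grid; local
#' maxima above `min_height_frac` of the global maximum are reported sorted
#' by height. `method = "gmm"` instead fits Gaussian mixtures to log(Ks) with
#' BIC component selection and reports component means.
#'
#' @param ks Numeric Ks values (saturated pairs enter as NA and are dropped).
#' @param window Analysis window; the default `[0.01, 5]` excludes allelic
#'   near-zero pairs and saturated tails.
#' @param bw_adjust Bandwidth scale on Silverman's rule (default 0.7).
#' @param min_height_frac Peak floor as a fraction of the highest peak.
#' @param n_grid Density grid size.
#' @param method `"kde"` (default) or `"gmm"`.
#' @param max_components Maximum mixture components for `method = "gmm"`.
#' @return A `ks_peaks` object: tibble `peaks` (ks, height), the density
#'   grid, bandwidth, n used, and a low-confidence flag (n < 50).
#' @export
ks_peaks <- function(ks, window = c(0.01, 5), bw_adjust = 0.7,
                     min_height_frac = 0.1, n_grid = 512,
                     method = c("kde", "gmm"), max_components = 4) {
  method <- match.arg(method)
  x <- ks[is.finite(ks)]
  x <- x[x >= window[1] & x <= window[2]]
  low_conf <- length(x) < 50
  if (low_conf) {
    warning(sprintf("only %d Ks values in window: peaks are low-confidence",
                    length(x)))
  }
  if (length(x) < 2) {
    return(structure(list(
      peaks = tibble::tibble(ks = numeric(0), height = numeric(0)),
      density = tibble::tibble(x = numeric(0), y = numeric(0)),
      bw = NA_real_, n = length(x), low_confidence = low_conf, method = method
    ), class = "ks_peaks"))
  }
  if (method == "kde") {
    bw <- stats::bw.nrd0(x) * bw_adjust
    den <- stats::density(x, bw = bw, from = window[1], to = window[2], n = n_grid)
    y <- den$y
    n <- length(y)
    is_max <- c(y[1] > y[2],
                y[2:(n - 1)] > y[1:(n - 2)] & y[2:(n - 1)] >= y[3:n],
                y[n] > y[n - 1])
    keep <- is_max & y >= min_height_frac * max(y)
    peaks <- tibble::tibble(ks = den$x[keep], height = y[keep]) |>
      dplyr::arrange(dplyr::desc(.data$height))
    density <- tibble::tibble(x = den$x, y = den$y)
  } else {
    bic <- mclust::mclustBIC(log(x), G = seq_len(max_components),
                             modelNames = "V", verbose = FALSE)
    fit <- mclust::Mclust(log(x), x = bic, verbose = FALSE)
    peaks <- tibble::tibble(
      ks = exp(as.numeric(fit$parameters$mean)),
      height = as.numeric(fit$parameters$pro)
    ) |> dplyr::arrange(dplyr::desc(.data$height))
    bw <- NA_real_
    density <- tibble::tibble(x = numeric(0), y = numeric(0))
  }
  structure(list(
    peaks = peaks, density = density, bw = if (method == "kde") bw else NA_real_,
    n = length(x), low_confidence = low_conf, method = method
  ), class = "ks_peaks")
}

#' Dominant Ks mode of a peak set
#' @param x A `ks_peaks` object.
#' @export
ks_mode <- function(x) {
  stopifnot(inherits(x, "ks_peaks"))
  if (nrow(x$peaks) == 0) NA_real_ else x$peaks$ks[1]
}

#' @export
print.ks_peaks <- function(x, ...) {
  cat(sprintf("<ks_peaks> %s on %d values%s\n", x$method, x$n,
              ifelse(x$low_confidence, " [low confidence]", "")))
  print(x$peaks, n = 5)
  invisible(x)
}

#' Order the duplication event against the lineage split
#'
#' Compares each species' dominant paralog Ks mode with the between-species
#' ortholog mode. The duplication predates the split when every paralog mode
#' exceeds the ortholog mode by at least `delta`; it postdates the split when
#' every paralog mode is at least `delta` below it; anything else (including
#' missing peaks) is ambiguous.
#'
#' @param paralog_modes Numeric vector of dominant paralog Ks modes (one per
#'   species, names optional).
#' @param ortholog_mode Dominant ortholog Ks mode.
#' @param delta Decision margin on Ks (default 0.05).
#' @return List with `order` (one of `WGD_BEFORE_DIVERGENCE`,
#'   `WGD_AFTER_DIVERGENCE`, `AMBIGUOUS`), `margin`, and `reason`.
#' @export
order_events <- function(paralog_modes, ortholog_mode, delta = 0.05) {
  if (length(paralog_modes) == 0 || anyNA(paralog_modes) || is.na(ortholog_mode)) {
    return(list(order = "AMBIGUOUS", margin = NA_real_,
                reason = "missing peak(s)"))
  }
  m <- paralog_modes - ortholog_mode
  if (min(m) >= delta) {
    list(order = "WGD_BEFORE_DIVERGENCE", margin = min(m),
         reason = "every paralog peak is older than the ortholog peak")
  } else if (max(m) <= -delta) {
    list(order = "WGD_AFTER_DIVERGENCE", margin = max(m),
         reason = "every paralog peak is younger than the ortholog peak")
  } else {
    list(order = "AMBIGUOUS", margin = m[which.min(abs(m))],
         reason = sprintf("peak separation within the +/-%g margin", delta))
  }
}
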