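#' Simulate a tidal-exposure expression matrix from simulator truth
#'
#' Generates FPKM values for every species-A gene under a four-group design:
#' submerged controls (C) and individuals exposed at low (L), medium (M) and
#' high (H) shore elevation, i.e. increasing air-exposure time. Functional
#' genes draw a log-normal baseline with log-normal replicate noise;
#' nonfunctionalized genes are 0 in every sample; each neo-/subfunctionalized
#' gene responds (up-shift by `effect_log2fc`) from a uniformly drawn onset
#' elevation upward, so the expected number of responding genes increases
#' monotonically C -> L -> M -> H.
#'
#' @param sim A `sim_dataset` from [simulate_genome()] (or any list with
#'   `truth$fate_labels`).
#' @param n_reps Replicates per group (>= 2; differential expression is
#'   undefined below that).
#' @param groups Group labels in increasing exposure order.
#' @param baseline_log2_mean,baseline_log2_sd Log2 mean/sd of per-gene
#'   baseline FPKM.
#' @param noise_log2_sd Log2 sd of replicate noise.
#' @param effect_log2fc Log2 fold change applied to responding genes.
#' @param seed Random seed.
#'
#' @return A list with `expr` (tibble, gene_id x samples), `samples`
#'   (tibble: sample, group) and `fate` (the truth labels used).
#' @export
simulate_expression <- function(sim,
                                n_reps = 3,
                                groups = c("C", "L", "M", "H"),
                                baseline_log2_mean = 5,
                                baseline_log2_sd = 1.5,
                                noise_log2_sd = 0.5,
                                effect_log2fc = 2,
                                seed = 1L) {
  if (n_reps < 2) stop("need >= 2 replicates per group", call. = FALSE)
  fate <- if (inherits(sim, "sim_dataset")) sim$truth$fate_labels else sim$fate_labels
  stopifnot(is.data.frame(fate), all(c("gene_id", "fate") %in% names(fate)))
  set.seed(seed)

  samples <- tibble::tibble(
    sample = paste0(rep(groups, each = n_reps), "_", rep(seq_len(n_reps), length(groups))),
    group = rep(groups, each = n_reps)
  )
  n_g <- nrow(fate)
  n_s <- nrow(samples)
  baseline <- 2^stats::rnorm(n_g, baseline_log2_mean, baseline_log2_sd)
  mat <- baseline * 2^matrix(stats::rnorm(n_g * n_s, 0, noise_log2_sd), n_g, n_s)

  exposure_rank <- stats::setNames(seq_along(groups) - 1L, groups)
  is_neo <- fate$fate == "neo_sub"
  if (any(is_neo)) {
    # onset elevation: responds in all groups at or above it
    onset <- sample(groups[-1], sum(is_neo), replace = TRUE)
    shift <- outer(exposure_rank[onset], exposure_rank[samples$group], "<=")
    mat[is_neo, ] <- mat[is_neo, , drop = FALSE] * ifelse(shift, 2^effect_log2fc, 1)
  }
  mat[fate$fate == "nonfunctionalized", ] <- 0

  expr <- tibble::as_tibble(as.data.frame(mat))
  names(expr) <- samples$sample
  expr <- dplyr::bind_cols(tibble::tibble(gene_id = fate$gene_id), expr)
  list(expr = expr, samples = samples, fate = fate)
}

#' Simulate a two-group metabolome with class-structured shifts
#'
#' Two-group (submerged control C vs exposed M) log-normal intensity table
#' with compound-class annotation. A designated number of metabolites are
#' shifted up or down by `fold` in the exposed group, with configurable class
#' membership of the shifts (by default 34 of the 71 up-shifts are
#' acyl-carnitines and 8 of the 45 down-shifts long-chain free fatty acids,
#' the composition reported for air-exposed barnacles).
#'
#' @param n_metabolites Total metabolites.
#' @param n_per_group Samples per group (>= 3 for OPLS-DA fitting).
#' @param n_up,n_down Number of metabolites shifted up/down in group M.
#' @param n_up_acylcarnitine Up-shifted metabolites drawn from the
#'   acyl-carnitine class.
#' @param n_down_ffa Down-shifted metabolites drawn from the long-chain FFA
#'   class.
#' @param fold Raw-scale fold applied to shifted metabolites (>= 1).
#' @param class_sizes Named class sizes; must sum to `n_metabolites`.
#' @param base_log2_mean,base_log2_sd Log2 mean/sd of baseline intensity.
#' @param noise_log2_sd Log2 sd of replicate noise.
#' @param seed Random seed.
#'
#' @return A list with `intensities` (tibble: metabolite_id, class,
#'   samples...), `samples` (tibble: sample, group) and `truth` (tibble:
#'   metabolite_id, class, shifted in up/down/none).
#' @export
simulate_metabolome <- function(n_metabolites = 300,
                                n_per_group = 6,
                                n_up = 71,
                                n_down = 45,
                                n_up_acylcarnitine = 34,
                                n_down_ffa = 8,
                                fold = 4,
                                class_sizes = c("acyl-carnitine" = 40,
                                                "long-chain FFA" = 30,
                                                "other" = 230),
                                base_log2_mean = 16,
                                base_log2_sd = 2,
                                noise_log2_sd = 0.4,
                                seed = 1L) {
  if (fold < 1) stop("fold must be >= 1", call. = FALSE)
  if (sum(class_sizes) != n_metabolites) {
    stop("class_sizes must sum to n_metabolites", call. = FALSE)
  }
  if (n_up + n_down > n_metabolites) stop("more shifts than metabolites", call. = FALSE)
  if (n_up_acylcarnitine > min(n_up, class_sizes["acyl-carnitine"]) ||
      n_down_ffa > min(n_down, class_sizes["long-chain FFA"])) {
    stop("class-specific shift counts exceed class or direction totals", call. = FALSE)
  }
  set.seed(seed)

  cls <- rep(names(class_sizes), class_sizes)
  ids <- sprintf("met%04d", seq_len(n_metabolites))
  samples <- tibble::tibble(
    sample = c(paste0("C_", seq_len(n_per_group)), paste0("M_", seq_len(n_per_group))),
    group = rep(c("C", "M"), each = n_per_group)
  )

  shifted <- rep("none", n_metabolites)
  ac <- which(cls == "acyl-carnitine")
  ffa <- which(cls == "long-chain FFA")
  other_pool <- seq_len(n_metabolites)
  up_ac <- sample(ac, n_up_acylcarnitine)
  down_ffa <- sample(ffa, n_down_ffa)
  rest <- setdiff(other_pool, c(up_ac, down_ffa))
  up_rest <- sample(rest, n_up - n_up_acylcarnitine)
  rest <- setdiff(rest, up_rest)
  down_rest <- sample(rest, n_down - n_down_ffa)
  shifted[c(up_ac, up_rest)] <- "up"
  shifted[c(down_ffa, down_rest)] <- "down"

  base <- 2^stats::rnorm(n_metabolites, base_log2_mean, base_log2_sd)
  mat <- base * 2^matrix(stats::rnorm(n_metabolites * nrow(samples), 0, noise_log2_sd),
                         n_metabolites, nrow(samples))
  in_m <- samples$group == "M"
  mat[shifted == "up", in_m] <- mat[shifted == "up", in_m, drop = FALSE] * fold
  mat[shifted == "down", in_m] <- mat[shifted == "down", in_m, drop = FALSE] / fold

  intensities <- dplyr::bind_cols(
    tibble::tibble(metabolite_id = ids, class = cls),
    stats::setNames(tibble::as_tibble(as.data.frame(mat)), samples$sample)
  )
  list(
    intensities = intensities,
    samples = samples,
    truth = tibble::tibble(metabolite_id = ids, class = cls, shifted = shifted)
  )
}
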