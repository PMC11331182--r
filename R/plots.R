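#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a Ks distribution with its detected peaks
#'
#' Kernel density curve with vertical dashed lines at each detected peak
#' (KDE method) or peak positions only (GMM method).
#'
#' @param object A [ks_peaks()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ks_peaks <- function(object, ...) {
  p <- ggplot2::ggplot()
  if (nrow(object$density) > 0) {
    p <- p + ggplot2::geom_line(
      data = object$density,
      ggplot2::aes(x = .data$x, y = .data$y)
    )
  }
  if (nrow(object$peaks) > 0) {
    p <- p + ggplot2::geom_vline(
      data = object$peaks,
      ggplot2::aes(xintercept = .data$ks),
      linetype = "dashed", colour = "firebrick"
    )
  }
  p + ggplot2::labs(
    x = "Ks (synonymous substitutions per synonymous site)",
    y = "density",
    title = sprintf("Ks distribution (%d pairs)", object$n)
  )
}

#' Plot the paralog-density matrix of a chromosome pairing
#'
#' Heatmap of interchromosomal best-hit paralog counts with the declared
#' pairs outlined.
#'
#' @param object A [pair_chromosomes()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chrom_pairing <- function(object, ...) {
  m <- object$counts
  df <- tibble::as_tibble(as.data.frame.table(m, responseName = "n",
                                              stringsAsFactors = FALSE))
  names(df)[1:2] <- c("chrom1", "chrom2")
  pairs <- object$pairs
  ggplot2::ggplot(df, ggplot2::aes(x = .data$chrom2, y = .data$chrom1)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$n)) +
    ggplot2::geom_tile(
      data = dplyr::bind_rows(
        pairs,
        dplyr::rename(pairs, chrom1 = "chrom2", chrom2 = "chrom1")
      ),
      fill = NA, colour = "firebrick", linewidth = 0.8
    ) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue") +
    ggplot2::labs(x = NULL, y = NULL, fill = "paralog\nbest hits",
                  title = "Paralogous chromosome pairing") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot OPLS-DA scores
#'
#' Predictive score (t) against the first orthogonal score (t_ortho), colored
#' by group; falls back to sample index on the y axis when no orthogonal
#' component was retained.
#'
#' @param object A fitted [fit_opls()] model.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.opls_model <- function(object, ...) {
  df <- tibble::tibble(
    t = object$scores,
    t_ortho = if (object$n_ortho > 0) object$ortho[[1]]$t
              else seq_along(object$scores),
    group = object$samples$group
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$t_ortho,
                                   colour = .data$group)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(
      x = "predictive score t",
      y = if (object$n_ortho > 0) "orthogonal score t_o" else "sample index",
      title = sprintf("OPLS-DA scores (R2Y = %.2f, Q2 = %.2f)",
                      object$R2Y, object$Q2)
    )
}

#' Volcano-style plot of metabolite calls
#'
#' log2 fold change against VIP with the inclusive decision thresholds drawn
#' and regulated metabolites highlighted.
#'
#' @param diff A [call_differential()] table.
#' @param fc_up,fc_down,vip_min The thresholds used for the calls (drawn as
#'   reference lines; defaults 2, 0.5, 1).
#' @return A ggplot object.
#' @export
plot_differential <- function(diff, fc_up = 2, fc_down = 0.5, vip_min = 1) {
  ggplot2::ggplot(diff, ggplot2::aes(x = log2(.data$fold_change), y = .data$vip,
                                     colour = .data$regulated)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_vline(xintercept = log2(c(fc_down, fc_up)), linetype = "dotted") +
    ggplot2::geom_hline(yintercept = vip_min, linetype = "dotted") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "VIP",
                  title = "Differential metabolite calls")
}

#' Dot plot of synteny blocks for one chromosome pair
#'
#' Anchor positions (gene ranks) with chained blocks colored; the classic
#' synteny dot plot restricted to one chromosome pair.
#'
#' @param blocks A [detect_blocks()] result.
#' @param chrom1,chrom2 Chromosome pair to draw (all blocks when omitted).
#' @return A ggplot object.
#' @export
plot_blocks <- function(blocks, chrom1 = NULL, chrom2 = NULL) {
  ba <- block_anchors(blocks)
  if (!is.null(chrom1)) ba <- dplyr::filter(ba, .data$chrom1 == !!chrom1)
  if (!is.null(chrom2)) ba <- dplyr::filter(ba, .data$chrom2 == !!chrom2)
  ggplot2::ggplot(ba, ggplot2::aes(x = .data$rank1, y = .data$rank2,
                                   colour = factor(.data$block_id))) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "gene rank (side 1)", y = "gene rank (side 2)",
                  colour = "block",
                  title = "Collinear block anchors")
}
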