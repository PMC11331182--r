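#' Fit an OPLS-DA model to a two-group metabolite table
#'
#' Orthogonal projections to latent structures discriminant analysis in the
#' classical NIPALS formulation: intensities are log2-transformed and
#' mean-centered (in that order), the class vector is coded +1/-1 and
#' centered, orthogonal components (variation uncorrelated with class) are
#' stripped, and one predictive component is fit on the filtered matrix.
#' Everything is deterministic: the predictive weight vector is X'y, no
#' random initialization is used.
#'
#' Q2 is estimated by 7-fold cross-validation with round-robin fold
#' assignment in sample order; permuted class labels should drive Q2 to or
#' below zero, which is the standard overfitting guard for OPLS-DA.
#'
#' @param intensities Tibble: metabolite_id, optionally class, then one
#'   numeric column per sample (intensities > 0).
#' @param samples Sample sheet tibble: sample, group (exactly two groups,
#'   at least 3 samples each).
#' @param n_ortho Number of orthogonal components (default 1).
#' @param cv_folds Cross-validation folds for Q2 (default 7, capped at n).
#' @return An `opls_model` with scores, loadings, weights, VIP, Q2, R2Y and
#'   the preprocessing record.
#' @export
fit_opls <- function(intensities, samples, n_ortho = 1, cv_folds = 7) {
  stopifnot("metabolite_id" %in% names(intensities),
            all(c("sample", "group") %in% names(samples)))
  groups <- unique(samples$group)
  if (length(groups) != 2) stop("OPLS-DA needs exactly two groups", call. = FALSE)
  if (any(table(samples$group) < 3)) {
    stop("need >= 3 samples per group", call. = FALSE)
  }
  mat <- t(as.matrix(intensities[, samples$sample]))  # samples x metabolites
  if (any(mat <= 0)) stop("intensities must be > 0 for the log transform", call. = FALSE)
  ids <- intensities$metabolite_id
  lx <- log2(mat)
  keep <- apply(lx, 2, stats::var) > 0
  if (!all(keep)) {
    warning(sprintf("%d zero-variance metabolite(s) dropped", sum(!keep)))
    lx <- lx[, keep, drop = FALSE]
    ids <- ids[keep]
  }
  y_raw <- ifelse(samples$group == groups[1], 1, -1)

  fit_core <- function(X, y, n_ortho) {
    xm <- colMeans(X)
    X <- sweep(X, 2, xm)
    ym <- mean(y)
    y <- y - ym
    ortho <- list()
    for (k in seq_len(n_ortho)) {
      w <- drop(crossprod(X, y)); w <- w / sqrt(sum(w^2))
      t_p <- drop(X %*% w)
      p <- drop(crossprod(X, t_p)) / sum(t_p^2)
      w_o <- p - drop(crossprod(w, p)) * w
      nw <- sqrt(sum(w_o^2))
      if (nw < 1e-12) break  # no orthogonal variation left
      w_o <- w_o / nw
      t_o <- drop(X %*% w_o)
      p_o <- drop(crossprod(X, t_o)) / sum(t_o^2)
      X <- X - tcrossprod(t_o, p_o)
      ortho[[k]] <- list(w = w_o, t = t_o, p = p_o)
    }
    w <- drop(crossprod(X, y)); w <- w / sqrt(sum(w^2))
    t_p <- drop(X %*% w)
    p <- drop(crossprod(X, t_p)) / sum(t_p^2)
    q <- sum(y * t_p) / sum(t_p^2)
    list(x_means = xm, y_mean = ym, w = w, t = t_p, p = p, q = q,
         ortho = ortho, X_filtered = X)
  }

  core <- fit_core(lx, y_raw, n_ortho)
  y_c <- y_raw - core$y_mean
  y_hat <- core$q * core$t
  r2y <- 1 - sum((y_c - y_hat)^2) / sum(y_c^2)

  # 7-fold CV for Q2 (deterministic round-robin folds)
  n <- nrow(lx)
  folds <- rep_len(seq_len(min(cv_folds, n)), n)
  press <- 0
  for (f in unique(folds)) {
    tr <- folds != f
    cf <- fit_core(lx[tr, , drop = FALSE], y_raw[tr], n_ortho)
    Xte <- sweep(lx[!tr, , drop = FALSE], 2, cf$x_means)
    # strip the orthogonal components from the held-out samples
    for (o in cf$ortho) {
      t_o <- drop(Xte %*% o$w)
      Xte <- Xte - tcrossprod(t_o, o$p)
    }
    t_te <- drop(Xte %*% cf$w)
    pred <- cf$q * t_te + cf$y_mean
    press <- press + sum((y_raw[!tr] - pred)^2)
  }
  q2 <- 1 - press / sum((y_raw - mean(y_raw))^2)

  vip <- sqrt(length(core$w)) * abs(core$w) / sqrt(sum(core$w^2))

  structure(list(
    metabolite_id = ids,
    groups = groups,
    samples = samples,
    weights = core$w, scores = core$t, loadings = core$p, q = core$q,
    ortho = core$ortho,
    n_ortho = length(core$ortho),
    vip = stats::setNames(vip, ids),
    preprocessing = list(transform = "log2", centering = "mean",
                         x_means = core$x_means),
    R2Y = r2y, Q2 = q2
  ), class = "opls_model")
}

#' @export
print.opls_model <- function(x, ...) {
  cat(sprintf("<opls_model> 1 predictive + %d orthogonal component(s), %d metabolites\n",
              x$n_ortho, length(x$weights)))
  cat(sprintf("  R2Y = %.3f, Q2 = %.3f (groups: %s vs %s)\n",
              x$R2Y, x$Q2, x$groups[1], x$groups[2]))
  invisible(x)
}

#' Variable importance in projection
#'
#' VIP over the single predictive component: `sqrt(p) * |w_j| / ||w||`, so
#' the squared values average exactly 1 over retained metabolites.
#'
#' @param model A fitted `opls_model`.
#' @return Named numeric vector of VIP scores.
#' @export
vip <- function(model) {
  if (!inherits(model, "opls_model")) stop("not a fitted opls_model", call. = FALSE)
  model$vip
}

#' Call differential metabolites by fold change and VIP
#'
#' A metabolite is regulated when its raw-scale fold change (exposed / control
#' group mean) is >= `fc_up` or <= `fc_down` AND its VIP is >= `vip_min`; all
#' three thresholds are inclusive.
#'
#' @param intensities Metabolite tibble (metabolite_id, optional class,
#'   sample columns).
#' @param samples Sample sheet (two groups; `case` defaults to the second
#'   group in sheet order, typically the exposed group).
#' @param model Optional pre-fitted [fit_opls()] model (fit on the fly
#'   otherwise).
#' @param case,control Group labels for the fold-change ratio case/control.
#' @param fc_up,fc_down,vip_min Inclusive thresholds (defaults 2, 0.5, 1).
#' @return Tibble: metabolite_id, class (if present), fold_change, vip,
#'   regulated, direction.
#' @export
call_differential <- function(intensities, samples, model = NULL,
                              case = NULL, control = "C",
                              fc_up = 2, fc_down = 0.5, vip_min = 1) {
  if (is.null(model)) model <- fit_opls(intensities, samples)
  groups <- unique(samples$group)
  if (is.null(case)) case <- setdiff(groups, control)[1]
  mat <- as.matrix(intensities[, samples$sample])
  fc <- rowMeans(mat[, samples$group == case, drop = FALSE]) /
    rowMeans(mat[, samples$group == control, drop = FALSE])
  v <- rep(NA_real_, nrow(intensities))
  hit <- match(model$metabolite_id, intensities$metabolite_id)
  v[hit] <- model$vip
  out <- tibble::tibble(
    metabolite_id = intensities$metabolite_id,
    fold_change = fc,
    vip = v,
    regulated = !is.na(v) & v >= vip_min & (fc >= fc_up | fc <= fc_down),
    direction = dplyr::if_else(fc >= 1, "up", "down")
  )
  if ("class" %in% names(intensities)) {
    out <- dplyr::mutate(out, class = intensities$class, .after = "metabolite_id")
  }
  out
}

#' Compound-class shares among regulated metabolites
#'
#' Counts and percentage shares per compound class among metabolites
#' regulated in one direction; percentages are reported to two decimals
#' (100 * count / total regulated in that direction).
#'
#' @param diff A [call_differential()] table with a `class` column.
#' @param direction `"up"` or `"down"`.
#' @return Tibble: class, n, percent (sorted by n, descending).
#' @export
class_share <- function(diff, direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot("class" %in% names(diff))
  d <- dplyr::filter(diff, .data$regulated, .data$direction == !!direction)
  if (nrow(d) == 0) {
    return(tibble::tibble(class = character(0), n = integer(0),
                          percent = numeric(0)))
  }
  d |>
    dplyr::count(.data$class, name = "n") |>
    dplyr::mutate(percent = round(100 * .data$n / sum(.data$n), 2)) |>
    dplyr::arrange(dplyr::desc(.data$n), .data$class)
}
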