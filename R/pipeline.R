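#' Run the whole-genome-duplication inference pipeline end to end
#'
#' Orchestrates simulate-or-ingest, homology search, synteny block detection,
#' chromosome pairing, Ks estimation and peak dating, duplicate
#' classification, ohnolog fate classification on simulated exposure
#' expression, and OPLS-DA metabolite calls, returning a machine-readable
#' report.
#'
#' Input is either a simulation `config` (the default "barnacle" scenario) or
#' an `inputs` list of file paths (exactly one of the two): `inputs` must have
#' elements `a` and `b`, each a list with `proteins`, `cds` (FASTA) and
#' `annotation` (GFF3) paths; all referenced files must exist before any
#' stage runs. With file inputs the truth-dependent stages (fate and
#' metabolite simulation) are skipped unless `expression`/`samples` are
#' supplied.
#'
#' Stages run in dependency order; a failed stage is recorded in the report
#' and its dependents are skipped. When `out_dir` is set, each stage result
#' is cached on disk keyed by a hash of its parameters and upstream keys, so
#' a rerun with unchanged inputs skips the stage and returns identical
#' output.
#'
#' @param config A [sim_config()] (default barnacle scenario).
#' @param inputs Optional list of input paths (see Details); mutually
#'   exclusive with `config`.
#' @param out_dir Optional directory for stage caching and the report files.
#' @param search Homology engine: `"blast"` (external blastp, default) or
#'   `"internal"` (the package aligner; quadratic, small inputs only).
#' @param max_evalue,top_n Hit filtering (defaults 1e-5 and 5).
#' @param min_genes,max_gap Block detection parameters (defaults 5 and 25).
#' @param expression,samples Optional expression matrix and sample sheet for
#'   the fate stage when running from file inputs.
#' @param quiet Suppress progress messages.
#' @return A `wgd_report` list: `stages` (status tibble), per-stage
#'   summaries, and `provenance` (config hash, seed, package version), plus
#'   a `timestamp` field isolated so the rest of the report is deterministic.
#' @export
run_wgd_pipeline <- function(config = sim_config(), inputs = NULL,
                             out_dir = NULL,
                             search = c("blast", "internal"),
                             max_evalue = 1e-5, top_n = 5,
                             min_genes = 5, max_gap = 25,
                             expression = NULL, samples = NULL,
                             quiet = FALSE) {
  search <- match.arg(search)
  if (!is.null(inputs)) {
    config <- NULL
    paths <- unlist(inputs)
    missing <- paths[!file.exists(paths)]
    if (length(missing) > 0) {
      stop(sprintf("input file(s) not found: %s", paste(missing, collapse = ", ")),
           call. = FALSE)
    }
    needed <- c("proteins", "cds", "annotation")
    if (!all(c("a", "b") %in% names(inputs)) ||
        !all(needed %in% names(inputs$a)) || !all(needed %in% names(inputs$b))) {
      stop("inputs must list a/b, each with proteins, cds and annotation",
           call. = FALSE)
    }
  }
  if (!is.null(out_dir) && !dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  say <- function(...) if (!quiet) message(sprintf(...))

  params <- list(search = search, max_evalue = max_evalue, top_n = top_n,
                 min_genes = min_genes, max_gap = max_gap)
  base_key <- rlang::hash(list(
    config = if (is.null(config)) NULL else unclass(config),
    inputs = inputs, params = params
  ))

  status <- list()
  results <- new.env(parent = emptyenv())
  stage <- function(name, deps = character(0), compute) {
    failed_dep <- deps[vapply(deps, function(d) {
      isTRUE(status[[d]] %in% c("failed", "skipped"))
    }, logical(1))]
    if (length(failed_dep) > 0) {
      status[[name]] <<- "skipped"
      say("stage %-12s skipped (upstream: %s)", name, failed_dep[1])
      return(invisible(NULL))
    }
    key <- rlang::hash(list(base_key, name,
                            lapply(deps, function(d) attr(results[[d]], "stage_key"))))
    if (!is.null(out_dir)) {
      kf <- file.path(out_dir, paste0("stage_", name, ".key"))
      rf <- file.path(out_dir, paste0("stage_", name, ".rds"))
      if (file.exists(kf) && file.exists(rf) && identical(readLines(kf)[1], key)) {
        results[[name]] <- readRDS(rf)
        status[[name]] <<- "cached"
        say("stage %-12s cached", name)
        return(invisible(NULL))
      }
    }
    val <- tryCatch(compute(), error = function(e) e)
    if (inherits(val, "error")) {
      status[[name]] <<- "failed"
      say("stage %-12s FAILED: %s", name, conditionMessage(val))
      attr(val, "stage_key") <- key
      results[[name]] <- val
      return(invisible(NULL))
    }
    if (!is.null(val)) attr(val, "stage_key") <- key
    results[[name]] <- val
    status[[name]] <<- "ok"
    if (!is.null(out_dir)) {
      saveRDS(val, rf)
      writeLines(key, kf)
    }
    say("stage %-12s ok", name)
    invisible(NULL)
  }

  # --- data -----------------------------------------------------------------
  stage("data", compute = function() {
    if (!is.null(config)) {
      sim <- simulate_genome(config)
      list(sim = sim,
           species = lapply(sim$species, function(s) {
             list(annotation = add_ranks(s$annotation),
                  cds = s$cds, protein = s$protein)
           }))
    } else {
      list(sim = NULL, species = lapply(inputs, function(p) {
        list(annotation = add_ranks(read_annotation(p$annotation)),
             cds = read_fasta(p$cds), protein = read_fasta(p$proteins))
      }))
    }
  })

  # --- homology ---------------------------------------------------------------
  stage("homology", deps = "data", compute = function() {
    sp <- results$data$species
    hit <- function(x, y = NULL) {
      h <- if (search == "blast") blast_hits(x, y) else all_vs_all(x, y)
      filter_hits(h, max_evalue = max_evalue, top_n = top_n)
    }
    list(intra_a = hit(sp$a$protein %||% sp$A$protein),
         intra_b = hit(sp$b$protein %||% sp$B$protein),
         ortho = hit(sp$a$protein %||% sp$A$protein,
                     sp$b$protein %||% sp$B$protein))
  })

  # --- synteny ----------------------------------------------------------------
  stage("synteny", deps = "homology", compute = function() {
    sp <- results$data$species
    ann_a <- (sp$a %||% sp$A)$annotation
    ann_b <- (sp$b %||% sp$B)$annotation
    h <- results$homology
    blocks_a <- detect_blocks(build_anchors(h$intra_a, ann_a),
                              min_genes = min_genes, max_gap = max_gap)
    blocks_b <- detect_blocks(build_anchors(h$intra_b, ann_b),
                              min_genes = min_genes, max_gap = max_gap)
    blocks_o <- detect_blocks(build_anchors(h$ortho, ann_a, ann_b),
                              min_genes = min_genes, max_gap = max_gap)
    list(
      blocks_a = blocks_a, blocks_b = blocks_b, blocks_ortho = blocks_o,
      pairing_a = pair_chromosomes(h$intra_a, ann_a),
      pairing_b = pair_chromosomes(h$intra_b, ann_b),
      classes_a = classify_duplicates(h$intra_a, ann_a, blocks_a),
      shared = shared_blocks(blocks_a, blocks_b, blocks_o)
    )
  })

  # --- ks ---------------------------------------------------------------------
  stage("ks", deps = "synteny", compute = function() {
    sp <- results$data$species
    cds_a <- (sp$a %||% sp$A)$cds
    cds_b <- (sp$b %||% sp$B)$cds
    syn <- results$synteny
    ks_a <- block_ks(syn$blocks_a, cds_a)
    ks_b <- block_ks(syn$blocks_b, cds_b)
    # ortholog ages come from reciprocal best hits, not block anchors: every
    # chromosome is collinear with BOTH homeologs of the other species, so
    # block anchors mix same-copy and cross-copy pairs and bias the mode up
    h <- results$homology$ortho
    best_ab <- h |>
      dplyr::group_by(.data$query) |>
      dplyr::slice_max(.data$bitscore, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    best_ba <- h |>
      dplyr::group_by(.data$subject) |>
      dplyr::slice_max(.data$bitscore, n = 1, with_ties = FALSE) |>
      dplyr::ungroup()
    rbh <- dplyr::inner_join(best_ab[, c("query", "subject")],
                             best_ba[, c("query", "subject")],
                             by = c("query", "subject"))
    ks_o <- pairs_ks(dplyr::rename(rbh, gene1 = "query", gene2 = "subject"),
                     cds_a, cds_b)
    peaks_a <- ks_peaks(ks_a$ks)
    peaks_b <- ks_peaks(ks_b$ks)
    peaks_o <- ks_peaks(ks_o$ks)
    list(
      ks_a = ks_a, ks_b = ks_b, ks_ortho = ks_o,
      peaks_a = peaks_a, peaks_b = peaks_b, peaks_ortho = peaks_o,
      ordering = order_events(
        c(A = ks_mode(peaks_a), B = ks_mode(peaks_b)), ks_mode(peaks_o)
      )
    )
  })

  # --- fate -------------------------------------------------------------------
  stage("fate", deps = "synteny", compute = function() {
    sim <- results$data$sim
    if (is.null(expression) && is.null(sim)) return(NULL)
    if (is.null(expression)) {
      om <- simulate_expression(sim, seed = sim$config$seed)
      expression <- om$expr
      samples <- om$samples
    }
    pairs <- block_anchors(results$synteny$blocks_a)[, c("gene1", "gene2")] |>
      dplyr::distinct()
    fates <- classify_fates(pairs, expression, samples)
    de <- differential_expression(expression, samples)
    list(fates = fates, summary = fate_summary(fates), trend = up_trend(de))
  })

  # --- metabolome -------------------------------------------------------------
  stage("metabolome", deps = "data", compute = function() {
    if (is.null(results$data$sim)) return(NULL)
    met <- simulate_metabolome(seed = if (!is.null(config)) config$seed else 1L)
    model <- fit_opls(met$intensities, met$samples)
    diff <- call_differential(met$intensities, met$samples, model = model,
                              case = "M")
    list(model = model, diff = diff,
         share_up = class_share(diff, "up"),
         share_down = class_share(diff, "down"))
  })

  # --- report -----------------------------------------------------------------
  summarize <- function() {
    syn <- results$synteny; ks <- results$ks
    fate <- results$fate; met <- results$metabolome
    list(
      blocks = if (!is.null(syn) && !inherits(syn, "error")) list(
        n_blocks_a = nrow(syn$blocks_a), n_blocks_b = nrow(syn$blocks_b),
        n_blocks_ortho = nrow(syn$blocks_ortho),
        n_shared_quartets = nrow(syn$shared$quartets),
        chromosome_pairs_a = nrow(syn$pairing_a$pairs),
        duplicate_classes_a = as.list(table(syn$classes_a$class))
      ),
      ks = if (!is.null(ks) && !inherits(ks, "error")) list(
        mode_paralog_a = ks_mode(ks$peaks_a),
        mode_paralog_b = ks_mode(ks$peaks_b),
        mode_ortholog = ks_mode(ks$peaks_ortho),
        event_order = ks$ordering$order,
        margin = ks$ordering$margin
      ),
      fate = if (!is.null(fate) && !inherits(fate, "error")) as.list(fate$summary),
      metabolome = if (!is.null(met) && !inherits(met, "error")) list(
        n_up = sum(met$diff$regulated & met$diff$direction == "up"),
        n_down = sum(met$diff$regulated & met$diff$direction == "down"),
        Q2 = met$model$Q2, R2Y = met$model$R2Y,
        top_up_class = if (nrow(met$share_up) > 0) met$share_up$class[1] else NA,
        top_up_share = if (nrow(met$share_up) > 0) met$share_up$percent[1] else NA
      )
    )
  }

  report <- structure(list(
    stages = tibble::tibble(stage = names(status),
                            status = unlist(status, use.names = FALSE)),
    summary = summarize(),
    results = results,
    provenance = list(
      config_hash = base_key,
      seed = if (!is.null(config)) config$seed else NA_integer_,
      package_version = as.character(utils::packageVersion("paleoploid"))
    ),
    timestamp = format(Sys.time(), tz = "UTC")
  ), class = "wgd_report")

  if (!is.null(out_dir)) {
    write_report(report, file.path(out_dir, "report.json"))
    writeLines(utils::capture.output(print(report)),
               file.path(out_dir, "report.txt"))
  }
  if (any(report$stages$status == "failed")) {
    warning("one or more stages failed; see report$stages")
  }
  report
}

#' Write a pipeline report as JSON
#'
#' Serializes the stage statuses, summaries and provenance (not the full
#' result objects). All fields except `timestamp` are deterministic for a
#' fixed config and seed.
#'
#' @param report A `wgd_report`.
#' @param path Output JSON path.
#' @return Invisibly, `path`.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "wgd_report"))
  out <- list(
    schema = "paleoploid-report/1",
    stages = report$stages,
    summary = report$summary,
    provenance = report$provenance,
    timestamp = report$timestamp
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.wgd_report <- function(x, ...) {
  cat("<wgd_report>\n")
  for (i in seq_len(nrow(x$stages))) {
    cat(sprintf("  %-12s %s\n", x$stages$stage[i], x$stages$status[i]))
  }
  s <- x$summary
  if (!is.null(s$blocks)) {
    cat(sprintf("  blocks: A %d, B %d, ortho %d; %d chromosome pairs (A); %d shared quartets\n",
                s$blocks$n_blocks_a, s$blocks$n_blocks_b, s$blocks$n_blocks_ortho,
                s$blocks$chromosome_pairs_a, s$blocks$n_shared_quartets))
  }
  if (!is.null(s$ks)) {
    cat(sprintf("  Ks modes: paralog A %.2f, paralog B %.2f, ortholog %.2f -> %s\n",
                s$ks$mode_paralog_a, s$ks$mode_paralog_b, s$ks$mode_ortholog,
                s$ks$event_order))
  }
  if (!is.null(s$fate)) {
    cat(sprintf("  fates: %.2f%% nonfunctionalized, %.2f%% neo/sub of %d ohnolog genes\n",
                s$fate$pct_nonfunctionalized, s$fate$pct_neo_sub,
                s$fate$n_ohnolog_genes))
  }
  if (!is.null(s$metabolome)) {
    cat(sprintf("  metabolites: %d up / %d down (Q2 = %.2f); top up class %s (%.2f%%)\n",
                s$metabolome$n_up, s$metabolome$n_down, s$metabolome$Q2,
                s$metabolome$top_up_class, s$metabolome$top_up_share))
  }
  cat(sprintf("  seed %s | %s\n", x$provenance$seed, x$timestamp))
  invisible(x)
}
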