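#' Write a simulated dataset to disk in standard formats
#'
#' Emits, per species, protein and CDS FASTA files and a gene-level GFF3, plus
#' TSV truth tables (ohnolog pairs, chromosome pairs, fate labels, tandem ids)
#' and the configuration as YAML. File contents are byte-stable for a fixed
#' simulation seed.
#'
#' @param sim A [simulate_genome()] result.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the named character vector of paths written.
#' @export
write_sim_dataset <- function(sim, dir) {
  stopifnot(inherits(sim, "sim_dataset"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (sp in names(sim$species)) {
    s <- sim$species[[sp]]
    p_prot <- file.path(dir, paste0(sp, "_proteins.fasta"))
    p_cds <- file.path(dir, paste0(sp, "_cds.fasta"))
    p_gff <- file.path(dir, paste0(sp, "_annotation.gff3"))
    Biostrings::writeXStringSet(Biostrings::AAStringSet(s$protein), p_prot)
    Biostrings::writeXStringSet(Biostrings::DNAStringSet(s$cds), p_cds)
    write_annotation(s$annotation, p_gff)
    paths <- c(paths, stats::setNames(
      c(p_prot, p_cds, p_gff),
      paste0(sp, c("_proteins", "_cds", "_annotation"))
    ))
  }
  truth_tabs <- sim$truth
  for (nm in names(truth_tabs)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    readr::write_tsv(truth_tabs[[nm]], p)
    paths <- c(paths, stats::setNames(p, nm))
  }
  p_cfg <- file.path(dir, "config.yaml")
  yaml::write_yaml(unclass(sim$config), p_cfg)
  paths <- c(paths, config = p_cfg)
  invisible(paths)
}

#' Write a gene annotation as GFF3
#'
#' One `gene` feature per row with the gene id in the `ID` attribute.
#'
#' @param ann Annotation tibble: chrom, gene_id, start, end, strand.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_annotation <- function(ann, path) {
  stopifnot(all(c("chrom", "gene_id", "start", "end", "strand") %in% names(ann)))
  lines <- c(
    "##gff-version 3",
    sprintf("%s\tsim\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
            ann$chrom, as.integer(ann$start), as.integer(ann$end),
            ann$strand, ann$gene_id)
  )
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene annotation from GFF3
#'
#' Reads `gene` features and extracts the `ID` attribute as `gene_id`.
#' Malformed rows (wrong column count, non-numeric coordinates, missing ID)
#' raise an error naming the offending line.
#'
#' @param path A GFF3 file.
#' @return Annotation tibble: chrom, gene_id, start, end, strand.
#' @export
read_annotation <- function(path) {
  raw <- readLines(path)
  body_idx <- which(!startsWith(raw, "#") & nzchar(raw))
  fields <- strsplit(raw[body_idx], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9L)
  if (length(bad) > 0) {
    stop(sprintf("%s: line %d has %d fields (expected 9)",
                 path, body_idx[bad[1]], lengths(fields)[bad[1]]), call. = FALSE)
  }
  m <- do.call(rbind, fields)
  keep <- m[, 3] == "gene"
  m <- m[keep, , drop = FALSE]
  lineno <- body_idx[keep]
  start <- suppressWarnings(as.integer(m[, 4]))
  end <- suppressWarnings(as.integer(m[, 5]))
  if (anyNA(start) || anyNA(end)) {
    i <- which(is.na(start) | is.na(end))[1]
    stop(sprintf("%s: line %d has non-numeric coordinates", path, lineno[i]),
         call. = FALSE)
  }
  id <- stringr::str_match(m[, 9], "(?:^|;)ID=([^;]+)")[, 2]
  if (anyNA(id)) {
    stop(sprintf("%s: line %d has no ID attribute", path, lineno[which(is.na(id))[1]]),
         call. = FALSE)
  }
  tibble::tibble(
    chrom = m[, 1], gene_id = id, start = start, end = end, strand = m[, 7]
  )
}

#' Read a FASTA file as a named character vector
#'
#' @param path FASTA file of protein or nucleotide sequences.
#' @return Named character vector (names are the first whitespace-delimited
#'   token of each header).
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readBStringSet(path)
  out <- as.character(x)
  names(out) <- stringr::word(names(x), 1)
  out
}

#' Write a result table as TSV
#'
#' Thin wrapper around [readr::write_tsv()] that drops list-columns (such as
#' per-block anchor tables) with a message, so any result tibble in the
#' package can be serialized.
#'
#' @param x A tibble.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_table <- function(x, path) {
  is_list <- vapply(x, is.list, logical(1))
  if (any(is_list)) {
    message(sprintf("dropping list column(s): %s",
                    paste(names(x)[is_list], collapse = ", ")))
    x <- x[, !is_list, drop = FALSE]
  }
  readr::write_tsv(tibble::as_tibble(x), path)
  invisible(path)
}
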