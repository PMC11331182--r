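#' @importFrom rlang .data
NULL

.HIT_COLS <- c("query", "subject", "pident", "length", "mismatch", "gapopen",
               "qstart", "qend", "sstart", "send", "evalue", "bitscore")

# gapped-BLOSUM62 Karlin-Altschul constants (gap open 11, extend 1),
# fixed for reproducibility of the E < 1e-5 cut
.KA_LAMBDA <- 0.267
.KA_K <- 0.041

blosum62 <- function() {
  if (is.null(.paleo_cache$blosum62)) {
    e <- new.env()
    utils::data("BLOSUM62", package = "Biostrings", envir = e)
    .paleo_cache$blosum62 <- e$BLOSUM62
  }
  .paleo_cache$blosum62
}

new_hit_table <- function(hits, m, n) {
  hits <- tibble::as_tibble(hits)
  attr(hits, "search_space") <- c(m = m, n = n)
  hits
}

#' @keywords internal
search_space <- function(hits) attr(hits, "search_space")

clean_proteins <- function(x, label) {
  if (length(x) == 0) stop(sprintf("empty protein set '%s'", label), call. = FALSE)
  if (is.null(names(x)) || anyDuplicated(names(x))) {
    stop(sprintf("protein set '%s' needs unique names", label), call. = FALSE)
  }
  x <- toupper(x)
  std <- "ACDEFGHIKLMNPQRSTVWYX"
  bad_frac <- vapply(x, function(s) {
    ch <- strsplit(s, "")[[1]]
    mean(!ch %in% strsplit(std, "")[[1]])
  }, numeric(1))
  if (any(bad_frac > 0)) {
    if (any(bad_frac > 0.2)) {
      warning(sprintf("%d sequence(s) in '%s' have > 20%% non-standard residues; masked to X",
                      sum(bad_frac > 0.2), label))
    }
    x <- vapply(x, function(s) gsub(sprintf("[^%s]", std), "X", s), character(1))
  }
  if (any(nchar(x) == 0)) stop("empty sequence in protein set", call. = FALSE)
  x
}

seq_kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  unique(substring(s, 1:(n - k + 1), k:n))
}

#' All-vs-all protein similarity search (internal Smith-Waterman)
#'
#' Local alignment (BLOSUM62, affine gaps 11/1) for every sequence pair that
#' survives a shared k-mer prescreen, with BLAST-style bit scores
#' S' = (lambda*S - ln K)/ln 2 and E = m*n*2^(-S') under fixed
#' gapped-BLOSUM62 constants (lambda = 0.267, K = 0.041). Self-hits are
#' removed in intra mode (`b = NULL`). Intended for desk-scale sets; use
#' [blast_hits()] for genome-scale searches.
#'
#' @param a,b Named character vectors of amino-acid sequences; `b = NULL`
#'   searches `a` against itself (paralog mode).
#' @param k K-mer length of the prescreen.
#' @param min_shared_kmers Minimum shared k-mers to trigger an alignment.
#' @param max_evalue Hits above this E-value are not reported.
#' @return A tibble in 12-column tabular layout (query, subject, pident,
#'   length, mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore)
#'   with the search-space sizes attached as attribute `search_space`.
#' @export
all_vs_all <- function(a, b = NULL, k = 3, min_shared_kmers = 1, max_evalue = 10) {
  intra <- is.null(b)
  a <- clean_proteins(a, "a")
  b2 <- if (intra) a else clean_proteins(b, "b")
  m <- sum(nchar(a)); n <- sum(nchar(b2))

  kma <- lapply(a, seq_kmers, k = k)
  kmb <- if (intra) kma else lapply(b2, seq_kmers, k = k)
  bset <- Biostrings::AAStringSet(b2)
  mat <- blosum62()

  rows <- vector("list", length(a))
  for (qi in seq_along(a)) {
    shared <- vapply(kmb, function(kw) sum(kw %in% kma[[qi]]), numeric(1))
    cand <- which(shared >= min_shared_kmers)
    if (intra) cand <- setdiff(cand, qi)
    if (length(cand) == 0) next
    aln <- Biostrings::pairwiseAlignment(
      pattern = bset[cand], subject = Biostrings::AAString(a[[qi]]),
      type = "local", substitutionMatrix = mat,
      gapOpening = 11, gapExtension = 1
    )
    s_al <- as.character(Biostrings::alignedPattern(aln))
    q_al <- as.character(Biostrings::alignedSubject(aln))
    stats_al <- purrr::map2(q_al, s_al, function(qs, ss) {
      qc <- strsplit(qs, "")[[1]]; sc <- strsplit(ss, "")[[1]]
      len <- length(qc)
      idn <- sum(qc == sc & qc != "-")
      gaps <- sum(rle(qc == "-")$values) + sum(rle(sc == "-")$values)
      mism <- sum(qc != sc & qc != "-" & sc != "-")
      c(len = len, idn = idn, gapopen = gaps, mismatch = mism)
    })
    sc <- Biostrings::score(aln)
    bit <- (.KA_LAMBDA * sc - log(.KA_K)) / log(2)
    ev <- m * n * 2^(-bit)
    st <- do.call(rbind, stats_al)
    rows[[qi]] <- tibble::tibble(
      query = names(a)[qi],
      subject = names(b2)[cand],
      pident = unname(round(100 * st[, "idn"] / st[, "len"], 2)),
      length = unname(st[, "len"]),
      mismatch = unname(st[, "mismatch"]),
      gapopen = unname(st[, "gapopen"]),
      qstart = Biostrings::start(Biostrings::subject(aln)),
      qend = Biostrings::end(Biostrings::subject(aln)),
      sstart = Biostrings::start(Biostrings::pattern(aln)),
      send = Biostrings::end(Biostrings::pattern(aln)),
      evalue = ev,
      bitscore = round(bit, 1)
    )
  }
  hits <- dplyr::bind_rows(rows)
  if (nrow(hits) > 0) hits <- dplyr::filter(hits, .data$evalue <= max_evalue)
  if (nrow(hits) == 0) {
    hits <- tibble::as_tibble(stats::setNames(
      as.data.frame(matrix(nrow = 0, ncol = 12)), .HIT_COLS))
    hits$query <- character(0); hits$subject <- character(0)
  }
  new_hit_table(hits, m, n)
}

#' All-vs-all protein search through the BLAST+ command line
#'
#' Writes the sets to FASTA, runs `makeblastdb` + `blastp -outfmt 6`
#' single-threaded, and parses the 12-column output with [read_hits()].
#' Self-hits are removed in intra mode.
#'
#' @inheritParams all_vs_all
#' @param evalue_max E-value cutoff passed to blastp (filter later with
#'   [filter_hits()] for the strict `< 1e-5` rule).
#' @param max_target_seqs Per-query hit cap passed to blastp.
#' @return A hit tibble as in [all_vs_all()].
#' @export
blast_hits <- function(a, b = NULL, evalue_max = 1, max_target_seqs = 50) {
  if (Sys.which("blastp") == "" || Sys.which("makeblastdb") == "") {
    stop("blastp/makeblastdb not found on PATH", call. = FALSE)
  }
  intra <- is.null(b)
  a <- clean_proteins(a, "a")
  b2 <- if (intra) a else clean_proteins(b, "b")
  td <- tempfile("blast")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  qf <- file.path(td, "query.faa"); df <- file.path(td, "db.faa")
  Biostrings::writeXStringSet(Biostrings::AAStringSet(a), qf)
  Biostrings::writeXStringSet(Biostrings::AAStringSet(b2), df)
  out <- file.path(td, "hits.tsv")
  system2("makeblastdb", c("-in", df, "-dbtype", "prot"),
          stdout = file.path(td, "mkdb.log"), stderr = file.path(td, "mkdb.log"))
  status <- system2("blastp", c(
    "-query", qf, "-db", df, "-outfmt", "6", "-out", out,
    "-evalue", format(evalue_max), "-num_threads", "1",
    "-max_target_seqs", format(max_target_seqs)
  ), stdout = file.path(td, "blast.log"), stderr = file.path(td, "blast.log"))
  if (status != 0) stop("blastp failed", call. = FALSE)
  hits <- read_hits(out, m = sum(nchar(a)), n = sum(nchar(b2)))
  if (intra && nrow(hits) > 0) {
    hits <- dplyr::filter(hits, .data$query != .data$subject)
  }
  new_hit_table(hits, sum(nchar(a)), sum(nchar(b2)))
}

#' Read a 12-column tabular hit file
#'
#' Parses the standard tab-separated dialect (query, subject, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore), keeping
#' input order. Lines with the wrong field count or non-numeric E-values are
#' rejected with their line number.
#'
#' @param path File path (an empty file yields an empty table).
#' @param m,n Search-space sizes in residues (recorded as an attribute).
#' @export
read_hits <- function(path, m = NA_real_, n = NA_real_) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    empty <- tibble::tibble(
      query = character(0), subject = character(0), pident = numeric(0),
      length = numeric(0), mismatch = numeric(0), gapopen = numeric(0),
      qstart = numeric(0), qend = numeric(0), sstart = numeric(0),
      send = numeric(0), evalue = numeric(0), bitscore = numeric(0)
    )
    return(new_hit_table(empty, m, n))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L)) {
    stop(sprintf("line %d: expected 12 tab-separated fields, found %d",
                 which(nf != 12L)[1], nf[nf != 12L][1]), call. = FALSE)
  }
  mx <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  num <- suppressWarnings(apply(mx[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10L)
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0)[1]
    stop(sprintf("line %d: non-numeric value in a numeric field", bad), call. = FALSE)
  }
  if (any(num[, 9] < 0)) stop("negative E-value", call. = FALSE)
  hits <- tibble::tibble(
    query = mx[, 1], subject = mx[, 2],
    pident = num[, 1], length = num[, 2], mismatch = num[, 3],
    gapopen = num[, 4], qstart = num[, 5], qend = num[, 6],
    sstart = num[, 7], send = num[, 8], evalue = num[, 9], bitscore = num[, 10]
  )
  new_hit_table(hits, m, n)
}

#' Write hits in the 12-column tabular dialect
#' @param hits Hit tibble.
#' @param path Output path.
#' @export
write_hits <- function(hits, path) {
  readr::write_tsv(hits[, .HIT_COLS], path, col_names = FALSE)
  invisible(path)
}

#' Filter hits by E-value and per-query rank
#'
#' Applies the strict `E < max_evalue` rule (a hit at exactly the threshold
#' is removed) and keeps at most `top_n` hits per query, ranked by bit score
#' with ties broken by higher identity then lexicographic subject id.
#' Idempotent.
#'
#' @param hits Hit tibble.
#' @param max_evalue Strict upper bound on E-value (default the conventional
#'   1e-5 paralog-detection cut).
#' @param top_n Hits kept per query (default 5).
#' @export
filter_hits <- function(hits, max_evalue = 1e-5, top_n = 5) {
  ss <- search_space(hits)
  out <- hits |>
    dplyr::filter(.data$evalue < max_evalue) |>
    dplyr::arrange(.data$query, dplyr::desc(.data$bitscore),
                   dplyr::desc(.data$pident), .data$subject) |>
    dplyr::group_by(.data$query) |>
    dplyr::slice_head(n = top_n) |>
    dplyr::ungroup()
  new_hit_table(out, ss[["m"]], ss[["n"]])
}
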