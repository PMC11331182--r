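# Genetic-code machinery shared by the genome simulator and the Ks estimator:
# single-nucleotide codon neighborhoods, NG86-style site fractions, and
# minimal-mutation-path averaged difference counts split by
# transition/transversion and synonymous/nonsynonymous.

.paleo_cache <- new.env(parent = emptyenv())

.NUCS <- c("A", "C", "G", "T")

#' @keywords internal
codon_strings <- function() {
  as.vector(outer(outer(.NUCS, .NUCS, paste0), .NUCS, paste0)) |> sort()
}

.is_transition <- function(from, to) {
  (from == "A" & to == "G") | (from == "G" & to == "A") |
    (from == "C" & to == "T") | (from == "T" & to == "C")
}

# Build the full codon table set once per session.
codon_tables <- function() {
  if (!is.null(.paleo_cache$tab)) {
    return(.paleo_cache$tab)
  }
  codons <- codon_strings()
  gc <- Biostrings::GENETIC_CODE[codons]
  aa <- unname(gc)
  is_stop <- aa == "*"
  idx <- stats::setNames(seq_along(codons), codons)

  # neighbors: for each codon, the 9 single-nucleotide variants
  neigh <- vector("list", length(codons))
  for (i in seq_along(codons)) {
    cod <- codons[i]
    chars <- strsplit(cod, "")[[1]]
    pos <- integer(0); to <- character(0); ts <- logical(0)
    for (p in 1:3) {
      for (n in setdiff(.NUCS, chars[p])) {
        v <- chars; v[p] <- n
        pos <- c(pos, p)
        to <- c(to, paste(v, collapse = ""))
        ts <- c(ts, .is_transition(chars[p], n))
      }
    }
    j <- idx[to]
    neigh[[i]] <- data.frame(
      pos = pos, to = unname(j), ts = ts,
      stop = is_stop[j],
      syn = !is_stop[i] & !is_stop[j] & aa[j] == aa[i],
      stringsAsFactors = FALSE
    )
  }

  # NG86 site fractions with mutations to stop codons excluded and each
  # position renormalized to one site
  syn_sites <- numeric(length(codons))
  for (i in seq_along(codons)) {
    if (is_stop[i]) { syn_sites[i] <- NA_real_; next }
    nb <- neigh[[i]]
    s <- 0
    for (p in 1:3) {
      at <- nb[nb$pos == p & !nb$stop, , drop = FALSE]
      if (nrow(at) > 0) s <- s + sum(at$syn) / nrow(at)
    }
    syn_sites[i] <- s
  }
  nonsyn_sites <- ifelse(is_stop, NA_real_, 3 - syn_sites)

  # neighbor summaries used by the simulator's event sampler
  syn_ts <- integer(length(codons)); syn_tv <- integer(length(codons))
  non_ts <- integer(length(codons)); non_tv <- integer(length(codons))
  for (i in seq_along(codons)) {
    nb <- neigh[[i]]
    ok <- !nb$stop & !is_stop[i]
    syn_ts[i] <- sum(ok & nb$syn & nb$ts)
    syn_tv[i] <- sum(ok & nb$syn & !nb$ts)
    non_ts[i] <- sum(ok & !nb$syn & nb$ts)
    non_tv[i] <- sum(ok & !nb$syn & !nb$ts)
  }

  .paleo_cache$tab <- list(
    codons = codons, aa = aa, is_stop = is_stop, idx = idx,
    neigh = neigh, syn_sites = syn_sites, nonsyn_sites = nonsyn_sites,
    syn_ts = syn_ts, syn_tv = syn_tv, non_ts = non_ts, non_tv = non_tv
  )
  .paleo_cache$tab
}

# Path-averaged pairwise difference counts (NG86): for every ordered codon
# pair, average over all minimal mutation paths (orderings of the differing
# positions) that avoid stop codons; if every path passes through a stop the
# unrestricted average is used. Returns four 64x64 matrices: synonymous and
# nonsynonymous differences, each split into transitions and transversions.
codon_pair_tables <- function() {
  if (!is.null(.paleo_cache$pair)) {
    return(.paleo_cache$pair)
  }
  tab <- codon_tables()
  n <- length(tab$codons)
  chars <- strsplit(tab$codons, "")
  sd_ts <- matrix(0, n, n); sd_tv <- matrix(0, n, n)
  nd_ts <- matrix(0, n, n); nd_tv <- matrix(0, n, n)

  perms <- list(
    `1` = list(1L),
    `2` = list(c(1L, 2L), c(2L, 1L)),
    `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
               c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L))
  )

  step_counts <- function(ci, cj) {
    # ci -> cj differ at exactly one position
    p <- which(chars[[ci]] != chars[[cj]])
    ts <- .is_transition(chars[[ci]][p], chars[[cj]][p])
    syn <- tab$aa[ci] == tab$aa[cj]
    c(sd_ts = syn && ts, sd_tv = syn && !ts,
      nd_ts = !syn && ts, nd_tv = !syn && !ts)
  }

  for (i in seq_len(n)) {
    if (tab$is_stop[i]) next
    for (j in seq_len(n)) {
      if (tab$is_stop[j] || i == j) next
      dpos <- which(chars[[i]] != chars[[j]])
      nd <- length(dpos)
      acc <- matrix(0, 0, 4)
      acc_all <- matrix(0, 0, 4)
      for (perm in perms[[as.character(nd)]]) {
        cur <- chars[[i]]
        counts <- c(0, 0, 0, 0)
        valid <- TRUE
        ci <- i
        for (p in perm) {
          nxt <- cur; nxt[dpos[p]] <- chars[[j]][dpos[p]]
          cj <- tab$idx[paste(nxt, collapse = "")]
          if (tab$is_stop[cj]) valid <- FALSE
          counts <- counts + step_counts(ci, cj)
          cur <- nxt; ci <- cj
        }
        acc_all <- rbind(acc_all, counts)
        if (valid) acc <- rbind(acc, counts)
      }
      use <- if (nrow(acc) > 0) acc else acc_all
      m <- colMeans(use)
      sd_ts[i, j] <- m[1]; sd_tv[i, j] <- m[2]
      nd_ts[i, j] <- m[3]; nd_tv[i, j] <- m[4]
    }
  }
  .paleo_cache$pair <- list(sd_ts = sd_ts, sd_tv = sd_tv,
                            nd_ts = nd_ts, nd_tv = nd_tv)
  .paleo_cache$pair
}

# integer codon vector <-> DNA string helpers
codons_to_dna <- function(cod_idx) {
  tab <- codon_tables()
  paste(tab$codons[cod_idx], collapse = "")
}

dna_to_codons <- function(seq) {
  tab <- codon_tables()
  if (nchar(seq) %% 3 != 0) {
    stop("coding sequence length is not a multiple of 3", call. = FALSE)
  }
  trip <- substring(seq, seq(1, nchar(seq), 3), seq(3, nchar(seq), 3))
  out <- unname(tab$idx[trip])
  if (anyNA(out)) stop("non-ACGT characters in coding sequence", call. = FALSE)
  out
}

translate_codons <- function(cod_idx) {
  tab <- codon_tables()
  paste(tab$aa[cod_idx], collapse = "")
}
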