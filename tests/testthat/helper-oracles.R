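# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately re-derive results by enumeration or naive
# dynamic programming, independent of the package's implementation paths.

# --- toy gene models -------------------------------------------------------

# Build a gene_models object from a compact description:
# list(gene_id = list(t1 = list(c(start, end), ...), t2 = ...))
toy_models <- function(genes, chrom = "chr1", strand = "+") {
  rows <- list()
  for (g in names(genes)) {
    for (t in names(genes[[g]])) {
      for (ex in genes[[g]][[t]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = g, transcript_id = paste(g, t, sep = "."),
          chrom = chrom, strand = strand,
          start = ex[1L], end = ex[2L], stringsAsFactors = FALSE)
      }
    }
  }
  gene_models(do.call(rbind, rows))
}

# Random gene: pool of non-overlapping exons, transcripts are random ordered
# subsets. Used for the extraction-oracle equivalence checks.
random_toy_gene <- function(n_exons = NULL, n_tx = NULL) {
  n_exons <- n_exons %||% sample(3:10, 1L)
  n_tx <- n_tx %||% sample(2:5, 1L)
  pool <- list(); pos <- 0L
  for (i in seq_len(n_exons)) {
    pos <- pos + sample(30:150, 1L)         # intergenic/intronic gap
    w <- sample(30:120, 1L)
    pool[[i]] <- c(pos, pos + w)
    pos <- pos + w
  }
  tx <- list()
  for (t in seq_len(n_tx)) {
    k <- sample(seq_len(n_exons), sample(1:n_exons, 1L))
    tx[[paste0("t", t)]] <- pool[sort(k)]
  }
  tx
}

# Exhaustive event enumeration: for every transcript, every internal exon,
# check every intron of every other transcript of the same gene.
brute_force_events <- function(models) {
  ex <- models$exons
  found <- character(0)
  for (g in unique(ex$gene_id)) {
    gx <- ex[ex$gene_id == g, ]
    txs <- split(gx, gx$transcript_id)
    for (ti in seq_along(txs)) {
      t <- txs[[ti]]
      t <- t[order(t$start), ]
      if (nrow(t) < 3L) next
      for (i in 2L:(nrow(t) - 1L)) {
        c1 <- t$end[i - 1L]; c2 <- t$start[i]; c3 <- t$end[i]; c4 <- t$start[i + 1L]
        for (tj in seq_along(txs)) {
          if (tj == ti) next
          o <- txs[[tj]]; o <- o[order(o$start), ]
          if (nrow(o) < 2L) next
          for (k in seq_len(nrow(o) - 1L)) {
            if (o$end[k] == c1 && o$start[k + 1L] == c4) {
              found <- c(found, paste(g, c1, c2, c3, c4, sep = "_"))
            }
          }
        }
      }
    }
  }
  sort(unique(found))
}

event_key <- function(events) {
  sort(unique(paste(events$gene_id, events$coord1, events$coord2,
                    events$coord3, events$coord4, sep = "_")))
}

# --- Smith-Waterman oracle -------------------------------------------------

# Naive affine-gap local alignment; gap of length L costs open + L * extend
# (both positive). Returns the maximal score and, via traceback, the number
# of matches and aligned columns of one optimal alignment.
sw_oracle <- function(a, b, match = 2, mismatch = -3, open = 5, extend = 2) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B)
  M <- matrix(0, n + 1L, m + 1L)   # ending in match/mismatch
  X <- matrix(-Inf, n + 1L, m + 1L) # gap in b (consume a)
  Y <- matrix(-Inf, n + 1L, m + 1L) # gap in a (consume b)
  best <- 0; best_ij <- c(1L, 1L)
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      s <- if (A[i - 1L] == B[j - 1L]) match else mismatch
      M[i, j] <- max(0, M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + s
      X[i, j] <- max(M[i - 1L, j] - open - extend, X[i - 1L, j] - extend)
      Y[i, j] <- max(M[i, j - 1L] - open - extend, Y[i, j - 1L] - extend)
      h <- max(M[i, j], X[i, j], Y[i, j])
      if (h > best) { best <- h; best_ij <- c(i, j) }
    }
  }
  list(score = best)
}

# --- exact rank-sum and hypergeometric enumeration -------------------------

# Two-sided exact Wilcoxon rank-sum p by enumeration of all C(n+m, n)
# assignments of ranks to group x (no ties assumed).
wilcox_enum <- function(x, y) {
  n <- length(x); m <- length(y)
  ranks <- rank(c(x, y))
  w_obs <- sum(ranks[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  all_ranks <- rank(c(x, y))
  ws <- apply(combs, 2L, function(idx) sum(all_ranks[idx]) - n * (n + 1) / 2)
  mu <- n * m / 2
  mean(abs(ws - mu) >= abs(w_obs - mu) - 1e-9)
}

# Upper-tail hypergeometric by full enumeration of draws from a small
# universe: P[X >= k] when drawing `size` from N items of which K are hits.
hyper_enum <- function(k, K, N, size) {
  total <- choose(N, size)
  sum(vapply(k:min(K, size), function(x) {
    choose(K, x) * choose(N - K, size - x)
  }, numeric(1))) / total
}

# --- misc ------------------------------------------------------------------

toy_genome <- function(...) {
  seqs <- c(...)
  Biostrings::DNAStringSet(seqs)
}

write_sam <- function(path, reads, chrom = "chr1", chrom_len = 10000L) {
  header <- c("@HD\tVN:1.6\tSO:coordinate",
              sprintf("@SQ\tSN:%s\tLN:%d", chrom, chrom_len))
  body <- vapply(reads, function(r) {
    sprintf("r%d\t%d\t%s\t%d\t60\t%s\t*\t0\t0\t%s\t*",
            sample.int(1e6, 1L), r$flag %||% 0L, chrom, r$pos, r$cigar,
            strrep("A", 10L))
  }, character(1))
  writeLines(c(header, body), path)
  path
}
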