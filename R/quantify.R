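# Junction-read quantification: anchor-filtered junction extraction from SAM,
# RPK30M normalisation, percent-spliced-in (psi) and delta-psi computation,
# expression filtering and per-event response classification.

#' Extract anchor-filtered junction counts from a SAM file
#'
#' Each `N` operation in a read's CIGAR contributes one count to its splice
#' junction iff the aligned block on each side of that `N` spans at least
#' `min_anchor` nucleotides into the flanking exons. Reads with malformed
#' CIGAR strings are skipped with a warning. The per-sample library size is
#' the number of retained mapped reads.
#'
#' @param path SAM file (text).
#' @param sample sample name recorded in the output.
#' @param min_anchor minimum anchor length in nt (default 8).
#' @return data.frame with columns chrom, intron_start, intron_end, strand,
#'   sample, count (intron coordinates 0-based half-open) and attribute
#'   `library_size`.
#' @export
junctions_from_sam <- function(path, sample = "sample1", min_anchor = 8L) {
  if (!file.exists(path)) stop("SAM file not found: ", path)
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "@")]
  counts <- new.env(parent = emptyenv())
  n_reads <- 0L
  for (ln in lines) {
    if (!nzchar(ln)) next
    f <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 6L) { warning("skipping malformed SAM record"); next }
    flag <- suppressWarnings(as.integer(f[2L]))
    if (is.na(flag) || bitwAnd(flag, 4L) != 0L) next  # unmapped
    cigar <- f[6L]
    ops <- tryCatch(list(
      op = GenomicAlignments::explodeCigarOps(cigar)[[1L]],
      len = GenomicAlignments::explodeCigarOpLengths(cigar)[[1L]]
    ), error = function(e) NULL)
    if (is.null(ops) || cigar == "*") {
      warning("skipping record with malformed CIGAR: ", cigar)
      next
    }
    n_reads <- n_reads + 1L
    pos0 <- suppressWarnings(as.integer(f[4L])) - 1L  # 0-based ref offset
    chrom <- f[3L]
    strand <- if (bitwAnd(flag, 16L) != 0L) "-" else "+"
    # walk reference-consuming ops; aligned block = contiguous M/=/X/D run
    ref_off <- 0L
    block_len <- 0L
    pending <- NULL  # junction waiting for its right anchor
    flush <- function(pending, right_len) {
      if (!is.null(pending) && pending$left >= min_anchor &&
          right_len >= min_anchor) {
        key <- paste(chrom, pending$start, pending$end, strand, sep = "\r")
        counts[[key]] <- get0(key, envir = counts, ifnotfound = 0L) + 1L
      }
    }
    for (k in seq_along(ops$op)) {
      op <- ops$op[k]; len <- ops$len[k]
      if (op %in% c("M", "=", "X", "D")) {
        block_len <- block_len + len
        ref_off <- ref_off + len
      } else if (op == "N") {
        flush(pending, block_len)
        pending <- list(left = block_len,
                        start = pos0 + ref_off,
                        end = pos0 + ref_off + len)
        block_len <- 0L
        ref_off <- ref_off + len
      }
      # I, S, H, P consume no reference and break no block
    }
    flush(pending, block_len)
  }
  keys <- ls(counts)
  if (length(keys)) {
    parts <- do.call(rbind, strsplit(keys, "\r", fixed = TRUE))
    df <- data.frame(chrom = parts[, 1L],
                     intron_start = as.integer(parts[, 2L]),
                     intron_end = as.integer(parts[, 3L]),
                     strand = parts[, 4L],
                     sample = sample,
                     count = vapply(keys, function(k) counts[[k]], integer(1)),
                     stringsAsFactors = FALSE)
    df <- df[order(df$chrom, df$intron_start, df$intron_end), , drop = FALSE]
    rownames(df) <- NULL
  } else {
    df <- data.frame(chrom = character(), intron_start = integer(),
                     intron_end = integer(), strand = character(),
                     sample = character(), count = integer())
  }
  attr(df, "library_size") <- n_reads
  df
}

#' Read a junction-count table
#'
#' @param path TSV with columns chrom, intron_start, intron_end, strand,
#'   sample, count; intron coordinates 0-based half-open.
#' @return data.frame.
#' @export
read_junction_counts <- function(path) {
  df <- read_tsv_file(path, required = c("chrom", "intron_start",
                                         "intron_end", "strand", "sample",
                                         "count"))
  if (any(df$count < 0)) stop("negative junction counts")
  if (any(df$intron_start >= df$intron_end)) stop("intron_start must be < intron_end")
  df
}

#' Reads per kilobase per 30 million mapped reads
#'
#' `count / ((feature_length/1000) * (library_size/3e7))`.
#'
#' @param count read count (vectorised).
#' @param feature_length feature length in nt (> 0).
#' @param library_size total mapped reads in the sample (> 0).
#' @return numeric expression value(s).
#' @export
rpk30m <- function(count, feature_length, library_size) {
  if (any(feature_length <= 0)) stop("feature_length must be positive")
  if (any(library_size <= 0)) stop("library_size must be positive")
  count / ((feature_length / 1000) * (library_size / 3e7))
}

#' Percent spliced in from the three junction counts of a cassette event
#'
#' psi = (j_up + j_down) / (j_up + j_down + 2 * j_skip). The inclusion
#' isoform contributes two junctions and the skipping isoform one, hence the
#' factor 2 on the skip count. Undefined (NA) when all three counts are 0;
#' an undefined psi is never coerced to 0.
#'
#' @param j_up,j_down,j_skip non-negative junction read counts (vectorised).
#' @return numeric psi in \[0, 1\] or NA.
#' @export
compute_psi <- function(j_up, j_down, j_skip) {
  if (any(c(j_up, j_down, j_skip) < 0)) stop("junction counts must be non-negative")
  inc <- j_up + j_down
  den <- inc + 2 * j_skip
  ifelse(den == 0, NA_real_, inc / den)
}

#' Expression filter for an exon-skipping event
#'
#' An event fails iff the gene expression is below `gene_min` RPK30M in all
#' replicates, or the total RPK30M of its three junctions is below
#' `junction_min` in any single replicate of either condition (the strictest
#' reading of the filter; both cutoffs configurable).
#'
#' @param gene_expr numeric gene RPK30M per sample (all samples).
#' @param junction_expr numeric per-sample total RPK30M of the event's three
#'   junctions.
#' @param gene_min,junction_min cutoffs (defaults 16 and 4).
#' @return logical: TRUE if the event passes.
#' @export
passes_expression_filter <- function(gene_expr, junction_expr,
                                     gene_min = 16, junction_min = 4) {
  if (length(gene_expr) == 0L || length(junction_expr) == 0L) {
    stop("expression values missing")
  }
  if (anyNA(gene_expr) || anyNA(junction_expr)) stop("expression values missing")
  if (all(gene_expr < gene_min)) return(FALSE)
  if (any(junction_expr < junction_min)) return(FALSE)
  TRUE
}

#' Classify the response of one event from replicate delta-psi values
#'
#' Classes, evaluated in order:
#' `others:no_expression` (any replicate delta-psi undefined),
#' `others:psi_too_low` (all sample psi < `psi_low`),
#' `others:inconsistent` (one replicate >= +0.05 while the other <= 0, or
#' one <= -0.05 while the other >= 0),
#' `skip` (<= -0.05 in either replicate and < 0 in the other),
#' `inclusion` (>= +0.05 in either replicate and > 0 in the other),
#' `no_change` otherwise (both within (-0.05, 0.05)).
#'
#' @param delta_psi numeric length 2, per-replicate delta-psi (may be NA).
#' @param psi numeric per-sample psi values (may be NA).
#' @param cutoff class cutoff on |delta-psi| (default 0.05).
#' @param psi_low low-inclusion cutoff (default 0.05).
#' @return character scalar response class.
#' @export
classify_response <- function(delta_psi, psi, cutoff = 0.05, psi_low = 0.05) {
  if (length(delta_psi) != 2L) stop("exactly two replicate delta-psi values required")
  if (anyNA(delta_psi)) return("others:no_expression")
  if (!anyNA(psi) && all(psi < psi_low)) return("others:psi_too_low")
  d1 <- delta_psi[1L]; d2 <- delta_psi[2L]
  inconsistent <- (d1 >= cutoff && d2 <= 0) || (d2 >= cutoff && d1 <= 0) ||
    (d1 <= -cutoff && d2 >= 0) || (d2 <= -cutoff && d1 >= 0)
  if (inconsistent) return("others:inconsistent")
  if ((d1 <= -cutoff && d2 < 0) || (d2 <= -cutoff && d1 < 0)) return("skip")
  if ((d1 >= cutoff && d2 > 0) || (d2 >= cutoff && d1 > 0)) return("inclusion")
  "no_change"
}

#' Strict skip-enhancement call
#'
#' TRUE iff mean(psi_treat) - mean(psi_ctrl) <= `dpsi_threshold` and a
#' two-sided pooled-variance two-sample t test on the replicate psi values
#' gives p < `alpha`. With zero variance in both groups the t statistic is
#' degenerate; p is taken as 0 when the means differ and 1 otherwise.
#'
#' @param psi_ctrl,psi_treat numeric replicate psi values (>= 2 each).
#' @param dpsi_threshold delta-psi threshold (default -0.25).
#' @param alpha significance cutoff (default 0.05).
#' @return logical.
#' @export
strict_skip_call <- function(psi_ctrl, psi_treat, dpsi_threshold = -0.25,
                             alpha = 0.05) {
  if (length(psi_ctrl) < 2L || length(psi_treat) < 2L) {
    stop("at least two replicates per condition required")
  }
  if (anyNA(psi_ctrl) || anyNA(psi_treat)) return(FALSE)
  dpsi <- mean(psi_treat) - mean(psi_ctrl)
  if (dpsi > dpsi_threshold) return(FALSE)
  if (stats::sd(psi_ctrl) == 0 && stats::sd(psi_treat) == 0) {
    p <- if (mean(psi_ctrl) == mean(psi_treat)) 1 else 0
  } else {
    p <- stats::t.test(psi_treat, psi_ctrl, var.equal = TRUE)$p.value
  }
  p < alpha
}

# Look up one junction count (0 when absent from the table)
junction_count <- function(junctions, chrom, s, e, sample) {
  i <- which(junctions$chrom == chrom & junctions$intron_start == s &
             junctions$intron_end == e & junctions$sample == sample)
  if (length(i) == 0L) 0L else sum(junctions$count[i])
}

#' Per-event psi/delta-psi table over a two-condition, two-replicate design
#'
#' For each event and sample, the upstream-inclusion (coord1-coord2),
#' downstream-inclusion (coord3-coord4) and skip (coord1-coord4) junction
#' counts are looked up (absent junctions count 0) and psi computed. Per
#' replicate, delta-psi = psi_treatment - psi_control; the replicate-mean
#' delta-psi and the response class are added.
#'
#' @param events `skipping_events` data.frame.
#' @param junctions junction-count data.frame (all samples).
#' @param design design data.frame: sample, condition, replicate. Exactly
#'   two conditions, two replicates each.
#' @param control,treatment condition labels; defaults are the design's
#'   first and second condition in sorted order.
#' @param cutoff,psi_low classification cutoffs, see [classify_response()].
#' @return data.frame of class `psi_records`: event_id, psi per sample
#'   (columns `psi_<sample>`), dpsi_rep1, dpsi_rep2, delta_psi_avg,
#'   response_class.
#' @export
psi_table <- function(events, junctions, design, control = NULL,
                      treatment = NULL, cutoff = 0.05, psi_low = 0.05) {
  conds <- sort(unique(design$condition))
  if (length(conds) != 2L) stop("design must have exactly two conditions")
  control <- control %||% conds[1L]
  treatment <- treatment %||% conds[2L]
  reps <- sort(unique(design$replicate))
  if (length(reps) != 2L) stop("design must have exactly two replicates")
  sample_of <- function(cond, rep) {
    s <- design$sample[design$condition == cond & design$replicate == rep]
    if (length(s) != 1L) stop("design must have one sample per condition/replicate")
    s
  }
  samples <- c(ctrl1 = sample_of(control, reps[1L]),
               ctrl2 = sample_of(control, reps[2L]),
               treat1 = sample_of(treatment, reps[1L]),
               treat2 = sample_of(treatment, reps[2L]))
  n <- nrow(events)
  psi_mat <- matrix(NA_real_, n, 4L,
                    dimnames = list(NULL, paste0("psi_", samples)))
  # index junction table once for speed
  key <- paste(junctions$chrom, junctions$intron_start, junctions$intron_end,
               junctions$sample, sep = "\r")
  cnt <- tapply(junctions$count, key, sum)
  lookup <- function(chrom, s, e, sample) {
    v <- cnt[paste(chrom, s, e, sample, sep = "\r")]
    if (is.na(v)) 0 else as.numeric(v)
  }
  for (i in seq_len(n)) {
    for (j in seq_along(samples)) {
      sm <- samples[j]
      ju <- lookup(events$chrom[i], events$coord1[i], events$coord2[i], sm)
      jd <- lookup(events$chrom[i], events$coord3[i], events$coord4[i], sm)
      js <- lookup(events$chrom[i], events$coord1[i], events$coord4[i], sm)
      psi_mat[i, j] <- compute_psi(ju, jd, js)
    }
  }
  dpsi1 <- psi_mat[, 3L] - psi_mat[, 1L]
  dpsi2 <- psi_mat[, 4L] - psi_mat[, 2L]
  cls <- character(n)
  for (i in seq_len(n)) {
    cls[i] <- classify_response(c(dpsi1[i], dpsi2[i]), psi_mat[i, ],
                                cutoff = cutoff, psi_low = psi_low)
  }
  res <- data.frame(event_id = events$event_id, psi_mat,
                    dpsi_rep1 = dpsi1, dpsi_rep2 = dpsi2,
                    delta_psi_avg = (dpsi1 + dpsi2) / 2,
                    response_class = cls, stringsAsFactors = FALSE)
  attr(res, "samples") <- samples
  class(res) <- c("psi_records", "data.frame")
  res
}

#' Delta-psi distribution summary with baseline fluctuation
#'
#' Returns, per event, the replicate-mean delta-psi and the between-replicate
#' baseline statistic (psi_ctrl.rep1 - psi_ctrl.rep2 + psi_treat.rep1 -
#' psi_treat.rep2) / 2, plus the counts of skip-enhanced (delta-psi_avg <=
#' -cutoff) and inclusion-enhanced (>= +cutoff) events.
#'
#' @param psi_records output of [psi_table()].
#' @param cutoff skip/inclusion cutoff (default 0.05).
#' @return list with elements `per_event` (data.frame event_id,
#'   delta_psi_avg, baseline), `n_skip_enhanced`, `n_inclusion_enhanced`.
#' @export
delta_psi_distribution <- function(psi_records, cutoff = 0.05) {
  pm <- as.matrix(psi_records[, grep("^psi_", names(psi_records)), drop = FALSE])
  baseline <- (pm[, 1L] - pm[, 2L] + pm[, 3L] - pm[, 4L]) / 2
  d <- psi_records$delta_psi_avg
  list(per_event = data.frame(event_id = psi_records$event_id,
                              delta_psi_avg = d, baseline = baseline,
                              stringsAsFactors = FALSE),
       n_skip_enhanced = sum(d <= -cutoff, na.rm = TRUE),
       n_inclusion_enhanced = sum(d >= cutoff, na.rm = TRUE))
}
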