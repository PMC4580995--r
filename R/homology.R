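# Cross-species homologous exon pairing: Smith-Waterman local alignment with
# blastn-like scoring, identity/coverage selection, deterministic
# tie-breaking, and flanking-exon resolution by junction read support.

#' Local alignment of two nucleotide sequences
#'
#' Maximal-scoring Smith-Waterman local alignment under blastn-like scoring
#' (match +2, mismatch -3, gap open -5, gap extend -2 by default). Percent
#' identity is computed over aligned columns with gap columns counted as
#' mismatches (the BLAST convention); coverage is the aligned span on each
#' sequence divided by its full length. Alignments scoring below `min_score`
#' are reported as no hit (NULL).
#'
#' @param seq_a,seq_b non-empty ACGT strings.
#' @param match,mismatch match/mismatch scores.
#' @param gap_open,gap_extend gap penalties (negative).
#' @param min_score minimum alignment score for a hit (default 20).
#' @return NULL, or a list: score, aligned_length (columns incl. gaps),
#'   matches, percent_identity, coverage_a, coverage_b.
#' @export
local_align <- function(seq_a, seq_b, match = 2, mismatch = -3,
                        gap_open = -5, gap_extend = -2, min_score = 20) {
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("empty sequence")
  sub <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                  mismatch = mismatch,
                                                  baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(seq_a), Biostrings::DNAString(seq_b),
    type = "local", substitutionMatrix = sub,
    gapOpening = abs(gap_open), gapExtension = abs(gap_extend))
  score <- Biostrings::score(aln)
  if (score < min_score) return(NULL)
  ap <- as.character(Biostrings::alignedPattern(aln))
  aligned_length <- nchar(ap)
  matches <- Biostrings::nmatch(aln)
  list(score = score,
       aligned_length = aligned_length,
       matches = matches,
       percent_identity = 100 * matches / aligned_length,
       coverage_a = Biostrings::width(Biostrings::pattern(aln)) / nchar(seq_a),
       coverage_b = Biostrings::width(Biostrings::subject(aln)) / nchar(seq_b))
}

#' Select the best homologous exon for a cassette exon
#'
#' Aligns the query exon against each candidate exon sequence; candidates
#' must pass percent identity > `min_identity` (strict) and coverage > 0.9
#' on both sides, then the winner maximises (percent identity, coverage sum)
#' lexicographically, with residual ties broken by lowest candidate genomic
#' start coordinate.
#'
#' @param exon_seq_a query exon sequence (transcript orientation).
#' @param candidates data.frame with columns exon_id, seq, start (genomic
#'   start used only for tie-breaking).
#' @param min_identity identity threshold in percent (default 70, strict >).
#' @param min_coverage coverage threshold (default 0.9, strict >).
#' @param ... passed to [local_align()].
#' @return NULL if no candidate passes, else a one-row data.frame: exon_id,
#'   percent_identity, coverage_a, coverage_b.
#' @export
select_homolog <- function(exon_seq_a, candidates, min_identity = 70,
                           min_coverage = 0.9, ...) {
  if (is.null(candidates) || nrow(candidates) == 0L) return(NULL)
  hits <- lapply(seq_len(nrow(candidates)), function(i) {
    al <- local_align(exon_seq_a, candidates$seq[i], ...)
    if (is.null(al)) return(NULL)
    if (al$percent_identity <= min_identity) return(NULL)
    if (al$coverage_a <= min_coverage || al$coverage_b <= min_coverage) return(NULL)
    data.frame(exon_id = candidates$exon_id[i],
               percent_identity = al$percent_identity,
               coverage_a = al$coverage_a, coverage_b = al$coverage_b,
               start = candidates$start[i], stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, hits[!vapply(hits, is.null, logical(1))])
  if (is.null(hits) || nrow(hits) == 0L) return(NULL)
  o <- order(-hits$percent_identity, -(hits$coverage_a + hits$coverage_b),
             hits$start)
  hits[o[1L], c("exon_id", "percent_identity", "coverage_a", "coverage_b"),
       drop = FALSE]
}

#' Internal exons of a gene with all annotated flanking-exon pairs
#'
#' @param models `gene_models` object.
#' @param gene_id gene to inspect.
#' @return data.frame: exon_id, chrom, strand, start, end, up_end (coord1),
#'   down_start (coord4), one row per distinct (exon, flanking pair).
#' @export
internal_exons <- function(models, gene_id) {
  gx <- models$exons[models$exons$gene_id == gene_id, , drop = FALSE]
  if (nrow(gx) == 0L) return(NULL)
  out <- list()
  for (tx in split(gx, gx$transcript_id)) {
    if (nrow(tx) < 3L) next
    for (i in 2L:(nrow(tx) - 1L)) {
      out[[length(out) + 1L]] <- data.frame(
        exon_id = sprintf("%s:%d-%d", gene_id, tx$start[i], tx$end[i]),
        chrom = tx$chrom[1L], strand = tx$strand[1L],
        start = tx$start[i], end = tx$end[i],
        up_end = tx$end[i - 1L], down_start = tx$start[i + 1L],
        stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) return(NULL)
  df <- unique(do.call(rbind, out))
  rownames(df) <- NULL
  df
}

#' Resolve the flanking exons of a homologous exon by junction support
#'
#' When the annotation offers several (upstream, downstream) flanking-exon
#' pairs for an internal exon, the pair whose three event junctions have the
#' highest total read count summed over all samples is chosen. Ties are
#' broken deterministically on genomic coordinates (lowest upstream end,
#' then lowest downstream start).
#'
#' @param exon one row (or list) with chrom, start, end.
#' @param flanking data.frame of candidate pairs with columns up_end,
#'   down_start (as produced by [internal_exons()] for this exon).
#' @param junctions junction-count data.frame (all samples).
#' @return one-row data.frame: up_end, down_start, junction_total.
#' @export
resolve_flanking <- function(exon, flanking, junctions) {
  if (is.null(flanking) || nrow(flanking) == 0L) {
    stop("exon is not internal in any transcript")
  }
  key <- paste(junctions$chrom, junctions$intron_start, junctions$intron_end,
               sep = "\r")
  cnt <- tapply(junctions$count, key, sum)
  total <- function(s, e) {
    v <- cnt[paste(exon$chrom, s, e, sep = "\r")]
    if (is.na(v)) 0 else as.numeric(v)
  }
  flanking <- unique(flanking[, c("up_end", "down_start"), drop = FALSE])
  flanking$junction_total <- vapply(seq_len(nrow(flanking)), function(i) {
    total(flanking$up_end[i], exon$start) +
      total(exon$end, flanking$down_start[i]) +
      total(flanking$up_end[i], flanking$down_start[i])
  }, numeric(1))
  o <- order(-flanking$junction_total, flanking$up_end, flanking$down_start)
  row <- flanking[o[1L], , drop = FALSE]
  rownames(row) <- NULL
  row
}

# Transcript-orientation sequence of an exon
exon_sequence <- function(genome, chrom, start, end, strand) {
  s <- genome_slice(genome, chrom, start, end)
  if (strand == "-") revcomp(s) else s
}

#' Pair species-A cassette events with their best species-B homologous exons
#'
#' For each species-A event, candidate exons are the internal exons of the
#' B genes linked to the A gene in the homology table. The best candidate is
#' chosen by [select_homolog()]; its flanking exons are resolved by
#' [resolve_flanking()], which defines the B-side event. Genes absent from
#' the homology table yield no pair (reason logged with `message()`).
#'
#' @param events_a species-A `skipping_events`.
#' @param genome_a,genome_b genomes as [Biostrings::DNAStringSet].
#' @param models_b species-B `gene_models`.
#' @param homology homology data.frame (gene_id_A, gene_id_B).
#' @param junctions_b species-B junction counts (for flanking resolution).
#' @param min_identity,min_coverage selection thresholds.
#' @return data.frame of class `homolog_pairs`: event_id_A, gene_id_B,
#'   exon_id_B, percent_identity, coverage_a, coverage_b, B event
#'   coordinates (chrom_B, strand_B, coord1_B..coord4_B) and event_id_B.
#' @export
pair_homologs <- function(events_a, genome_a, genome_b, models_b, homology,
                          junctions_b, min_identity = 70, min_coverage = 0.9) {
  rows <- list()
  for (i in seq_len(nrow(events_a))) {
    ev <- events_a[i, ]
    genes_b <- homology$gene_id_B[homology$gene_id_A == ev$gene_id]
    if (length(genes_b) == 0L) {
      message("no homologous gene for ", ev$gene_id)
      next
    }
    cand <- do.call(rbind, lapply(genes_b, internal_exons, models = models_b))
    if (is.null(cand) || nrow(cand) == 0L) next
    exons <- unique(cand[, c("exon_id", "chrom", "strand", "start", "end")])
    exons$seq <- vapply(seq_len(nrow(exons)), function(k) {
      exon_sequence(genome_b, exons$chrom[k], exons$start[k], exons$end[k],
                    exons$strand[k])
    }, character(1))
    seq_a <- exon_sequence(genome_a, ev$chrom, ev$coord2, ev$coord3, ev$strand)
    best <- select_homolog(seq_a, exons, min_identity = min_identity,
                           min_coverage = min_coverage)
    if (is.null(best)) next
    bx <- exons[exons$exon_id == best$exon_id, , drop = FALSE][1L, ]
    flank <- resolve_flanking(bx, cand[cand$exon_id == best$exon_id, ,
                                       drop = FALSE], junctions_b)
    gene_b <- sub(":.*$", "", best$exon_id)
    rows[[length(rows) + 1L]] <- data.frame(
      event_id_A = ev$event_id, gene_id_B = gene_b,
      exon_id_B = best$exon_id,
      percent_identity = best$percent_identity,
      coverage_a = best$coverage_a, coverage_b = best$coverage_b,
      chrom_B = bx$chrom, strand_B = bx$strand,
      coord1_B = flank$up_end, coord2_B = bx$start,
      coord3_B = bx$end, coord4_B = flank$down_start,
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) {
    pairs <- data.frame(event_id_A = character(), gene_id_B = character(),
                        exon_id_B = character(), percent_identity = numeric(),
                        coverage_a = numeric(), coverage_b = numeric(),
                        chrom_B = character(), strand_B = character(),
                        coord1_B = integer(), coord2_B = integer(),
                        coord3_B = integer(), coord4_B = integer(),
                        event_id_B = character(), stringsAsFactors = FALSE)
  } else {
    pairs <- do.call(rbind, rows)
    pairs$event_id_B <- event_id(pairs$gene_id_B, pairs$coord1_B,
                                 pairs$coord2_B, pairs$coord3_B,
                                 pairs$coord4_B)
  }
  class(pairs) <- c("homolog_pairs", "data.frame")
  pairs
}

#' Species-B events table from homolog pairs
#'
#' Recasts the B-side coordinates of [pair_homologs()] output as a
#' `skipping_events` table so psi can be computed with [psi_table()].
#' @param pairs `homolog_pairs` data.frame.
#' @return `skipping_events` data.frame (deduplicated on event_id).
#' @export
pairs_as_events_b <- function(pairs) {
  ev <- data.frame(event_id = pairs$event_id_B, gene_id = pairs$gene_id_B,
                   chrom = pairs$chrom_B, strand = pairs$strand_B,
                   coord1 = pairs$coord1_B, coord2 = pairs$coord2_B,
                   coord3 = pairs$coord3_B, coord4 = pairs$coord4_B,
                   stringsAsFactors = FALSE)
  ev <- unique(ev)
  ev$cassette_length <- ev$coord3 - ev$coord2
  rownames(ev) <- NULL
  class(ev) <- c("skipping_events", "data.frame")
  ev
}
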