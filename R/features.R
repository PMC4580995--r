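# Per-event sequence features: splice-site k-mers (9-mer donor = 3 exonic +
# 6 intronic nt; 23-mer acceptor = 20 intronic + 3 exonic nt), position
# weight model scoring, ESE/ESS motif counting, branch-point heuristic over
# the 100-nt upstream-intron window, and the polypyrimidine tract score.

DONOR_EXONIC <- 3L
DONOR_INTRONIC <- 6L
ACCEPTOR_INTRONIC <- 20L
ACCEPTOR_EXONIC <- 3L
UPSTREAM_WINDOW <- 100L

#' Extract the splice-site sequences of a cassette event
#'
#' Returns the cassette exon's donor 9-mer (3 exonic + 6 intronic nt), its
#' acceptor 23-mer (20 intronic + 3 exonic nt), the 100-nt upstream-intron
#' window ending at the cassette acceptor, plus the outer sites: the donor
#' of the upstream exon and the acceptor of the downstream exon. All
#' sequences are in transcript orientation (reverse-complemented for
#' minus-strand events). Windows running past a contig end or into an
#' intron shorter than nominal are truncated and flagged.
#'
#' @param event one row of a `skipping_events` table.
#' @param genome [Biostrings::DNAStringSet].
#' @return list: donor, acceptor, upstream_window, donor_flank (upstream
#'   exon donor), acceptor_flank (downstream exon acceptor), exon (cassette
#'   exon sequence), truncated (logical flag for the upstream window).
#' @export
splice_site_sequences <- function(event, genome) {
  ch <- event$chrom; st <- event$strand
  c1 <- event$coord1; c2 <- event$coord2; c3 <- event$coord3; c4 <- event$coord4
  slice <- function(s, e) genome_slice(genome, ch, s, e)
  if (st == "+") {
    donor <- slice(c3 - DONOR_EXONIC, c3 + DONOR_INTRONIC)
    acceptor <- slice(c2 - ACCEPTOR_INTRONIC, c2 + ACCEPTOR_EXONIC)
    up_len <- c2 - c1
    win_start <- max(c1, c2 - UPSTREAM_WINDOW)
    upstream <- slice(win_start, c2)
    donor_flank <- slice(c1 - DONOR_EXONIC, c1 + DONOR_INTRONIC)
    acceptor_flank <- slice(c4 - ACCEPTOR_INTRONIC, c4 + ACCEPTOR_EXONIC)
    exon <- slice(c2, c3)
  } else {
    donor <- revcomp(slice(c2 - DONOR_INTRONIC, c2 + DONOR_EXONIC))
    acceptor <- revcomp(slice(c3 - ACCEPTOR_EXONIC, c3 + ACCEPTOR_INTRONIC))
    up_len <- c4 - c3   # transcriptionally upstream intron is the genomic downstream one
    win_end <- min(c4, c3 + UPSTREAM_WINDOW)
    upstream <- revcomp(slice(c3, win_end))
    donor_flank <- revcomp(slice(c4 - DONOR_INTRONIC, c4 + DONOR_EXONIC))
    acceptor_flank <- revcomp(slice(c1 - ACCEPTOR_EXONIC, c1 + ACCEPTOR_INTRONIC))
    exon <- revcomp(slice(c2, c3))
  }
  list(donor = donor, acceptor = acceptor, upstream_window = upstream,
       donor_flank = donor_flank, acceptor_flank = acceptor_flank,
       exon = exon, truncated = nchar(upstream) < UPSTREAM_WINDOW)
}

#' Position-weight splice-site model
#'
#' A model is a list with `k` (k-mer length) and `pwm`, a 4 x k matrix of
#' per-position base probabilities (rows A, C, G, T). The score of a k-mer
#' is sum over positions of log2(p(base) / 0.25). The uniform model scores
#' every k-mer 0.
#'
#' @param pwm 4 x k probability matrix with rownames A, C, G, T.
#' @return object of class `splice_model`.
#' @export
splice_model <- function(pwm) {
  stopifnot(is.matrix(pwm), nrow(pwm) == 4L,
            identical(rownames(pwm), c("A", "C", "G", "T")))
  if (any(pwm <= 0)) stop("PWM probabilities must be positive")
  structure(list(k = ncol(pwm), pwm = pwm), class = "splice_model")
}

#' @rdname splice_model
#' @param k k-mer length.
#' @export
uniform_splice_model <- function(k) {
  splice_model(matrix(0.25, 4L, k, dimnames = list(c("A", "C", "G", "T"), NULL)))
}

#' Train a first-order position weight model from annotated splice sites
#'
#' Collects the donor 9-mers (or acceptor 23-mers) of every intron in the
#' gene models and estimates per-position base probabilities with a
#' pseudocount of 0.5.
#'
#' @param models `gene_models` object.
#' @param genome [Biostrings::DNAStringSet].
#' @param site "donor" or "acceptor".
#' @return `splice_model`.
#' @export
train_splice_model <- function(models, genome, site = c("donor", "acceptor")) {
  site <- match.arg(site)
  ex <- models$exons
  kmers <- character(0)
  for (tx in split(ex, ex$transcript_id)) {
    if (nrow(tx) < 2L) next
    ch <- tx$chrom[1L]; st <- tx$strand[1L]
    for (i in seq_len(nrow(tx) - 1L)) {
      de <- tx$end[i]; as_ <- tx$start[i + 1L]   # intron [de, as_)
      if (st == "+") {
        km <- if (site == "donor") {
          genome_slice(genome, ch, de - DONOR_EXONIC, de + DONOR_INTRONIC)
        } else {
          genome_slice(genome, ch, as_ - ACCEPTOR_INTRONIC, as_ + ACCEPTOR_EXONIC)
        }
      } else {
        km <- if (site == "donor") {
          revcomp(genome_slice(genome, ch, as_ - DONOR_INTRONIC, as_ + DONOR_EXONIC))
        } else {
          revcomp(genome_slice(genome, ch, de - ACCEPTOR_EXONIC, de + ACCEPTOR_INTRONIC))
        }
      }
      kexp <- if (site == "donor") DONOR_EXONIC + DONOR_INTRONIC else
        ACCEPTOR_INTRONIC + ACCEPTOR_EXONIC
      if (nchar(km) == kexp && !grepl("[^ACGT]", km)) {
        kmers <- c(kmers, km)
      }
    }
  }
  k <- if (site == "donor") DONOR_EXONIC + DONOR_INTRONIC else
    ACCEPTOR_INTRONIC + ACCEPTOR_EXONIC
  if (length(kmers) == 0L) return(uniform_splice_model(k))
  mat <- do.call(rbind, strsplit(kmers, ""))
  pwm <- vapply(seq_len(k), function(j) {
    counts <- table(factor(mat[, j], levels = c("A", "C", "G", "T"))) + 0.5
    as.numeric(counts / sum(counts))
  }, numeric(4))
  rownames(pwm) <- c("A", "C", "G", "T")
  splice_model(pwm)
}

#' Score a splice-site k-mer under a position weight model
#'
#' @param kmer ACGT string of length `model$k`.
#' @param model `splice_model`.
#' @return log2-odds score against the uniform background.
#' @export
score_splice_site <- function(kmer, model) {
  stopifnot(inherits(model, "splice_model"))
  if (nchar(kmer) != model$k) {
    stop("k-mer length ", nchar(kmer), " does not match model k = ", model$k)
  }
  bases <- match(strsplit(kmer, "")[[1L]], c("A", "C", "G", "T"))
  if (anyNA(bases)) stop("non-ACGT base in k-mer")
  sum(log2(model$pwm[cbind(bases, seq_len(model$k))] / 0.25))
}

#' Write / read a splice-site model as a plain-text table
#' @param model `splice_model`.
#' @param path TSV path (columns pos, A, C, G, T).
#' @export
write_splice_model <- function(model, path) {
  df <- data.frame(pos = seq_len(model$k), t(model$pwm))
  write_tsv_file(df, path)
}

#' @rdname write_splice_model
#' @export
read_splice_model <- function(path) {
  df <- read_tsv_file(path, required = c("pos", "A", "C", "G", "T"))
  pwm <- t(as.matrix(df[order(df$pos), c("A", "C", "G", "T")]))
  rownames(pwm) <- c("A", "C", "G", "T")
  splice_model(pwm)
}

#' Count ESE and ESS motif occurrences in an exon
#'
#' Every occurrence of every motif is counted, overlapping occurrences
#' included. Positive-score motifs count toward `n_ese`, negative-score
#' ones toward `n_ess`; zero-score motifs are ignored.
#'
#' @param exon_seq exon sequence (transcript orientation), non-empty.
#' @param motif_table data.frame: factor, motif, score.
#' @return named integer vector c(n_ese, n_ess).
#' @export
count_motifs <- function(exon_seq, motif_table) {
  if (!nzchar(exon_seq)) stop("empty exon sequence")
  if (is.null(motif_table) || nrow(motif_table) == 0L) {
    return(c(n_ese = 0L, n_ess = 0L))
  }
  subject <- Biostrings::DNAString(exon_seq)
  hits <- vapply(motif_table$motif, function(m) {
    Biostrings::countPattern(m, subject)
  }, integer(1))
  c(n_ese = sum(hits[motif_table$score > 0]),
    n_ess = sum(hits[motif_table$score < 0]))
}

# Branch-point consensus position weight model (yUnAy-type heptamer with the
# branch adenosine at position 6). Probabilities sum to 1 per position.
bp_default_pwm <- function() {
  pwm <- cbind(
    c(0.15, 0.30, 0.15, 0.40),  # p1: mild pyrimidine bias
    c(0.12, 0.28, 0.10, 0.50),  # p2
    c(0.10, 0.35, 0.10, 0.45),  # p3: y
    c(0.06, 0.07, 0.07, 0.80),  # p4: U
    c(0.30, 0.20, 0.30, 0.20),  # p5: n (slight purine)
    c(0.97, 0.01, 0.01, 0.01),  # p6: branch A
    c(0.10, 0.45, 0.10, 0.35)   # p7: y
  )
  rownames(pwm) <- c("A", "C", "G", "T")
  pwm
}

#' Predict the branch point in an upstream-intron window
#'
#' Scans every heptamer whose position 6 is an adenosine against a
#' branch-consensus position weight model (log2-odds vs uniform background)
#' and returns the highest-scoring candidate; ties go to the candidate
#' closest to the 3' end. Adenosines falling within the final 3 nt of the
#' window (the acceptor AG region) are not candidates. Returns NULL when
#' the window is shorter than 7 nt or contains no candidate adenosine.
#'
#' @param window upstream-intron sequence ending at the acceptor (<= 100 nt
#'   by convention).
#' @param pwm optional 4 x 7 probability matrix (rows A, C, G, T).
#' @return NULL or list(bp_pos, score) with `bp_pos` the 1-based position of
#'   the branch adenosine within the window.
#' @export
predict_branch_point <- function(window, pwm = bp_default_pwm()) {
  L <- nchar(window)
  if (L < 7L) return(NULL)
  bases <- strsplit(window, "")[[1L]]
  best <- NULL
  for (i in seq_len(L - 6L)) {
    bp <- i + 5L
    if (bp > L - 3L) break          # branch A must lie upstream of the final 3 nt
    if (bases[bp] != "A") next
    hept <- match(bases[i:(i + 6L)], c("A", "C", "G", "T"))
    if (anyNA(hept)) next
    sc <- sum(log2(pwm[cbind(hept, 1:7)] / 0.25))
    if (is.null(best) || sc >= best$score) {  # >= keeps the 3'-most on ties
      best <- list(bp_pos = bp, score = sc)
    }
  }
  best
}

#' Polypyrimidine tract score
#'
#' The scored region is the bases strictly between the branch adenosine and
#' the final 3 nt of the window (which contain the acceptor AG). The score
#' is (number of pyrimidines in the region) + (length of the longest
#' uninterrupted pyrimidine run); an empty region scores 0.
#'
#' @param window upstream-intron window (same sequence given to
#'   [predict_branch_point()]).
#' @param bp_pos 1-based position of the branch adenosine in the window.
#' @return non-negative numeric score.
#' @export
ppt_score <- function(window, bp_pos) {
  L <- nchar(window)
  if (bp_pos < 1L || bp_pos > L) stop("bp_pos outside window")
  if (bp_pos + 1L > L - 3L) return(0)
  region <- strsplit(substr(window, bp_pos + 1L, L - 3L), "")[[1L]]
  is_py <- region %in% c("C", "T")
  if (!any(is_py)) return(0)
  runs <- rle(is_py)
  sum(is_py) + max(runs$lengths[runs$values])
}

#' Assemble the full feature vector of one event
#'
#' Exon length and intron lengths come from the event coordinates (strand
#' resolved); ESE/ESS counts from [count_motifs()]; splice-site scores from
#' the supplied donor/acceptor models (the same scoring models are meant to
#' be used for both species); branch and PPT scores from the 100-nt
#' upstream-intron window. When no branch point is predictable both
#' branch_score and ppt_score are NA and the event is excluded from
#' PPT-based analyses downstream.
#'
#' @param event one row of a `skipping_events` table.
#' @param genome [Biostrings::DNAStringSet].
#' @param motif_table motif data.frame (factor, motif, score).
#' @param donor_model,acceptor_model `splice_model` objects.
#' @param bp_pwm optional branch-point PWM.
#' @return one-row data.frame (see fields in the source).
#' @export
feature_vector <- function(event, genome, motif_table, donor_model,
                           acceptor_model, bp_pwm = bp_default_pwm()) {
  seqs <- splice_site_sequences(event, genome)
  mot <- count_motifs(seqs$exon, motif_table)
  score_or_na <- function(kmer, model) {
    if (nchar(kmer) != model$k || grepl("[^ACGT]", kmer)) return(NA_real_)
    score_splice_site(kmer, model)
  }
  bp <- predict_branch_point(seqs$upstream_window, pwm = bp_pwm)
  if (event$strand == "+") {
    up_len <- event$coord2 - event$coord1
    down_len <- event$coord4 - event$coord3
  } else {
    up_len <- event$coord4 - event$coord3
    down_len <- event$coord2 - event$coord1
  }
  data.frame(
    event_id = event$event_id,
    exon_length = event$coord3 - event$coord2,
    n_ese = unname(mot["n_ese"]), n_ess = unname(mot["n_ess"]),
    score_5ss = score_or_na(seqs$donor, donor_model),
    score_3ss = score_or_na(seqs$acceptor, acceptor_model),
    branch_score = if (is.null(bp)) NA_real_ else bp$score,
    ppt_score = if (is.null(bp)) NA_real_ else
      ppt_score(seqs$upstream_window, bp$bp_pos),
    upstream_intron_length = up_len,
    downstream_intron_length = down_len,
    score_5ss_upstream_intron = score_or_na(seqs$donor_flank, donor_model),
    score_3ss_downstream_intron = score_or_na(seqs$acceptor_flank, acceptor_model),
    window_truncated = seqs$truncated,
    stringsAsFactors = FALSE)
}

#' Feature table over many events
#' @param events `skipping_events` data.frame.
#' @inheritParams feature_vector
#' @return data.frame, one row per event.
#' @export
feature_table <- function(events, genome, motif_table, donor_model,
                          acceptor_model, bp_pwm = bp_default_pwm()) {
  do.call(rbind, lapply(seq_len(nrow(events)), function(i) {
    feature_vector(events[i, ], genome, motif_table, donor_model,
                   acceptor_model, bp_pwm)
  }))
}
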