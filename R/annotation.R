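# Gene-model parsing and annotated exon-skipping (cassette exon) event
# extraction. An event is described by four genomic coordinates:
#   coord1 = 5' end of the upstream intron (end of the upstream exon)
#   coord2 = cassette exon start
#   coord3 = cassette exon end
#   coord4 = 3' end of the downstream intron (start of the downstream exon)
# all 0-based half-open on the genomic axis, so coord1 < coord2 < coord3 < coord4.

#' Parse gene models from a GTF file
#'
#' Reads exon features (attributes `gene_id` and `transcript_id` required)
#' and converts coordinates from GTF 1-based inclusive to the internal
#' 0-based half-open convention. Exons within a transcript must be
#' non-overlapping; they are sorted in genomic order.
#'
#' @param path GTF file.
#' @return An object of class `gene_models`: a list with element `exons`, a
#'   data.frame with columns gene_id, transcript_id, chrom, strand, start,
#'   end (0-based half-open).
#' @export
read_gene_models <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  if (file.size(path) == 0L) {
    return(gene_models(data.frame(gene_id = character(), transcript_id = character(),
                                  chrom = character(), strand = character(),
                                  start = integer(), end = integer())))
  }
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (length(gr) == 0L) {
    return(gene_models(data.frame(gene_id = character(), transcript_id = character(),
                                  chrom = character(), strand = character(),
                                  start = integer(), end = integer())))
  }
  if (is.null(gr$gene_id) || is.null(gr$transcript_id) ||
      anyNA(gr$gene_id) || anyNA(gr$transcript_id)) {
    stop("GTF exon records must carry gene_id and transcript_id attributes")
  }
  grd <- as.data.frame(gr)
  df <- data.frame(
    gene_id = as.character(grd$gene_id),
    transcript_id = as.character(grd$transcript_id),
    chrom = as.character(grd$seqnames),
    strand = as.character(grd$strand),
    start = grd$start - 1L,   # to 0-based half-open
    end = grd$end,
    stringsAsFactors = FALSE
  )
  gene_models(df)
}

#' Construct gene models from an exon table
#'
#' @param exons data.frame with columns gene_id, transcript_id, chrom,
#'   strand, start, end (0-based half-open).
#' @return `gene_models` object.
#' @export
gene_models <- function(exons) {
  req <- c("gene_id", "transcript_id", "chrom", "strand", "start", "end")
  stopifnot(all(req %in% names(exons)))
  exons <- exons[order(exons$gene_id, exons$transcript_id, exons$start), , drop = FALSE]
  rownames(exons) <- NULL
  if (nrow(exons)) {
    if (any(exons$end <= exons$start)) stop("exon with non-positive width")
    # non-overlap check within each transcript (exons sorted by start)
    by_tx <- split(seq_len(nrow(exons)), exons$transcript_id)
    for (idx in by_tx) {
      if (length(idx) > 1L) {
        s <- exons$start[idx]; e <- exons$end[idx]
        if (any(e[-length(e)] > s[-1L])) {
          stop("overlapping exons within transcript ",
               exons$transcript_id[idx[1L]])
        }
      }
    }
  }
  structure(list(exons = exons), class = "gene_models")
}

#' @export
print.gene_models <- function(x, ...) {
  cat("Gene models:", length(unique(x$exons$gene_id)), "genes,",
      length(unique(x$exons$transcript_id)), "transcripts,",
      nrow(x$exons), "exons\n")
  invisible(x)
}

# Introns of one transcript (exons pre-sorted): data.frame(start, end)
transcript_introns <- function(starts, ends) {
  n <- length(starts)
  if (n < 2L) return(data.frame(start = integer(), end = integer()))
  data.frame(start = ends[-n], end = starts[-1L])
}

#' Extract annotated exon-skipping events from gene models
#'
#' For every internal exon of every transcript, an event is emitted iff some
#' other transcript of the same gene contains an intron running exactly from
#' the 5' end of the exon's upstream intron (coord1) to the 3' end of its
#' downstream intron (coord4), i.e. an intron with no annotated exon between
#' those boundaries. Events are deduplicated on (gene_id, coord1..coord4);
#' cross-gene coordinate coincidences are never merged.
#'
#' @param models a `gene_models` object.
#' @return data.frame of class `skipping_events`: event_id, gene_id, chrom,
#'   strand, coord1..coord4, cassette_length.
#' @export
extract_skipping_events <- function(models) {
  stopifnot(inherits(models, "gene_models"))
  ex <- models$exons
  out <- vector("list", 64L); n_out <- 0L
  for (gene in unique(ex$gene_id)) {
    gx <- ex[ex$gene_id == gene, , drop = FALSE]
    txs <- split(gx, gx$transcript_id)
    if (length(txs) < 2L) next
    # intron keys per transcript
    intron_keys <- lapply(txs, function(t) {
      ii <- transcript_introns(t$start, t$end)
      paste(ii$start, ii$end)
    })
    for (ti in seq_along(txs)) {
      t <- txs[[ti]]
      if (nrow(t) < 3L) next
      other_introns <- unique(unlist(intron_keys[-ti], use.names = FALSE))
      if (is.null(other_introns)) next
      for (i in 2L:(nrow(t) - 1L)) {
        c1 <- t$end[i - 1L]; c2 <- t$start[i]
        c3 <- t$end[i]; c4 <- t$start[i + 1L]
        if (paste(c1, c4) %in% other_introns) {
          n_out <- n_out + 1L
          if (n_out > length(out)) out <- c(out, vector("list", length(out)))
          out[[n_out]] <- data.frame(
            gene_id = gene, chrom = t$chrom[1L], strand = t$strand[1L],
            coord1 = c1, coord2 = c2, coord3 = c3, coord4 = c4,
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (n_out == 0L) {
    ev <- data.frame(event_id = character(), gene_id = character(),
                     chrom = character(), strand = character(),
                     coord1 = integer(), coord2 = integer(),
                     coord3 = integer(), coord4 = integer(),
                     cassette_length = integer(), stringsAsFactors = FALSE)
    class(ev) <- c("skipping_events", "data.frame")
    return(ev)
  }
  ev <- do.call(rbind, out[seq_len(n_out)])
  ev <- unique(ev)
  ev <- ev[order(ev$gene_id, ev$coord1, ev$coord2, ev$coord3, ev$coord4), ,
           drop = FALSE]
  rownames(ev) <- NULL
  ev <- cbind(event_id = event_id(ev$gene_id, ev$coord1, ev$coord2,
                                  ev$coord3, ev$coord4),
              ev, stringsAsFactors = FALSE)
  ev$cassette_length <- ev$coord3 - ev$coord2
  class(ev) <- c("skipping_events", "data.frame")
  ev
}

#' Deterministic event identifier from the 4-coordinate description
#' @noRd
event_id <- function(gene_id, c1, c2, c3, c4) {
  sprintf("%s:%d-%d-%d-%d", gene_id, c1, c2, c3, c4)
}

#' Write / read an events table
#' @param events `skipping_events` data.frame.
#' @param path TSV path.
#' @export
write_events <- function(events, path) {
  write_tsv_file(as.data.frame(events), path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  ev <- read_tsv_file(path, required = c("event_id", "gene_id", "chrom",
                                         "strand", "coord1", "coord2",
                                         "coord3", "coord4"))
  if (!"cassette_length" %in% names(ev)) ev$cassette_length <- ev$coord3 - ev$coord2
  class(ev) <- c("skipping_events", "data.frame")
  ev
}
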