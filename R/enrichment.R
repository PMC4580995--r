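# 48-bin stratified enrichment of skip-enhanced exons over feature strata
# (exon length x ESE count x ESS count x polypyrimidine tract score), with
# upper-tail hypergeometric tests and a nested decision-tree style report.

#' Bin scheme for the stratified enrichment analysis
#'
#' Default strata: exon length (0-64, >=65 nt), ESE count (0-4, 5-15, >=16),
#' ESS count (0-19, >=20), PPT score (0-9, 10-19, 20-29, >=30), giving
#' 2 x 3 x 2 x 4 = 48 bins. All edges are configurable.
#'
#' @param length_cut exon-length cut (first long value, default 65).
#' @param ese_cuts two increasing ESE cuts (default c(5, 16)).
#' @param ess_cut ESS cut (default 20).
#' @param ppt_cuts three increasing PPT cuts (default c(10, 20, 30)).
#' @return object of class `bin_scheme`.
#' @export
bin_scheme <- function(length_cut = 65, ese_cuts = c(5, 16), ess_cut = 20,
                       ppt_cuts = c(10, 20, 30)) {
  stopifnot(length(ese_cuts) == 2L, diff(ese_cuts) > 0,
            length(ppt_cuts) == 3L, all(diff(ppt_cuts) > 0))
  sc <- list(
    length_breaks = c(0, length_cut, Inf),
    length_labels = c(sprintf("len0-%d", length_cut - 1),
                      sprintf("len%d+", length_cut)),
    ese_breaks = c(0, ese_cuts, Inf),
    ese_labels = c(sprintf("ESE0-%d", ese_cuts[1] - 1),
                   sprintf("ESE%d-%d", ese_cuts[1], ese_cuts[2] - 1),
                   sprintf("ESE%d+", ese_cuts[2])),
    ess_breaks = c(0, ess_cut, Inf),
    ess_labels = c(sprintf("ESS0-%d", ess_cut - 1), sprintf("ESS%d+", ess_cut)),
    ppt_breaks = c(0, ppt_cuts, Inf),
    ppt_labels = c(sprintf("PPT0-%d", ppt_cuts[1] - 1),
                   sprintf("PPT%d-%d", ppt_cuts[1], ppt_cuts[2] - 1),
                   sprintf("PPT%d-%d", ppt_cuts[2], ppt_cuts[3] - 1),
                   sprintf("PPT%d+", ppt_cuts[3])))
  structure(sc, class = "bin_scheme")
}

#' Enumerate all bins of a scheme
#' @param scheme `bin_scheme`.
#' @return character vector of bin ids (length 48 for the default scheme).
#' @export
all_bins <- function(scheme) {
  g <- expand.grid(ppt = scheme$ppt_labels, ese = scheme$ese_labels,
                   ess = scheme$ess_labels, len = scheme$length_labels,
                   stringsAsFactors = FALSE)
  paste(g$len, g$ess, g$ese, g$ppt, sep = "|")
}

axis_bin <- function(x, breaks, labels) {
  labels[findInterval(x, breaks, rightmost.closed = FALSE)]
}

#' Assign an event to its feature bin
#'
#' Events with a missing PPT score (no predictable branch point) are not
#' binnable and return NA.
#'
#' @param exon_length,n_ese,n_ess,ppt_score feature values (vectorised).
#' @param scheme `bin_scheme`.
#' @return character bin id(s) of the form `len|ESS|ESE|PPT`, or NA.
#' @export
assign_bin <- function(exon_length, n_ese, n_ess, ppt_score,
                       scheme = bin_scheme()) {
  out <- paste(axis_bin(exon_length, scheme$length_breaks, scheme$length_labels),
               axis_bin(n_ess, scheme$ess_breaks, scheme$ess_labels),
               axis_bin(n_ese, scheme$ese_breaks, scheme$ese_labels),
               axis_bin(ppt_score, scheme$ppt_breaks, scheme$ppt_labels),
               sep = "|")
  out[is.na(exon_length) | is.na(n_ese) | is.na(n_ess) | is.na(ppt_score)] <- NA
  out
}

#' Stratified enrichment of a hit set over feature bins
#'
#' For each bin: group size, number of hits, enrichment ratio
#' (hits/size) / baseline with baseline = total hits / total binned events,
#' an upper-tail hypergeometric p-value (probability of >= hits successes
#' when drawing `size` from the universe), and a `reportable` flag requiring
#' at least `min_hits` hits (default 3).
#'
#' @param bins character bin id per event (NA = excluded).
#' @param is_hit logical per event (e.g. strongly skip-enhanced).
#' @param scheme `bin_scheme` used to enumerate empty bins too.
#' @param min_hits minimum hits for a bin to be reportable.
#' @return data.frame of class `enrichment_rows` with attribute `baseline`;
#'   one row per bin of the scheme.
#' @export
enrichment_analysis <- function(bins, is_hit, scheme = bin_scheme(),
                                min_hits = 3L) {
  stopifnot(length(bins) == length(is_hit))
  keep <- !is.na(bins)
  bins <- bins[keep]; is_hit <- as.logical(is_hit)[keep]
  n_total <- length(bins)
  k_total <- sum(is_hit)
  ids <- all_bins(scheme)
  size <- as.integer(table(factor(bins, levels = ids)))
  hits <- as.integer(tapply(is_hit, factor(bins, levels = ids), sum))
  hits[is.na(hits)] <- 0L
  baseline <- if (n_total > 0) k_total / n_total else NA_real_
  enrich <- if (!is.na(baseline) && baseline > 0) {
    (hits / size) / baseline
  } else {
    rep(NA_real_, length(ids))
  }
  p <- rep(NA_real_, length(ids))
  if (n_total > 0 && k_total > 0) {
    p <- stats::phyper(hits - 1L, k_total, n_total - k_total, size,
                       lower.tail = FALSE)
  }
  out <- data.frame(bin = ids, size = size, hits = hits,
                    enrichment = enrich, p_value = p,
                    reportable = hits >= min_hits,
                    stringsAsFactors = FALSE)
  attr(out, "baseline") <- baseline
  attr(out, "n_total") <- n_total
  attr(out, "k_total") <- k_total
  class(out) <- c("enrichment_rows", "data.frame")
  out
}

enrichment_level <- function(e) {
  br <- c(-Inf, 0.5, 1, 2, 4, Inf)
  lb <- c("depleted", "below-baseline", "1-2x", "2-4x", ">4x")
  ifelse(is.na(e) | is.nan(e), "empty", lb[findInterval(e, br)])
}

#' Decision-tree style enrichment report
#'
#' Nests the enrichment rows as length -> ESS -> ESE -> PPT with a coarse
#' enrichment level per leaf, and surfaces two regions of interest: region
#' "a" (short exons with low ESS and low/mid ESE counts, ordered by PPT
#' bin - where a weak-PPT enrichment trend is expected) and region "b"
#' (short exons with high ESS counts, where strong-PPT enrichment has been
#' observed but no rule is modelled).
#'
#' @param rows output of [enrichment_analysis()].
#' @param scheme the `bin_scheme` used.
#' @return list of class `enrichment_report` with elements `tree`,
#'   `region_a`, `region_b`, `baseline`; serialisable with
#'   [jsonlite::toJSON()].
#' @export
decision_tree_report <- function(rows, scheme = bin_scheme()) {
  parts <- strsplit(rows$bin, "|", fixed = TRUE)
  rows$len_bin <- vapply(parts, `[`, "", 1L)
  rows$ess_bin <- vapply(parts, `[`, "", 2L)
  rows$ese_bin <- vapply(parts, `[`, "", 3L)
  rows$ppt_bin <- vapply(parts, `[`, "", 4L)
  rows$level <- enrichment_level(rows$enrichment)
  tree <- lapply(stats::setNames(scheme$length_labels, scheme$length_labels),
                 function(L) {
    lapply(stats::setNames(scheme$ess_labels, scheme$ess_labels), function(S) {
      lapply(stats::setNames(scheme$ese_labels, scheme$ese_labels), function(E) {
        sub <- rows[rows$len_bin == L & rows$ess_bin == S & rows$ese_bin == E, ]
        sub <- sub[match(scheme$ppt_labels, sub$ppt_bin), ]
        stats::setNames(lapply(seq_len(nrow(sub)), function(i) {
          list(size = sub$size[i], hits = sub$hits[i],
               enrichment = sub$enrichment[i], p_value = sub$p_value[i],
               reportable = sub$reportable[i], level = sub$level[i])
        }), sub$ppt_bin)
      })
    })
  })
  short <- scheme$length_labels[1L]
  low_ess <- scheme$ess_labels[1L]
  region_a <- rows[rows$len_bin == short & rows$ess_bin == low_ess &
                     rows$ese_bin %in% scheme$ese_labels[1:2], ]
  region_a <- region_a[order(region_a$ese_bin,
                             match(region_a$ppt_bin, scheme$ppt_labels)), ]
  region_b <- rows[rows$len_bin == short & rows$ess_bin == scheme$ess_labels[2L], ]
  region_b <- region_b[order(region_b$ese_bin,
                             match(region_b$ppt_bin, scheme$ppt_labels)), ]
  drop_cols <- function(d) {
    rownames(d) <- NULL
    d[, c("bin", "size", "hits", "enrichment", "p_value", "reportable", "level")]
  }
  structure(list(tree = tree, region_a = drop_cols(region_a),
                 region_b = drop_cols(region_b),
                 baseline = attr(rows, "baseline")),
            class = "enrichment_report")
}

#' Write an enrichment report as JSON
#' @param report `enrichment_report`.
#' @param path output file.
#' @export
write_enrichment_report <- function(report, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
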