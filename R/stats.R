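# Inferential layer: control-set construction, Wilcoxon rank-sum
# comparisons, the nine-category cross-species conservation table with a
# chi-square test against independence, the set-overlap independence test,
# and the four-way feature comparison report.

#' Build the control set of cross-species insensitive homologous pairs
#'
#' Keeps pairs where both the species-A and species-B events have delta-psi
#' exactly 0 in both replicates.
#'
#' @param pairs `homolog_pairs` data.frame (with event_id_A, event_id_B).
#' @param psi_a,psi_b `psi_records` for the two species.
#' @return subset of `pairs`.
#' @export
build_control_set <- function(pairs, psi_a, psi_b) {
  if (nrow(pairs) == 0L) return(pairs)
  zero_ids <- function(psi) {
    ok <- !is.na(psi$dpsi_rep1) & !is.na(psi$dpsi_rep2) &
      psi$dpsi_rep1 == 0 & psi$dpsi_rep2 == 0
    psi$event_id[ok]
  }
  keep <- pairs$event_id_A %in% zero_ids(psi_a) &
    pairs$event_id_B %in% zero_ids(psi_b)
  pairs[keep, , drop = FALSE]
}

#' Two-sided Wilcoxon rank-sum p-value
#'
#' Exact enumeration when there are no ties and min(n, m) <= 8; otherwise
#' the normal approximation with tie correction (no continuity correction).
#'
#' @param x,y non-empty numeric groups.
#' @return p-value.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) stop("empty group")
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && min(length(x), length(y)) <= 8L
  suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE)$p.value)
}

#' Nine-category cross-species conservation analysis
#'
#' Cross-tabulates the per-species response classes (skip / no_effect /
#' inclusion) of homologous event pairs into a 3 x 3 table, computes the
#' expected counts under independence (no conservation of the treatment
#' effect between species) from the marginals, and a Pearson chi-square
#' statistic with 4 degrees of freedom.
#'
#' @param class_a,class_b character vectors of classes, one pair per
#'   element; values must be in {skip, no_effect, inclusion}.
#' @return object of class `nine_category`: list(observed, expected, chisq,
#'   df, p_value, n, reliable).
#' @export
nine_category_analysis <- function(class_a, class_b) {
  lv <- c("skip", "no_effect", "inclusion")
  if (length(class_a) != length(class_b)) stop("class vectors differ in length")
  if (length(class_a) == 0L) stop("no pairs to tabulate")
  bad <- setdiff(unique(c(class_a, class_b)), lv)
  if (length(bad)) stop("unknown class labels: ", paste(bad, collapse = ", "))
  obs <- table(factor(class_a, levels = lv), factor(class_b, levels = lv))
  n <- sum(obs)
  exp <- outer(rowSums(obs), colSums(obs)) / n
  reliable <- all(exp > 0)
  cells <- exp > 0
  chisq <- sum((obs[cells] - exp[cells])^2 / exp[cells])
  structure(list(observed = unclass(obs), expected = exp, chisq = chisq,
                 df = 4L, p_value = stats::pchisq(chisq, 4L, lower.tail = FALSE),
                 n = n, reliable = reliable),
            class = "nine_category")
}

#' @export
print.nine_category <- function(x, ...) {
  cat("Nine-category conservation table (n =", x$n, "pairs)\n")
  print(x$observed)
  cat("chi-square =", format(x$chisq, digits = 4), "on", x$df,
      "df, p =", format(x$p_value, digits = 4), "\n")
  if (!x$reliable) cat("warning: zero expected cell(s); chi-square unreliable\n")
  invisible(x)
}

#' Set-overlap test against independence
#'
#' Observed overlap of two subsets of a common universe versus the expected
#' overlap |A| * |B| / N under independence, with a chi-square test (df 1,
#' no continuity correction) on the 2 x 2 membership table.
#'
#' @param set_a,set_b vectors of member identifiers.
#' @param universe_size N, at least |A union B|.
#' @return list(observed, expected, chisq, p_value).
#' @export
overlap_independence_test <- function(set_a, set_b, universe_size) {
  set_a <- unique(set_a); set_b <- unique(set_b)
  n_union <- length(union(set_a, set_b))
  if (universe_size < n_union) stop("universe smaller than |A union B|")
  both <- length(intersect(set_a, set_b))
  a_only <- length(set_a) - both
  b_only <- length(set_b) - both
  neither <- universe_size - both - a_only - b_only
  obs <- matrix(c(both, a_only, b_only, neither), 2L, 2L)
  n <- sum(obs)
  exp <- outer(rowSums(obs), colSums(obs)) / n
  cells <- exp > 0
  chisq <- sum((obs[cells] - exp[cells])^2 / exp[cells])
  list(observed = both,
       expected = length(set_a) * length(set_b) / universe_size,
       chisq = chisq,
       p_value = stats::pchisq(chisq, 1L, lower.tail = FALSE))
}

FEATURE_COLUMNS <- c("exon_length", "n_ese", "n_ess", "score_5ss",
                     "score_3ss", "branch_score", "ppt_score",
                     "upstream_intron_length", "downstream_intron_length",
                     "score_5ss_upstream_intron", "score_3ss_downstream_intron")

p_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
                              ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
}

#' Four-way feature comparison report
#'
#' For each sequence feature, computes group quartiles and the four
#' Wilcoxon rank-sum comparisons: A = species-A skip-enhanced vs their
#' paired species-B insensitive homologs; B = control A vs control B;
#' C = A skip-enhanced vs A controls; D = paired B insensitive vs B
#' controls. Raw p-values carry significance stars (0.05 / 0.01 / 0.001);
#' Benjamini-Hochberg adjusted values are reported alongside.
#'
#' @param h_skip,m_paired,h_ctrl,m_ctrl feature data.frames (as from
#'   [feature_table()]) for the four groups.
#' @param features feature column names to compare.
#' @return data.frame of class `comparison_report`, one row per feature.
#' @export
four_way_comparison <- function(h_skip, m_paired, h_ctrl, m_ctrl,
                                features = FEATURE_COLUMNS) {
  groups <- list(h_skip = h_skip, m_paired = m_paired,
                 h_ctrl = h_ctrl, m_ctrl = m_ctrl)
  for (g in names(groups)) {
    if (is.null(groups[[g]]) || nrow(groups[[g]]) == 0L) {
      stop("empty comparison group: ", g)
    }
  }
  rows <- lapply(features, function(f) {
    vals <- lapply(groups, function(g) g[[f]][!is.na(g[[f]])])
    q <- lapply(vals, function(v) {
      if (length(v)) stats::quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
      else rep(NA_real_, 3L)
    })
    pw <- function(a, b) {
      if (length(a) == 0L || length(b) == 0L) return(NA_real_)
      wilcoxon_rank_sum(a, b)
    }
    data.frame(
      feature = f,
      h_skip_median = q$h_skip[2L], m_paired_median = q$m_paired[2L],
      h_ctrl_median = q$h_ctrl[2L], m_ctrl_median = q$m_ctrl[2L],
      h_skip_q1 = q$h_skip[1L], h_skip_q3 = q$h_skip[3L],
      m_paired_q1 = q$m_paired[1L], m_paired_q3 = q$m_paired[3L],
      h_ctrl_q1 = q$h_ctrl[1L], h_ctrl_q3 = q$h_ctrl[3L],
      m_ctrl_q1 = q$m_ctrl[1L], m_ctrl_q3 = q$m_ctrl[3L],
      p_A = pw(vals$h_skip, vals$m_paired),
      p_B = pw(vals$h_ctrl, vals$m_ctrl),
      p_C = pw(vals$h_skip, vals$h_ctrl),
      p_D = pw(vals$m_paired, vals$m_ctrl),
      stringsAsFactors = FALSE)
  })
  rep <- do.call(rbind, rows)
  for (cmp in c("A", "B", "C", "D")) {
    p <- rep[[paste0("p_", cmp)]]
    rep[[paste0("stars_", cmp)]] <- p_stars(p)
    rep[[paste0("p_adj_", cmp)]] <- stats::p.adjust(p, method = "BH")
  }
  class(rep) <- c("comparison_report", "data.frame")
  rep
}
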