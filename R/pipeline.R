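# Pipeline orchestration: configuration, staged execution with plain-TSV
# inter-stage contracts, the filtering cascade, and the end-to-end run.

#' Pipeline configuration
#'
#' All thresholds default to the published values of the method: 8-nt
#' junction anchors, gene expression >= 16 RPK30M in at least one
#' replicate, three-junction total >= 4 RPK30M in every replicate,
#' response-class cutoff |delta-psi| = 0.05, strict skip cutoff
#' delta-psi <= -0.25 with t-test alpha 0.05, homology identity > 70 % and
#' coverage > 0.9.
#'
#' @param annotation_A,annotation_B GTF paths.
#' @param genome_A,genome_B FASTA paths.
#' @param junctions_A,junctions_B junction-count TSV paths.
#' @param design_A,design_B design TSV paths (need a `library_size` column
#'   for RPK30M).
#' @param homology gene homology TSV path.
#' @param motifs motif TSV path.
#' @param out_dir directory for stage outputs.
#' @param min_anchor,gene_min_rpk30m,junction_min_rpk30m,dpsi_cutoff,psi_low,strict_cutoff,alpha,min_identity,min_coverage,junction_feature_length
#'   thresholds (see description).
#' @param scheme enrichment [bin_scheme()].
#' @param seed RNG seed recorded in the run manifest.
#' @return object of class `pipeline_config`.
#' @export
pipeline_config <- function(annotation_A, annotation_B, genome_A, genome_B,
                            junctions_A, junctions_B, design_A, design_B,
                            homology, motifs, out_dir,
                            min_anchor = 8L, gene_min_rpk30m = 16,
                            junction_min_rpk30m = 4, dpsi_cutoff = 0.05,
                            psi_low = 0.05, strict_cutoff = -0.25,
                            alpha = 0.05, min_identity = 70,
                            min_coverage = 0.9,
                            junction_feature_length = 100,
                            scheme = bin_scheme(), seed = 1L) {
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Pipeline configuration from a synthetic-dataset bundle
#' @param bundle return value of [generate_dataset()].
#' @param out_dir stage-output directory.
#' @param ... threshold overrides passed to [pipeline_config()].
#' @export
pipeline_config_from_sim <- function(bundle, out_dir, ...) {
  p <- bundle$paths
  pipeline_config(annotation_A = p$annotation_A, annotation_B = p$annotation_B,
                  genome_A = p$genome_A, genome_B = p$genome_B,
                  junctions_A = p$junctions_A, junctions_B = p$junctions_B,
                  design_A = p$design_A, design_B = p$design_B,
                  homology = p$homology, motifs = p$motifs,
                  out_dir = out_dir, seed = bundle$config$seed, ...)
}

stage_path <- function(cfg, name) file.path(cfg$out_dir, name)

need_file <- function(path, stage) {
  if (!file.exists(path)) {
    stop("stage '", stage, "' is missing prerequisite file: ", path)
  }
  path
}

# Assign junction rows to genes by span containment (genes do not overlap
# in the supported annotations); returns per-gene, per-sample read totals.
gene_junction_totals <- function(models, junctions) {
  ex <- models$exons
  spans <- do.call(rbind, lapply(split(ex, ex$gene_id), function(g) {
    data.frame(gene_id = g$gene_id[1L], chrom = g$chrom[1L],
               start = min(g$start), end = max(g$end),
               stringsAsFactors = FALSE)
  }))
  spans$length <- spans$end - spans$start
  res <- list()
  for (ch in unique(spans$chrom)) {
    sp <- spans[spans$chrom == ch, , drop = FALSE]
    sp <- sp[order(sp$start), , drop = FALSE]
    jr <- junctions[junctions$chrom == ch, , drop = FALSE]
    if (nrow(jr) == 0L) next
    idx <- findInterval(jr$intron_start, sp$start)
    ok <- idx >= 1L & jr$intron_end <= sp$end[pmax(idx, 1L)]
    jr <- jr[ok, , drop = FALSE]
    jr$gene_id <- sp$gene_id[idx[ok]]
    res[[ch]] <- jr
  }
  jr <- do.call(rbind, res)
  totals <- stats::aggregate(count ~ gene_id + sample, data = jr, FUN = sum)
  list(totals = totals, spans = spans)
}

# Per-event quantification: psi records plus expression-filter and strict
# skip columns.
core_quantify <- function(events, junctions, design, models, cfg) {
  psi <- psi_table(events, junctions, design, cutoff = cfg$dpsi_cutoff,
                   psi_low = cfg$psi_low)
  samples <- attr(psi, "samples")
  if (!"library_size" %in% names(design)) {
    stop("design table needs a library_size column for RPK30M")
  }
  lib <- stats::setNames(design$library_size, design$sample)
  gj <- gene_junction_totals(models, junctions)
  gene_len <- stats::setNames(gj$spans$length, gj$spans$gene_id)
  gene_expr <- function(gene, sample) {
    cnt <- gj$totals$count[gj$totals$gene_id == gene &
                             gj$totals$sample == sample]
    cnt <- if (length(cnt)) sum(cnt) else 0
    rpk30m(cnt, gene_len[[gene]], lib[[sample]])
  }
  key <- paste(junctions$chrom, junctions$intron_start, junctions$intron_end,
               junctions$sample, sep = "\r")
  cnt_tab <- tapply(junctions$count, key, sum)
  jc <- function(chrom, s, e, sample) {
    v <- cnt_tab[paste(chrom, s, e, sample, sep = "\r")]
    if (is.na(v)) 0 else as.numeric(v)
  }
  n <- nrow(events)
  passes <- logical(n); strict <- logical(n)
  for (i in seq_len(n)) {
    ev <- events[i, ]
    ge <- vapply(samples, function(sm) gene_expr(ev$gene_id, sm), numeric(1))
    je <- vapply(samples, function(sm) {
      tot <- jc(ev$chrom, ev$coord1, ev$coord2, sm) +
        jc(ev$chrom, ev$coord3, ev$coord4, sm) +
        jc(ev$chrom, ev$coord1, ev$coord4, sm)
      rpk30m(tot, cfg$junction_feature_length, lib[[sm]])
    }, numeric(1))
    passes[i] <- passes_expression_filter(ge, je,
                                          gene_min = cfg$gene_min_rpk30m,
                                          junction_min = cfg$junction_min_rpk30m)
    pm <- as.numeric(psi[i, paste0("psi_", samples)])
    strict[i] <- !anyNA(pm) && strict_skip_call(
      pm[1:2], pm[3:4], dpsi_threshold = cfg$strict_cutoff, alpha = cfg$alpha)
  }
  psi$passes_filter <- passes
  psi$strict_skip <- strict & passes
  psi
}

#' Run a single pipeline stage
#'
#' Stages: `simulate` (needs `sim`, a [sim_config()], writes the dataset to
#' `dirname(config$annotation_A)`), `events`, `quantify`, `pair`,
#' `features`, `stats`, `enrich`. Each stage reads the TSV outputs of its
#' prerequisites from `config$out_dir` and writes its own; missing
#' prerequisites raise an error naming the file.
#'
#' @param stage stage name.
#' @param config `pipeline_config`.
#' @param sim optional [sim_config()] for the `simulate` stage.
#' @return invisibly, the paths written.
#' @export
run_stage <- function(stage, config,
                      sim = NULL) {
  cfg <- config
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  switch(stage,
    simulate = {
      if (is.null(sim)) stop("stage 'simulate' needs a sim_config")
      bundle <- generate_dataset(sim, dirname(cfg$annotation_A))
      invisible(unlist(bundle$paths))
    },
    events = {
      ev_a <- extract_skipping_events(read_gene_models(cfg$annotation_A))
      ev_b <- extract_skipping_events(read_gene_models(cfg$annotation_B))
      write_events(ev_a, stage_path(cfg, "events_A.tsv"))
      write_events(ev_b, stage_path(cfg, "events_B.tsv"))
      message("events: ", nrow(ev_a), " (A), ", nrow(ev_b), " (B)")
      invisible(stage_path(cfg, c("events_A.tsv", "events_B.tsv")))
    },
    quantify = {
      ev_a <- read_events(need_file(stage_path(cfg, "events_A.tsv"), stage))
      psi_a <- core_quantify(ev_a, read_junction_counts(cfg$junctions_A),
                             read_design(cfg$design_A),
                             read_gene_models(cfg$annotation_A), cfg)
      write_tsv_file(as.data.frame(psi_a), stage_path(cfg, "psi_A.tsv"))
      message("quantify: ", sum(psi_a$passes_filter), "/", nrow(psi_a),
              " events pass the expression filter; ",
              sum(psi_a$strict_skip), " strict skip-enhanced")
      invisible(stage_path(cfg, "psi_A.tsv"))
    },
    pair = {
      ev_a <- read_events(need_file(stage_path(cfg, "events_A.tsv"), stage))
      psi_a <- read_tsv_file(need_file(stage_path(cfg, "psi_A.tsv"), stage))
      junc_b <- read_junction_counts(cfg$junctions_B)
      wanted <- psi_a$event_id[psi_a$passes_filter &
                                 (psi_a$strict_skip |
                                    (!is.na(psi_a$dpsi_rep1) &
                                       psi_a$dpsi_rep1 == 0 &
                                       psi_a$dpsi_rep2 == 0))]
      pairs <- pair_homologs(ev_a[ev_a$event_id %in% wanted, ],
                             read_genome(cfg$genome_A),
                             read_genome(cfg$genome_B),
                             read_gene_models(cfg$annotation_B),
                             read_homology_table(cfg$homology), junc_b,
                             min_identity = cfg$min_identity,
                             min_coverage = cfg$min_coverage)
      write_tsv_file(as.data.frame(pairs), stage_path(cfg, "pairs.tsv"))
      ev_b <- pairs_as_events_b(pairs)
      psi_b <- psi_table(ev_b, junc_b, read_design(cfg$design_B),
                         cutoff = cfg$dpsi_cutoff, psi_low = cfg$psi_low)
      write_tsv_file(as.data.frame(psi_b), stage_path(cfg, "psi_B.tsv"))
      message("pair: ", nrow(pairs), " homologous pairs")
      invisible(stage_path(cfg, c("pairs.tsv", "psi_B.tsv")))
    },
    features = {
      ev_a <- read_events(need_file(stage_path(cfg, "events_A.tsv"), stage))
      pairs_path <- need_file(stage_path(cfg, "pairs.tsv"), stage)
      pairs <- utils::read.table(pairs_path, header = TRUE, sep = "\t",
                                 stringsAsFactors = FALSE)
      genome_a <- read_genome(cfg$genome_A)
      genome_b <- read_genome(cfg$genome_B)
      motifs <- read_motif_table(cfg$motifs)
      models_a <- read_gene_models(cfg$annotation_A)
      donor <- train_splice_model(models_a, genome_a, "donor")
      acceptor <- train_splice_model(models_a, genome_a, "acceptor")
      write_splice_model(donor, stage_path(cfg, "model_donor.tsv"))
      write_splice_model(acceptor, stage_path(cfg, "model_acceptor.tsv"))
      ft_a <- feature_table(ev_a, genome_a, motifs, donor, acceptor)
      write_tsv_file(ft_a, stage_path(cfg, "features_A.tsv"))
      if (nrow(pairs)) {
        class(pairs) <- c("homolog_pairs", "data.frame")
        ft_b <- feature_table(pairs_as_events_b(pairs), genome_b, motifs,
                              donor, acceptor)
        write_tsv_file(ft_b, stage_path(cfg, "features_B.tsv"))
      } else {
        write_tsv_file(feature_table(ev_a[0, ], genome_a, motifs, donor,
                                     acceptor) %||%
                         data.frame(event_id = character()),
                       stage_path(cfg, "features_B.tsv"))
      }
      invisible(stage_path(cfg, c("features_A.tsv", "features_B.tsv")))
    },
    stats = {
      psi_a <- read_tsv_file(need_file(stage_path(cfg, "psi_A.tsv"), stage))
      psi_b <- read_tsv_file(need_file(stage_path(cfg, "psi_B.tsv"), stage))
      pairs <- read_tsv_file(need_file(stage_path(cfg, "pairs.tsv"), stage))
      ft_a <- read_tsv_file(need_file(stage_path(cfg, "features_A.tsv"), stage))
      ft_b <- read_tsv_file(need_file(stage_path(cfg, "features_B.tsv"), stage))
      st <- core_stats(psi_a, psi_b, pairs, ft_a, ft_b)
      write_tsv_file(as.data.frame(st$comparisons),
                     stage_path(cfg, "comparisons.tsv"))
      jsonlite::write_json(
        list(observed = st$nine$observed, expected = st$nine$expected,
             chisq = st$nine$chisq, df = st$nine$df,
             p_value = st$nine$p_value, n = st$nine$n),
        stage_path(cfg, "nine_category.json"), auto_unbox = TRUE, digits = NA,
        matrix = "rowmajor", pretty = TRUE)
      invisible(stage_path(cfg, c("comparisons.tsv", "nine_category.json")))
    },
    enrich = {
      psi_a <- read_tsv_file(need_file(stage_path(cfg, "psi_A.tsv"), stage))
      ft_a <- read_tsv_file(need_file(stage_path(cfg, "features_A.tsv"), stage))
      en <- core_enrich(psi_a, ft_a, cfg)
      write_tsv_file(as.data.frame(en$rows), stage_path(cfg, "enrichment.tsv"))
      write_enrichment_report(en$report,
                              stage_path(cfg, "enrichment_report.json"))
      invisible(stage_path(cfg, c("enrichment.tsv", "enrichment_report.json")))
    },
    stop("unknown stage: ", stage)
  )
}

# Four-way comparisons + nine-category table from stage tables
core_stats <- function(psi_a, psi_b, pairs, ft_a, ft_b) {
  if (nrow(pairs) == 0L) stop("no homologous pairs; cannot run stats stage")
  cls_a <- stats::setNames(psi_a$response_class, psi_a$event_id)
  cls_b <- stats::setNames(psi_b$response_class, psi_b$event_id)
  strict_a <- stats::setNames(psi_a$strict_skip, psi_a$event_id)
  pairs$class_A <- cls_a[pairs$event_id_A]
  pairs$class_B <- cls_b[pairs$event_id_B]
  pairs$strict_A <- strict_a[pairs$event_id_A]
  dz <- function(psi, ids) {
    ok <- !is.na(psi$dpsi_rep1) & !is.na(psi$dpsi_rep2) &
      psi$dpsi_rep1 == 0 & psi$dpsi_rep2 == 0
    ids %in% psi$event_id[ok]
  }
  ctrl <- pairs[dz(psi_a, pairs$event_id_A) & dz(psi_b, pairs$event_id_B), ]
  hs <- pairs[which(pairs$strict_A), ]
  hs_div <- hs[hs$class_B == "no_change", ]
  ftab <- function(ft, ids) ft[match(ids, ft$event_id), , drop = FALSE]
  comparisons <- four_way_comparison(
    h_skip = ftab(ft_a, unique(hs_div$event_id_A)),
    m_paired = ftab(ft_b, unique(hs_div$event_id_B)),
    h_ctrl = ftab(ft_a, unique(ctrl$event_id_A)),
    m_ctrl = ftab(ft_b, unique(ctrl$event_id_B)))
  to3 <- function(x) ifelse(x == "no_change", "no_effect", x)
  ok <- pairs$class_A %in% c("skip", "no_change", "inclusion") &
    pairs$class_B %in% c("skip", "no_change", "inclusion")
  nine <- nine_category_analysis(to3(pairs$class_A[ok]), to3(pairs$class_B[ok]))
  list(comparisons = comparisons, nine = nine, pairs = pairs,
       control_pairs = ctrl, divergent_pairs = hs_div,
       n_strict_with_homolog = length(unique(hs$event_id_A)))
}

core_enrich <- function(psi_a, ft_a, cfg) {
  keep <- psi_a$passes_filter
  ids <- psi_a$event_id[keep]
  ft <- ft_a[match(ids, ft_a$event_id), , drop = FALSE]
  bins <- assign_bin(ft$exon_length, ft$n_ese, ft$n_ess, ft$ppt_score,
                     cfg$scheme)
  hits <- psi_a$strict_skip[keep]
  rows <- enrichment_analysis(bins, hits, scheme = cfg$scheme)
  list(rows = rows, report = decision_tree_report(rows, cfg$scheme),
       n_binned = sum(!is.na(bins)))
}

#' Run the full pipeline
#'
#' Executes event extraction, quantification and response classification,
#' homologous-exon pairing, feature extraction, the statistical comparisons
#' and the enrichment analysis, writing each stage's TSV under
#' `config$out_dir`, and returns the assembled results with the filtering
#' cascade (events left after each step) and a run manifest.
#'
#' @param config `pipeline_config`.
#' @return object of class `cassex_run`: list with events_A, psi_A, pairs,
#'   psi_B, features_A, features_B, comparisons, nine_category,
#'   control_pairs, divergent_pairs, enrichment, enrichment_report,
#'   cascade, manifest.
#' @export
run_full <- function(config) {
  cfg <- config
  for (p in c("annotation_A", "annotation_B", "genome_A", "genome_B",
              "junctions_A", "junctions_B", "design_A", "design_B",
              "homology", "motifs")) {
    if (!file.exists(cfg[[p]])) stop("missing input: ", p, " (", cfg[[p]], ")")
  }
  set.seed(cfg$seed)
  run_stage("events", cfg)
  run_stage("quantify", cfg)
  run_stage("pair", cfg)
  run_stage("features", cfg)
  run_stage("stats", cfg)
  run_stage("enrich", cfg)
  events_a <- read_events(stage_path(cfg, "events_A.tsv"))
  psi_a <- read_tsv_file(stage_path(cfg, "psi_A.tsv"))
  psi_b <- read_tsv_file(stage_path(cfg, "psi_B.tsv"))
  pairs <- read_tsv_file(stage_path(cfg, "pairs.tsv"))
  ft_a <- read_tsv_file(stage_path(cfg, "features_A.tsv"))
  ft_b <- read_tsv_file(stage_path(cfg, "features_B.tsv"))
  st <- core_stats(psi_a, psi_b, pairs, ft_a, ft_b)
  en <- core_enrich(psi_a, ft_a, cfg)
  cascade <- data.frame(
    stage = c("annotated_events", "expressed", "strict_skip_enhanced",
              "with_homolog", "divergent_pairs"),
    n = c(nrow(events_a), sum(psi_a$passes_filter), sum(psi_a$strict_skip),
          st$n_strict_with_homolog, nrow(st$divergent_pairs)),
    stringsAsFactors = FALSE)
  write_tsv_file(cascade, stage_path(cfg, "cascade.tsv"))
  manifest <- list(package_version = as.character(utils::packageVersion("cassex")),
                   seed = cfg$seed,
                   thresholds = cfg[c("min_anchor", "gene_min_rpk30m",
                                      "junction_min_rpk30m", "dpsi_cutoff",
                                      "psi_low", "strict_cutoff", "alpha",
                                      "min_identity", "min_coverage")])
  jsonlite::write_json(manifest, stage_path(cfg, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  structure(list(events_A = events_a, psi_A = psi_a, pairs = st$pairs,
                 psi_B = psi_b, features_A = ft_a, features_B = ft_b,
                 comparisons = st$comparisons, nine_category = st$nine,
                 control_pairs = st$control_pairs,
                 divergent_pairs = st$divergent_pairs,
                 enrichment = en$rows, enrichment_report = en$report,
                 cascade = cascade, manifest = manifest),
            class = "cassex_run")
}

#' @export
print.cassex_run <- function(x, ...) {
  cat("Comparative cassette-exon run\n")
  cat("Filtering cascade:\n")
  for (i in seq_len(nrow(x$cascade))) {
    cat(sprintf("  %-24s %6d\n", x$cascade$stage[i], x$cascade$n[i]))
  }
  top <- x$enrichment[x$enrichment$reportable &
                        !is.na(x$enrichment$enrichment), ]
  if (nrow(top)) {
    top <- top[order(-top$enrichment), ][1L, ]
    cat(sprintf("Top enriched bin: %s (%.2fx, p = %.3g)\n",
                top$bin, top$enrichment, top$p_value))
  }
  invisible(x)
}
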