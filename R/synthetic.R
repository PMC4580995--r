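# Synthetic two-species dataset generator. Emulates the study conditions of
# a two-condition (control vs splicing-modulator treatment), two-replicate
# RNA-seq comparison between two species: toy genomes whose genes carry one
# cassette exon each (inclusion + skipping transcript annotated), a gene
# homology table, a splicing-factor motif table, per-sample junction counts,
# and a ground-truth table of which exons are modulator-sensitive.
#
# Sensitivity is generated from sequence features: sensitive exons are
# short (< 65 nt), have few ESEs (< 5) and ESSs, and a weak polypyrimidine
# tract (target score in [10, 20)); their species-B homologs are insensitive
# with strong tracts, mirroring the biology the downstream comparisons are
# designed to detect.

#' Simulation configuration
#'
#' @param n_genes number of genes per species.
#' @param n_cassette_per_gene cassette exons per gene (currently 1).
#' @param frac_sensitive fraction of species-A cassette exons that respond
#'   to the treatment.
#' @param identity_target exonic sequence identity between homologs
#'   (default 0.936).
#' @param effect_size_skip delta-psi shift of sensitive exons (negative,
#'   default -0.3).
#' @param replicate_noise_sd sd of replicate noise on logit(psi)
#'   (default 0.1, calibrated so baseline |delta-psi| stays mostly within
#'   0.05).
#' @param library_size total mapped reads per sample (default 3e7).
#' @param seed integer RNG seed.
#' @return object of class `sim_config`.
#' @export
sim_config <- function(n_genes = 500L, n_cassette_per_gene = 1L,
                       frac_sensitive = 0.05, identity_target = 0.936,
                       effect_size_skip = -0.3, replicate_noise_sd = 0.1,
                       library_size = 3e7, seed = 1L) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (n_cassette_per_gene != 1L) stop("only one cassette exon per gene is supported")
  if (frac_sensitive < 0 || frac_sensitive > 1) stop("frac_sensitive must be in [0,1]")
  if (identity_target < 0 || identity_target > 1) stop("identity_target must be in [0,1]")
  if (effect_size_skip >= 0) stop("effect_size_skip must be negative")
  if (replicate_noise_sd < 0) stop("replicate_noise_sd must be >= 0")
  if (library_size <= 0) stop("library_size must be positive")
  structure(list(n_genes = as.integer(n_genes),
                 n_cassette_per_gene = 1L,
                 frac_sensitive = frac_sensitive,
                 identity_target = identity_target,
                 effect_size_skip = effect_size_skip,
                 replicate_noise_sd = replicate_noise_sd,
                 library_size = library_size,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Mutate a sequence to a target point-substitution identity
#'
#' Substitutes `round((1 - identity_target) * nchar(seq))` positions, each
#' to a different base, so the returned sequence has exactly the target
#' identity (up to rounding) and the same length.
#'
#' @param seq non-empty ACGT string.
#' @param identity_target fraction in \[0, 1\].
#' @param seed optional seed for reproducibility (caller RNG untouched).
#' @return mutated sequence.
#' @export
mutate_homolog <- function(seq, identity_target, seed = NULL) {
  if (!nzchar(seq)) stop("empty sequence")
  if (grepl("[^ACGT]", seq)) stop("sequence must be over ACGT")
  if (identity_target < 0 || identity_target > 1) {
    stop("identity_target must be in [0,1]")
  }
  run <- function() {
    bases <- strsplit(seq, "")[[1L]]
    n_mut <- round((1 - identity_target) * length(bases))
    if (n_mut == 0L) return(seq)
    pos <- sample(length(bases), n_mut)
    for (p in pos) {
      bases[p] <- sample(setdiff(c("A", "C", "G", "T"), bases[p]), 1L)
    }
    paste(bases, collapse = "")
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Fixed splicing-factor motif table. Every motif contains >= 2 G so that
# G-free filler sequence in generated exons cannot create accidental hits.
default_motif_table <- function() {
  data.frame(
    factor = c("SRSF1", "SRSF5", "hnRNPA1", "hnRNPH"),
    motif = c("GGAGGA", "GAAGAA", "TAGGT", "TGTGG"),
    score = c(4.0, 2.5, -3.5, -2.5),
    stringsAsFactors = FALSE)
}

# --- sequence building blocks (transcript orientation) ---------------------

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  if (n <= 0L) return("")
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# 100-nt upstream-intron window with a planted branch heptamer (TTCTAAC,
# branch A at heptamer position 6) and a polypyrimidine region composed to
# hit `target` = (#pyrimidines + longest pyrimidine run) exactly. The
# window is adenosine-free outside the heptamer so the branch-point scan
# lands on the planted site, and ends with the acceptor CAG.
make_ppt_window <- function(target) {
  stopifnot(target >= 4)
  r <- min(max(1L, round(target / 3)), floor((target - 1) / 2))
  k <- target - 1L - 2L * r
  content <- paste0("C", "G", strrep("T", r), "G", strrep("CG", k))
  region_len <- max(25L, nchar(content))
  region <- paste0(content, strrep("G", region_len - nchar(content)))
  bp <- 97L - region_len
  stopifnot(bp >= 7L)
  prefix <- rand_seq(bp - 6L, alphabet = c("C", "G", "T"))
  win <- paste0(prefix, "TTCTAA", region, "CAG")
  stopifnot(nchar(win) == 100L)
  win
}

# Exon with exactly n_ese / n_ess motif occurrences: motifs are planted with
# C spacers inside a G-free filler body; first 3 nt "ACC", last 3 nt "CAG"
# (donor exonic consensus).
make_exon <- function(len, n_ese, n_ess, motifs) {
  ese_pool <- motifs$motif[motifs$score > 0]
  ess_pool <- motifs$motif[motifs$score < 0]
  planted <- c(if (n_ese > 0) sample(ese_pool, n_ese, replace = TRUE),
               if (n_ess > 0) sample(ess_pool, n_ess, replace = TRUE))
  if (length(planted)) planted <- sample(planted)
  body_len <- len - 6L
  blocks <- if (length(planted)) paste0("C", planted, "C") else character(0)
  need <- sum(nchar(blocks))
  if (need > body_len) stop("exon too short for requested motif counts")
  filler_total <- body_len - need
  n_gaps <- length(blocks) + 1L
  cuts <- if (filler_total > 0) {
    tabulate(sample(n_gaps, filler_total, replace = TRUE), nbins = n_gaps)
  } else rep(0L, n_gaps)
  parts <- character(0)
  for (i in seq_len(n_gaps)) {
    parts <- c(parts, rand_seq(cuts[i], alphabet = c("A", "C", "T")))
    if (i <= length(blocks)) parts <- c(parts, blocks[i])
  }
  paste0("ACC", paste(parts, collapse = ""), "CAG")
}

# Cap motif counts to what fits in the exon body (with spacers)
fit_motif_counts <- function(len, n_ese, n_ess, motifs) {
  max_ese <- max(nchar(motifs$motif[motifs$score > 0])) + 2L
  max_ess <- max(nchar(motifs$motif[motifs$score < 0])) + 2L
  body <- len - 6L
  while (n_ese * max_ese + n_ess * max_ess > body && n_ess > 0L) n_ess <- n_ess - 1L
  while (n_ese * max_ese > body && n_ese > 0L) n_ese <- n_ese - 1L
  c(n_ese = n_ese, n_ess = n_ess)
}

EXON_UP_LEN <- 120L
EXON_DOWN_LEN <- 130L
INTRON1_LEN <- 160L   # last 100 nt = controlled upstream window
INTRON2_LEN <- 130L
SPACER_LEN <- 200L

# One gene in transcript orientation. Returns sequence plus transcript-space
# exon intervals.
build_gene_seq <- function(cassette_seq, ppt_window, up_seq = NULL,
                           down_seq = NULL) {
  up <- up_seq %||% paste0("ACC", rand_seq(EXON_UP_LEN - 6L), "CAG")
  down <- down_seq %||% paste0("ACC", rand_seq(EXON_DOWN_LEN - 3L))
  intron1 <- paste0("GTAAGT", rand_seq(INTRON1_LEN - 6L - 100L), ppt_window)
  intron2 <- paste0("GTAAGT", rand_seq(INTRON2_LEN - 6L - 20L),
                    "TCTTTCTTTTCTTTCTT", "CAG")
  le <- nchar(cassette_seq)
  seq <- paste0(up, intron1, cassette_seq, intron2, down)
  tx <- list(
    up = c(0L, EXON_UP_LEN),
    cassette = c(EXON_UP_LEN + INTRON1_LEN, EXON_UP_LEN + INTRON1_LEN + le),
    down = c(EXON_UP_LEN + INTRON1_LEN + le + INTRON2_LEN,
             EXON_UP_LEN + INTRON1_LEN + le + INTRON2_LEN + EXON_DOWN_LEN))
  list(seq = seq, tx = tx, up_seq = up, down_seq = down)
}

# Map a transcript-space half-open interval to genomic coordinates
map_interval <- function(iv, offset, gene_len, strand) {
  if (strand == "+") c(offset + iv[1L], offset + iv[2L])
  else c(offset + gene_len - iv[2L], offset + gene_len - iv[1L])
}

write_gtf <- function(exons, path) {
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s";',
                      exons$gene_id, exons$transcript_id)
  lines <- sprintf("%s\tcassex\texon\t%d\t%d\t.\t%s\t.\t%s",
                   exons$chrom, exons$start + 1L, exons$end, exons$strand,
                   attr_str)
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  writeLines(lines, path)
  invisible(path)
}

clip01 <- function(x, lo = 0.001, hi = 0.999) pmin(hi, pmax(lo, x))

#' Generate the synthetic two-species dataset
#'
#' Writes, under `out_dir`: genome FASTAs (`genome_A.fa`, `genome_B.fa`),
#' annotations with one inclusion and one skipping transcript per gene
#' (`annotation_A.gtf`, `annotation_B.gtf`), a gene homology table
#' (`homology.tsv`), a motif table (`motifs.tsv`), per-species junction
#' counts over 2 conditions x 2 replicates (`junctions_A.tsv`,
#' `junctions_B.tsv`), design tables (`design_A.tsv`, `design_B.tsv`) and a
#' ground-truth table (`truth.tsv`).
#'
#' Junction counts are multinomial draws per gene with weights
#' (psi, psi, 1 - psi) over (upstream-inclusion, downstream-inclusion,
#' skip); replicate noise is applied on logit(psi) and clipped to
#' (0.001, 0.999). A fraction of insensitive events is constitutively
#' included (psi = 1 exactly, so both replicates have delta-psi = 0),
#' providing the strict control set.
#'
#' @param config a [sim_config()].
#' @param out_dir output directory (created).
#' @return invisibly, a list with `paths` (named file paths), `truth`
#'   (data.frame) and `config`.
#' @export
generate_dataset <- function(config, out_dir) {
  stopifnot(inherits(config, "sim_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  motifs <- default_motif_table()
  res <- with_seed(config$seed, {
    n <- config$n_genes
    n_sens <- round(config$frac_sensitive * n)
    sens <- seq_len(n) %in% sample(n, n_sens)
    # feature parameters, species A
    le <- integer(n); ese <- integer(n); ess <- integer(n); ppt_a <- integer(n)
    ppt_b <- integer(n); constitutive <- logical(n)
    for (i in seq_len(n)) {
      if (sens[i]) {
        le[i] <- sample(45:63, 1L)
        cnt <- fit_motif_counts(le[i], sample(0:4, 1L), sample(0:6, 1L), motifs)
        ppt_a[i] <- sample(11:18, 1L)
        ppt_b[i] <- sample(25:40, 1L)   # B homolog insensitive: strong tract
      } else {
        le[i] <- if (stats::runif(1) < 0.5) sample(45:63, 1L) else sample(70:240, 1L)
        body <- le[i] - 6L
        ese_max <- min(22L, floor(0.6 * body / 8L))
        ess_max <- max(0L, min(26L, floor((body - 8L * min(4L, ese_max)) / 7L)))
        cnt <- fit_motif_counts(le[i], sample(0:max(0L, ese_max), 1L),
                                sample(0:ess_max, 1L), motifs)
        u <- stats::runif(1)
        ppt_a[i] <- if (u < 0.2) sample(4:8, 1L) else if (u < 0.35)
          sample(11:18, 1L) else if (u < 0.7) sample(21:28, 1L) else
            sample(31:45, 1L)
        ppt_b[i] <- ppt_a[i]
        constitutive[i] <- stats::runif(1) < 0.3
      }
      ese[i] <- cnt["n_ese"]; ess[i] <- cnt["n_ess"]
    }
    # true psi
    psi_ctrl <- numeric(n); psi_trt <- numeric(n)
    for (i in seq_len(n)) {
      if (sens[i]) {
        psi_ctrl[i] <- stats::runif(1, 0.7, 0.9)
        psi_trt[i] <- max(0.05, psi_ctrl[i] + config$effect_size_skip)
      } else if (constitutive[i]) {
        psi_ctrl[i] <- 1; psi_trt[i] <- 1
      } else {
        psi_ctrl[i] <- stats::runif(1, 0.35, 0.95)
        psi_trt[i] <- psi_ctrl[i]
      }
    }
    # build genomes
    gene_id_a <- sprintf("gA%04d", seq_len(n))
    gene_id_b <- sprintf("gB%04d", seq_len(n))
    strands <- rep(c("+", "-"), length.out = n)
    build_species <- function(species) {
      chrom <- paste0("chr", species)
      offset <- 0L
      chrom_parts <- character(0)
      exon_rows <- list()
      cassette_info <- list()
      for (i in seq_len(n)) {
        if (species == "A") {
          cas <- make_exon(le[i], ese[i], ess[i], motifs)
          win <- make_ppt_window(ppt_a[i])
          g <- build_gene_seq(cas, win)
          cassette_seqs_a[[i]] <<- cas
          up_seqs_a[[i]] <<- g$up_seq
          down_seqs_a[[i]] <<- g$down_seq
        } else {
          cas <- mutate_homolog(cassette_seqs_a[[i]], config$identity_target)
          win <- make_ppt_window(ppt_b[i])
          g <- build_gene_seq(
            cas, win,
            up_seq = mutate_homolog(up_seqs_a[[i]], config$identity_target),
            down_seq = mutate_homolog(down_seqs_a[[i]], config$identity_target))
        }
        gene_len <- nchar(g$seq)
        gseq <- if (strands[i] == "-") revcomp(g$seq) else g$seq
        gid <- if (species == "A") gene_id_a[i] else gene_id_b[i]
        iv <- lapply(g$tx, map_interval, offset = offset,
                     gene_len = gene_len, strand = strands[i])
        for (tx_id in c("t1", "t2")) {
          use <- if (tx_id == "t1") c("up", "cassette", "down") else c("up", "down")
          for (ex in use) {
            exon_rows[[length(exon_rows) + 1L]] <- data.frame(
              gene_id = gid, transcript_id = paste0(gid, ".", tx_id),
              chrom = chrom, strand = strands[i],
              start = iv[[ex]][1L], end = iv[[ex]][2L],
              stringsAsFactors = FALSE)
          }
        }
        coords <- if (strands[i] == "+") {
          c(iv$up[2L], iv$cassette[1L], iv$cassette[2L], iv$down[1L])
        } else {
          # genomic-left flanking exon is the transcript's downstream exon
          c(iv$down[2L], iv$cassette[1L], iv$cassette[2L], iv$up[1L])
        }
        cassette_info[[i]] <- list(gene_id = gid, seq = cas, coords = coords)
        chrom_parts <- c(chrom_parts, gseq, rand_seq(SPACER_LEN))
        offset <- offset + gene_len + SPACER_LEN
      }
      list(chrom = chrom,
           genome = paste(chrom_parts, collapse = ""),
           exons = do.call(rbind, exon_rows),
           cassettes = cassette_info)
    }
    cassette_seqs_a <- vector("list", n)
    up_seqs_a <- vector("list", n)
    down_seqs_a <- vector("list", n)
    sp_a <- build_species("A")
    sp_b <- build_species("B")
    # junction counts: 4 samples per species
    design <- data.frame(sample = c("ctrl_1", "ctrl_2", "treat_1", "treat_2"),
                         condition = c("control", "control", "treatment",
                                       "treatment"),
                         replicate = c(1L, 2L, 1L, 2L),
                         library_size = config$library_size,
                         stringsAsFactors = FALSE)
    depth <- round(config$library_size / n)
    sim_counts <- function(sp, species) {
      rows <- list()
      for (i in seq_len(n)) {
        cc <- sp$cassettes[[i]]$coords
        for (s in seq_len(nrow(design))) {
          # species-B homologs are insensitive: treatment psi = control psi
          base <- if (design$condition[s] == "control" || species == "B")
            psi_ctrl[i] else psi_trt[i]
          psi <- if (constitutive[i] && !sens[i]) 1 else {
            clip01(stats::plogis(stats::qlogis(clip01(base)) +
                                   stats::rnorm(1, 0, config$replicate_noise_sd)))
          }
          cts <- stats::rmultinom(1, depth, c(psi, psi, 1 - psi))[, 1L]
          rows[[length(rows) + 1L]] <- data.frame(
            chrom = sp$chrom,
            intron_start = c(cc[1L], cc[3L], cc[1L]),
            intron_end = c(cc[2L], cc[4L], cc[4L]),
            strand = strands[i],
            sample = design$sample[s],
            count = cts,
            stringsAsFactors = FALSE)
        }
      }
      do.call(rbind, rows)
    }
    junc_a <- sim_counts(sp_a, "A")
    junc_b <- sim_counts(sp_b, "B")
    # truth table
    scheme <- bin_scheme()
    truth <- list()
    for (i in seq_len(n)) {
      for (species in c("A", "B")) {
        sp <- if (species == "A") sp_a else sp_b
        cc <- sp$cassettes[[i]]$coords
        cnt <- count_motifs(sp$cassettes[[i]]$seq, motifs)
        ppt <- if (species == "A") ppt_a[i] else ppt_b[i]
        truth[[length(truth) + 1L]] <- data.frame(
          event_id = event_id(sp$cassettes[[i]]$gene_id, cc[1L], cc[2L],
                              cc[3L], cc[4L]),
          gene_id = sp$cassettes[[i]]$gene_id,
          species = species,
          sensitive = if (species == "A") sens[i] else FALSE,
          true_psi_ctrl = psi_ctrl[i],
          true_psi_treat = if (species == "A") psi_trt[i] else psi_ctrl[i],
          feature_class = assign_bin(le[i], cnt["n_ese"], cnt["n_ess"], ppt,
                                     scheme),
          exon_length = le[i], n_ese = unname(cnt["n_ese"]),
          n_ess = unname(cnt["n_ess"]), ppt_target = ppt,
          constitutive = constitutive[i],
          stringsAsFactors = FALSE)
      }
    }
    truth <- do.call(rbind, truth)
    # write everything
    paths <- list(
      genome_A = file.path(out_dir, "genome_A.fa"),
      genome_B = file.path(out_dir, "genome_B.fa"),
      annotation_A = file.path(out_dir, "annotation_A.gtf"),
      annotation_B = file.path(out_dir, "annotation_B.gtf"),
      homology = file.path(out_dir, "homology.tsv"),
      motifs = file.path(out_dir, "motifs.tsv"),
      junctions_A = file.path(out_dir, "junctions_A.tsv"),
      junctions_B = file.path(out_dir, "junctions_B.tsv"),
      design_A = file.path(out_dir, "design_A.tsv"),
      design_B = file.path(out_dir, "design_B.tsv"),
      truth = file.path(out_dir, "truth.tsv"))
    ga <- Biostrings::DNAStringSet(stats::setNames(sp_a$genome, sp_a$chrom))
    gb <- Biostrings::DNAStringSet(stats::setNames(sp_b$genome, sp_b$chrom))
    Biostrings::writeXStringSet(ga, paths$genome_A)
    Biostrings::writeXStringSet(gb, paths$genome_B)
    write_gtf(sp_a$exons, paths$annotation_A)
    write_gtf(sp_b$exons, paths$annotation_B)
    write_tsv_file(data.frame(gene_id_A = gene_id_a, gene_id_B = gene_id_b),
                   paths$homology)
    write_tsv_file(motifs, paths$motifs)
    write_tsv_file(junc_a, paths$junctions_A)
    write_tsv_file(junc_b, paths$junctions_B)
    write_tsv_file(design, paths$design_A)
    write_tsv_file(design, paths$design_B)
    write_tsv_file(truth, paths$truth)
    list(paths = paths, truth = truth, config = config)
  })
  invisible(res)
}
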