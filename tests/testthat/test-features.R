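# A fully hand-written toy locus: one plus-strand event with known sequence,
# so every extracted window can be checked by string slicing.
toy_event_genome <- function() {
  set.seed(99)
  chrom <- paste(sample(c("A", "C", "G", "T"), 1000, TRUE), collapse = "")
  genome <- toy_genome(chr1 = chrom)
  ev <- data.frame(event_id = "e1", gene_id = "g1", chrom = "chr1",
                   strand = "+", coord1 = 100, coord2 = 300, coord3 = 364,
                   coord4 = 600, stringsAsFactors = FALSE)
  list(genome = genome, event = ev, seq = chrom)
}

test_that("splice-site windows equal hand-extracted substrings (plus strand)", {
  tg <- toy_event_genome()
  s <- tg$seq
  w <- splice_site_sequences(tg$event, tg$genome)
  # donor: 3 exonic (362..364) + 6 intronic (365..370), 1-based substring
  expect_equal(w$donor, substr(s, 362, 370))
  # acceptor: 20 intronic (281..300) + 3 exonic (301..303)
  expect_equal(w$acceptor, substr(s, 281, 303))
  # upstream window: 100 nt before the cassette acceptor
  expect_equal(w$upstream_window, substr(s, 201, 300))
  expect_equal(w$exon, substr(s, 301, 364))
  expect_equal(w$donor_flank, substr(s, 98, 106))
  expect_equal(w$acceptor_flank, substr(s, 581, 603))
  expect_false(w$truncated)
})

test_that("minus-strand windows are reverse complements of the mirrored slices", {
  tg <- toy_event_genome()
  ev <- tg$event; ev$strand <- "-"
  w <- splice_site_sequences(ev, tg$genome)
  s <- tg$seq
  expect_equal(w$donor, revcomp(substr(s, 295, 303)))
  expect_equal(w$acceptor, revcomp(substr(s, 362, 384)))
  expect_equal(w$upstream_window, revcomp(substr(s, 365, 464)))
  expect_equal(w$exon, revcomp(substr(s, 301, 364)))
})

test_that("short upstream introns produce truncated, flagged windows", {
  tg <- toy_event_genome()
  ev <- tg$event; ev$coord1 <- 240   # upstream intron of 60 nt
  w <- splice_site_sequences(ev, tg$genome)
  expect_equal(nchar(w$upstream_window), 60L)
  expect_true(w$truncated)
})

test_that("position-weight scoring matches its closed form", {
  expect_equal(score_splice_site("CAGGTAAGT", uniform_splice_model(9)), 0)
  # every consensus base twice the background: score = 9 * log2(2) = 9
  cons <- strsplit("CAGGTAAGT", "")[[1]]
  pwm <- matrix(1 / 6, 4, 9, dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in 1:9) pwm[cons[j], j] <- 0.5
  expect_equal(score_splice_site("CAGGTAAGT", splice_model(pwm)), 9)
  expect_error(score_splice_site("CAGGTAAG", splice_model(pwm)), "length")
  expect_error(score_splice_site("CAGGTAANT", splice_model(pwm)), "ACGT")
})

test_that("splice models round-trip through their text format", {
  tg <- toy_event_genome()
  m <- toy_models(list(g1 = list(
    t1 = list(c(100, 300), c(300 + 0, 364), c(600, 700)))))
  # train on a tiny annotation; model must reproduce scores after reload
  mod <- train_splice_model(m, tg$genome, "donor")
  path <- tempfile(fileext = ".tsv")
  write_splice_model(mod, path)
  mod2 <- read_splice_model(path)
  expect_equal(score_splice_site("CAGGTAAGT", mod2),
               score_splice_site("CAGGTAAGT", mod))
})

test_that("motif counting includes overlaps and splits by score sign", {
  tab <- data.frame(factor = "F", motif = "GAAGAA", score = 1)
  expect_equal(unname(count_motifs("GAAGAAGAA", tab)["n_ese"]), 2L)
  expect_equal(unname(count_motifs("CCCCCC", tab)), c(0L, 0L))
  neg <- data.frame(factor = "S", motif = "TAGGT", score = -2)
  expect_equal(unname(count_motifs("AATAGGTAA", neg)["n_ess"]), 1L)
  expect_equal(unname(count_motifs("ACGT", NULL)), c(0L, 0L))
  # additive over disjoint motif tables
  both <- rbind(tab, neg)
  seqx <- "GAAGAAGAATAGGT"
  expect_equal(count_motifs(seqx, both),
               count_motifs(seqx, tab) + count_motifs(seqx, neg))
})

test_that("branch-point scan matches exhaustive heptamer scoring", {
  win <- paste0("TTTTTCTAAC", strrep("T", 27), "AG")
  bp <- predict_branch_point(win)
  # independent exhaustive scan over all A-at-position-6 heptamers
  pwm <- cassex:::bp_default_pwm()
  L <- nchar(win); bases <- strsplit(win, "")[[1]]
  cand <- data.frame(pos = integer(), score = numeric())
  for (i in seq_len(L - 6)) {
    p6 <- i + 5
    if (p6 > L - 3 || bases[p6] != "A") next
    idx <- match(bases[i:(i + 6)], c("A", "C", "G", "T"))
    cand <- rbind(cand, data.frame(pos = p6,
                                   score = sum(log2(pwm[cbind(idx, 1:7)] / 0.25))))
  }
  best <- cand[order(-cand$score, -cand$pos), ][1, ]
  expect_equal(bp$bp_pos, best$pos)
  expect_equal(bp$score, best$score)
  # the predicted branch adenosine is the branch A of the CTAAC consensus
  expect_equal(substr(win, bp$bp_pos - 3, bp$bp_pos + 1), "CTAAC")
})

test_that("branch-point edge cases: no adenosine, ties, short windows", {
  expect_null(predict_branch_point(paste(rep("T", 50), collapse = "")))
  expect_null(predict_branch_point("TTTTT"))
  # two identical candidates: the 3'-most wins
  win <- paste0("GGG", "TTCTAAC", "GGG", "TTCTAAC", strrep("G", 20))
  bp <- predict_branch_point(win)
  expect_equal(bp$bp_pos, 19)
})

test_that("polypyrimidine tract score = pyrimidine count + longest run", {
  expect_equal(ppt_score(paste0("AAAAAA", "GAGAGAGAGA", "TAG"), 6), 0)
  expect_equal(ppt_score(paste0("AAAAAA", "TTTTTTTTTT", "TAG"), 6), 20)
  expect_equal(ppt_score(paste0("AAAAAA", "TCAGTT", "CAG"), 6), 6)
  expect_error(ppt_score("ACGT", 9), "outside")
})

test_that("ppt score is monotone under purine-to-pyrimidine substitution", {
  withr::with_seed(3, {
    for (i in 1:25) {
      region <- sample(c("A", "C", "G", "T"), 30, TRUE)
      win <- paste0("AAAAAA", paste(region, collapse = ""), "CAG")
      s0 <- ppt_score(win, 6)
      pur <- which(region %in% c("A", "G") &
                     seq_along(region) > 0)
      if (!length(pur)) next
      j <- sample(pur, 1)
      region[j] <- sample(c("C", "T"), 1)
      win2 <- paste0("AAAAAA", paste(region, collapse = ""), "CAG")
      expect_gte(ppt_score(win2, 6), s0)
    }
  })
})

test_that("feature vectors agree per-field with hand-computed oracles", {
  b <- generate_dataset(sim_config(n_genes = 6, frac_sensitive = 0.5, seed = 4),
                        file.path(tempdir(), "ftsim"))
  genome <- read_genome(b$paths$genome_A)
  motifs <- read_motif_table(b$paths$motifs)
  models <- read_gene_models(b$paths$annotation_A)
  ev <- extract_skipping_events(models)
  don <- train_splice_model(models, genome, "donor")
  acc <- train_splice_model(models, genome, "acceptor")
  ft <- feature_table(ev, genome, motifs, don, acc)
  truth <- b$truth[b$truth$species == "A", ]
  i <- match(truth$event_id, ft$event_id)
  expect_equal(ft$exon_length[i], truth$exon_length)
  expect_equal(ft$n_ese[i], truth$n_ese)
  expect_equal(ft$n_ess[i], truth$n_ess)
  expect_equal(ft$ppt_score[i], truth$ppt_target)
  expect_equal(ft$exon_length, ev$coord3[match(ft$event_id, ev$event_id)] -
                 ev$coord2[match(ft$event_id, ev$event_id)])
})

test_that("feature extraction is strand-consistent", {
  b <- generate_dataset(sim_config(n_genes = 8, frac_sensitive = 0.25, seed = 6),
                        file.path(tempdir(), "strandsim"))
  genome <- read_genome(b$paths$genome_A)
  motifs <- read_motif_table(b$paths$motifs)
  models <- read_gene_models(b$paths$annotation_A)
  ev <- extract_skipping_events(models)
  don <- train_splice_model(models, genome, "donor")
  acc <- train_splice_model(models, genome, "acceptor")
  ft <- feature_table(ev, genome, motifs, don, acc)
  # reverse-complement the chromosome and flip all coordinates and strands
  L <- length(genome[[1]])
  rc <- Biostrings::reverseComplement(genome)
  ev2 <- ev
  ev2$coord1 <- L - ev$coord4
  ev2$coord2 <- L - ev$coord3
  ev2$coord3 <- L - ev$coord2
  ev2$coord4 <- L - ev$coord1
  ev2$strand <- ifelse(ev$strand == "+", "-", "+")
  ft2 <- feature_table(ev2, rc, motifs, don, acc)
  for (col in setdiff(names(ft), "event_id")) {
    expect_equal(ft2[[col]], ft[[col]], info = col)
  }
})

test_that("events without a predictable branch point get missing PPT fields", {
  # upstream window with no adenosine at all
  genome <- toy_genome(chr1 = paste0(
    strrep("C", 120), strrep("G", 100), strrep("C", 64), strrep("G", 130),
    strrep("C", 120)))
  ev <- data.frame(event_id = "e1", gene_id = "g1", chrom = "chr1",
                   strand = "+", coord1 = 120, coord2 = 220, coord3 = 284,
                   coord4 = 414, stringsAsFactors = FALSE)
  fv <- feature_vector(ev, genome, NULL, uniform_splice_model(9),
                       uniform_splice_model(23))
  expect_true(is.na(fv$branch_score))
  expect_true(is.na(fv$ppt_score))
  expect_equal(fv$exon_length, 64)
})
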