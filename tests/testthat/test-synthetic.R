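test_that("invalid configurations are rejected", {
  expect_error(sim_config(n_genes = 0), "n_genes")
  expect_error(sim_config(frac_sensitive = 1.2), "frac_sensitive")
  expect_error(sim_config(effect_size_skip = 0.1), "negative")
  expect_error(sim_config(library_size = 0), "library_size")
  expect_error(sim_config(identity_target = -0.1), "identity_target")
})

test_that("frac_sensitive = 0 yields a truth table with no sensitive records", {
  b <- generate_dataset(sim_config(n_genes = 10, frac_sensitive = 0, seed = 2),
                        file.path(tempdir(), "sim_zero"))
  expect_false(any(b$truth$sensitive))
})

test_that("the same seed reproduces byte-identical output files", {
  d1 <- file.path(tempdir(), "sim_det1")
  d2 <- file.path(tempdir(), "sim_det2")
  b1 <- generate_dataset(sim_config(n_genes = 12, frac_sensitive = 0.25,
                                    seed = 5), d1)
  b2 <- generate_dataset(sim_config(n_genes = 12, frac_sensitive = 0.25,
                                    seed = 5), d2)
  for (nm in names(b1$paths)) {
    expect_identical(unname(tools::md5sum(b1$paths[[nm]])),
                     unname(tools::md5sum(b2$paths[[nm]])), info = nm)
  }
  b3 <- generate_dataset(sim_config(n_genes = 12, frac_sensitive = 0.25,
                                    seed = 6), file.path(tempdir(), "sim_det3"))
  expect_false(identical(unname(tools::md5sum(b1$paths$genome_A)),
                         unname(tools::md5sum(b3$paths$genome_A))))
})

test_that("ground-truth sensitive exons satisfy the generated feature constraints", {
  b <- generate_dataset(sim_config(n_genes = 40, frac_sensitive = 0.3, seed = 9),
                        file.path(tempdir(), "sim_constraints"))
  tr <- b$truth
  sens <- tr[tr$sensitive, ]
  expect_gt(nrow(sens), 0)
  expect_true(all(sens$species == "A"))
  expect_true(all(sens$exon_length < 65))
  expect_true(all(sens$n_ese < 5))
  expect_true(all(sens$n_ess < 20))
  expect_true(all(sens$ppt_target >= 10 & sens$ppt_target < 20))
  expect_true(all(sens$true_psi_treat < sens$true_psi_ctrl))
  # insensitive records never shift psi
  insens <- tr[!tr$sensitive, ]
  expect_true(all(insens$true_psi_treat == insens$true_psi_ctrl))
  # species-B partners of sensitive exons carry strong tracts
  ids <- sub("^gA", "", sub(":.*", "", sens$event_id))
  b_side <- tr[tr$species == "B" &
                 sub("^gB", "", sub(":.*", "", tr$event_id)) %in% ids, ]
  expect_true(all(b_side$ppt_target >= 20))
})

test_that("junction counts conserve the per-gene library allocation", {
  cfg <- sim_config(n_genes = 15, frac_sensitive = 0.2, seed = 12,
                    library_size = 150000)
  b <- generate_dataset(cfg, file.path(tempdir(), "sim_cons"))
  junc <- read_junction_counts(b$paths$junctions_A)
  depth <- round(cfg$library_size / cfg$n_genes)
  # per gene (identified by its event's junction span) and sample, counts
  # sum to the allocated depth
  ev <- extract_skipping_events(read_gene_models(b$paths$annotation_A))
  for (i in seq_len(nrow(ev))) {
    sub <- junc[junc$intron_start >= ev$coord1[i] &
                  junc$intron_end <= ev$coord4[i], ]
    per_sample <- tapply(sub$count, sub$sample, sum)
    expect_true(all(per_sample == depth))
  }
})

test_that("empirical psi converges to the true psi at deep coverage", {
  cfg <- sim_config(n_genes = 30, frac_sensitive = 0.2, seed = 14,
                    library_size = 3e6, replicate_noise_sd = 0)
  b <- generate_dataset(cfg, file.path(tempdir(), "sim_mc"))
  ev <- extract_skipping_events(read_gene_models(b$paths$annotation_A))
  junc <- read_junction_counts(b$paths$junctions_A)
  design <- read_design(b$paths$design_A)
  psi <- psi_table(ev, junc, design)
  tr <- b$truth[b$truth$species == "A", ]
  i <- match(psi$event_id, tr$event_id)
  err_ctrl <- abs(psi[[2]] - tr$true_psi_ctrl[i])
  err_trt <- abs(psi[[4]] - tr$true_psi_treat[i])
  expect_gte(mean(c(err_ctrl, err_trt) < 0.02), 0.95)
})

test_that("generated files round-trip through the pipeline readers", {
  b <- generate_dataset(sim_config(n_genes = 6, frac_sensitive = 0.5, seed = 3),
                        file.path(tempdir(), "sim_rt"))
  m <- read_gene_models(b$paths$annotation_A)
  expect_equal(length(unique(m$exons$gene_id)), 6L)
  expect_equal(length(unique(m$exons$transcript_id)), 12L)
  g <- read_genome(b$paths$genome_A)
  expect_equal(names(g), "chrA")
  expect_true(nrow(read_junction_counts(b$paths$junctions_A)) > 0)
  expect_equal(nrow(read_design(b$paths$design_A)), 4L)
  expect_equal(nrow(read_homology_table(b$paths$homology)), 6L)
  expect_gt(nrow(read_motif_table(b$paths$motifs)), 0L)
  # each gene has >= 3 exons in its inclusion transcript
  per_tx <- table(m$exons$transcript_id)
  expect_true(all(per_tx[grepl("t1$", names(per_tx))] == 3L))
})
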