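test_that("simulated genomes hit the requested size and GC", {
  for (gc in c(0.20, 0.50)) {
    sim <- simulate_genome(simulation_config(
      seed = 42, genome_length = 60000, gc_target = gc, n_genes = 60,
      mean_gene_length = 200))
    expect_equal(nchar(sim$genome$sequence), 60000)
    # recompute GC by direct base count, independent of the generator
    bases <- table(strsplit(sim$genome$sequence, "")[[1]])
    gc_direct <- sum(bases[c("G", "C")]) / sum(bases)
    expect_lt(abs(gc_direct - gc), 0.02)
    expect_equal(sim$truth$achieved_gc, unname(gc_direct))
    expect_equal(sum(sim$features$type == "CDS" &
                     sim$features$segment == 1L), 60)
  }
})

test_that("generated CDS are ATG-initiated, stop-terminated and stop-free", {
  sim <- small_sim(seed = 3)
  for (tag in unique(sim$features$locus_tag)) {
    cds <- extract_cds(sim$genome, feature_rows(sim$features, tag))
    expect_equal(nchar(cds) %% 3, 0)
    expect_equal(substr(cds, 1, 3), "ATG")
    tr <- translate_cds(cds)
    expect_true(tr$has_terminal_stop)
    expect_equal(nrow(tr$internal_stops), 0)
  }
})

test_that("simulation is byte-deterministic under a fixed seed", {
  cfg <- simulation_config(seed = 7, genome_length = 40000, n_genes = 40)
  s1 <- simulate_genome(cfg)
  s2 <- simulate_genome(cfg)
  expect_identical(s1$genome$sequence, s2$genome$sequence)
  expect_identical(as.data.frame(s1$features), as.data.frame(s2$features))
  d1 <- tempfile(); d2 <- tempfile()
  write_simulation(s1, d1); write_simulation(s2, d2)
  for (f in basename(list.files(d1))) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  }
})

test_that("infeasible packing is rejected before generation", {
  expect_error(simulation_config(genome_length = 10000, n_genes = 150),
               "infeasible")
})

test_that("pathway gene symbols are planted and recorded in the truth", {
  sim <- simulate_genome(simulation_config(
    seed = 9, genome_length = 40000, n_genes = 40,
    pathway_assignment = list(biotin = c("bioA", "bioB"),
                              riboflavin = "ribD")))
  truth <- sim$truth$planted_genes
  expect_setequal(truth$symbol, c("bioA", "bioB", "ribD"))
  expect_setequal(sim$features$gene[!is.na(sim$features$gene)],
                  c("bioA", "bioB", "ribD"))
})

test_that("plant_split_genes rewrites one codon and splits the annotation", {
  sim <- small_sim(seed = 5)
  out <- plant_split_genes(sim$genome, sim$features, n = 6, seed = 21)
  tr <- out$truth$split_records
  expect_equal(nrow(tr), 6)
  # exactly one codon differs per split gene; frame is untouched
  diffs <- which(strsplit(sim$genome$sequence, "")[[1]] !=
                 strsplit(out$genome$sequence, "")[[1]])
  expect_lte(length(diffs), 3 * 6)
  for (i in seq_len(nrow(tr))) {
    halves <- out$features[out$features$locus_tag %in%
      c(tr$first_locus_tag[i], tr$second_locus_tag[i]), ]
    expect_equal(nrow(halves), 2)
    first <- halves[halves$locus_tag == tr$first_locus_tag[i], ]
    cds1 <- extract_cds(out$genome, first)
    # first half ends at the planted stop codon
    expect_equal(substr(cds1, nchar(cds1) - 2, nchar(cds1)),
                 tr$internal_stop_codon[i])
    expect_equal(nchar(cds1) / 3 - 1, tr$internal_stop_codon_index[i])
  }
  # n = 0 is the identity
  same <- plant_split_genes(sim$genome, sim$features, n = 0, seed = 1)
  expect_identical(same$genome$sequence, sim$genome$sequence)
  # asking for more splits than eligible genes fails
  expect_error(plant_split_genes(sim$genome, sim$features, n = 10000),
               "only")
})

test_that("planted internal stop codons follow the requested distribution", {
  # law-of-large-numbers check on the planting distribution itself
  dist <- c(TAA = 0.55, TAG = 0.09, TGA = 0.36)
  draws <- character(0)
  for (s in 1:5) {
    sim <- small_sim(seed = 100 + s)
    out <- plant_split_genes(sim$genome, sim$features, n = 30,
                             stop_dist = dist, seed = 200 + s)
    draws <- c(draws, out$truth$split_records$internal_stop_codon)
  }
  freq <- table(factor(draws, levels = names(dist))) / length(draws)
  chi <- suppressWarnings(
    stats::chisq.test(table(factor(draws, levels = names(dist))),
                      p = dist))
  expect_gt(chi$p.value, 1e-4)
  expect_lt(max(abs(freq - dist)), 0.10)  # 150 draws, loose bound
})

test_that("mutate_pair plants the exact number of substitutions", {
  sim <- small_sim(seed = 13)
  mp <- mutate_pair(sim$genome, 0, seed = 1)
  expect_identical(mp$genome$sequence, sim$genome$sequence)

  mp <- mutate_pair(sim$genome, 25, seed = 2, features = sim$features)
  xa <- strsplit(sim$genome$sequence, "")[[1]]
  xb <- strsplit(mp$genome$sequence, "")[[1]]
  expect_equal(which(xa != xb), mp$snp_positions)
  expect_length(mp$snp_positions, 25)
  # the stop-codon guard keeps the split detector blind to the SNPs
  expect_equal(nrow(find_split_candidates(mp$genome, sim$features)), 0)

  expect_error(mutate_pair(sim$genome, nchar(sim$genome$sequence) + 1),
               "exceeds")
})

test_that("16S pairs realise their target identity", {
  p <- simulate_16s_pair(1500, 1.0, seed = 4)
  expect_identical(p$seq1, p$seq2)
  for (target in c(0.96, 0.84)) {
    p <- simulate_16s_pair(1500, target, seed = 4)
    ident <- mean(strsplit(p$seq1, "")[[1]] == strsplit(p$seq2, "")[[1]])
    expect_lt(abs(ident - target), 0.005)
  }
  expect_error(simulate_16s_pair(1500, 0), "target_identity")
})

test_that("consortium simulation drives multiple genomes from one config", {
  cfg <- list(seed = 31, genomes = list(
    symA = list(genome_length = 30000, n_genes = 30,
                pathway_assignment = list(biotin = "bioB")),
    symB = list(genome_length = 30000, n_genes = 30, gc_target = 0.25)))
  sims <- simulate_consortium(cfg)
  expect_named(sims, c("symA", "symB"))
  expect_equal(sims$symA$genome$id, "symA")
  expect_equal(unique(sims$symB$features$genome_id), "symB")
  expect_true("bioB" %in% sims$symA$features$gene)
  # distinct seeds -> distinct sequences
  expect_false(sims$symA$genome$sequence == sims$symB$genome$sequence)
})
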