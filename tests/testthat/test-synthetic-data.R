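test_that("zero-noise single-pattern pools give exactly one pattern per group", {
  cfg <- simulation_config(n_groups = 3, samples_per_group = 5,
                           pool_sizes = 1, noise_rate = 0, seed = 201)
  sim <- simulate_protein_alignment(cfg)
  expect_equal(nrow(sim$alignment$records), 15)
  expect_equal(sim$alignment$region_length, 47)
  catalog <- catalog_patterns(sim$alignment)
  expect_equal(pattern_counts(catalog)[["full"]], 3L)
  # emitted sequences equal the planted pool concatenations
  for (id in sim$alignment$records$sample_id) {
    tr <- sim$truth[[id]]
    planted <- paste(vapply(names(sim$pools), function(r) {
      sim$pools[[r]][[tr$group]][tr$pool_choice[r]]
    }, character(1)), collapse = "")
    expect_equal(
      sim$alignment$records$aa[sim$alignment$records$sample_id == id],
      planted)
  }
})

test_that("motif-anchor columns carry the canonical residues in every sample", {
  sim <- simulate_protein_alignment(simulation_config(seed = 211))
  anchors <- anchor_columns()
  cols <- as.integer(names(anchors))
  for (s in sim$alignment$records$aa) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    expect_equal(ch[cols], unname(anchors))
  }
})

test_that("the generator is a deterministic function of config and seed", {
  cfg <- simulation_config(seed = 221)
  a <- simulate_protein_alignment(cfg)
  b <- simulate_protein_alignment(cfg)
  expect_identical(a, b)
  c <- simulate_protein_alignment(simulation_config(seed = 222))
  expect_false(identical(a$alignment$records$aa,
                         c$alignment$records$aa))
})

test_that("observed mutation fraction matches the binomial expectation", {
  cfg <- simulation_config(n_groups = 1, samples_per_group = 100,
                           pool_sizes = 1, noise_rate = 0.05, seed = 231)
  sim <- simulate_protein_alignment(cfg)
  n_mut <- sum(vapply(sim$truth, function(t) nrow(t$substitutions),
                      integer(1)))
  n_eligible <- (47 - length(anchor_columns())) * 100
  p_hat <- n_mut / n_eligible
  se3 <- 3 * sqrt(0.05 * 0.95 / n_eligible)
  expect_lt(abs(p_hat - 0.05), se3)
  # and the truth matches the emitted sequences
  ref <- sim$pools
  for (id in head(sim$alignment$records$sample_id, 10)) {
    tr <- sim$truth[[id]]
    planted <- paste(vapply(names(ref), function(r)
      ref[[r]][[tr$group]][tr$pool_choice[r]], character(1)),
      collapse = "")
    got <- sim$alignment$records$aa[
      sim$alignment$records$sample_id == id]
    diff <- which(strsplit(planted, "")[[1]] != strsplit(got, "")[[1]])
    expect_equal(sort(diff), sort(tr$substitutions$column))
  }
})

test_that("property-preserving noise stays within the residue's class", {
  cfg <- simulation_config(n_groups = 1, samples_per_group = 50,
                           pool_sizes = 1, noise_rate = 0.1,
                           property_preserving = TRUE, seed = 241)
  sim <- simulate_protein_alignment(cfg)
  classes <- amino_acid_classes()
  class_of <- function(a) names(which(vapply(classes, function(m)
    a %in% m, logical(1))))
  for (tr in sim$truth) {
    if (nrow(tr$substitutions) == 0) next
    expect_equal(vapply(tr$substitutions$from, class_of, character(1)),
                 vapply(tr$substitutions$to, class_of, character(1)),
                 ignore_attr = TRUE)
  }
})

test_that("gaps fall only inside the FAD-GG interval", {
  cfg <- simulation_config(n_groups = 2, samples_per_group = 20,
                           pool_sizes = 1, noise_rate = 0,
                           gap_rate = 0.05, seed = 251)
  sim <- simulate_protein_alignment(cfg)
  gap_cols <- unique(unlist(lapply(sim$alignment$records$aa, function(s) {
    which(strsplit(s, "", fixed = TRUE)[[1]] == "-")
  })))
  expect_true(length(gap_cols) > 0)
  expect_true(all(gap_cols >= 12 & gap_cols <= 32))
})

test_that("an infeasible pattern pool is rejected", {
  expect_error(
    simulation_config(n_groups = 8, samples_per_group = 2,
                      pool_sizes = c(1, 2000, 1, 1, 1)),
    "FAD")
})

test_that("back-translation inverts translation and respects the code table", {
  y <- back_translate(region_alignment(c(s = "Y")), seed = 261)
  codon <- substr(y$records$nt[1], 3, 5)
  expect_true(codon %in% c("TAT", "TAC"))

  set.seed(262)
  seqs <- setNames(vapply(1:50, function(i) rand_seq(47), character(1)),
                   sprintf("r%02d", 1:50))
  aln <- back_translate(region_alignment(seqs), seed = 263)
  expect_equal(unique(nchar(aln$records$nt)), 143L)
  retr <- vapply(aln$records$nt, translate_region, character(1),
                 USE.NAMES = FALSE)
  expect_equal(retr, unname(seqs))

  # seeded codon choices are reproducible
  a <- back_translate(region_alignment(seqs), seed = 7)
  b <- back_translate(region_alignment(seqs), seed = 7)
  expect_identical(a$records$nt, b$records$nt)
})

test_that("gap columns are carried as codon gaps through back-translation", {
  aln <- back_translate(region_alignment(c(g = "L-Y")), seed = 271)
  nt <- aln$records$nt[1]
  expect_equal(substr(nt, 6, 8), "---")
  expect_equal(translate_region(nt), "L-Y")
})

test_that("simulated SS profiles follow group templates exactly at zero perturbation", {
  cfg <- simulation_config(n_groups = 2, samples_per_group = 2,
                           ss_perturbation_rate = 0, seed = 281)
  # unequal group sizes, so state frequencies (hence scores) differ
  # between the two templates' columns
  pats <- data.frame(pattern_id = 1:6,
                     group = rep(c("gastropod", "mammal"), c(4, 2)),
                     stringsAsFactors = FALSE)
  ss <- simulate_ss(pats, cfg)
  expect_equal(unname(as.character(ss$profiles)[1:4]),
               rep(ss$truth$templates[["gastropod"]], 4))
  expect_equal(unname(as.character(ss$profiles)[5:6]),
               rep(ss$truth$templates[["mammal"]], 2))
  # distinct groups get distinct templates, so k=2 recovers them
  res <- simplify_and_cluster(ss$profiles, k = 2, subk = 1)
  expect_equal(partition_signature(res$assignment$labels),
               partition_signature(pats$group, ids = as.character(1:6)))

  # gaps in the protein pattern propagate to the SS string
  ss2 <- simulate_ss(pats[1, , drop = FALSE], cfg,
                     pattern_strings = c(`1` = paste0(
                       "--", paste(rep("A", 45), collapse = ""))))
  expect_equal(substr(as.character(ss2$profiles)[1], 1, 2), "--")
})

test_that("heavy perturbation lowers conservation scores on average", {
  pats <- data.frame(pattern_id = 1:20, group = "gastropod",
                     stringsAsFactors = FALSE)
  clean <- simulate_ss(pats, simulation_config(
    n_groups = 1, ss_perturbation_rate = 0, seed = 291))
  noisy <- simulate_ss(pats, simulation_config(
    n_groups = 1, ss_perturbation_rate = 1, seed = 291))
  sc_clean <- score_structural_conservation(clean$profiles)
  sc_noisy <- score_structural_conservation(noisy$profiles)
  expect_lt(mean(sc_noisy), mean(sc_clean))
})
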