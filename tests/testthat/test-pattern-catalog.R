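test_that("the default scheme partitions the region into 5/6/21/8/7", {
  scheme <- default_subregion_scheme()
  expect_equal(scheme$name, c("bFAD", "FAD", "FAD-GG", "GG", "aGG"))
  expect_equal(scheme$length, c(5L, 6L, 21L, 8L, 7L))
  expect_equal(scheme$start[1], 1L)
  expect_equal(scheme$end[5], 47L)
  expect_error(subregion_scheme(c("a", "b"), c(1, 7), c(5, 10)),
               "contiguous")
})

test_that("sub-region extraction is a partition: concatenation restores the input", {
  set.seed(51)
  seqs <- rand_aln_strings(20, L = 47)
  sub <- extract_subregions(seqs)
  expect_equal(dim(sub), c(20L, 5L))
  expect_equal(unname(nchar(sub[1, ])), c(5L, 6L, 21L, 8L, 7L))
  recon <- apply(sub, 1, paste, collapse = "")
  expect_equal(unname(recon), unname(seqs))

  one <- subregion_scheme("all", 1, 47)
  expect_equal(unname(extract_subregions(seqs, one)[, 1]), unname(seqs))

  expect_error(extract_subregions(rand_aln_strings(3, L = 40)),
               "scheme covers")
})

test_that("cataloguing deduplicates with first-occurrence ids", {
  aln <- region_alignment(rep("GAGVVG", 5))
  catalog <- catalog_patterns(aln, subregion_scheme("all", 1, 6))
  expect_equal(unname(pattern_counts(catalog)), c(1L, 1L))
  expect_equal(unname(catalog$assignments[, "full"]), rep(1L, 5))

  aln2 <- region_alignment(c(a = "ABCDE", b = "ABCDE", c = "ABCDF"))
  cat2 <- catalog_patterns(aln2, subregion_scheme("all", 1, 5))
  expect_equal(cat2$scopes$all$patterns$n_samples, c(2L, 1L))
  expect_equal(cat2$scopes$all$members[[1]], c("a", "b"))
})

test_that("catalogue ids agree with a naive quadratic deduplicator", {
  set.seed(61)
  for (rep in 1:5) {
    n <- sample(5:120, 1)
    seqs <- rand_aln_strings(n, L = 47, pool = 7, mut = 0.05)
    catalog <- catalog_patterns(region_alignment(seqs))
    for (scope in names(catalog$scopes)) {
      strings <- if (scope == "full") seqs
                 else extract_subregions(seqs)[, scope]
      expect_equal(unname(catalog$assignments[, scope]),
                   brute_pattern_ids(strings))
    }
  }
})

test_that("five-digit tuples are equal exactly when full patterns are equal", {
  set.seed(71)
  seqs <- rand_aln_strings(60, L = 47, pool = 5, mut = 0.03)
  catalog <- catalog_patterns(region_alignment(seqs))
  codes <- encode_five_digit(catalog)
  expect_equal(unname(codes[1, ]), rep(1L, 5))  # first record is first-seen
  full_eq <- outer(seqs, seqs, "==")
  code_eq <- Reduce(`&`, lapply(1:5, function(r) {
    outer(codes[, r], codes[, r], "==")
  }))
  expect_equal(unname(code_eq), unname(full_eq))

  # differing only inside FAD-GG differs exactly at digit 3
  s1 <- rand_seq(47)
  s2 <- paste0(substr(s1, 1, 19), ifelse(substr(s1, 20, 20) == "A",
                                         "C", "A"), substr(s1, 21, 47))
  cat2 <- catalog_patterns(region_alignment(c(x = s1, y = s2)))
  c2 <- encode_five_digit(cat2)
  expect_equal(which(c2[1, ] != c2[2, ]), c(`FAD-GG` = 3L))
})

test_that("per-pattern codes and strings mirror the sample-level catalogue", {
  set.seed(81)
  seqs <- rand_aln_strings(40, pool = 4, mut = 0.02)
  catalog <- catalog_patterns(region_alignment(seqs))
  codes_p <- encode_five_digit(catalog, by = "pattern")
  expect_equal(nrow(codes_p), pattern_counts(catalog)[["full"]])
  # every sample's code equals its full pattern's code
  codes_s <- encode_five_digit(catalog)
  full_id <- catalog$assignments[, "full"]
  expect_equal(unname(codes_s),
               unname(codes_p[as.character(full_id), ]))
  recon <- apply(subregion_strings(catalog), 1, paste, collapse = "")
  expect_equal(unname(recon), catalog$scopes$full$patterns$pattern)
})

test_that("property profiles count residues and classes per column", {
  prof <- compute_property_profile(c("GDL", "GEL", "GDV", "GEI", "GDK"))
  expect_equal(unname(prof$class_freq["nonpolar_aliphatic", 1]), 1)
  expect_equal(unname(prof$class_freq["negatively_charged", 2]), 1)
  expect_equal(unname(prof$class_freq["nonpolar_aliphatic", 3]), 0.8)
  expect_equal(unname(prof$class_freq["positively_charged", 3]), 0.2)
  expect_equal(unname(colSums(prof$class_freq)), rep(1, 3))

  # gaps and X are excluded from denominators
  prof2 <- compute_property_profile(c("G-", "GX", "GD", "GE"))
  expect_equal(unname(prof2$n_obs), c(4L, 2L))
  expect_equal(unname(prof2$class_freq["negatively_charged", 2]), 1)

  expect_error(compute_property_profile(c("AB", "ABC")), "equal length")
})

test_that("consensus marks literals, class tokens and wildcards correctly", {
  # a single pattern is literal everywhere
  m1 <- derive_consensus("GGRAAT")
  expect_true(all(m1$type == "literal"))
  expect_equal(render_motif(m1), "GGRAAT")

  # planted GxGxxG: positions 1, 3, 6 invariant, the rest scattered
  set.seed(91)
  pats <- replicate(40, {
    ch <- sample(AA, 6, replace = TRUE)
    ch[c(1, 3, 6)] <- "G"
    paste(ch, collapse = "")
  })
  m2 <- derive_consensus(pats)
  expect_equal(render_motif(m2), "G-x-G-x(2)-G")

  # a position holding only I/L/V renders as the class token [ILV]
  set.seed(92)
  pats3 <- replicate(40, {
    ch <- sample(AA, 4, replace = TRUE)
    ch[2] <- sample(c("I", "L", "V"), 1)
    paste(ch, collapse = "")
  })
  m3 <- derive_consensus(pats3)
  expect_equal(m3$token[2], "[ILV]")
  expect_equal(m3$type[2], "class")

  expect_error(derive_consensus(character(0)), "no patterns")
})

test_that("at threshold 1 the literal positions are exactly the invariant ones", {
  set.seed(101)
  for (rep in 1:5) {
    pats <- rand_aln_strings(15, L = 12, pool = 3, mut = 0.2)
    m <- derive_consensus(unname(pats))
    mat <- do.call(rbind, strsplit(unname(pats), ""))
    invariant <- apply(mat, 2, function(col) length(unique(col)) == 1)
    expect_equal(m$type == "literal", unname(invariant))
  }
})

test_that("excluded outlier patterns do not weaken the consensus", {
  pats <- c(p1 = "GGRAAT", p2 = "GGRCCT", p3 = "GGRDDT",
            bact = "AARCCC")
  with_out <- derive_consensus(pats)
  expect_false("G" %in% with_out$token[1])
  without <- derive_consensus(pats, exclude = "bact")
  expect_equal(without$token[c(1, 2, 3, 6)], c("G", "G", "R", "T"))
  expect_equal(render_motif(without, trim = TRUE), "GGR-x(2)-T")
})

test_that("rendered motifs re-parse to the same position list", {
  set.seed(111)
  for (rep in 1:8) {
    pats <- rand_aln_strings(10, L = sample(5:20, 1), pool = 3, mut = 0.3)
    m <- derive_consensus(unname(pats))
    parsed <- parse_motif(render_motif(m))
    expect_equal(parsed$type, m$type)
    expect_equal(parsed$token, m$token)
    expect_equal(nrow(parsed), nrow(m))
  }
  expect_equal(parse_motif("L-x(3)-G-x(5)-[ILV]-x-E")$type,
               c("literal", rep("wildcard", 3), "literal",
                 rep("wildcard", 5), "class", "wildcard", "literal"))
})
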