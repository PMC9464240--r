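test_that("planted mismatch strata are recovered exactly", {
  kmer <- random_target_kmer(seed = 1)
  proto <- substr(kmer, 5, 25)
  sim <- generate_genome(10000, seed = 2,
                         planted = planted_site(kmer, copies = 4,
                                                mutations_per_copy = c(0, 1, 2, 4)))
  hits <- find_offtargets(proto, sim$genome, max_mm = 3)
  prof <- mismatch_profile(hits)
  expect_equal(prof$n, c(1L, 1L, 1L, 0L))
  # the 4-mismatch copy is invisible at max_mm = 3 but exists in the truth
  expect_equal(sort(sim$truth$mismatches), c(0L, 1L, 2L, 4L))
})

test_that("reverse-complemented genome mirrors hits (strict mode)", {
  strict <- pam_pattern(mode = "strict")
  kmer <- random_target_kmer(seed = 3)
  proto <- substr(kmer, 5, 25)
  sim <- generate_genome(8000, seed = 4, pam = strict,
                         planted = planted_site(kmer, copies = 3,
                                                mutations_per_copy = c(0, 1, 2)))
  g <- sim$genome
  hits <- find_offtargets(proto, g, max_mm = 3, pam = strict)
  g_rc <- c(contig1 = reverse_complement(g$seq[1]))
  hits_rc <- find_offtargets(proto, g_rc, max_mm = 3, pam = strict)
  expect_equal(nrow(hits_rc), nrow(hits))
  expect_equal(sort(hits_rc$mismatches), sort(hits$mismatches))
  # strands flip and coordinates mirror: start0' = L - (start0 + 25)
  L <- g$length[1]
  mirrored <- sort(L - (hits$start0 + 25L))
  expect_equal(sort(hits_rc$start0), mirrored)
  expect_equal(sort(hits_rc$strand),
               sort(ifelse(hits$strand == "+", "-", "+")))
})

test_that("a PAM-free genome yields no hits", {
  hits <- find_offtargets(strrep("C", 21), c(s = cg_background(2000, seed = 5)))
  expect_equal(nrow(hits), 0L)
})

test_that("off-target search equals the brute-force oracle on random cases", {
  withr::with_seed(77, {
    for (i in 1:20) {
      len <- sample(500:4000, 1)
      g <- c(chr = random_genome_chr(len, seed = 1000 + i,
                                     freqs = c(0.3, 0.2, 0.2, 0.3)))
      q <- random_genome_chr(21, seed = 2000 + i)
      mm_cap <- sample(0:3, 1)
      hits <- find_offtargets(q, g, max_mm = mm_cap)
      ora <- oracle_offtargets(q, g, max_mm = mm_cap)
      expect_equal(nrow(hits), nrow(ora))
      expect_equal(hits$start0, ora$start0)
      expect_equal(hits$strand, ora$strand)
      expect_equal(hits$mismatches, ora$mismatches)
    }
  })
})

test_that("hit sets are nested in max_mm and deterministic", {
  g <- c(chr = random_genome_chr(6000, seed = 6, freqs = c(0.3, 0.2, 0.2, 0.3)))
  q <- random_genome_chr(21, seed = 7)
  prev <- NULL
  for (mm in 0:4) {
    h <- find_offtargets(q, g, max_mm = mm)
    key <- paste(h$seqid, h$start0, h$strand)
    if (!is.null(prev)) expect_true(all(prev %in% key))
    prev <- key
  }
  expect_identical(find_offtargets(q, g, max_mm = 3),
                   find_offtargets(q, g, max_mm = 3))
})

test_that("max_mm = 0 self-search recovers each record's copy number", {
  # planted sites on a PAM-free background: no protospacer collisions
  strict <- pam_pattern(mode = "strict")
  s <- cg_background(3000, seed = 8)
  k1 <- paste0("TTTA", cg_background(21, seed = 9))
  k2 <- paste0("TTTG", chartr("CG", "GC", cg_background(21, seed = 10)))
  s <- splice_at(s, 100, k1)
  s <- splice_at(s, 600, k1)
  s <- splice_at(s, 1200, reverse_complement(k2))  # minus-strand copy
  g <- c(chr = s)
  lib <- scan_targets(g, pam = strict)
  recs <- tidy(lib)
  expect_equal(nrow(recs), 2L)
  for (i in seq_len(nrow(recs))) {
    h <- find_offtargets(recs$protospacer[i], g, max_mm = 0, pam = strict)
    expect_equal(nrow(h), recs$copy_number[i])
  }
})

test_that("specificity verdict flips exactly at the mismatch threshold", {
  kmer <- random_target_kmer(seed = 11)
  proto <- substr(kmer, 5, 25)
  subject <- generate_genome(8000, seed = 12,
                             planted = planted_site(kmer, copies = 2))$genome
  adult_3mm <- generate_genome(6000, seed = 13,
                               planted = planted_site(kmer, copies = 1,
                                                      mutations_per_copy = 3))$genome
  adult_4mm <- generate_genome(6000, seed = 14, max_mm = 4,
                               planted = planted_site(kmer, copies = 1,
                                                      mutations_per_copy = 4))$genome
  adult_empty <- genome_set(c(a = cg_background(6000, seed = 15)))

  expect_false(specificity_screen(proto, subject,
                                  list(bad = adult_3mm))$passes)
  expect_true(specificity_screen(proto, subject,
                                 list(far = adult_4mm))$passes)
  expect_true(specificity_screen(proto, subject,
                                 list(none = adult_empty))$passes)

  rep3 <- specificity_screen(proto, subject, list(bad = adult_3mm,
                                                  none = adult_empty))
  expect_equal(rep3$failing_genomes, "bad")
  expect_equal(sum(rep3$subject_profile$n[rep3$subject_profile$mismatches == 0]), 2L)
  g <- glance(rep3)
  expect_false(g$passes)
  expect_equal(g$failing_genomes, "bad")
  td <- tidy(rep3)
  expect_setequal(unique(td$genome), c("subject", "bad", "none"))
})

test_that("final target selection ranks passing candidates by copy number", {
  candidates <- tibble::tibble(
    kmer = c(paste0("TTTA", cg_background(21, seed = 21)),
             paste0("TTTC", chartr("CG", "GC", cg_background(21, seed = 22))),
             paste0("TTTG", cg_background(21, seed = 23))),
    orientation = "fwd",
    copy_number = c(9L, 201L, 23L)
  )
  candidates$protospacer <- substr(candidates$kmer, 5, 25)
  subject <- genome_set(c(chr = splice_at(cg_background(2000, seed = 24), 50,
                                          candidates$kmer[1])))
  clean <- genome_set(c(a = cg_background(1500, seed = 25)))
  sel <- select_final_targets(candidates, subject, list(a1 = clean))
  expect_equal(sel$copy_number, c(201L, 23L, 9L))

  # tie on copy number -> lexicographic kmer order
  tie <- candidates
  tie$copy_number <- 5L
  sel_tie <- select_final_targets(tie, subject, list(a1 = clean))
  expect_equal(sel_tie$kmer, sort(tie$kmer))

  # a candidate planted in one adulterant is excluded, naming that genome
  dirty <- genome_set(c(a = splice_at(cg_background(1500, seed = 26), 200,
                                      candidates$kmer[2])))
  sel2 <- select_final_targets(candidates, subject,
                               list(clean = clean, dirty = dirty))
  expect_equal(sel2$copy_number, c(23L, 9L))
  rej <- attr(sel2, "rejected")
  expect_equal(rej$kmer, candidates$kmer[2])
  expect_equal(rej$failing_genomes, "dirty")
})

test_that("protospacer validation rejects bad input", {
  expect_error(find_offtargets("ACGTN", c(s = strrep("A", 50))), "A/C/G/T")
  expect_error(find_offtargets("ACGT", c(s = strrep("A", 50)), max_mm = -1), ">= 0")
})
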