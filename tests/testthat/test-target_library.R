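test_that("single forward target is found and decomposed", {
  lib <- scan_targets(c(s = "TTTACCCCCCCCCCCCCCCCCCCCCG"))
  rec <- tidy(lib)
  expect_equal(nrow(rec), 1L)
  expect_equal(rec$pam, "TTTA")
  expect_equal(rec$orientation, "fwd")
  expect_equal(rec$copy_number, 1L)
  expect_equal(rec$occurrences[[1]]$start0, 0L)
  expect_equal(rec$protospacer, strrep("C", 21))
  expect_equal(lib$total_count, 1L)
})

test_that("PAM-free genome yields an empty library with undefined density", {
  lib <- scan_targets(c(s = strrep("G", 200)))
  expect_equal(lib$total_count, 0L)
  expect_equal(lib$dedup_count, 0L)
  expect_warning(d <- density(lib), "undefined")
  expect_true(is.na(d))
})

test_that("window matching both PAM patterns is one occurrence, orientation both", {
  win <- paste0("TTTC", strrep("G", 17), "GAAA")
  expect_equal(nchar(win), 25L)
  lib <- scan_targets(c(s = win))
  rec <- tidy(lib)
  expect_equal(lib$total_count, 1L)
  expect_equal(rec$orientation, "both")
  # both reads as fwd for decomposition
  expect_equal(rec$pam, "TTTC")
})

test_that("mode=paper takes VAAA-ending windows; mode=strict takes BAAA", {
  # TAAA-ending: rev under neither (T not in V, T in B)... T is in B, not V
  win_vaaa <- paste0("G", strrep("C", 20), "CAAA")   # ends VAAA (C in V) and BAAA (C in B)
  win_taaa <- paste0("G", strrep("C", 20), "TAAA")   # ends BAAA only
  expect_equal(scan_targets(c(s = win_vaaa))$total_count, 1L)
  expect_equal(scan_targets(c(s = win_taaa))$total_count, 0L)
  strict <- pam_pattern(mode = "strict")
  expect_equal(scan_targets(c(s = win_taaa), pam = strict)$total_count, 1L)
  expect_equal(strict$reverse, "BAAA")
})

test_that("windows containing N or ambiguity codes are skipped", {
  lib <- scan_targets(c(s = paste0("TTTA", strrep("C", 10), "N",
                                   strrep("C", 10), "G")))
  expect_equal(lib$total_count, 0L)
  # but genome length still counts the N
  expect_equal(lib$genome_length, 26L)
})

test_that("planted multi-copy kmer gets the right copy number", {
  kmer <- random_target_kmer(seed = 5)
  sim <- generate_genome(50000, seed = 42,
                         planted = planted_site(kmer, copies = 7))
  lib <- scan_targets(sim$genome)
  rec <- tidy(lib)[tidy(lib)$kmer == kmer, ]
  expect_equal(rec$copy_number, 7L)
  expect_setequal(rec$occurrences[[1]]$start0,
                  sim$truth$start0)
})

test_that("density is genome length over total count and scale-invariant", {
  g1 <- c(s = random_genome_chr(2000, seed = 3))
  lib1 <- scan_targets(g1)
  expect_equal(density(lib1), lib1$genome_length / lib1$total_count)
  # duplicated genome: counts and length both double
  lib2 <- scan_targets(c(a = g1[["s"]], b = g1[["s"]]))
  expect_equal(density(lib2), density(lib1))
  expect_equal(lib2$total_count, 2L * lib1$total_count)
})

test_that("scanner agrees with the regex oracle on random genomes", {
  withr::with_seed(99, {
    for (i in 1:20) {
      len <- sample(60:3000, 1)
      freqs <- c(0.3, 0.2, 0.2, 0.3)
      g <- c(chr = random_genome_chr(len, seed = i * 17 + 1, freqs = freqs))
      lib <- scan_targets(g)
      occ <- dplyr::bind_rows(tidy(lib)$occurrences)
      occ <- occ[order(occ$start0), ]
      ora <- oracle_scan(g)
      expect_equal(occ$start0, ora$start0)
      expect_equal(occ$orientation, ora$orientation)
      expect_equal(lib$total_count, nrow(ora))
      # conservation invariants
      expect_equal(sum(tidy(lib)$copy_number), lib$total_count)
      expect_lte(lib$dedup_count, lib$total_count)
      expect_true(all(occ$start0 >= 0 & occ$start0 <= len - 25))
    }
  })
})

test_that("strict-mode scan of the reverse complement mirrors protospacers", {
  g <- c(chr = random_genome_chr(4000, seed = 8))
  strict <- pam_pattern(mode = "strict")
  lib_f <- scan_targets(g, pam = strict)
  lib_r <- scan_targets(c(chr = reverse_complement(g[["chr"]])), pam = strict)
  # windows of the rc genome are exactly the rc of the original windows
  multiset <- function(lib) sort(rep(tidy(lib)$kmer, tidy(lib)$copy_number))
  expect_equal(sort(reverse_complement(multiset(lib_f))), multiset(lib_r))
  expect_equal(lib_f$total_count, lib_r$total_count)
  # fwd/rev-only records swap orientation; protospacers are preserved
  uni <- function(lib) {
    r <- tidy(lib)[tidy(lib)$orientation != "both", ]
    sort(rep(r$protospacer, r$copy_number))
  }
  expect_equal(uni(lib_f), uni(lib_r))
})

test_that("appending sequence never decreases the total count", {
  withr::with_seed(21, {
    g <- random_genome_chr(800, seed = 1)
    lib0 <- scan_targets(c(s = g))
    for (extra in c(10, 100, 500)) {
      g2 <- paste0(g, random_genome_chr(extra, seed = extra))
      expect_gte(scan_targets(c(s = g2))$total_count, lib0$total_count)
    }
  })
})

test_that("region extraction keeps genome-wide copy numbers", {
  kmer <- random_target_kmer(seed = 7)
  sim <- generate_genome(30000, seed = 10,
                         planted = planted_site(kmer, copies = 6))
  lib <- scan_targets(sim$genome)
  hit <- sim$truth[1, ]
  reg <- region(hit$seqid, hit$start0, hit$start0 + 25, "probe")
  out <- extract_region_targets(lib, reg)
  expect_equal(out$kmer, kmer)
  expect_equal(out$copy_number, 6L)   # genome-wide, not in-region
  expect_equal(out$n_in_region, 1L)

  # region narrower than k cannot contain a window
  expect_equal(nrow(extract_region_targets(lib, region(hit$seqid, 0, 20))), 0L)
  expect_error(extract_region_targets(lib, region("nope", 0, 100)), "seqid")
  expect_error(extract_region_targets(lib, region(hit$seqid, 0, 10^7)), "bounds")
})

test_that("region-only library matches a whole-genome scan restricted to it", {
  frag <- cg_background(400, seed = 2)
  frag <- splice_at(frag, 50, paste0("TTTA", strrep("C", 21)))
  frag <- splice_at(frag, 200, paste0("TTTG", strrep("G", 21)))
  lib_frag <- build_region_library(c(ITS2 = frag))
  expect_equal(lib_frag$dedup_count, 2L)

  whole <- c(chr = paste0(cg_background(300, seed = 4), frag,
                          cg_background(300, seed = 5)))
  lib_whole <- scan_targets(whole)
  reg_recs <- extract_region_targets(lib_whole, region("chr", 300, 700, "ITS2"))
  expect_setequal(reg_recs$kmer, tidy(lib_frag)$kmer)

  # strict mode with no TTTV/BAAA site in the fragment
  strict <- pam_pattern(mode = "strict")
  none <- build_region_library(c(ITS2 = cg_background(400, seed = 6)), pam = strict)
  expect_equal(none$total_count, 0L)
})

test_that("library TSV round-trips", {
  sim <- generate_genome(5000, seed = 3,
                         planted = planted_site(random_target_kmer(seed = 1), 3))
  lib <- scan_targets(sim$genome)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_target_library(lib, f)
  lib2 <- read_target_library(f)
  expect_equal(tidy(lib2), tidy(lib))
  expect_equal(glance(lib2), glance(lib))
})

test_that("scan_targets validates its inputs", {
  expect_error(scan_targets(c(s = "ACGT")), "at least k")
  expect_error(scan_targets(c(s = strrep("A", 30)), k = 4), "exceed")
  expect_error(scan_targets(character(0)), "at least one")
})
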