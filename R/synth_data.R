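# All generator randomness flows from one integer seed through withr's
# scoped RNG so callers' random state is never touched.

BASES <- c("A", "C", "G", "T")

#' Base-composition presets
#'
#' `uniform_freqs()` gives equiprobable A/C/G/T; `at_rich_freqs()` gives an
#' AT-rich composition (33% A, 33% T) typical of plant genomes, which raises
#' TTTV/VAAA PAM density toward the 18-30 bp-per-target range seen in real
#' plant assemblies.
#'
#' @return Named numeric vector of A/C/G/T probabilities summing to 1.
#' @export
uniform_freqs <- function() c(A = 0.25, C = 0.25, G = 0.25, T = 0.25)

#' @rdname uniform_freqs
#' @export
at_rich_freqs <- function() c(A = 0.33, C = 0.17, G = 0.17, T = 0.33)

check_freqs <- function(base_freqs) {
  if (!is.numeric(base_freqs) || length(base_freqs) != 4 ||
      any(base_freqs < 0) || abs(sum(base_freqs) - 1) > 1e-8) {
    stop("`base_freqs` must be 4 non-negative probabilities summing to 1")
  }
  if (is.null(names(base_freqs))) names(base_freqs) <- BASES
  base_freqs[BASES]
}

random_dna <- function(n, base_freqs = uniform_freqs()) {
  paste(sample(BASES, n, replace = TRUE, prob = base_freqs), collapse = "")
}

#' Random PAM-bearing k-mer
#'
#' Draws a k-mer that starts with a concrete realisation of the forward PAM
#' (e.g. TTTA/TTTC/TTTG for TTTV) followed by a random protospacer — a handy
#' way to make planted target sites.
#'
#' @param k Window width (default 25).
#' @param pam A [pam_pattern()].
#' @param seed Optional integer seed.
#' @return A k-nt DNA string.
#' @export
random_target_kmer <- function(k = 25L, pam = pam_pattern(), seed = NULL) {
  draw <- function() {
    pat <- strsplit(pam$forward, "")[[1]]
    head <- vapply(pat, function(l) sample(IUPAC_SETS[[l]], 1), character(1))
    paste0(paste(head, collapse = ""), random_dna(k - length(pat)))
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Specify a planted target site
#'
#' @param kmer The k-mer to plant (forward reading: PAM then protospacer).
#' @param copies Number of copies to plant.
#' @param mutations_per_copy Hamming edits applied to each copy's protospacer
#'   (never the PAM); recycled across copies.
#' @param orientation `"fwd"` plants the k-mer literally; `"rev"` plants its
#'   reverse complement (recycled across copies).
#' @return A `planted_site` list for [generate_genome()].
#' @export
planted_site <- function(kmer, copies = 1L, mutations_per_copy = 0L,
                         orientation = "fwd") {
  kmer <- toupper(kmer)
  if (stringi::stri_detect_regex(kmer, "[^ACGT]")) {
    stop("planted kmer must be concrete A/C/G/T")
  }
  structure(list(kmer = kmer, copies = as.integer(copies),
                 mutations_per_copy = rep_len(as.integer(mutations_per_copy), copies),
                 orientation = rep_len(orientation, copies)),
            class = "planted_site")
}

# Apply `n_mut` random substitutions to the protospacer part of a literal
# window. For fwd windows the protospacer is the tail (after the PAM); for
# rev windows (a reverse-complemented insert) it is the head.
mutate_protospacer <- function(literal, n_mut, orientation, pam_len) {
  if (n_mut == 0) return(literal)
  k <- nchar(literal)
  pos_pool <- if (orientation == "fwd") (pam_len + 1L):k else 1L:(k - pam_len)
  pos <- sample(pos_pool, n_mut)
  chars <- strsplit(literal, "")[[1]]
  for (p in pos) chars[p] <- sample(setdiff(BASES, chars[p]), 1)
  paste(chars, collapse = "")
}

#' Generate a synthetic genome with planted target sites
#'
#' Draws i.i.d. background sequence from `base_freqs`, then splices in the
#' planted k-mer copies (optionally protospacer-mutated, PAM intact) at
#' random non-overlapping positions. The finished genome is verified against
#' the planned truth: for every planted site (and every protospacer in
#' `avoid`), a full mismatch-tolerant scan must find exactly the planted
#' occurrences within `max_mm` mismatches — accidental background matches
#' trigger regeneration with a derived seed, so the returned truth table is
#' exact, not probabilistic.
#'
#' @param length Total genome length in bp.
#' @param seed Integer seed; the whole genome is a deterministic function of
#'   the arguments and this seed.
#' @param base_freqs A/C/G/T probabilities (see [uniform_freqs()]).
#' @param n_contigs Number of sequences to split the length over.
#' @param planted List of [planted_site()]s.
#' @param avoid Protospacers that must have no site within `max_mm`
#'   mismatches anywhere in the genome (used to build adulterant genomes that
#'   are certifiably free of a subject target).
#' @param max_mm Mismatch radius used for collision checking (default 3).
#' @param pam A [pam_pattern()] (used for collision checking).
#' @param max_retries Regeneration attempts before giving up.
#' @return A list with `genome` (a `genome_set`) and `truth`, a tibble with
#'   one row per planted copy: `site`, `kmer`, `seqid`, `start0`,
#'   `orientation`, `realized` (the literal spliced window), `mismatches`,
#'   `scannable` (whether the literal window carries a PAM under `pam`, i.e.
#'   will be found by [scan_targets()]).
#' @export
generate_genome <- function(length, seed, base_freqs = uniform_freqs(),
                            n_contigs = 1L, planted = list(), avoid = character(),
                            max_mm = 3L, pam = pam_pattern(),
                            max_retries = 20L) {
  base_freqs <- check_freqs(base_freqs)
  pam <- as_pam_pattern(pam)
  if (inherits(planted, "planted_site")) planted <- list(planted)
  k <- if (length(planted)) nchar(planted[[1]]$kmer) else 25L
  if (length(planted) && any(vapply(planted, function(p) nchar(p$kmer), 1L) != k)) {
    stop("all planted kmers must share one length")
  }
  contig_len <- diff(round(seq(0, length, length.out = n_contigs + 1)))
  if (any(contig_len < k)) stop("contigs too short for the window width")

  for (attempt in seq_len(max_retries)) {
    res <- withr::with_seed(seed + (attempt - 1L) * 7919L, {
      genome <- stats::setNames(
        vapply(contig_len, random_dna, character(1), base_freqs = base_freqs),
        paste0("contig", seq_len(n_contigs))
      )
      # place all copies without overlap
      plan <- dplyr::bind_rows(purrr::imap(planted, function(p, i) {
        tibble::tibble(site = i, kmer = p$kmer,
                       n_mut = p$mutations_per_copy,
                       orientation = p$orientation)
      }))
      ok <- TRUE
      if (nrow(plan) > 0) {
        taken <- list()
        pos <- integer(nrow(plan))
        ctg <- character(nrow(plan))
        for (i in seq_len(nrow(plan))) {
          placed <- FALSE
          for (try in 1:200) {
            ci <- sample(n_contigs, 1)
            id <- names(genome)[ci]
            s0 <- sample.int(contig_len[ci] - k + 1L, 1) - 1L
            prev <- taken[[id]]
            if (is.null(prev) || all(abs(prev - s0) >= k)) {
              taken[[id]] <- c(prev, s0)
              pos[i] <- s0; ctg[i] <- id; placed <- TRUE
              break
            }
          }
          if (!placed) { ok <- FALSE; break }
        }
        if (ok) {
          plan$seqid <- ctg
          plan$start0 <- pos
          plan$realized <- vapply(seq_len(nrow(plan)), function(i) {
            lit <- if (plan$orientation[i] == "rev") {
              reverse_complement(plan$kmer[i])
            } else plan$kmer[i]
            mutate_protospacer(lit, plan$n_mut[i], plan$orientation[i],
                               nchar(pam$forward))
          }, character(1))
          for (i in seq_len(nrow(plan))) {
            s <- genome[[plan$seqid[i]]]
            substr(s, plan$start0[i] + 1L, plan$start0[i] + k) <- plan$realized[i]
            genome[[plan$seqid[i]]] <- s
          }
        }
      }
      list(ok = ok, genome = genome, plan = plan)
    })
    if (!res$ok) next

    g <- genome_set(res$genome)
    plan <- res$plan
    pam_len <- nchar(pam$forward)
    if (nrow(plan) > 0) {
      # realized protospacer mismatch count, on the planted kmer's own reading
      plan$mismatches <- vapply(seq_len(nrow(plan)), function(i) {
        a <- strsplit(plan$realized[i], "")[[1]]
        b <- strsplit(if (plan$orientation[i] == "rev") {
          reverse_complement(plan$kmer[i])
        } else plan$kmer[i], "")[[1]]
        sum(a != b)
      }, integer(1))
      plan$scannable <- vapply(plan$realized, function(w) {
        iupac_match_starts(strsplit(w, "")[[1]], pam$forward)[1] ||
          rev(iupac_match_starts(strsplit(w, "")[[1]], pam$reverse))[1]
      }, logical(1))
    }

    # collision check: the scan of each planted protospacer (and each avoided
    # one) must recover exactly the planted copies, nothing more
    clash <- FALSE
    for (i in seq_along(planted)) {
      proto <- substr(planted[[i]]$kmer, pam_len + 1L, k)
      hits <- find_offtargets(proto, g, max_mm = max_mm, pam = pam)
      want <- plan[plan$site == i & plan$mismatches <= max_mm, , drop = FALSE]
      extra <- dplyr::anti_join(hits, want,
                                by = c(seqid = "seqid", start0 = "start0"))
      missing <- dplyr::anti_join(want, hits,
                                  by = c(seqid = "seqid", start0 = "start0"))
      if (nrow(extra) > 0 || nrow(missing) > 0) { clash <- TRUE; break }
    }
    if (!clash) for (proto in avoid) {
      if (nrow(find_offtargets(proto, g, max_mm = max_mm, pam = pam)) > 0) {
        clash <- TRUE; break
      }
    }
    if (clash) next

    truth <- if (nrow(plan)) {
      plan[, c("site", "kmer", "seqid", "start0", "orientation",
               "realized", "mismatches", "scannable")]
    } else {
      tibble::tibble(site = integer(), kmer = character(), seqid = character(),
                     start0 = integer(), orientation = character(),
                     realized = character(), mismatches = integer(),
                     scannable = logical())
    }
    return(list(genome = g, truth = truth))
  }
  stop("could not generate a collision-free genome in ", max_retries,
       " attempts; lower the planting density or mismatch radius")
}

#' Generate a toy annotation for a synthetic genome
#'
#' Places non-overlapping protein-coding genes (each with 1-3 CDS intervals
#' inside the gene body) and non-coding RNA features (miRNA/rRNA/snRNA/tRNA)
#' on the genome, and emits valid GFF3 (gene -> mRNA -> CDS hierarchy).
#'
#' @param genome A `genome_set` (or anything [genome_set()] accepts).
#' @param n_genes,n_ncrna Number of coding genes and ncRNA features.
#' @param seed Integer seed.
#' @param gene_len,ncrna_len Length ranges (bp) to draw feature sizes from.
#' @param path Optional path; when given, the GFF3 is written there.
#' @return List with `features` (tibble in [read_gff3()] layout) and `gff3`
#'   (character vector of GFF3 lines).
#' @export
generate_annotation <- function(genome, n_genes = 3L, n_ncrna = 2L, seed = 1L,
                                gene_len = c(300L, 900L),
                                ncrna_len = c(60L, 120L), path = NULL) {
  g <- as_genome_set(genome)
  withr::with_seed(seed, {
    lens <- stats::setNames(g$length, g$id)
    taken <- stats::setNames(vector("list", length(lens)), names(lens))
    place <- function(width) {
      for (try in 1:500) {
        ci <- sample(length(lens), 1)
        id <- names(lens)[ci]
        if (lens[ci] < width) next
        s0 <- sample.int(lens[ci] - width + 1L, 1) - 1L
        prev <- taken[[id]]
        if (is.null(prev) ||
            all(s0 + width <= prev[, 1] | s0 >= prev[, 2])) {
          taken[[id]] <<- rbind(prev, c(s0, s0 + width))
          return(list(seqid = id, start0 = s0, end0 = s0 + width))
        }
      }
      stop("could not place features without overlap; reduce counts/lengths")
    }

    feats <- list()
    gff <- "##gff-version 3"
    for (i in seq_len(n_genes)) {
      w <- sample(gene_len[1]:gene_len[2], 1)
      loc <- place(w)
      gid <- sprintf("gene%02d", i)
      mid <- sprintf("mRNA%02d", i)
      feats[[length(feats) + 1L]] <- tibble::tibble(
        seqid = loc$seqid, start0 = loc$start0, end0 = loc$end0, strand = "+",
        ftype = "gene", gene_id = gid, category = "coding_gene")
      gff <- c(gff,
               sprintf("%s\tsynth\tgene\t%d\t%d\t.\t+\t.\tID=%s;gene_biotype=protein_coding",
                       loc$seqid, loc$start0 + 1L, loc$end0, gid),
               sprintf("%s\tsynth\tmRNA\t%d\t%d\t.\t+\t.\tID=%s;Parent=%s",
                       loc$seqid, loc$start0 + 1L, loc$end0, mid, gid))
      # 1-3 disjoint CDS intervals inside the gene body
      n_cds <- sample(1:3, 1)
      cuts <- sort(sample(seq(loc$start0, loc$end0 - 30L, by = 30L), n_cds))
      for (j in seq_len(n_cds)) {
        cs <- cuts[j]
        ce <- min(cs + 30L + sample(0:60, 1), loc$end0)
        feats[[length(feats) + 1L]] <- tibble::tibble(
          seqid = loc$seqid, start0 = cs, end0 = ce, strand = "+",
          ftype = "CDS", gene_id = gid, category = "CDS")
        gff <- c(gff,
                 sprintf("%s\tsynth\tCDS\t%d\t%d\t.\t+\t0\tID=CDS%02d.%d;Parent=%s",
                         loc$seqid, cs + 1L, ce, i, j, mid))
      }
    }
    nc_types <- c("miRNA", "rRNA", "snRNA", "tRNA")
    for (i in seq_len(n_ncrna)) {
      w <- sample(ncrna_len[1]:ncrna_len[2], 1)
      loc <- place(w)
      ty <- sample(nc_types, 1)
      nid <- sprintf("ncRNA%02d", i)
      feats[[length(feats) + 1L]] <- tibble::tibble(
        seqid = loc$seqid, start0 = loc$start0, end0 = loc$end0, strand = "+",
        ftype = ty, gene_id = "", category = ty)
      gff <- c(gff,
               sprintf("%s\tsynth\t%s\t%d\t%d\t.\t+\t.\tID=%s",
                       loc$seqid, ty, loc$start0 + 1L, loc$end0, nid))
    }
    features <- dplyr::bind_rows(feats)
    if (!is.null(path)) writeLines(gff, path)
    list(features = features, gff3 = gff)
  })
}

#' Derive an adulterant genome by point substitution
#'
#' Substitutes each base of the subject genome independently with probability
#' `divergence` (uniformly to one of the three other bases). This is a
#' deliberately simple divergence model — no indels, no rearrangement — whose
#' purpose is to produce related genomes in which subject-specific targets
#' drift beyond the off-target mismatch radius.
#'
#' @param subject Subject genome (any form [scan_targets()] accepts).
#' @param divergence Per-base substitution probability in \[0, 1\].
#' @param seed Integer seed.
#' @return A `genome_set` with the same ids and lengths as the subject.
#' @export
generate_adulterant <- function(subject, divergence, seed) {
  if (divergence < 0 || divergence > 1) stop("`divergence` must be in [0, 1]")
  g <- as_genome_set(subject)
  withr::with_seed(seed, {
    seqs <- vapply(g$seq, function(s) {
      chars <- strsplit(s, "")[[1]]
      hit <- which(stats::runif(length(chars)) < divergence &
                     chars %in% BASES)
      for (p in hit) chars[p] <- sample(setdiff(BASES, chars[p]), 1)
      paste(chars, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    genome_set(stats::setNames(seqs, g$id), header = g$header)
  })
}

#' Simulate a fluorescence dilution series
#'
#' Generates replicate fluorescence time series for a ten-fold dilution
#' ladder plus a no-template control, with a saturating mean curve and
#' Gaussian noise:
#' `reading = baseline + A(c) * (1 - exp(-t / tau)) + N(0, noise_sd)`,
#' where the plateau amplitude follows a steep Hill-type transfer
#' `A(c) = amplitude / (1 + (midpoint / c)^hill)` (and `A(0) = 0` for the
#' control). The steep transfer emulates the threshold-like response of
#' amplification-free Cas12a reporter assays: concentrations above the
#' midpoint saturate the plateau while those below stay near the noise
#' floor. The planted detection threshold — the smallest concentration whose
#' plateau amplitude clears 6 noise SDs — is recorded in the `"truth"`
#' attribute.
#'
#' @param concentrations Dilution ladder in ng/uL (default the ten-fold
#'   series 10 .. 1e-4).
#' @param timepoints_min Measurement grid in minutes.
#' @param n_replicates Replicates per group (default 3).
#' @param seed Integer seed.
#' @param amplitude Plateau amplitude in fluorescence units.
#' @param baseline Background fluorescence.
#' @param noise_sd Gaussian noise SD.
#' @param hill Hill coefficient of the concentration transfer.
#' @param midpoint Transfer midpoint in ng/uL (default the geometric mean of
#'   0.01 and 0.001, placing the planted threshold at 0.01).
#' @param tau Saturation time constant in minutes.
#' @param control Label for the 0-concentration control group.
#' @return Long tibble (`group`, `concentration`, `replicate`,
#'   `timepoint_min`, `reading`) ready for [detection_call()] / [lod_scan()];
#'   `attr(, "truth")` holds the generator parameters and `planted_lod`.
#' @export
generate_assay_series <- function(concentrations = c(10, 1, 0.1, 0.01, 0.001, 1e-4),
                                  timepoints_min = c(0, 3, 6, 9, 12, 15, 25, 35, 45, 60),
                                  n_replicates = 3L, seed = 1L,
                                  amplitude = 2000, baseline = 100,
                                  noise_sd = 50, hill = 4,
                                  midpoint = sqrt(0.01 * 0.001), tau = 8,
                                  control = "CK") {
  if (n_replicates < 2) stop("need at least 2 replicates")
  amp <- function(c) ifelse(c > 0, amplitude / (1 + (midpoint / c)^hill), 0)
  conc_all <- c(concentrations, 0)
  labels <- c(paste0(format(concentrations, trim = TRUE, scientific = FALSE),
                     " ng/uL"), control)
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(
      i = seq_along(conc_all),
      replicate = seq_len(n_replicates),
      timepoint_min = timepoints_min
    )
    mu <- baseline + amp(conc_all[grid$i]) * (1 - exp(-grid$timepoint_min / tau))
    out <- tibble::tibble(
      group = labels[grid$i],
      concentration = conc_all[grid$i],
      replicate = grid$replicate,
      timepoint_min = grid$timepoint_min,
      reading = pmax(0, stats::rnorm(nrow(grid), mean = mu, sd = noise_sd))
    )
    detectable <- concentrations[amp(concentrations) >= 6 * noise_sd]
    attr(out, "truth") <- list(
      planted_lod = if (length(detectable)) min(detectable) else NA_real_,
      amplitude = amplitude, baseline = baseline, noise_sd = noise_sd,
      hill = hill, midpoint = midpoint, tau = tau, control = control
    )
    out
  })
}
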