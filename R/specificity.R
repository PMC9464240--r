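check_protospacer <- function(protospacer) {
  protospacer <- toupper(protospacer)
  if (length(protospacer) != 1 || !nzchar(protospacer) ||
      stringi::stri_detect_regex(protospacer, "[^ACGT]")) {
    stop("`protospacer` must be a single DNA string over A/C/G/T")
  }
  protospacer
}

# Hamming distances between the query chars and the m-mers starting at the
# candidate positions `idx` (1-based) of `chars`.
hamming_at <- function(chars, idx, query_chars, offset = 0L) {
  mm <- integer(length(idx))
  for (j in seq_along(query_chars)) {
    mm <- mm + (chars[idx + offset + j - 1L] != query_chars[j])
  }
  mm
}

#' Mismatch-tolerant off-target search
#'
#' Finds every genomic site whose PAM matches the pattern exactly (IUPAC
#' semantics, zero tolerance) and whose protospacer is within `max_mm`
#' Hamming mismatches of the query protospacer — the search semantics of
#' off-target enumeration tools such as Cas-OFFinder. Both strands are
#' scanned; `+` sites read PAM-then-protospacer on the forward strand, `-`
#' sites are windows ending in the reverse PAM whose protospacer is the
#' reverse complement of the window's first bases. Mismatches are counted on
#' the protospacer only.
#'
#' @param protospacer Query protospacer (21-nt DNA for Cas12a defaults).
#' @param genome Genome to scan (any form [scan_targets()] accepts).
#' @param max_mm Maximum protospacer mismatches (default 3).
#' @param pam A [pam_pattern()]; scanning follows its mode (paper: literal
#'   `VAAA`-ending reverse sites; strict: `BAAA`, the true reverse strand).
#' @return A tibble of hits sorted by (seqid, start0, strand): `seqid`,
#'   `start0` (0-based start of the full PAM+protospacer site on the forward
#'   strand), `strand`, `site_seq` (forward-strand sequence), `pam` (as read
#'   on the matched strand), `mismatches`.
#' @export
find_offtargets <- function(protospacer, genome, max_mm = 3L,
                            pam = pam_pattern()) {
  protospacer <- check_protospacer(protospacer)
  if (max_mm < 0) stop("`max_mm` must be >= 0")
  genome <- as_genome_set(genome)
  pam <- as_pam_pattern(pam)
  pam_len <- nchar(pam$forward)
  m <- nchar(protospacer)
  k <- pam_len + m
  q <- strsplit(protospacer, "")[[1]]
  qr <- strsplit(reverse_complement(protospacer), "")[[1]]

  one_seq <- function(id, seq) {
    chars <- strsplit(seq, "")[[1]]
    L <- length(chars)
    nW <- L - k + 1L
    if (nW < 1L) return(NULL)
    clean_run <- cumsum(chars %in% c("A", "C", "G", "T"))
    clean <- (clean_run[k:L] - c(0L, clean_run)[1:nW]) == k

    fwd <- iupac_match_starts(chars, pam$forward)[seq_len(nW)] & clean
    mr <- nchar(pam$reverse)
    rev <- iupac_match_starts(chars, pam$reverse)[(k - mr + 1L):(k - mr + nW)] & clean

    out <- list()
    fi <- which(fwd)
    if (length(fi)) {
      mm <- hamming_at(chars, fi, q, offset = pam_len)
      keep <- mm <= max_mm
      out$f <- tibble::tibble(seqid = id, start0 = fi[keep] - 1L, strand = "+",
                              mismatches = mm[keep])
    }
    ri <- which(rev)
    if (length(ri)) {
      # Hamming(revcomp(site[1..m]), q) == Hamming(site[1..m], revcomp(q))
      mm <- hamming_at(chars, ri, qr, offset = 0L)
      keep <- mm <= max_mm
      out$r <- tibble::tibble(seqid = id, start0 = ri[keep] - 1L, strand = "-",
                              mismatches = mm[keep])
    }
    hits <- dplyr::bind_rows(out)
    if (nrow(hits)) hits$site_seq <- substring(seq, hits$start0 + 1L, hits$start0 + k)
    hits
  }

  hits <- dplyr::bind_rows(purrr::map2(genome$id, genome$seq, one_seq))
  if (nrow(hits) == 0) {
    return(tibble::tibble(seqid = character(), start0 = integer(),
                          strand = character(), site_seq = character(),
                          pam = character(), mismatches = integer()))
  }
  hits$pam <- ifelse(hits$strand == "+",
                     substr(hits$site_seq, 1L, pam_len),
                     reverse_complement(substr(hits$site_seq, m + 1L, k)))
  hits |>
    dplyr::select("seqid", "start0", "strand", "site_seq", "pam", "mismatches") |>
    dplyr::arrange(.data$seqid, .data$start0, .data$strand)
}

#' Mismatch-stratified hit counts
#'
#' @param hits Hit tibble from [find_offtargets()].
#' @param max_mm Largest stratum to report.
#' @return A tibble with columns `mismatches` (0..max_mm) and `n`.
#' @export
mismatch_profile <- function(hits, max_mm = 3L) {
  tibble::tibble(
    mismatches = 0:max_mm,
    n = vapply(0:max_mm, function(m) sum(hits$mismatches == m), integer(1))
  )
}

#' Species-specificity screen of one candidate target
#'
#' Runs [find_offtargets()] for the query against the subject genome and each
#' adulterant genome. The candidate passes when no adulterant carries any
#' site within `max_mm` mismatches — the criterion that a target must be
#' present in the subject species' genome and absent (beyond off-target
#' reach) from the adulterants'. The subject profile is reported for
#' information only and does not affect the verdict.
#'
#' @param protospacer Query protospacer (DNA).
#' @param subject Subject-species genome.
#' @param adulterants Named list of adulterant genomes (>= 1).
#' @param max_mm Mismatch tolerance (default 3, the conventional off-target
#'   reach of Cas12a).
#' @param pam A [pam_pattern()].
#' @return A `specificity_report`: query, per-genome mismatch profiles,
#'   `passes`. See [tidy.specificity_report()] / [glance.specificity_report()].
#' @export
specificity_screen <- function(protospacer, subject, adulterants,
                               max_mm = 3L, pam = pam_pattern()) {
  protospacer <- check_protospacer(protospacer)
  if (!is.list(adulterants) || length(adulterants) == 0 ||
      is.null(names(adulterants)) || any(!nzchar(names(adulterants)))) {
    stop("`adulterants` must be a non-empty named list of genomes")
  }
  subject_profile <- mismatch_profile(
    find_offtargets(protospacer, subject, max_mm = max_mm, pam = pam), max_mm)
  adult_profiles <- purrr::map(adulterants, function(g) {
    mismatch_profile(find_offtargets(protospacer, g, max_mm = max_mm, pam = pam),
                     max_mm)
  })
  failing <- names(adult_profiles)[
    vapply(adult_profiles, function(p) sum(p$n) > 0, logical(1))
  ]
  structure(list(
    protospacer = protospacer,
    subject_profile = subject_profile,
    adulterant_profiles = adult_profiles,
    max_mm = as.integer(max_mm),
    passes = length(failing) == 0,
    failing_genomes = failing
  ), class = "specificity_report")
}

#' @export
print.specificity_report <- function(x, ...) {
  cat("<specificity_report>", x$protospacer, "\n")
  cat("  subject hits by mismatches:",
      paste(sprintf("%d:%d", x$subject_profile$mismatches,
                    x$subject_profile$n), collapse = " "), "\n")
  for (nm in names(x$adulterant_profiles)) {
    p <- x$adulterant_profiles[[nm]]
    cat("  ", nm, ":", paste(sprintf("%d:%d", p$mismatches, p$n),
                             collapse = " "), "\n")
  }
  cat("  passes (no adulterant site within", x$max_mm, "mismatches):",
      x$passes, "\n")
  invisible(x)
}

#' Tidy a specificity report into a long profile tibble
#'
#' @param x A `specificity_report`.
#' @param ... Unused.
#' @return Tibble with columns `genome`, `role` (subject/adulterant),
#'   `mismatches`, `n`.
#' @method tidy specificity_report
#' @export
tidy.specificity_report <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$subject_profile, genome = "subject", role = "subject"),
    dplyr::bind_rows(
      purrr::imap(x$adulterant_profiles,
                  ~ dplyr::mutate(.x, genome = .y, role = "adulterant"))
    )
  ) |>
    dplyr::select("genome", "role", "mismatches", "n")
}

#' One-row summary of a specificity report
#'
#' @param x A `specificity_report`.
#' @param ... Unused.
#' @return One-row tibble: `protospacer`, `max_mm`, `subject_hits`,
#'   `adulterant_hits`, `passes`, `failing_genomes`.
#' @method glance specificity_report
#' @export
glance.specificity_report <- function(x, ...) {
  tibble::tibble(
    protospacer = x$protospacer,
    max_mm = x$max_mm,
    subject_hits = sum(x$subject_profile$n),
    adulterant_hits = sum(vapply(x$adulterant_profiles,
                                 function(p) sum(p$n), integer(1))),
    passes = x$passes,
    failing_genomes = paste(x$failing_genomes, collapse = ";")
  )
}

#' Screen and rank candidate targets for final selection
#'
#' Screens each candidate record with [specificity_screen()] and returns the
#' passing candidates ranked by genome-wide copy number (descending; ties
#' broken by lexicographic k-mer order) — high-copy, species-specific targets
#' make the most sensitive assays. Rejected candidates, with the adulterant
#' genomes that disqualified them, are kept in the `"rejected"` attribute.
#'
#' @param candidates Record tibble (from [tidy.target_library()] or
#'   [extract_region_targets()]); needs `kmer`, `protospacer`, `copy_number`.
#' @inheritParams specificity_screen
#' @return Tibble of passing candidates with a `report` list-column of
#'   `specificity_report`s; `attr(, "rejected")` holds the failures with a
#'   `failing_genomes` column.
#' @export
select_final_targets <- function(candidates, subject, adulterants,
                                 max_mm = 3L, pam = pam_pattern()) {
  stopifnot(all(c("kmer", "protospacer", "copy_number") %in% names(candidates)))
  reports <- purrr::map(candidates$protospacer, specificity_screen,
                        subject = subject, adulterants = adulterants,
                        max_mm = max_mm, pam = pam)
  passes <- vapply(reports, `[[`, logical(1), "passes")
  out <- candidates |>
    dplyr::mutate(report = reports, passes = passes) |>
    dplyr::arrange(dplyr::desc(.data$copy_number), .data$kmer)
  rejected <- out[!out$passes, , drop = FALSE]
  rejected$failing_genomes <- vapply(rejected$report, function(r) {
    paste(r$failing_genomes, collapse = ";")
  }, character(1))
  out <- out[out$passes, , drop = FALSE]
  attr(out, "rejected") <- rejected
  out
}
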