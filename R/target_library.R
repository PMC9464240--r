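#' PAM pattern specification
#'
#' A candidate target is a k-mer that either starts with the forward PAM
#' (default `TTTV`, the LbCas12a motif; V = A/C/G) or ends with the reverse
#' PAM. Two conventions for the reverse motif are supported:
#'
#' * `mode = "paper"` (default): the literal `VAAA`-ending rule.
#' * `mode = "strict"`: the reverse motif is the reverse complement of the
#'   forward motif (`BAAA` for `TTTV`), i.e. a genuine reverse-strand PAM.
#'
#' @param forward IUPAC motif required at the k-mer start (default `"TTTV"`).
#' @param reverse IUPAC motif required at the k-mer end. Defaults to
#'   `"VAAA"` in paper mode and `reverse_complement(forward)` in strict mode.
#' @param mode `"paper"` or `"strict"`.
#' @return A `pam_pattern` list with elements `forward`, `reverse`, `mode`.
#' @examples
#' pam_pattern()                  # TTTV / VAAA
#' pam_pattern(mode = "strict")   # TTTV / BAAA
#' @export
pam_pattern <- function(forward = "TTTV", reverse = NULL,
                        mode = c("paper", "strict")) {
  mode <- match.arg(mode)
  forward <- toupper(forward)
  if (!nzchar(forward) ||
      stringi::stri_detect_regex(forward, paste0("[^", IUPAC_LETTERS, "]"))) {
    stop("`forward` must be a non-empty IUPAC motif")
  }
  if (is.null(reverse)) {
    reverse <- if (mode == "strict") reverse_complement(forward)
               else if (forward == "TTTV") "VAAA"
               else reverse_complement(forward)
  }
  reverse <- toupper(reverse)
  if (mode == "strict" && !identical(reverse, reverse_complement(forward))) {
    stop("strict mode requires reverse = reverse_complement(forward)")
  }
  structure(list(forward = forward, reverse = reverse, mode = mode),
            class = "pam_pattern")
}

as_pam_pattern <- function(pam) {
  if (inherits(pam, "pam_pattern")) return(pam)
  if (is.character(pam) && length(pam) == 1) return(pam_pattern(forward = pam))
  stop("`pam` must be a pam_pattern or a single forward motif string")
}

# Logical vector over start positions 1..(L-m+1): does the IUPAC `pattern`
# match `chars` starting there? Concrete subject letters only (N in the
# subject never matches).
iupac_match_starts <- function(chars, pattern) {
  L <- length(chars)
  pat <- strsplit(toupper(pattern), "")[[1]]
  m <- length(pat)
  if (L < m) return(logical(0))
  n <- L - m + 1L
  ok <- rep(TRUE, n)
  for (j in seq_len(m)) {
    allowed <- IUPAC_SETS[[pat[j]]]
    if (is.null(allowed)) stop("illegal IUPAC letter in pattern: ", pat[j])
    ok <- ok & (chars[j:(j + n - 1L)] %in% allowed)
  }
  ok
}

# Scan one sequence: which k-windows are PAM-qualified, and how.
# Returns a tibble(start0, orientation). Windows containing a non-ACGT
# letter are skipped entirely.
scan_one_sequence <- function(seq, k, pam) {
  chars <- strsplit(seq, "")[[1]]
  L <- length(chars)
  nW <- L - k + 1L
  if (nW < 1L) return(tibble::tibble(start0 = integer(), orientation = character()))

  # window i (1-based start) is clean iff all k of its bases are concrete
  clean_run <- cumsum(chars %in% c("A", "C", "G", "T"))
  clean <- (clean_run[k:L] - c(0L, clean_run)[1:nW]) == k

  fwd_all <- iupac_match_starts(chars, pam$forward)
  fwd <- fwd_all[seq_len(nW)]

  mr <- nchar(pam$reverse)
  rev_all <- iupac_match_starts(chars, pam$reverse)
  # reverse motif sits at the window's last mr bases: start position i+k-mr
  rev <- rev_all[(k - mr + 1L):(k - mr + nW)]

  hit <- clean & (fwd | rev)
  idx <- which(hit)
  tibble::tibble(
    start0 = idx - 1L,
    orientation = dplyr::case_when(
      fwd[idx] & rev[idx] ~ "both",
      fwd[idx] ~ "fwd",
      TRUE ~ "rev"
    )
  )
}

# PAM/protospacer decomposition for a kmer read on the scanned strand.
decompose_kmer <- function(kmer, orientation, pam_len) {
  k <- nchar(kmer[1])
  fwdish <- orientation %in% c("fwd", "both")  # 'both' reads as fwd by default
  pam <- ifelse(fwdish,
                substr(kmer, 1L, pam_len),
                reverse_complement(substr(kmer, k - pam_len + 1L, k)))
  proto <- ifelse(fwdish,
                  substr(kmer, pam_len + 1L, k),
                  reverse_complement(substr(kmer, 1L, k - pam_len)))
  list(pam = pam, protospacer = proto)
}

#' Enumerate PAM-bearing candidate targets in a genome
#'
#' Slides a width-`k` window (default 25 bp) along the forward strand of every
#' sequence and keeps windows whose first 4 nt match the forward PAM or whose
#' last 4 nt match the reverse PAM (see [pam_pattern()]). A window matching
#' both patterns is counted once with orientation `both`. Windows containing
#' any non-ACGT letter are skipped. Identical k-mer strings aggregate into a
#' single deduplicated record with a copy number; no canonicalisation across
#' strands is performed, matching plain k-mer-counter semantics.
#'
#' @param genome A `genome_set` tibble (from [read_fasta()] /
#'   [genome_set()]), a named character vector, or a `DNAStringSet`.
#' @param k Window width in bp (default 25: 4-nt PAM + 21-nt protospacer).
#' @param pam A [pam_pattern()] (default TTTV/VAAA, paper mode).
#' @return A `target_library` object; see [tidy.target_library()] for the
#'   per-record tibble and [glance.target_library()] for summary statistics
#'   (total and deduplicated counts, bp-per-target density).
#' @examples
#' lib <- scan_targets(c(chr = "TTTACCCCCCCCCCCCCCCCCCCCCG"))
#' glance(lib)
#' @export
scan_targets <- function(genome, k = 25L, pam = pam_pattern()) {
  genome <- as_genome_set(genome)
  pam <- as_pam_pattern(pam)
  pam_len <- nchar(pam$forward)
  if (k <= pam_len) stop("`k` must exceed the PAM length")
  if (any(genome$length < k)) {
    stop("every sequence must be at least k = ", k, " bp long")
  }

  occ <- purrr::map2(genome$id, genome$seq, function(id, seq) {
    w <- scan_one_sequence(seq, k, pam)
    w$seqid <- rep(id, nrow(w))
    w$kmer <- if (nrow(w)) substring(seq, w$start0 + 1L, w$start0 + k) else character(0)
    w
  })
  occ <- dplyr::bind_rows(occ)[, c("kmer", "seqid", "start0", "orientation")]

  if (nrow(occ) == 0) {
    records <- tibble::tibble(
      kmer = character(), pam = character(), protospacer = character(),
      orientation = character(), copy_number = integer(),
      occurrences = list()
    )
  } else {
    records <- occ |>
      tidyr::nest(occurrences = c("seqid", "start0", "orientation")) |>
      dplyr::mutate(copy_number = vapply(.data$occurrences, nrow, integer(1)))
    # orientation is a function of the window content, hence constant per kmer
    ori <- vapply(records$occurrences, function(o) o$orientation[1], character(1))
    dec <- decompose_kmer(records$kmer, ori, pam_len)
    records <- records |>
      dplyr::mutate(orientation = ori, pam = dec$pam, protospacer = dec$protospacer) |>
      dplyr::select("kmer", "pam", "protospacer", "orientation",
                    "copy_number", "occurrences") |>
      dplyr::arrange(dplyr::desc(.data$copy_number), .data$kmer)
  }

  total <- sum(records$copy_number)
  structure(list(
    records = records,
    genome_length = genome_total_length(genome),
    contig_lengths = stats::setNames(genome$length, genome$id),
    k = as.integer(k),
    pam = pam,
    total_count = as.integer(total),
    dedup_count = nrow(records),
    density_bp = if (total > 0) genome_total_length(genome) / total else NA_real_
  ), class = "target_library")
}

#' Build a target library from a region-only FASTA
#'
#' Convenience wrapper for genomes too large to scan in full: scan only a
#' barcode-region FASTA (e.g. an ITS2 fragment) with identical semantics to
#' [scan_targets()].
#'
#' @inheritParams scan_targets
#' @param region_fasta The region sequences (any form [scan_targets()] takes).
#' @return A `target_library`.
#' @export
build_region_library <- function(region_fasta, k = 25L, pam = pam_pattern()) {
  scan_targets(region_fasta, k = k, pam = pam)
}

#' Target density in bp per target
#'
#' Genome length divided by the total (non-deduplicated) target count: "one
#' target per x bp". Lengths include N/ambiguity bases even though windows
#' containing them are never targets.
#'
#' @param x A `target_library`.
#' @param ... Unused.
#' @return bp-per-target as a double; `NA` with a warning when the library is
#'   empty (density undefined).
#' @export
density.target_library <- function(x, ...) {
  if (x$total_count == 0) {
    warning("library has no targets; density is undefined")
    return(NA_real_)
  }
  x$genome_length / x$total_count
}

#' Extract targets restricted to a region
#'
#' Returns the deduplicated records having at least one occurrence whose full
#' window lies inside the region (e.g. ITS2 coordinates on the assembly).
#' Records keep their genome-wide copy number, not the in-region count — the
#' point of a multi-copy barcode target is precisely its genome-wide
#' abundance.
#'
#' @param lib A `target_library` from [scan_targets()].
#' @param region A one-row region tibble from [region()] or [read_bed()].
#' @return Tibble of target records (same columns as [tidy.target_library()]),
#'   plus `n_in_region`, the number of occurrences inside the region.
#' @export
extract_region_targets <- function(lib, region) {
  stopifnot(inherits(lib, "target_library"))
  region <- as.data.frame(region)[1, , drop = FALSE]
  len <- lib$contig_lengths[region$seqid]
  if (is.na(len)) stop("region seqid not in the scanned genome: ", region$seqid)
  if (region$start0 < 0 || region$end0 > len || region$end0 <= region$start0) {
    stop("region outside sequence bounds: ", region$seqid,
         ":", region$start0, "-", region$end0)
  }
  k <- lib$k
  inside <- vapply(lib$records$occurrences, function(o) {
    sum(o$seqid == region$seqid &
          o$start0 >= region$start0 &
          o$start0 + k <= region$end0)
  }, integer(1))
  out <- lib$records[inside > 0L, , drop = FALSE]
  out$n_in_region <- inside[inside > 0L]
  out
}

#' @export
print.target_library <- function(x, ...) {
  cat("<target_library> k =", x$k,
      " PAM:", x$pam$forward, "start /", x$pam$reverse, "end",
      paste0("(", x$pam$mode, " mode)\n"))
  cat("  genome length:", format(x$genome_length, big.mark = ","), "bp over",
      length(x$contig_lengths), "sequence(s)\n")
  cat("  targets:", format(x$total_count, big.mark = ","), "total,",
      format(x$dedup_count, big.mark = ","), "deduplicated\n")
  if (!is.na(x$density_bp)) {
    cat("  density: one target per", sprintf("%.1f", x$density_bp), "bp\n")
  }
  invisible(x)
}

#' Tidy a target library into its per-record tibble
#'
#' @param x A `target_library`.
#' @param ... Unused.
#' @return A tibble with one row per deduplicated target: `kmer`, `pam`,
#'   `protospacer`, `orientation`, `copy_number` and a nested `occurrences`
#'   tibble (`seqid`, `start0`, `orientation`).
#' @method tidy target_library
#' @export
tidy.target_library <- function(x, ...) x$records

#' One-row summary of a target library
#'
#' @param x A `target_library`.
#' @param ... Unused.
#' @return A one-row tibble: `genome_length`, `k`, `pam_forward`,
#'   `pam_reverse`, `pam_mode`, `total_count`, `dedup_count`, `density_bp`.
#' @method glance target_library
#' @export
glance.target_library <- function(x, ...) {
  tibble::tibble(
    genome_length = x$genome_length, k = x$k,
    pam_forward = x$pam$forward, pam_reverse = x$pam$reverse,
    pam_mode = x$pam$mode,
    total_count = x$total_count, dedup_count = x$dedup_count,
    density_bp = x$density_bp
  )
}

#' Write a target library to TSV
#'
#' Columns: kmer, pam, protospacer, orientation, copy_number, occurrences
#' (semicolon-joined `seqid:start0:orientation`). Library metadata (genome
#' length, k, PAM) is stored on `##` comment lines so the file round-trips
#' through [read_target_library()].
#'
#' @param lib A `target_library`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_target_library <- function(lib, path) {
  stopifnot(inherits(lib, "target_library"))
  df <- lib$records
  df$occurrences <- vapply(df$occurrences, function(o) {
    paste(sprintf("%s:%d:%s", o$seqid, o$start0, o$orientation), collapse = ";")
  }, character(1))
  con <- file(path, "wt")
  on.exit(close(con))
  writeLines(c(
    sprintf("## genome_length=%d", lib$genome_length),
    sprintf("## contig_lengths=%s",
            paste(sprintf("%s:%d", names(lib$contig_lengths),
                          lib$contig_lengths), collapse = ",")),
    sprintf("## k=%d", lib$k),
    sprintf("## pam_forward=%s pam_reverse=%s pam_mode=%s",
            lib$pam$forward, lib$pam$reverse, lib$pam$mode),
    paste0("#", paste(names(df), collapse = "\t"))
  ), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a target library written by [write_target_library()]
#'
#' @param path TSV path.
#' @return A `target_library`.
#' @export
read_target_library <- function(path) {
  lines <- readLines(path)
  meta <- lines[startsWith(lines, "##")]
  get_meta <- function(key) {
    m <- regmatches(meta, regexpr(paste0(key, "=[^ ]+"), meta))
    sub(paste0(key, "="), "", m[1])
  }
  cl <- strsplit(strsplit(get_meta("contig_lengths"), ",")[[1]], ":")
  contig_lengths <- stats::setNames(
    as.integer(vapply(cl, `[`, character(1), 2)),
    vapply(cl, `[`, character(1), 1)
  )
  header <- lines[startsWith(lines, "#") & !startsWith(lines, "##")][1]
  cols <- strsplit(sub("^#", "", header), "\t")[[1]]
  body <- lines[!startsWith(lines, "#")]
  records <- if (length(body)) {
    df <- utils::read.table(text = body, sep = "\t", col.names = cols,
                            stringsAsFactors = FALSE, comment.char = "")
    df$occurrences <- lapply(strsplit(df$occurrences, ";", fixed = TRUE), function(v) {
      parts <- strsplit(v, ":", fixed = TRUE)
      tibble::tibble(
        seqid = vapply(parts, `[`, character(1), 1),
        start0 = as.integer(vapply(parts, `[`, character(1), 2)),
        orientation = vapply(parts, `[`, character(1), 3)
      )
    })
    tibble::as_tibble(df)
  } else {
    tibble::tibble(kmer = character(), pam = character(),
                   protospacer = character(), orientation = character(),
                   copy_number = integer(), occurrences = list())
  }
  total <- sum(records$copy_number)
  glen <- as.integer(get_meta("genome_length"))
  pm <- pam_pattern(forward = get_meta("pam_forward"),
                    reverse = get_meta("pam_reverse"),
                    mode = get_meta("pam_mode"))
  structure(list(
    records = records, genome_length = glen, contig_lengths = contig_lengths,
    k = as.integer(get_meta("k")), pam = pm,
    total_count = as.integer(total), dedup_count = nrow(records),
    density_bp = if (total > 0) glen / total else NA_real_
  ), class = "target_library")
}
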