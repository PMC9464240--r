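# Independent reference implementations used to check the package's scanner
# and off-target search. These deliberately take a different route: regex
# PAM tests on fully materialised windows, per-window character comparison
# for Hamming distance, and Biostrings for reverse complements.

iupac_regex <- function(pattern) {
  sets <- list(A = "A", C = "C", G = "G", T = "T",
               R = "[AG]", Y = "[CT]", S = "[CG]", W = "[AT]",
               K = "[GT]", M = "[AC]", B = "[CGT]", D = "[AGT]",
               H = "[ACT]", V = "[ACG]", N = "[ACGT]")
  paste(vapply(strsplit(pattern, "")[[1]], function(l) sets[[l]], character(1)),
        collapse = "")
}

oracle_rc <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

oracle_hamming <- function(a, b) {
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# All k-windows of every sequence, with PAM orientation calls, via regex.
oracle_scan <- function(genome, k = 25, fwd = "TTTV", rev = "VAAA") {
  g <- if (is.data.frame(genome)) stats::setNames(genome$seq, genome$id) else genome
  re_f <- paste0("^", iupac_regex(fwd))
  re_r <- paste0(iupac_regex(rev), "$")
  out <- list()
  for (id in names(g)) {
    s <- g[[id]]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1)
    win <- substring(s, starts, starts + k - 1)
    clean <- !grepl("[^ACGT]", win)
    f <- grepl(re_f, win) & clean
    r <- grepl(re_r, win) & clean
    keep <- f | r
    if (any(keep)) {
      out[[id]] <- data.frame(
        seqid = id, start0 = starts[keep] - 1L, kmer = win[keep],
        orientation = ifelse(f[keep] & r[keep], "both",
                             ifelse(f[keep], "fwd", "rev")),
        stringsAsFactors = FALSE
      )
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    res <- data.frame(seqid = character(), start0 = integer(),
                      kmer = character(), orientation = character())
  }
  res[order(res$seqid, res$start0), , drop = FALSE]
}

# Brute-force double-strand off-target enumeration: materialise every
# window, regex the PAM, per-window character comparison for the distance.
oracle_offtargets <- function(protospacer, genome, max_mm = 3,
                              fwd = "TTTV", rev = "VAAA") {
  g <- if (is.data.frame(genome)) stats::setNames(genome$seq, genome$id) else genome
  m <- nchar(protospacer)
  pl <- nchar(fwd)
  k <- pl + m
  re_f <- paste0("^", iupac_regex(fwd))
  re_r <- paste0(iupac_regex(rev), "$")
  rows <- list()
  for (id in names(g)) {
    s <- g[[id]]
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1)
    win <- substring(s, starts, starts + k - 1)
    clean <- !grepl("[^ACGT]", win)
    for (i in which(grepl(re_f, win) & clean)) {
      mm <- oracle_hamming(substr(win[i], pl + 1, k), protospacer)
      if (mm <= max_mm) {
        rows[[length(rows) + 1]] <- data.frame(
          seqid = id, start0 = i - 1L, strand = "+", mismatches = mm)
      }
    }
    for (i in which(grepl(re_r, win) & clean)) {
      mm <- oracle_hamming(oracle_rc(substr(win[i], 1, m)), protospacer)
      if (mm <= max_mm) {
        rows[[length(rows) + 1]] <- data.frame(
          seqid = id, start0 = i - 1L, strand = "-", mismatches = mm)
      }
    }
  }
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(seqid = character(), start0 = integer(),
                      strand = character(), mismatches = integer())
  }
  res[order(res$seqid, res$start0, res$strand), , drop = FALSE]
}

# Exact two-sided permutation test over all label reassignments.
oracle_permutation_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  obs <- abs(mean(x) - mean(y))
  diffs <- apply(idx, 2, function(i) {
    abs(mean(pooled[i]) - mean(pooled[-i]))
  })
  mean(diffs >= obs - 1e-12)
}

# A C/G-only background cannot contain any TTTV/VAAA/BAAA motif, so planted
# A/T-containing windows are the only PAM sites — handy for sharp fixtures.
cg_background <- function(n, seed = 1) {
  withr::with_seed(seed, paste(sample(c("C", "G"), n, TRUE), collapse = ""))
}

splice_at <- function(seq, start0, insert) {
  substr(seq, start0 + 1, start0 + nchar(insert)) <- insert
  seq
}

random_genome_chr <- function(len, seed, freqs = c(0.25, 0.25, 0.25, 0.25)) {
  withr::with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), len, TRUE, prob = freqs), collapse = ""))
}
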