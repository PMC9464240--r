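# Mature LbCas12a direct repeat (21 nt). The repeat sits 5' of the spacer in
# the assembled crRNA; configurable for other Cas12a orthologs.
LB_CAS12A_REPEAT <- "UAAUUUCUACUAAGUGUAGAU"

#' Extract the protospacer from a target record
#'
#' Forward-orientation targets read the protospacer directly after the PAM
#' (`kmer[5..25]` for defaults); reverse-orientation targets read the reverse
#' complement of the window's first 21 nt. Windows matching both PAMs use the
#' forward reading.
#'
#' @param target A one-row record tibble (from [tidy.target_library()]) or a
#'   list with `kmer` and `orientation`.
#' @param pam_len PAM length (default 4).
#' @return The protospacer DNA string.
#' @export
extract_protospacer <- function(target, pam_len = 4L) {
  kmer <- toupper(target$kmer[[1]])
  orientation <- target$orientation[[1]]
  if (nchar(kmer) <= pam_len) stop("target kmer shorter than the PAM")
  decompose_kmer(kmer, orientation, pam_len)$protospacer
}

#' Design the crRNA for a target
#'
#' Assembles the CRISPR RNA as direct repeat (5') + spacer (3'), where the
#' spacer is the target's protospacer transcribed to RNA (T -> U). The
#' default repeat is the 21-nt mature LbCas12a direct repeat; pass another
#' repeat for other orthologs.
#'
#' @inheritParams extract_protospacer
#' @param repeat_rna Direct-repeat RNA sequence (5' of the spacer).
#' @return One-row tibble: `target_kmer`, `pam`, `protospacer`, `repeat_rna`,
#'   `spacer_rna`, `crrna` (the full repeat+spacer RNA).
#' @examples
#' rec <- tidy(scan_targets(c(s = "TTTACCCCCCCCCCCCCCCCCCCCCG")))[1, ]
#' design_crrna(rec)$crrna
#' @export
design_crrna <- function(target, repeat_rna = LB_CAS12A_REPEAT, pam_len = 4L) {
  repeat_rna <- toupper(repeat_rna)
  if (!nzchar(repeat_rna) ||
      stringi::stri_detect_regex(repeat_rna, "[^ACGU]")) {
    stop("`repeat_rna` must be a non-empty RNA string over A/C/G/U")
  }
  proto <- extract_protospacer(target, pam_len = pam_len)
  kmer <- toupper(target$kmer[[1]])
  spacer <- dna_to_rna(proto)
  tibble::tibble(
    target_kmer = kmer,
    pam = decompose_kmer(kmer, target$orientation[[1]], pam_len)$pam,
    protospacer = proto,
    repeat_rna = repeat_rna,
    spacer_rna = spacer,
    crrna = paste0(repeat_rna, spacer)
  )
}

#' Design crRNAs for every record in a table
#'
#' @param candidates Record tibble with `kmer` and `orientation` columns.
#' @inheritParams design_crrna
#' @return Tibble with one crRNA row per input record.
#' @export
design_crrnas <- function(candidates, repeat_rna = LB_CAS12A_REPEAT,
                          pam_len = 4L) {
  dplyr::bind_rows(lapply(seq_len(nrow(candidates)), function(i) {
    design_crrna(candidates[i, , drop = FALSE], repeat_rna = repeat_rna,
                 pam_len = pam_len)
  }))
}
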