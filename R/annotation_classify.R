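# Flatten a library's occurrences into window GRanges (1-based, width k),
# remembering which deduplicated record each window belongs to.
occurrence_granges <- function(lib) {
  occ <- dplyr::bind_rows(
    purrr::imap(lib$records$occurrences, function(o, i) {
      tibble::tibble(record = i, seqid = o$seqid, start0 = o$start0)
    })
  )
  if (nrow(occ) == 0) {
    return(list(gr = GenomicRanges::GRanges(), record = integer(0)))
  }
  gr <- GenomicRanges::GRanges(
    seqnames = occ$seqid,
    ranges = IRanges::IRanges(start = occ$start0 + 1L, width = lib$k)
  )
  list(gr = gr, record = occ$record)
}

features_granges <- function(features, keep) {
  f <- features[features$category %in% keep, , drop = FALSE]
  if (nrow(f) == 0) return(GenomicRanges::GRanges())
  GenomicRanges::GRanges(
    seqnames = f$seqid,
    ranges = IRanges::IRanges(start = f$start0 + 1L, end = f$end0)
  )
}

# Occurrence indices whose full window is contained in >= 1 feature interval.
within_idx <- function(occ_gr, feat_gr) {
  if (length(feat_gr) == 0 || length(occ_gr) == 0) return(integer(0))
  unique(S4Vectors::queryHits(
    GenomicRanges::findOverlaps(occ_gr, feat_gr, type = "within")
  ))
}

NC_CATEGORIES <- c("miRNA", "rRNA", "snRNA", "tRNA")

#' Classify targets by genome annotation
#'
#' Partitions a target library's occurrences by annotation class, mirroring
#' the classic classification-statistics table: genome, unannotated regions,
#' annotated regions, coding genes, CDS regions and non-coding RNAs
#' (miRNA/rRNA/snRNA/tRNA). An occurrence belongs to a class when its full
#' k-bp window is contained in a feature of that class ("located in", not
#' merely overlapping). "Annotated" is containment in the union of coding
#' gene and ncRNA intervals, counted once, so annotated + unannotated always
#' equals the genome total even when features overlap; coding-gene and ncRNA
#' rows are not forced to be disjoint.
#'
#' @param lib A `target_library` from [scan_targets()].
#' @param features Feature tibble from [read_gff3()] (or built by hand with
#'   the same columns).
#' @return A tibble with one row per class: `class`, `total_count`
#'   (occurrences), `percentage` (of the genome total), `dedup_count`
#'   (deduplicated records with >= 1 occurrence in the class).
#' @export
classify_targets <- function(lib, features) {
  stopifnot(inherits(lib, "target_library"))
  known <- names(lib$contig_lengths)
  unknown <- setdiff(unique(features$seqid), known)
  if (length(unknown)) {
    warning("ignoring features on unknown seqid(s): ",
            paste(unknown, collapse = ", "))
    features <- features[features$seqid %in% known, , drop = FALSE]
  }

  occ <- occurrence_granges(lib)
  n_occ <- length(occ$gr)

  gr_gene <- features_granges(features, "coding_gene")
  gr_cds <- features_granges(features, "CDS")
  gr_nc <- features_granges(features, NC_CATEGORIES)
  gr_annot <- GenomicRanges::reduce(c(gr_gene, gr_nc))

  idx <- list(
    genome = seq_len(n_occ),
    annotated = within_idx(occ$gr, gr_annot),
    coding_genes = within_idx(occ$gr, gr_gene),
    CDS = within_idx(occ$gr, gr_cds),
    ncRNA = within_idx(occ$gr, gr_nc)
  )
  idx$unannotated <- setdiff(idx$genome, idx$annotated)

  classes <- c("genome", "unannotated", "annotated",
               "coding_genes", "CDS", "ncRNA")
  out <- tibble::tibble(
    class = classes,
    total_count = unname(vapply(idx[classes], length, integer(1))),
    percentage = if (n_occ > 0) .data$total_count / n_occ * 100 else NA_real_,
    dedup_count = unname(vapply(idx[classes], function(i) {
      length(unique(occ$record[i]))
    }, integer(1)))
  )
  class(out) <- c("classification_table", class(out))
  out
}

#' Per-gene CDS target coverage
#'
#' A coding gene counts as covered when at least one target window is fully
#' contained in at least one of its CDS intervals — the statistic behind
#' "targets cover x% of coding genes (CDS regions)". The base-level fraction
#' of CDS sequence under at least one target window is reported as a
#' secondary statistic.
#'
#' @inheritParams classify_targets
#' @return A one-row tibble: `n_genes`, `n_genes_with_cds_target`,
#'   `fraction`, `cds_base_fraction`. `fraction` is `NA` (with a warning)
#'   when there are no coding genes.
#' @export
gene_cds_coverage <- function(lib, features) {
  stopifnot(inherits(lib, "target_library"))
  genes <- features[features$category == "coding_gene", , drop = FALSE]
  cds <- features[features$category == "CDS" & nzchar(features$gene_id), ,
                  drop = FALSE]
  gene_ids <- unique(ifelse(nzchar(genes$gene_id), genes$gene_id,
                            paste0("gene", seq_len(nrow(genes)))))
  n_genes <- length(gene_ids)
  if (n_genes == 0) {
    warning("no coding genes in the annotation; coverage fraction undefined")
    return(tibble::tibble(n_genes = 0L, n_genes_with_cds_target = 0L,
                          fraction = NA_real_, cds_base_fraction = NA_real_))
  }
  occ <- occurrence_granges(lib)
  covered <- character(0)
  cds_base_fraction <- NA_real_
  if (nrow(cds) > 0) {
    gr_cds <- GenomicRanges::GRanges(
      seqnames = cds$seqid,
      ranges = IRanges::IRanges(start = cds$start0 + 1L, end = cds$end0)
    )
    hits <- GenomicRanges::findOverlaps(occ$gr, gr_cds, type = "within")
    covered <- unique(cds$gene_id[S4Vectors::subjectHits(hits)])
    cds_union <- GenomicRanges::reduce(gr_cds)
    win_union <- GenomicRanges::reduce(occ$gr)
    cov_bp <- sum(IRanges::width(GenomicRanges::intersect(cds_union, win_union)))
    cds_base_fraction <- cov_bp / sum(IRanges::width(cds_union))
  }
  n_cov <- length(intersect(covered, gene_ids))
  tibble::tibble(
    n_genes = n_genes,
    n_genes_with_cds_target = n_cov,
    fraction = n_cov / n_genes,
    cds_base_fraction = cds_base_fraction
  )
}
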