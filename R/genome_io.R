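# IUPAC nucleotide codes: letter -> set of concrete bases it stands for.
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

IUPAC_LETTERS <- paste(names(IUPAC_SETS), collapse = "")
# Complement in the same order as IUPAC_LETTERS (V<->B, R<->Y, ...).
IUPAC_COMPLEMENT <- "TGCAYRSWMKVHDBN"

#' Reverse complement of DNA sequences
#'
#' Watson-Crick reverse complement, vectorised over a character vector.
#' IUPAC ambiguity codes are complemented too (e.g. `V` (A/C/G) becomes
#' `B` (C/G/T)), which the PAM machinery relies on: the reverse-strand
#' reading of a `TTTV` motif is `BAAA`.
#'
#' @param x Character vector of DNA sequences over the IUPAC alphabet.
#' @return Character vector of the same length.
#' @examples
#' reverse_complement("TTTA")  # "TAAA"
#' reverse_complement("TTTV")  # "BAAA"
#' @export
reverse_complement <- function(x) {
  if (!is.character(x)) stop("`x` must be a character vector of DNA sequences")
  x <- toupper(x)
  bad <- stringi::stri_detect_regex(x, paste0("[^", IUPAC_LETTERS, "]"))
  if (any(bad, na.rm = TRUE)) {
    stop("illegal character in DNA sequence: ",
         substr(x[which(bad)[1]], 1, 40))
  }
  stringi::stri_reverse(chartr(IUPAC_LETTERS, IUPAC_COMPLEMENT, x))
}

# DNA -> RNA (T -> U); used for crRNA spacers.
dna_to_rna <- function(x) chartr("T", "U", toupper(x))
rna_to_dna <- function(x) chartr("U", "T", toupper(x))

#' Read a genome from FASTA
#'
#' Reads a (optionally gzip-compressed) FASTA file into a genome tibble with
#' one row per sequence record. Sequences are uppercased; record ids are the
#' first whitespace-delimited token of the header (the full header is kept in
#' the `header` column for round-tripping).
#'
#' @param path Path to a FASTA file (plain or `.gz`).
#' @return A tibble with columns `id`, `header`, `seq`, `length`, carrying
#'   class `genome_set`. `sum(length)` is the genome length L used by
#'   [density()] statistics, including N/ambiguity bases.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("not a valid FASTA file: ", path, " (", conditionMessage(e), ")")
  )
  if (length(set) == 0) stop("empty FASTA file: ", path)
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  if (anyDuplicated(ids)) {
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  genome_set(stats::setNames(toupper(as.character(set)), ids), header = headers)
}

#' Construct a genome tibble from named sequences
#'
#' @param seqs Named character vector of DNA sequences (names become ids).
#' @param header Optional full FASTA headers (defaults to the ids).
#' @return A `genome_set` tibble (columns `id`, `header`, `seq`, `length`).
#' @export
genome_set <- function(seqs, header = NULL) {
  if (length(seqs) == 0) stop("a genome must contain at least one sequence")
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) stop("every sequence needs a non-empty id")
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  out <- tibble::tibble(
    id = ids,
    header = if (is.null(header)) ids else header,
    seq = toupper(unname(seqs)),
    length = nchar(unname(seqs))
  )
  class(out) <- c("genome_set", class(out))
  out
}

as_genome_set <- function(genome) {
  if (inherits(genome, "genome_set")) return(genome)
  if (is.data.frame(genome)) {
    stopifnot(all(c("id", "seq") %in% names(genome)))
    return(genome_set(stats::setNames(genome$seq, genome$id),
                      header = if ("header" %in% names(genome)) genome$header else NULL))
  }
  if (inherits(genome, "DNAStringSet") || inherits(genome, "BStringSet")) {
    return(genome_set(stats::setNames(as.character(genome), names(genome))))
  }
  if (is.character(genome)) {
    if (length(genome) == 0) stop("a genome must contain at least one sequence")
    if (is.null(names(genome))) names(genome) <- paste0("seq", seq_along(genome))
    return(genome_set(genome))
  }
  stop("cannot interpret `genome` as a set of sequences")
}

genome_total_length <- function(genome) sum(as_genome_set(genome)$length)

#' Write a genome tibble to FASTA
#'
#' @param genome A `genome_set` tibble (or anything [genome_set()] accepts).
#' @param path Output path; `.gz` suffix compresses.
#' @param width Line width for wrapping.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(genome, path, width = 70L) {
  g <- as_genome_set(genome)
  set <- Biostrings::BStringSet(stats::setNames(g$seq, g$header))
  Biostrings::writeXStringSet(set, path, width = width,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

GFF_NC_TYPES <- c("miRNA", "rRNA", "snRNA", "tRNA")

#' Read genome features from GFF3
#'
#' Parses a GFF3 file (1-based inclusive coordinates) into a feature tibble
#' with 0-based half-open coordinates and a derived `category`:
#'
#' * `gene` records with a protein-coding biotype, or with CDS descendants,
#'   become `coding_gene`;
#' * `CDS` records become `CDS` and carry the ancestral gene's id;
#' * miRNA/rRNA/snRNA/tRNA records (by type or biotype) keep that category;
#' * everything else is `other`.
#'
#' @param path Path to a GFF3 file.
#' @return A tibble with columns `seqid`, `start0`, `end0`, `strand`,
#'   `ftype`, `gene_id`, `category`.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stop("GFF3 file not found: ", path)
  gr <- tryCatch(
    rtracklayer::import(path, format = "gff3"),
    error = function(e) stop("malformed GFF3 in ", path, ": ", conditionMessage(e))
  )
  md <- S4Vectors::mcols(gr)
  ftype <- as.character(md$type)
  fid <- if ("ID" %in% names(md)) as.character(md$ID) else rep(NA_character_, length(gr))
  parent <- if ("Parent" %in% names(md)) {
    vapply(md$Parent, function(p) if (length(p)) as.character(p[[1]]) else NA_character_, character(1))
  } else rep(NA_character_, length(gr))
  biotype <- rep(NA_character_, length(gr))
  for (col in c("gene_biotype", "biotype", "gene_type")) {
    if (col %in% names(md)) {
      v <- as.character(md[[col]])
      biotype[is.na(biotype) & !is.na(v)] <- v[is.na(biotype) & !is.na(v)]
    }
  }

  # Resolve the ancestral gene id of each feature by walking Parent links.
  id2parent <- stats::setNames(parent, fid)
  id2type <- stats::setNames(ftype, fid)
  gene_of <- function(i) {
    cur_id <- fid[i]
    cur_type <- ftype[i]
    steps <- 0L
    while (!is.na(cur_id) && !identical(cur_type, "gene") && steps < 10L) {
      nxt <- id2parent[[cur_id]]
      if (is.null(nxt) || is.na(nxt)) return(NA_character_)
      cur_id <- nxt
      cur_type <- if (!is.null(id2type[[cur_id]])) id2type[[cur_id]] else NA_character_
      steps <- steps + 1L
    }
    if (identical(cur_type, "gene")) cur_id else NA_character_
  }
  gene_id <- vapply(seq_along(gr), function(i) {
    if (ftype[i] == "gene") fid[i] else gene_of(i)
  }, character(1))

  # Genes owning CDS descendants are coding even without a biotype tag.
  cds_genes <- unique(gene_id[ftype == "CDS" & !is.na(gene_id)])
  category <- rep("other", length(gr))
  category[ftype == "CDS"] <- "CDS"
  nc <- ftype %in% GFF_NC_TYPES | (!is.na(biotype) & biotype %in% GFF_NC_TYPES)
  category[nc] <- ifelse(ftype[nc] %in% GFF_NC_TYPES, ftype[nc], biotype[nc])
  is_gene <- ftype == "gene"
  coding <- is_gene & ((!is.na(biotype) & biotype == "protein_coding") | fid %in% cds_genes)
  category[coding] <- "coding_gene"

  tibble::tibble(
    seqid = as.character(GenomicRanges::seqnames(gr)),
    start0 = GenomicRanges::start(gr) - 1L,
    end0 = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    ftype = ftype,
    gene_id = dplyr::coalesce(gene_id, ""),
    category = category
  )
}

#' Read regions from a BED file
#'
#' BED coordinates are already 0-based half-open and are kept as-is.
#'
#' @param path Path to a 3- or 4-column BED file.
#' @return A tibble with columns `seqid`, `start0`, `end0`, `name`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path)
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("seqid", "start0", "end0", "name")[1:4],
                          fill = TRUE, comment.char = "#",
                          colClasses = c("character", "integer", "integer", "character"))
  if (!"name" %in% names(df) || all(is.na(df$name))) df$name <- ""
  df$name[is.na(df$name)] <- ""
  if (any(df$end0 <= df$start0)) stop("BED interval with end <= start in ", path)
  tibble::as_tibble(df)
}

#' Construct a region record
#'
#' @param seqid Sequence id the region lies on.
#' @param start0,end0 0-based half-open coordinates.
#' @param name Region name, e.g. `"ITS2"`.
#' @return One-row tibble with columns `seqid`, `start0`, `end0`, `name`.
#' @export
region <- function(seqid, start0, end0, name = "") {
  stopifnot(start0 >= 0, end0 > start0)
  tibble::tibble(seqid = as.character(seqid), start0 = as.integer(start0),
                 end0 = as.integer(end0), name = as.character(name))
}

# Tabular outputs are TSV with one commented header line naming the columns.
write_tsv_commented <- function(df, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("#", paste(names(df), collapse = "\t")), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

read_tsv_commented <- function(path) {
  header <- readLines(path, n = 1L)
  if (!startsWith(header, "#")) stop("expected a commented '#' header line in ", path)
  cols <- strsplit(sub("^#", "", header), "\t", fixed = TRUE)[[1]]
  df <- utils::read.table(path, sep = "\t", header = FALSE, skip = 1L,
                          col.names = cols, comment.char = "",
                          stringsAsFactors = FALSE)
  tibble::as_tibble(df)
}
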