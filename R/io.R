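#' Read and write FASTA
#'
#' Thin wrappers over Biostrings so every pipeline stage shares one FASTA
#' dialect: sequences as a named character vector, full header lines kept
#' as names.
#'
#' @param x named character vector of sequences.
#' @param path file path.
#' @param type `"AA"` or `"DNA"`.
#' @return `read_fasta`: named character vector.
#' @export
write_fasta <- function(x, path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::AAStringSet(x) else
    Biostrings::DNAStringSet(x)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
read_fasta <- function(path, type = c("AA", "DNA")) {
  type <- match.arg(type)
  set <- if (type == "AA") Biostrings::readAAStringSet(path) else
    Biostrings::readDNAStringSet(path)
  setNames(as.character(set), names(set))
}

#' Write gene models as GFF3
#'
#' Emits `gene` and `exon` features with 1-based inclusive coordinates
#' (converting from the package-internal 0-based half-open intervals) and
#' `ID`/`Parent` attributes.
#'
#' @param genes gene data.frame with an `exons` list-column (see
#'   [generate_genome_fixture()]).
#' @param path output path.
#' @export
write_gene_gff3 <- function(genes, path) {
  lines <- "##gff-version 3"
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    lines <- c(lines, sprintf(
      "%s\tampevo\tgene\t%d\t%d\t.\t%s\t.\tID=%s;family=%s",
      g$scaffold, g$start + 1L, g$end, g$strand, g$gene_id, g$family_label))
    ex <- genes$exons[[i]]
    for (e in seq_len(nrow(ex)))
      lines <- c(lines, sprintf(
        "%s\tampevo\texon\t%d\t%d\t.\t%s\t.\tID=%s.e%d;Parent=%s",
        g$scaffold, ex[e, 1] + 1L, ex[e, 2], g$strand, g$gene_id, e, g$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Inverse of [write_gene_gff3()]: returns the package-internal gene table
#' (0-based half-open, `exons` list-column).
#'
#' @param path GFF3 file.
#' @return gene data.frame.
#' @export
read_gene_gff3 <- function(path) {
  ln <- readLines(path)
  ln <- ln[!startsWith(ln, "#") & nzchar(ln)]
  f <- do.call(rbind, strsplit(ln, "\t"))
  attr_of <- function(attrs, key) sub(paste0(".*", key, "=([^;]+).*"), "\\1", attrs)
  is_gene <- f[, 3] == "gene"
  genes <- data.frame(gene_id = attr_of(f[is_gene, 9], "ID"),
                      scaffold = f[is_gene, 1],
                      start = as.integer(f[is_gene, 4]) - 1L,
                      end = as.integer(f[is_gene, 5]),
                      strand = f[is_gene, 7],
                      family_label = attr_of(f[is_gene, 9], "family"))
  ex <- f[f[, 3] == "exon", , drop = FALSE]
  parents <- attr_of(ex[, 9], "Parent")
  genes$exons <- lapply(genes$gene_id, function(id) {
    m <- ex[parents == id, , drop = FALSE]
    cbind(as.integer(m[, 4]) - 1L, as.integer(m[, 5]))
  })
  genes
}

#' Write / read TE annotations as BED-like TSV
#'
#' Columns: scaffold, start, end (0-based half-open), strand, te_family,
#' te_class, divergence. No header, tab-separated, as produced by
#' RepeatMasker-out conversion scripts.
#'
#' @param tes TE data.frame.
#' @param path file path.
#' @export
write_te_bed <- function(tes, path) {
  write.table(tes[, c("scaffold", "start", "end", "strand", "te_family",
                      "te_class", "divergence")],
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' @rdname write_te_bed
#' @export
read_te_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE,
                   col.names = c("scaffold", "start", "end", "strand",
                                 "te_family", "te_class", "divergence"),
                   stringsAsFactors = FALSE)
  validate_te(df)
}

#' Write / read a family count matrix as TSV
#'
#' Families in rows, species in columns, first column `family`.
#'
#' @param counts matrix with rownames (families) and colnames (species).
#' @param path file path.
#' @export
write_counts_tsv <- function(counts, path) {
  df <- data.frame(family = rownames(counts), counts, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$family
  storage.mode(m) <- "integer"
  m
}
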