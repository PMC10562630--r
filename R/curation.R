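#' Peptide record
#'
#' Lightweight container for a protein sequence with optional precursor
#' region annotations (signal peptide, propeptide, mature peptide) given as
#' 1-based inclusive index ranges.
#'
#' @param id sequence identifier.
#' @param sequence amino-acid string (non-empty). A single trailing `*`
#'   (translated terminal stop) is stripped silently.
#' @param source_tag free-text provenance label.
#' @param regions optional named list of `c(start, end)` ranges with names
#'   among `signal`, `propeptide`, `mature`; ranges must be in order,
#'   disjoint and within the sequence.
#' @return a `peptide_record` list.
#' @export
peptide_record <- function(id, sequence, source_tag = "", regions = NULL) {
  sequence <- toupper(sequence)
  sequence <- sub("\\*$", "", sequence)
  if (!nzchar(sequence)) stop("sequence must be non-empty", call. = FALSE)
  if (!is.null(regions)) {
    bad <- setdiff(names(regions), c("signal", "propeptide", "mature"))
    if (length(bad)) stop("unknown region(s): ", paste(bad, collapse = ", "),
                          call. = FALSE)
    ord <- regions[order(vapply(regions, `[`, numeric(1), 1))]
    ends <- vapply(ord, `[`, numeric(1), 2)
    starts <- vapply(ord, `[`, numeric(1), 1)
    if (any(starts < 1) || any(ends > nchar(sequence)) || any(starts > ends) ||
        (length(ord) > 1 && any(starts[-1] <= ends[-length(ends)])))
      stop("regions must be ordered, disjoint and within bounds", call. = FALSE)
  }
  structure(list(id = id, sequence = sequence, source_tag = source_tag,
                 regions = regions),
            class = "peptide_record")
}

count_cys <- function(seq) lengths(regmatches(seq, gregexpr("C", seq, fixed = TRUE)))

#' Sequence-level peptide curation filters
#'
#' Applies, in this documented order, the predicates: length within
#' `[min_len, max_len]`; standard 20-letter alphabet; no internal stop
#' (`*`); at least `min_cys` cysteines; not an exact duplicate of an
#' earlier sequence (case-folded; first occurrence kept). The rejection
#' reason recorded is the first failing predicate.
#'
#' @param records list of [peptide_record()]s (or plain character vector of
#'   sequences, which are wrapped with positional ids).
#' @param min_len,max_len length band in residues (defaults 10 and 200).
#' @param min_cys minimum cysteine count (default 2).
#' @param dedup drop exact duplicate sequences (default TRUE).
#' @return a `filter_report` list with `kept` (records) and `rejected`
#'   (data.frame of id, reason); reasons are from
#'   `c("too_short", "too_long", "nonstandard_aa", "internal_stop",
#'   "low_cysteine", "duplicate")`.
#' @export
filter_peptides <- function(records, min_len = 10, max_len = 200, min_cys = 2,
                            dedup = TRUE) {
  if (min_len > max_len || min_len <= 0) stop("bad length band", call. = FALSE)
  if (is.character(records))
    records <- lapply(seq_along(records), function(i)
      peptide_record(paste0("seq", i), records[i]))
  kept <- list()
  seen <- character()
  rejected <- data.frame(id = character(), reason = character())
  for (rec in records) {
    s <- rec$sequence
    reason <- NULL
    n <- nchar(s)
    chars <- strsplit(s, "")[[1]]
    if (n < min_len) reason <- "too_short"
    else if (n > max_len) reason <- "too_long"
    else if (any(!chars %in% c(AA20, "*"))) reason <- "nonstandard_aa"
    else if (any(chars == "*")) reason <- "internal_stop"
    else if (count_cys(s) < min_cys) reason <- "low_cysteine"
    else if (dedup && s %in% seen) reason <- "duplicate"
    if (is.null(reason)) {
      kept <- c(kept, list(rec))
      seen <- c(seen, s)
    } else {
      rejected <- rbind(rejected, data.frame(id = rec$id, reason = reason))
    }
  }
  structure(list(kept = kept, rejected = rejected), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("Peptide filter report:", length(x$kept), "kept,",
      nrow(x$rejected), "rejected\n")
  if (nrow(x$rejected)) print(table(x$rejected$reason))
  invisible(x)
}

#' Cysteine-motif class of a peptide
#'
#' Defensins carry a conserved six-cysteine motif, cathelicidins a
#' four-cysteine motif in the cathelin propeptide. The examined region is
#' the annotated mature region when present, otherwise the full sequence.
#' Classification is by cysteine count: `>= 6` is `defensin6`, 4--5 is
#' `cathelicidin4`, anything else `none`. The band edges are exposed.
#'
#' @param record a [peptide_record()] or bare sequence string.
#' @param region `"mature-if-annotated-else-full"` (default), `"full"`, or
#'   a region name.
#' @param defensin_min minimum cysteines for `defensin6` (default 6).
#' @param cathelicidin_range inclusive cysteine band for `cathelicidin4`
#'   (default `c(4, 5)`).
#' @return one of `"defensin6"`, `"cathelicidin4"`, `"none"`.
#' @export
cysteine_motif_class <- function(record,
                                 region = "mature-if-annotated-else-full",
                                 defensin_min = 6,
                                 cathelicidin_range = c(4, 5)) {
  if (is.character(record)) record <- peptide_record("x", record)
  seq <- record$sequence
  if (region == "mature-if-annotated-else-full") {
    r <- record$regions[["mature"]]
    if (!is.null(r)) seq <- substr(seq, r[1], r[2])
  } else if (region != "full") {
    r <- record$regions[[region]]
    if (is.null(r)) stop("region not annotated: ", region, call. = FALSE)
    seq <- substr(seq, r[1], r[2])
  }
  nc <- count_cys(seq)
  if (nc >= defensin_min) "defensin6"
  else if (nc >= cathelicidin_range[1] && nc <= cathelicidin_range[2]) "cathelicidin4"
  else "none"
}

#' Filter gene models by genomic span
#'
#' Keeps genes whose genomic span is at least `min_nt` nucleotides; shorter
#' loci do not translate to full precursor peptides (signal, propeptide and
#' mature regions). The boundary is inclusive.
#'
#' @param genes data.frame of gene models with `start`, `end` columns
#'   (0-based half-open coordinates).
#' @param min_nt minimum span in bp (default 200).
#' @return the kept rows of `genes`.
#' @export
filter_genes_by_length <- function(genes, min_nt = 200) {
  if (nrow(genes) == 0) return(genes)
  if (any(genes$end <= genes$start)) stop("invalid gene coordinates", call. = FALSE)
  genes[(genes$end - genes$start) >= min_nt, , drop = FALSE]
}
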