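TE_CLASSES <- c("DIRS", "DNA", "LINE", "LTR", "RC", "Retroposon", "SINE",
                "Unknown", "Simple_repeat", "Low_complexity")

validate_te <- function(tes) {
  req <- c("scaffold", "start", "end", "strand", "te_family", "te_class",
           "divergence")
  if (!all(req %in% names(tes)))
    stop("TE table must have columns ", paste(req, collapse = ", "), call. = FALSE)
  if (nrow(tes) && (any(tes$start >= tes$end) || any(tes$divergence < 0)))
    stop("malformed TE intervals", call. = FALSE)
  tes
}

#' Resolve overlapping transposable-element annotations
#'
#' Cleans a RepeatMasker-style TE table before counting TEs in genes:
#' \enumerate{
#'   \item Simple-repeat and low-complexity records are discarded.
#'   \item Same-scaffold, same-strand pairs that overlap or lie within
#'     `max_gap` bp of each other are candidates.
#'   \item If the overlap covers at least `min_recip_cov` of the longer
#'     element, the pair merges into one record spanning the union and
#'     inherits family, class and divergence from the lower-divergence
#'     member. With `both_fractions = TRUE` the coverage test is applied
#'     to both members (overlap relative to each length).
#'   \item Overlapping candidates failing the coverage test keep only the
#'     lower-divergence member (or both, with `keep_both_unresolved`).
#'   \item Near-adjacent candidates with no actual overlap keep both.
#' }
#' The pass runs left-to-right on sorted input and iterates to a fixpoint,
#' so the result is idempotent.
#'
#' @param tes data.frame with columns `scaffold`, `start`, `end` (0-based
#'   half-open), `strand`, `te_family`, `te_class`, `divergence` (percent
#'   to consensus).
#' @param max_gap candidate distance in bp (default 10).
#' @param min_recip_cov coverage fraction of the longer element required to
#'   merge (default 0.80).
#' @param both_fractions apply the coverage test to both elements.
#' @param keep_both_unresolved keep both members of unresolvable overlaps
#'   instead of dropping the higher-divergence one.
#' @return the resolved TE data.frame.
#' @export
resolve_te_overlaps <- function(tes, max_gap = 10, min_recip_cov = 0.80,
                                both_fractions = FALSE,
                                keep_both_unresolved = FALSE) {
  tes <- validate_te(tes)
  tes <- tes[!tes$te_class %in% c("Simple_repeat", "Low_complexity"), ,
             drop = FALSE]
  repeat {
    tes <- tes[order(tes$scaffold, tes$strand, tes$start, tes$end), ,
               drop = FALSE]
    rownames(tes) <- NULL
    changed <- FALSE
    out <- list()
    for (grp in split(tes, list(tes$scaffold, tes$strand), drop = TRUE)) {
      i <- 1L
      while (i <= nrow(grp)) {
        cur <- grp[i, ]
        j <- i + 1L
        while (j <= nrow(grp)) {
          nxt <- grp[j, ]
          gap <- nxt$start - cur$end
          if (gap > max_gap) break
          ov <- min(cur$end, nxt$end) - max(cur$start, nxt$start)
          len_cur <- cur$end - cur$start
          len_nxt <- nxt$end - nxt$start
          longer <- max(len_cur, len_nxt)
          covered <- if (both_fractions)
            ov >= min_recip_cov * len_cur && ov >= min_recip_cov * len_nxt
          else ov >= min_recip_cov * longer
          if (ov > 0 && covered) {           # merge into union
            winner <- if (cur$divergence <= nxt$divergence) cur else nxt
            cur$start <- min(cur$start, nxt$start)
            cur$end <- max(cur$end, nxt$end)
            cur$te_family <- winner$te_family
            cur$te_class <- winner$te_class
            cur$divergence <- winner$divergence
            grp <- grp[-j, , drop = FALSE]
            changed <- TRUE
          } else if (ov > 0 && !keep_both_unresolved) { # drop worse member
            if (cur$divergence <= nxt$divergence) {
              grp <- grp[-j, , drop = FALSE]
            } else {
              grp[i, ] <- nxt
              cur <- grp[i, ]
              grp <- grp[-j, , drop = FALSE]
            }
            changed <- TRUE
          } else {
            j <- j + 1L                      # gap <= max_gap, no overlap
          }
        }
        grp[i, ] <- cur
        i <- i + 1L
      }
      out <- c(out, list(grp))
    }
    tes <- do.call(rbind, out) %||%
      tes[integer(0), , drop = FALSE]
    if (!changed) break
  }
  tes <- tes[order(tes$scaffold, tes$start, tes$end), , drop = FALSE]
  rownames(tes) <- NULL
  tes
}

#' Intersect gene models with resolved TEs
#'
#' A TE counts for a gene when it overlaps the gene span by at least 1 bp;
#' its contribution to the summed TE length is clipped to the gene span.
#' TEs that overlap any exon are tagged `exonic` and excluded from the
#' intronic per-gene summary, which is what intron TE accumulation tables
#' report.
#'
#' @param genes data.frame with `gene_id`, `scaffold`, `start`, `end`,
#'   `strand` and an `exons` list-column of two-column matrices (0-based
#'   half-open exon intervals), e.g. from [generate_genome_fixture()].
#' @param tes resolved TE data.frame (see [resolve_te_overlaps()]).
#' @return list with `summary` (per gene: `te_count`, `te_total_length`,
#'   per-class counts; intronic TEs only) and `hits` (per gene-TE pair
#'   with an `exonic` flag).
#' @export
intersect_genes_tes <- function(genes, tes) {
  classes <- setdiff(TE_CLASSES, c("Simple_repeat", "Low_complexity"))
  empty_sum <- function() {
    s <- data.frame(gene_id = genes$gene_id, te_count = 0L,
                    te_total_length = 0L)
    for (cl in classes) s[[cl]] <- 0L
    s
  }
  summary <- empty_sum()
  hits <- list()
  if (nrow(tes)) {
    for (gi in seq_len(nrow(genes))) {
      g <- genes[gi, ]
      cand <- tes[tes$scaffold == g$scaffold & tes$start < g$end &
                  tes$end > g$start, , drop = FALSE]
      if (!nrow(cand)) next
      ex <- genes$exons[[gi]]
      exq <- IRanges::IRanges(start = ex[, 1] + 1L, end = ex[, 2])
      teq <- IRanges::IRanges(start = cand$start + 1L, end = cand$end)
      exonic <- IRanges::overlapsAny(teq, exq)
      clip <- pmin(cand$end, g$end) - pmax(cand$start, g$start)
      hits[[length(hits) + 1]] <- data.frame(
        gene_id = g$gene_id, te_family = cand$te_family,
        te_class = cand$te_class, start = cand$start, end = cand$end,
        clipped_length = clip, exonic = exonic)
      keep <- !exonic
      summary$te_count[gi] <- sum(keep)
      summary$te_total_length[gi] <- sum(clip[keep])
      tab <- table(factor(cand$te_class[keep], levels = classes))
      for (cl in classes) summary[[cl]][gi] <- as.integer(tab[[cl]])
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(gene_id = character(), te_family = character(),
               te_class = character(), start = integer(), end = integer(),
               clipped_length = integer(), exonic = logical())
  list(summary = summary, hits = hits)
}

#' Gene-structure summary per AMP family
#'
#' Tallies exon counts (with percentages over the per-family total) and
#' reports the median and range of genomic spans, per AMP family label --
#' the layout of a full-length-gene structure table.
#'
#' @param genes data.frame with `gene_id`, `family_label`, `start`, `end`
#'   and either an `exons` list-column or an `exon_count` column.
#' @return data.frame: family, exon_count, n, percent (2 significant
#'   figures), plus per-family `median_length`, `min_length`, `max_length`.
#' @export
gene_structure_summary <- function(genes) {
  if (!"exon_count" %in% names(genes))
    genes$exon_count <- vapply(genes$exons, nrow, integer(1))
  genes$span <- genes$end - genes$start
  out <- lapply(split(genes, genes$family_label), function(g) {
    tab <- table(g$exon_count)
    data.frame(family = g$family_label[1],
               exon_count = as.integer(names(tab)),
               n = as.integer(tab),
               percent = signif(100 * as.integer(tab) / nrow(g), 2),
               family_total = nrow(g),
               median_length = median(g$span),
               min_length = min(g$span),
               max_length = max(g$span))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Detect gene clusters by single-linkage chaining
#'
#' Consecutive genes on the same scaffold join a cluster when the gap
#' between them (next start minus previous end) is at most `max_gap_bp`.
#' Chains of length 1 are reported as singletons, not clusters.
#'
#' @param genes data.frame with `gene_id`, `scaffold`, `start`, `end`.
#' @param max_gap_bp chaining distance (default 10000, the upper end of
#'   observed AMP cluster extents).
#' @return list with `clusters` (list of gene-id vectors, length >= 2) and
#'   `singletons` (gene ids).
#' @export
detect_clusters <- function(genes, max_gap_bp = 10000) {
  clusters <- list(); singletons <- character()
  for (g in split(genes, genes$scaffold)) {
    g <- g[order(g$start), ]
    if (nrow(g) == 1) { singletons <- c(singletons, g$gene_id); next }
    gap <- g$start[-1] - g$end[-nrow(g)]
    grp <- cumsum(c(0, gap > max_gap_bp))
    for (ids in split(g$gene_id, grp)) {
      if (length(ids) >= 2) clusters <- c(clusters, list(ids))
      else singletons <- c(singletons, ids)
    }
  }
  list(clusters = clusters, singletons = singletons)
}
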