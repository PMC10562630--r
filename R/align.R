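blosum62 <- local({
  env <- new.env()
  function() {
    if (is.null(env$m)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      env$m <- e$BLOSUM62
    }
    env$m
  }
})

#' Smith--Waterman local alignment with affine gaps
#'
#' Optimal local alignment score between two protein sequences under a
#' substitution matrix and affine gap penalties: a gap of length `L` costs
#' `gap_open + gap_extend * L`. Implemented with the standard three-state
#' (match / gap-in-query / gap-in-target) dynamic programme; the score of
#' the empty alignment is 0.
#'
#' @param query,target amino-acid strings (standard alphabet, non-empty).
#' @param matrix substitution matrix (default Biostrings' BLOSUM62).
#' @param gap_open gap opening cost (default 11, BLAST convention).
#' @param gap_extend per-residue gap extension cost (default 1).
#' @return list with `score` (raw score, matrix units), `query_range` and
#'   `target_range` (1-based inclusive spans of the optimal alignment;
#'   `c(0, 0)` if the best score is 0).
#' @examples
#' local_align("ACDE", "ACDE")$score  # 24
#' @export
local_align <- function(query, target, matrix = NULL, gap_open = 11,
                        gap_extend = 1) {
  if (!nzchar(query) || !nzchar(target))
    stop("sequences must be non-empty", call. = FALSE)
  m <- matrix %||% blosum62()
  q <- strsplit(toupper(query), "")[[1]]
  t_ <- strsplit(toupper(target), "")[[1]]
  if (any(!q %in% rownames(m)) || any(!t_ %in% colnames(m)))
    stop("sequence contains residues absent from the substitution matrix",
         call. = FALSE)
  nq <- length(q); nt <- length(t_)
  H <- matrix(0, nq + 1, nt + 1)     # best local score ending at (i, j)
  E <- matrix(-Inf, nq + 1, nt + 1)  # gap in query (consuming target)
  F_ <- matrix(-Inf, nq + 1, nt + 1) # gap in target (consuming query)
  best <- 0; best_ij <- c(0L, 0L)
  sub <- m[q, t_, drop = FALSE]
  for (i in seq_len(nq)) {
    for (j in seq_len(nt)) {
      E[i + 1, j + 1] <- max(H[i + 1, j] - gap_open - gap_extend,
                             E[i + 1, j] - gap_extend)
      F_[i + 1, j + 1] <- max(H[i, j + 1] - gap_open - gap_extend,
                              F_[i, j + 1] - gap_extend)
      h <- max(0, H[i, j] + sub[i, j], E[i + 1, j + 1], F_[i + 1, j + 1])
      H[i + 1, j + 1] <- h
      if (h > best) { best <- h; best_ij <- c(i, j) }
    }
  }
  # recover spans by walking back over positive-score cells
  qr <- tr <- c(0L, 0L)
  if (best > 0) {
    i <- best_ij[1]; j <- best_ij[2]
    qr[2] <- i; tr[2] <- j
    state <- "H"
    while (i > 0 && j > 0 && H[i + 1, j + 1] > 0) {
      if (state == "H") {
        if (H[i + 1, j + 1] == H[i, j] + sub[i, j]) { i <- i - 1; j <- j - 1 }
        else if (H[i + 1, j + 1] == E[i + 1, j + 1]) state <- "E"
        else if (H[i + 1, j + 1] == F_[i + 1, j + 1]) state <- "F"
        else break  # cell started a fresh alignment
      } else if (state == "E") {
        if (E[i + 1, j + 1] == E[i + 1, j] - gap_extend) j <- j - 1
        else { j <- j - 1; state <- "H" }
      } else {
        if (F_[i + 1, j + 1] == F_[i, j + 1] - gap_extend) i <- i - 1
        else { i <- i - 1; state <- "H" }
      }
    }
    qr[1] <- i + 1L; tr[1] <- j + 1L
  }
  list(score = best, query_range = qr, target_range = tr)
}

#' Karlin--Altschul bit score and e-value
#'
#' Converts a raw local-alignment score into a bit score and the expected
#' number of chance hits in a search of a query of length `m` against a
#' database of total length `n`:
#' `bit = (lambda * S - ln K) / ln 2`, `E = m * n * 2^(-bit)`.
#' Defaults are the published gapped-BLOSUM62 constants.
#'
#' @param raw_score raw alignment score S.
#' @param m query length (>= 1).
#' @param n database length (>= 1).
#' @param K,lambda Karlin--Altschul parameters (defaults 0.041, 0.267).
#' @return list with `bit_score` and `evalue`.
#' @examples
#' ka_evalue(100, 100, 100)  # bit ~43.1, E ~1e-9
#' @export
ka_evalue <- function(raw_score, m, n, K = 0.041, lambda = 0.267) {
  if (m < 1 || n < 1) stop("m and n must be >= 1", call. = FALSE)
  bit <- (lambda * raw_score - log(K)) / log(2)
  list(bit_score = bit, evalue = m * n * 2^(-bit))
}

#' Best-hit subfamily assignment
#'
#' Aligns every query against a labelled reference set with
#' [local_align()], converts scores to e-values with [ka_evalue()] (the
#' database length is the total reference residue count), and assigns each
#' query the family of its lowest-e-value hit when that e-value is
#' strictly below `e_max`. Ties are broken by higher raw score, then by
#' lexicographically smaller target id.
#'
#' @param queries named character vector of query sequences.
#' @param reference_db named character vector of reference sequences;
#'   `families` gives the family label per reference (same order), or
#'   reference names of the form `id family=LABEL` are parsed.
#' @param families character vector of family labels per reference.
#' @param e_max e-value cutoff (default 1e-6, strict `<`).
#' @return data.frame per query: `query`, `family` (NA when unassigned),
#'   `target`, `bit_score`, `evalue`.
#' @export
best_hit_assign <- function(queries, reference_db, families = NULL,
                            e_max = 1e-6) {
  if (length(reference_db) == 0) {
    warning("empty reference database; all queries unassigned", call. = FALSE)
    return(data.frame(query = names(queries), family = NA_character_,
                      target = NA_character_, bit_score = NA_real_,
                      evalue = NA_real_))
  }
  if (is.null(families)) {
    families <- sub(".*family=([^ ]+).*", "\\1", names(reference_db))
    names(reference_db) <- sub(" .*", "", names(reference_db))
  }
  dbn <- sum(nchar(reference_db))
  out <- lapply(seq_along(queries), function(qi) {
    qseq <- queries[qi]
    hits <- lapply(seq_along(reference_db), function(ti) {
      al <- local_align(qseq, reference_db[ti])
      ka <- ka_evalue(al$score, nchar(qseq), dbn)
      data.frame(target = names(reference_db)[ti], family = families[ti],
                 raw = al$score, bit_score = ka$bit_score, evalue = ka$evalue)
    })
    hits <- do.call(rbind, hits)
    hits <- hits[order(hits$evalue, -hits$raw, hits$target), ]
    top <- hits[1, ]
    if (top$evalue < e_max)
      data.frame(query = names(queries)[qi], family = top$family,
                 target = top$target, bit_score = top$bit_score,
                 evalue = top$evalue)
    else
      data.frame(query = names(queries)[qi], family = NA_character_,
                 target = top$target, bit_score = top$bit_score,
                 evalue = top$evalue)
  })
  do.call(rbind, out)
}

#' Relative bit-score hit filtering
#'
#' For each query, keeps hits whose bit score exceeds `fraction` times the
#' query's best bit score (strict `>`); the best hit itself is always
#' retained, so `fraction = 1` keeps exactly the best. This is the
#' fractional-of-best criterion used to retain ortholog hits (75% for
#' beta-defensins, 80% for alpha-defensins and cathelicidins).
#'
#' @param hits data.frame with columns `query` and `bit_score`.
#' @param fraction threshold fraction in (0, 1].
#' @return the kept rows of `hits`.
#' @export
relative_bitscore_filter <- function(hits, fraction) {
  if (fraction <= 0 || fraction > 1)
    stop("`fraction` must be in (0, 1]", call. = FALSE)
  if (nrow(hits) == 0) return(hits)
  keep <- unlist(lapply(split(seq_len(nrow(hits)), hits$query), function(idx) {
    b <- hits$bit_score[idx]
    idx[b > fraction * max(b) | b == max(b)]
  }))
  hits[sort(keep), , drop = FALSE]
}
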