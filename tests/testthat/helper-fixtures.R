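# Shared fixture builders; everything is generated in code, no files.

te_row <- function(start, end, div, strand = "+", cl = "LINE",
                   scaffold = "s", fam = "L1") {
  data.frame(scaffold = scaffold, start = start, end = end, strand = strand,
             te_family = fam, te_class = cl, divergence = div)
}

# star tree with unit branch lengths (ultrametric, no shared history)
star_tree <- function(n) {
  tr <- ape::stree(n, type = "star")
  tr$edge.length <- rep(1, nrow(tr$edge))
  tr$tip.label <- sprintf("sp%02d", seq_len(n))
  tr
}

# Brute-force local alignment oracle: enumerate every monotone alignment of
# every substring pair recursively, scoring affine gaps (open + len * ext).
# Exponential; only for tiny strings. Independent of the DP implementation.
brute_local_align <- function(q, t, m, gap_open = 11, gap_extend = 1) {
  qc <- strsplit(q, "")[[1]]; tc <- strsplit(t, "")[[1]]
  best <- 0
  rec <- function(i, j, score, state) {
    # i, j: next positions to consume in the current substrings
    best <<- max(best, score)
    if (i <= length(qc) && j <= length(tc)) {
      rec(i + 1, j + 1, score + m[qc[i], tc[j]], "M")
    }
    if (i <= length(qc)) {
      pen <- if (state == "I") gap_extend else gap_open + gap_extend
      rec(i + 1, j, score - pen, "I")
    }
    if (j <= length(tc)) {
      pen <- if (state == "D") gap_extend else gap_open + gap_extend
      rec(i, j + 1, score - pen, "D")
    }
  }
  for (i0 in seq_along(qc)) for (j0 in seq_along(tc))
    rec(i0, j0, 0, "S")
  best
}

# Enumeration oracle for the family-size likelihood on 2- and 3-tip trees:
# direct summation over root (and internal) states using the transition
# probability, independent of the pruning recursion.
enum_loglik_2tip <- function(t1, t2, c1, c2, lambda, root_states, smax = 60) {
  mean(vapply(root_states, function(r)
    bdp_transition_prob(r, c1, lambda, t1) *
      bdp_transition_prob(r, c2, lambda, t2), numeric(1))) |> log()
}

# tree ((A:ta, B:tb):tin, C:tc); internal node state summed 0..smax
enum_loglik_3tip <- function(ta, tb, tin, tc, ca, cb, cc, lambda,
                             root_states, smax = 60) {
  per_root <- vapply(root_states, function(r) {
    inner <- vapply(0:smax, function(s)
      bdp_transition_prob(r, s, lambda, tin) *
        bdp_transition_prob(s, ca, lambda, ta) *
        bdp_transition_prob(s, cb, lambda, tb), numeric(1))
    sum(inner) * bdp_transition_prob(r, cc, lambda, tc)
  }, numeric(1))
  log(mean(per_root))
}
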