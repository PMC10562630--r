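#' Transition probability of the equal-rate linear birth--death process
#'
#' Probability that a gene family of size `s` at the start of a branch has
#' size `c` after time `t`, when each gene copy independently duplicates and
#' is lost at the same rate `lambda` (the critical linear birth--death
#' process used for gene-family-size evolution). Zero copies is absorbing.
#'
#' The closed form is
#' \deqn{P(c \mid s) = \sum_{j=0}^{\min(s,c)} \binom{s}{j}
#'   \binom{s+c-j-1}{s-1} \alpha^{s+c-2j} (1-2\alpha)^j,
#'   \quad \alpha = \frac{\lambda t}{1+\lambda t}.}
#'
#' @param s parent (ancestral) count, non-negative integer.
#' @param c child (descendant) count, non-negative integer; may be a vector.
#' @param lambda birth = death rate per gene copy per unit time (>= 0).
#' @param t branch length in time units (>= 0).
#' @return numeric vector of probabilities, one per element of `c`.
#' @examples
#' bdp_transition_prob(1, 0, 0.5, 1)  # extinction probability = 1/3
#' sum(bdp_transition_prob(3, 0:100, 0.5, 1))  # ~1
#' @export
bdp_transition_prob <- function(s, c, lambda, t) {
  if (any(s < 0) || any(c < 0) || lambda < 0 || t < 0)
    stop("s, c, lambda and t must all be non-negative", call. = FALSE)
  s <- as.integer(s)
  if (length(s) != 1L) stop("`s` must be a single count", call. = FALSE)
  c <- as.integer(c)
  a <- lambda * t / (1 + lambda * t)
  vapply(c, function(ci) {
    if (s == 0L) return(as.numeric(ci == 0L))
    if (a == 0) return(as.numeric(ci == s))
    j <- 0:min(s, ci)
    terms <- lchoose(s, j) + lchoose(s + ci - j - 1, s - 1) +
      (s + ci - 2 * j) * log(a)
    onem2a <- 1 - 2 * a
    # (1-2a)^j: handle a = 1/2 (lambda*t = 1) where only j = 0 contributes
    pw <- ifelse(j == 0, 0, j * log(abs(onem2a)))
    sgn <- if (onem2a >= 0) rep(1, length(j)) else (-1)^j
    if (onem2a == 0) { keep <- j == 0; terms <- terms[keep]; pw <- pw[keep]; sgn <- sgn[keep] }
    sum(sgn * exp(terms + pw))
  }, numeric(1))
}

# (N+1) x (N+1) matrix M[s+1, c+1] = P(c | s) for s, c in 0..N.
# Same closed form as bdp_transition_prob, vectorised over the whole grid
# (one pass per j; impossible (s, c, j) combinations drop out through
# lchoose() returning -Inf).
bdp_transition_matrix <- function(N, lambda, t) {
  a <- lambda * t / (1 + lambda * t)
  if (a == 0) return(diag(N + 1))
  S <- matrix(0:N, N + 1, N + 1)
  C <- matrix(0:N, N + 1, N + 1, byrow = TRUE)
  onem2a <- 1 - 2 * a
  M <- matrix(0, N + 1, N + 1)
  for (j in 0:N) {
    lg <- lchoose(S, j) + lchoose(S + C - j - 1, S - 1) +
      (S + C - 2 * j) * log(a)
    if (j > 0) {
      if (onem2a == 0) break
      lg <- lg + j * log(abs(onem2a))
    }
    term <- exp(lg)
    term[!is.finite(term) | S < j | C < j] <- 0  # j runs 0..min(s, c) only
    if (onem2a < 0 && j %% 2 == 1) M <- M - term else M <- M + term
  }
  M[1, ] <- 0
  M[1, 1] <- 1   # zero is absorbing
  pmax(M, 0)
}

#' Mean-one discrete-gamma category multipliers
#'
#' Yang-style discretisation: `k` equal-probability categories of a
#' Gamma(shape, rate = shape) distribution (mean one), each represented by
#' its conditional category mean. Multiplying a rate by these factors with
#' equal weights models among-family rate variation.
#'
#' @param shape gamma shape parameter alpha (> 0).
#' @param k number of categories (>= 1).
#' @return numeric vector of `k` multipliers averaging exactly 1.
#' @export
discrete_gamma_categories <- function(shape, k) {
  if (shape <= 0) stop("`shape` must be positive", call. = FALSE)
  k <- as.integer(k)
  if (k < 1) stop("`k` must be >= 1", call. = FALSE)
  if (k == 1L) return(1)
  q <- qgamma(seq(0, 1, length.out = k + 1), shape = shape, rate = shape)
  m <- k * diff(pgamma(q, shape = shape + 1, rate = shape))
  m / mean(m) * 1  # guard rounding; means already average to 1
}

#' Birth--death model specification for gene-family counts
#'
#' @param lambdas per-class birth = death rates (events/gene/time), one per
#'   branch class.
#' @param branch_class integer vector over tree edges mapping each edge to a
#'   class in `seq_along(lambdas)`; `NULL` puts every branch in class 1.
#' @param gamma_shape optional shape of mean-one discrete-gamma among-family
#'   rate variation; `NULL` disables it.
#' @param n_categories number of gamma categories K (ignored when
#'   `gamma_shape` is `NULL`).
#' @param epsilon observation-error probability: with probability `epsilon`
#'   an observed tip count is off by one (symmetric, clamped at zero).
#' @param max_count truncation bound for ancestral counts.
#' @param root_count optional fixed (point-prior) root count; `NULL` uses a
#'   uniform prior over 1..max observed count, as is conventional for
#'   family-size likelihoods.
#' @return a `bd_model_spec` list.
#' @export
bd_model_spec <- function(lambdas, branch_class = NULL, gamma_shape = NULL,
                          n_categories = 1L, epsilon = 0, max_count = 50L,
                          root_count = NULL) {
  if (any(lambdas < 0)) stop("rates must be non-negative", call. = FALSE)
  if (epsilon < 0 || epsilon >= 0.5) stop("`epsilon` must be in [0, 0.5)", call. = FALSE)
  structure(list(lambdas = as.numeric(lambdas), branch_class = branch_class,
                 gamma_shape = gamma_shape, n_categories = as.integer(n_categories),
                 epsilon = epsilon, max_count = as.integer(max_count),
                 root_count = root_count),
            class = "bd_model_spec")
}

root_prior_states <- function(spec, counts) {
  if (!is.null(spec$root_count)) return(as.integer(spec$root_count))
  1:max(counts, 1)
}

# Tip likelihood vectors over 0..N for one species column of counts,
# epsilon-mixing observed counts with +/-1 miscounts.
tip_likelihood <- function(obs, N, epsilon) {
  L <- matrix(0, N + 1, length(obs))
  for (i in seq_along(obs)) {
    x <- obs[i]
    if (epsilon == 0) {
      L[x + 1, i] <- 1
    } else {
      lo <- max(x - 1, 0)
      hi <- min(x + 1, N)
      L[x + 1, i] <- L[x + 1, i] + 1 - epsilon
      L[lo + 1, i] <- L[lo + 1, i] + epsilon / 2
      L[hi + 1, i] <- L[hi + 1, i] + epsilon / 2
    }
  }
  L
}

#' Log-likelihood of gene-family counts under a birth--death model
#'
#' Felsenstein-style pruning over the species tree: each branch contributes
#' the birth--death transition matrix for its class rate (optionally scaled
#' by a discrete-gamma category multiplier), tip counts enter as indicator
#' (or epsilon-smeared) vectors, and the root is integrated over a uniform
#' prior on 1..max observed count. With gamma variation, the per-family
#' likelihood is averaged over the K equal-probability categories.
#'
#' @param tree ultrametric [ape::phylo] species tree.
#' @param counts integer matrix, families x species (colnames = tip labels).
#' @param spec a [bd_model_spec()].
#' @return total log-likelihood (sum over families).
#' @export
family_loglik <- function(tree, counts, spec) {
  stopifnot(inherits(spec, "bd_model_spec"))
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) || !all(tree$tip.label %in% colnames(counts)))
    stop("`counts` must have one column per tree tip", call. = FALSE)
  counts <- counts[, tree$tip.label, drop = FALSE]
  N <- max(spec$max_count, 2L * max(counts))
  repeat {
    res <- family_loglik_core(tree, counts, spec, N)
    if (res$tail_mass <= 1e-6 || N >= 4096L) return(res$lnL)
    warning("truncation bound ", N, " leaks probability mass; doubling",
            call. = FALSE)
    N <- 2L * N
  }
}

family_loglik_core <- function(tree, counts, spec, N) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nfam <- nrow(counts)
  bc <- spec$branch_class %||% rep(1L, nrow(tree$edge))
  mult <- if (is.null(spec$gamma_shape)) 1
          else discrete_gamma_categories(spec$gamma_shape, spec$n_categories)
  K <- length(mult)
  root_states <- root_prior_states(spec, counts)
  prior <- rep(1 / length(root_states), length(root_states))

  lik <- matrix(0, nfam, K)   # per-family likelihood per category
  tail_mass <- 0
  for (k in seq_len(K)) {
    L <- vector("list", nnode)
    for (i in seq_len(ntip))
      L[[i]] <- tip_likelihood(counts[, tree$tip.label[i]], N, spec$epsilon)
    for (e in seq_len(nrow(tree$edge))) {
      parent <- tree$edge[e, 1]; child <- tree$edge[e, 2]
      lam <- spec$lambdas[bc[e]] * mult[k]
      M <- bdp_transition_matrix(N, lam, tree$edge.length[e])
      # leak measured over the states tips/prior can occupy (lower half of
      # the bound); the very top rows always lose mass to truncation
      occ <- seq_len(floor(N / 2) + 1)
      tail_mass <- max(tail_mass, 1 - min(rowSums(M)[occ]))
      contrib <- M %*% L[[child]]
      L[[parent]] <- if (is.null(L[[parent]])) contrib else L[[parent]] * contrib
    }
    root <- ntip + 1L
    lik[, k] <- as.numeric(crossprod(L[[root]][root_states + 1, , drop = FALSE], prior))
  }
  list(lnL = sum(log(rowMeans(lik))), tail_mass = tail_mass)
}

#' Maximum-likelihood fit of a birth--death family-size model
#'
#' Maximises [family_loglik()] over the free rate parameters (and the gamma
#' shape, when the spec includes among-family variation) by Nelder--Mead on
#' log-transformed parameters, with `n_starts` random restarts to guard
#' against local optima. All restart log-likelihoods are retained so
#' convergence across runs can be inspected.
#'
#' @param tree species tree.
#' @param counts families x species count matrix.
#' @param spec a [bd_model_spec()] acting as template: its `lambdas` (and
#'   `gamma_shape` if non-`NULL`) are treated as free and used as the first
#'   start.
#' @param n_starts number of optimizer restarts (default 30).
#' @param seed integer seed controlling restart jitter.
#' @param fit_epsilon logical; also free the observation-error probability.
#' @return an object of class `amp_famsize` with elements `spec` (MLE
#'   plugged in), `mle`, `lnL`, `n_params`, `restart_lnL`.
#' @export
fit_family_model <- function(tree, counts, spec, n_starts = 30L, seed = 1L,
                             fit_epsilon = FALSE) {
  stopifnot(inherits(spec, "bd_model_spec"))
  counts <- as.matrix(counts)
  if (nrow(counts) < 1) stop("need at least one family", call. = FALSE)
  has_gamma <- !is.null(spec$gamma_shape)
  nl <- length(spec$lambdas)

  pack <- function(sp) {
    th <- log(pmax(sp$lambdas, 1e-8))
    if (has_gamma) th <- c(th, log(sp$gamma_shape))
    if (fit_epsilon) th <- c(th, qlogis(max(sp$epsilon, 1e-4) * 2))
    th
  }
  unpack <- function(th) {
    sp <- spec
    sp$lambdas <- exp(th[seq_len(nl)])
    i <- nl
    if (has_gamma) { i <- i + 1; sp$gamma_shape <- exp(th[i]) }
    if (fit_epsilon) { i <- i + 1; sp$epsilon <- plogis(th[i]) / 2 }
    sp
  }
  counts_o <- counts[, tree$tip.label, drop = FALSE]
  Nfit <- max(spec$max_count, 2L * max(counts))  # fixed bound during search
  nll <- function(th) {
    if (any(!is.finite(th)) || any(abs(th) > 8)) return(1e10)
    v <- try(-family_loglik_core(tree, counts_o, unpack(th), Nfit)$lnL,
             silent = TRUE)
    if (inherits(v, "try-error") || !is.finite(v)) 1e10 else v
  }

  th0 <- pack(spec)
  starts <- with_seed(seed, lapply(seq_len(n_starts), function(i) {
    if (i == 1) th0 else th0 + rnorm(length(th0), 0, 1)
  }))
  fits <- lapply(starts, function(st) {
    if (length(st) == 1L) {
      o <- optimize(nll, interval = c(st - 6, st + 6))
      list(par = o$minimum, value = o$objective)
    } else {
      o <- optim(st, nll, method = "Nelder-Mead",
                 control = list(maxit = 500, reltol = 1e-10))
      list(par = o$par, value = o$value)
    }
  })
  lnLs <- -vapply(fits, `[[`, numeric(1), "value")
  if (all(lnLs <= -1e9))
    stop("optimizer failed to converge in all ", n_starts, " starts", call. = FALSE)
  best <- fits[[which.max(lnLs)]]
  sp <- unpack(best$par)
  mle <- c(setNames(sp$lambdas, paste0("lambda", seq_len(nl))),
           if (has_gamma) c(gamma_shape = sp$gamma_shape),
           if (fit_epsilon) c(epsilon = sp$epsilon))
  structure(list(spec = sp, mle = mle, lnL = max(lnLs),
                 n_params = length(best$par), restart_lnL = lnLs,
                 tree = tree, counts = counts),
            class = "amp_famsize")
}

#' @export
print.amp_famsize <- function(x, ...) {
  cat("Birth-death gene-family-size model fit\n")
  cat("  families:", nrow(x$counts), " species:", ncol(x$counts), "\n")
  cat("  lnL:", format(x$lnL, digits = 8), " free parameters:", x$n_params, "\n")
  cat("  MLE:\n")
  print(round(x$mle, 5))
  invisible(x)
}

#' @method logLik amp_famsize
#' @export
logLik.amp_famsize <- function(object, ...) {
  structure(object$lnL, df = object$n_params, class = "logLik")
}

#' @method coef amp_famsize
#' @export
coef.amp_famsize <- function(object, ...) object$mle

#' Likelihood-ratio test between nested family-size models
#'
#' @param lnL_null log-likelihood of the simpler model.
#' @param lnL_alt log-likelihood of the richer model.
#' @param df difference in free-parameter counts (>= 1).
#' @return list with `statistic` (2 * (lnL_alt - lnL_null)) and `p_value`
#'   (upper tail of chi-squared with `df` degrees of freedom).
#' @examples
#' lrt(-648.749, -627.106, df = 2)  # p ~ 3.98e-10
#' @export
lrt <- function(lnL_null, lnL_alt, df) {
  if (df < 1) stop("`df` must be >= 1", call. = FALSE)
  stat <- 2 * (lnL_alt - lnL_null)
  if (stat < 0) {
    warning("alternative model has lower likelihood; statistic clipped at 0",
            call. = FALSE)
    stat <- 0
  }
  list(statistic = stat, p_value = pchisq(stat, df, lower.tail = FALSE))
}

# Draw child count after one branch: each of s copies leaves 0 with
# probability a, else 1 + Geometric(1 - a) descendants (exact for the
# critical linear birth-death process).
rbd_branch <- function(s, lambda, t) {
  if (s == 0 || lambda == 0 || t == 0) return(s)
  a <- lambda * t / (1 + lambda * t)
  surv <- rbinom(1, s, 1 - a)
  if (surv == 0) return(0L)
  surv + sum(rgeom(surv, 1 - a))
}

# Simulate one family's counts at every node; returns vector over nodes.
sim_family_on_tree <- function(tree_post, root_count, lambdas_edge) {
  ntip <- length(tree_post$tip.label)
  cnt <- integer(ntip + tree_post$Nnode)
  cnt[ntip + 1L] <- root_count
  for (e in rev(seq_len(nrow(tree_post$edge)))) {  # preorder on postorder tree
    p <- tree_post$edge[e, 1]; ch <- tree_post$edge[e, 2]
    cnt[ch] <- rbd_branch(cnt[p], lambdas_edge[e], tree_post$edge.length[e])
  }
  cnt
}

#' Maximum a posteriori ancestral family counts
#'
#' Max-product (Viterbi-style) pruning under the fitted model: for each
#' family, returns the jointly most probable count at every internal node
#' given the tip counts and a uniform root prior.
#'
#' @param fit an `amp_famsize` object.
#' @param max_count truncation bound (defaults to the fit's spec).
#' @return integer matrix families x nodes (tips carry observed counts).
#' @export
map_ancestral_counts <- function(fit, max_count = NULL) {
  spec <- fit$spec
  tree <- ape::reorder.phylo(fit$tree, "postorder")
  counts <- fit$counts[, tree$tip.label, drop = FALSE]
  N <- max(max_count %||% spec$max_count, max(counts))
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  bc <- spec$branch_class %||% rep(1L, nrow(tree$edge))
  # gamma variation: use category closest to mean rate for the MAP pass
  lam_edge <- spec$lambdas[bc]
  logM <- lapply(seq_len(nrow(tree$edge)), function(e)
    log(bdp_transition_matrix(N, lam_edge[e], tree$edge.length[e])))

  out <- matrix(0L, nrow(counts), nnode)
  root <- ntip + 1L
  root_states <- root_prior_states(spec, fit$counts)
  for (f in seq_len(nrow(counts))) {
    V <- matrix(0, N + 1, nnode)      # max log-prob of subtree given node count
    for (i in seq_len(ntip)) { V[, i] <- -Inf; V[counts[f, i] + 1, i] <- 0 }
    ptr <- vector("list", nrow(tree$edge))
    for (e in seq_len(nrow(tree$edge))) { # postorder: child vectors ready
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      sc <- logM[[e]] + matrix(V[, ch], N + 1, N + 1, byrow = TRUE)
      ptr[[e]] <- max.col(sc, ties.method = "first")
      V[, p] <- V[, p] + sc[cbind(seq_len(N + 1), ptr[[e]])]
    }
    node_state <- integer(nnode)
    node_state[root] <- root_states[which.max(V[root_states + 1, root])]
    for (e in rev(seq_len(nrow(tree$edge)))) { # preorder on a postorder tree
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      node_state[ch] <- ptr[[e]][node_state[p] + 1] - 1L
    }
    out[f, ] <- node_state
  }
  rownames(out) <- rownames(counts)
  colnames(out) <- c(tree$tip.label, paste0("node", (ntip + 1):nnode))
  attr(out, "tree") <- tree
  out
}

#' Per-branch expansion/contraction calls with Monte-Carlo p-values
#'
#' Simulates `n_null_sims` families under the fitted model and scores each
#' observed family by its log-likelihood; a family's p-value is the fraction
#' of null families at least as unlikely. On families significant at
#' `alpha`, branch calls are the sign of (MAP child count - parent count).
#'
#' @param fit an `amp_famsize` object.
#' @param n_null_sims number of null families (>= 100 recommended).
#' @param alpha significance level (default 0.05).
#' @param seed integer seed for the null simulation.
#' @return list with `family_p` (named vector), `calls` (data.frame of
#'   family, branch edge index, child node label, direction).
#' @export
branch_changes <- function(fit, n_null_sims = 1000L, alpha = 0.05, seed = 1L) {
  if (n_null_sims < 100) warning("fewer than 100 null simulations; p-values unstable",
                                 call. = FALSE)
  spec <- fit$spec
  tree <- ape::reorder.phylo(fit$tree, "postorder")
  counts <- fit$counts[, tree$tip.label, drop = FALSE]
  obs_lnl <- per_family_loglik(tree, counts, spec)

  ntip <- length(tree$tip.label)
  bc <- spec$branch_class %||% rep(1L, nrow(tree$edge))
  mult <- if (is.null(spec$gamma_shape)) 1
          else discrete_gamma_categories(spec$gamma_shape, spec$n_categories)
  root_states <- root_prior_states(spec, counts)
  null_counts <- with_seed(seed, {
    t(vapply(seq_len(n_null_sims), function(i) {
      m <- sample(mult, 1)
      r <- sample(root_states, 1)
      sim_family_on_tree(tree, r, spec$lambdas[bc] * m)[seq_len(ntip)]
    }, integer(ntip)))
  })
  colnames(null_counts) <- tree$tip.label
  null_lnl <- per_family_loglik(tree, null_counts, spec)
  family_p <- vapply(obs_lnl, function(l) mean(null_lnl <= l), numeric(1))
  names(family_p) <- rownames(counts) %||% paste0("fam", seq_len(nrow(counts)))

  anc <- map_ancestral_counts(fit)
  sig <- which(family_p < alpha)
  calls <- do.call(rbind, lapply(sig, function(f) {
    d <- anc[f, tree$edge[, 2]] - anc[f, tree$edge[, 1]]
    ch <- which(d != 0)
    if (!length(ch)) return(NULL)
    data.frame(family = names(family_p)[f], edge = ch,
               child = colnames(anc)[tree$edge[ch, 2]],
               direction = ifelse(d[ch] > 0, "expansion", "contraction"),
               row.names = NULL)
  }))
  if (is.null(calls))
    calls <- data.frame(family = character(), edge = integer(),
                        child = character(), direction = character())
  list(family_p = family_p, calls = calls)
}

# Vector of per-family log-likelihoods (same pruning as family_loglik).
per_family_loglik <- function(tree, counts, spec) {
  counts <- as.matrix(counts)
  N <- max(spec$max_count, max(counts))
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  bc <- spec$branch_class %||% rep(1L, nrow(tree$edge))
  mult <- if (is.null(spec$gamma_shape)) 1
          else discrete_gamma_categories(spec$gamma_shape, spec$n_categories)
  root_states <- root_prior_states(spec, counts)
  prior <- rep(1 / length(root_states), length(root_states))
  lik <- matrix(0, nrow(counts), length(mult))
  for (k in seq_along(mult)) {
    L <- vector("list", nnode)
    for (i in seq_len(ntip))
      L[[i]] <- tip_likelihood(counts[, tree$tip.label[i]], N, spec$epsilon)
    for (e in seq_len(nrow(tree$edge))) {
      p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
      M <- bdp_transition_matrix(N, spec$lambdas[bc[e]] * mult[k],
                                 tree$edge.length[e])
      contrib <- M %*% L[[ch]]
      L[[p]] <- if (is.null(L[[p]])) contrib else L[[p]] * contrib
    }
    lik[, k] <- as.numeric(crossprod(L[[ntip + 1L]][root_states + 1, , drop = FALSE], prior))
  }
  log(rowMeans(lik))
}

#' Species-overlap duplication calls on a gene tree
#'
#' For every internal node of a rooted binary gene tree, computes the
#' Jaccard overlap of the species sets of its two child clades. A node is
#' called a duplication when at least half the species are shared
#' (support >= 0.5): both child lineages retained the duplicated gene in
#' those species.
#'
#' @param gene_tree rooted binary [ape::phylo] gene tree.
#' @param tip_to_species named character vector mapping every tip label to a
#'   species.
#' @return data.frame with node id, `support` (Jaccard in \[0, 1\]) and
#'   `is_duplication`.
#' @export
species_overlap_duplications <- function(gene_tree, tip_to_species) {
  if (!inherits(gene_tree, "phylo")) stop("`gene_tree` must be phylo", call. = FALSE)
  missing <- setdiff(gene_tree$tip.label, names(tip_to_species))
  if (length(missing))
    stop("unmapped tip(s): ", paste(missing, collapse = ", "), call. = FALSE)
  ntip <- length(gene_tree$tip.label)
  nodes <- (ntip + 1):(ntip + gene_tree$Nnode)
  # clade species sets via one post-order pass
  sets <- vector("list", ntip + gene_tree$Nnode)
  tr <- ape::reorder.phylo(gene_tree, "postorder")
  for (i in seq_len(ntip)) sets[[i]] <- unname(tip_to_species[tr$tip.label[i]])
  for (e in seq_len(nrow(tr$edge))) {
    p <- tr$edge[e, 1]; ch <- tr$edge[e, 2]
    sets[[p]] <- union(sets[[p]] %||% character(), sets[[ch]])
  }
  support <- vapply(nodes, function(nd) {
    kids <- tr$edge[tr$edge[, 1] == nd, 2]
    if (length(kids) != 2) stop("gene tree must be binary", call. = FALSE)
    s1 <- sets[[kids[1]]]; s2 <- sets[[kids[2]]]
    length(intersect(s1, s2)) / length(union(s1, s2))
  }, numeric(1))
  data.frame(node = nodes, support = support,
             is_duplication = support >= 0.5)
}
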