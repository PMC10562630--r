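#' Highest posterior density interval
#'
#' Shortest contiguous interval containing `ceiling(prob * n)` of the sorted
#' samples; ties in width are broken towards the smallest lower bound.
#'
#' @param samples numeric vector (>= 2 values).
#' @param prob coverage probability (default 0.95).
#' @return numeric vector `c(lower, upper)`.
#' @export
hpd_interval <- function(samples, prob = 0.95) {
  if (length(samples) < 2) stop("need at least 2 samples", call. = FALSE)
  x <- sort(samples)
  n <- length(x)
  m <- min(ceiling(prob * n), n)
  lo <- x[seq_len(n - m + 1)]
  hi <- x[seq(m, n)]
  i <- which.min(hi - lo)  # which.min takes the first minimum: smallest lower
  c(lower = lo[i], upper = hi[i])
}

#' Effective sample size of an MCMC chain
#'
#' `n / (1 + 2 * sum(rho_k))` with the sum of autocorrelations truncated by
#' Geyer's initial-positive-sequence rule (stop when a consecutive pair of
#' autocorrelations sums to a non-positive value).
#'
#' @param samples numeric chain (>= 10 non-constant values).
#' @return effective sample size (capped at `length(samples)` from above
#'   only by the formula itself; can exceed n for antithetic chains).
#' @export
effective_sample_size <- function(samples) {
  n <- length(samples)
  if (n < 10) stop("need at least 10 samples", call. = FALSE)
  if (sd(samples) == 0) stop("constant chain has no effective sample size", call. = FALSE)
  rho <- acf(samples, lag.max = min(n - 1, 10 * floor(sqrt(n))),
             plot = FALSE)$acf[-1]
  s <- 0
  k <- 1
  while (k + 1 <= length(rho)) {
    pair <- rho[k] + rho[k + 1]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2
  }
  n / (1 + 2 * s)
}

#' Bayesian phylogenetic hierarchical regression of gene length on TE content
#'
#' Fits, by blocked Gibbs sampling with fully conjugate updates, the model
#' \deqn{\log(\mathrm{gene\_length}) = b_0 + b_1\,\mathrm{exon\_count}
#'  + b_2 \log(\mathrm{te\_length}+1) + b_3\,\mathrm{te\_count}
#'  + u_{species} + v_{family} + e}
#' with `u ~ N(0, sigma2_s * A)` for a phylogenetic relatedness matrix `A`
#' (see [tree_to_relatedness()]), `v ~ N(0, sigma2_f * I)` and
#' `e ~ N(0, sigma2_e * I)`. Coefficients get a flat-ish N(0, 1e8) prior;
#' variances get a weakly informative scaled-inverse-gamma (nu = 0.002,
#' V = 1), i.e. IG(0.001, 0.001).
#'
#' `te_length` is log(x + 1)-transformed so genes without TEs remain in the
#' model; the transform is recorded in the returned object.
#'
#' @param data data.frame with columns `species`, `amp_family`,
#'   `exon_count`, `te_count`, `te_length`, `gene_length`.
#' @param A relatedness matrix with dimnames covering all species in `data`.
#' @param iterations total MCMC iterations (production default 1e6; use
#'   ~2e4 for exploratory runs).
#' @param burn_in iterations discarded (default 1000).
#' @param thin keep every `thin`-th post-burn-in draw (default 500 at the
#'   production length; pass smaller values for short runs).
#' @param priors list overriding `beta_var`, `nu`, `V`.
#' @param seed integer seed; chains are reproducible.
#' @return an object of class `amp_phyloreg`: `summary` (a data.frame of
#'   posterior mean, 95% HPD bounds and ESS per parameter), `chains`
#'   (matrix draws x parameters), plus call metadata.
#' @export
fit_hierarchical_model <- function(data, A, iterations = 1e6, burn_in = 1000,
                                   thin = 500, priors = list(), seed = 1L) {
  req <- c("species", "amp_family", "exon_count", "te_count", "te_length",
           "gene_length")
  if (!all(req %in% names(data)))
    stop("`data` must have columns ", paste(req, collapse = ", "), call. = FALSE)
  if (iterations <= burn_in) stop("`iterations` must exceed `burn_in`", call. = FALSE)
  if (any(data$gene_length <= 0)) stop("gene_length must be positive", call. = FALSE)
  sp <- as.character(data$species)
  if (!all(sp %in% rownames(A)))
    stop("species missing from relatedness matrix: ",
         paste(setdiff(sp, rownames(A)), collapse = ", "), call. = FALSE)

  y <- log(data$gene_length)
  X <- cbind(intercept = 1, exon_count = data$exon_count,
             log_te_length = log(data$te_length + 1),
             te_count = data$te_count)
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    stop("singular design: column ", colnames(X)[qrX$pivot[qrX$rank + 1]],
         " is collinear", call. = FALSE)
  species <- sort(unique(sp))
  fams <- sort(unique(as.character(data$amp_family)))
  si <- match(sp, species)
  fi <- match(as.character(data$amp_family), fams)
  A <- A[species, species]
  Ainv <- solve(A)
  ns <- length(species); nf <- length(fams); n <- length(y)

  pr <- modifyList(list(beta_var = 1e8, nu = 0.002, V = 1), priors)
  ig_shape0 <- pr$nu / 2
  ig_scale0 <- pr$nu * pr$V / 2

  XtX <- crossprod(X)
  n_s <- tabulate(si, ns)
  n_f <- tabulate(fi, nf)
  Zs <- matrix(0, ns, n); Zs[cbind(si, seq_len(n))] <- 1  # group-sum operators
  Zf <- matrix(0, nf, n); Zf[cbind(fi, seq_len(n))] <- 1
  keep <- floor((iterations - burn_in) / thin)
  pars <- c(colnames(X), paste0("fam_", fams), "sigma2_species",
            "sigma2_family", "sigma2_resid")
  chains <- matrix(NA_real_, keep, length(pars), dimnames = list(NULL, pars))
  u_chain <- matrix(NA_real_, keep, ns, dimnames = list(NULL, species))

  with_seed(seed, {
    beta <- qr.coef(qrX, y)
    u <- rep(0, ns); v <- rep(0, nf)
    s2s <- s2f <- 1; s2e <- max(stats::var(y - X %*% beta), 1e-3)
    stored <- 0L
    for (it in seq_len(iterations)) {
      # beta | rest
      resid_b <- y - u[si] - v[fi]
      prec <- XtX / s2e + diag(1 / pr$beta_var, ncol(X))
      ch <- chol(prec)
      mu <- backsolve(ch, forwardsolve(t(ch), crossprod(X, resid_b) / s2e))
      beta <- drop(mu + backsolve(ch, rnorm(ncol(X))))
      xb <- drop(X %*% beta)
      # u | rest  (ns-dim MVN with precision Ainv/s2s + diag(n_s)/s2e)
      r_u <- y - xb - v[fi]
      prec_u <- Ainv / s2s + diag(n_s / s2e, ns)
      ch <- chol(prec_u)
      rhs <- drop(Zs %*% r_u) / s2e
      mu_u <- backsolve(ch, forwardsolve(t(ch), rhs))
      u <- drop(mu_u + backsolve(ch, rnorm(ns)))
      # v | rest
      r_v <- y - xb - u[si]
      prec_v <- 1 / s2f + n_f / s2e
      mu_v <- (drop(Zf %*% r_v) / s2e) / prec_v
      v <- rnorm(nf, mu_v, sqrt(1 / prec_v))
      # variances | rest
      s2s <- 1 / rgamma(1, ig_shape0 + ns / 2,
                        ig_scale0 + drop(crossprod(u, Ainv %*% u)) / 2)
      s2f <- 1 / rgamma(1, ig_shape0 + nf / 2, ig_scale0 + sum(v^2) / 2)
      e <- y - xb - u[si] - v[fi]
      s2e <- 1 / rgamma(1, ig_shape0 + n / 2, ig_scale0 + sum(e^2) / 2)
      if (it > burn_in && (it - burn_in) %% thin == 0 && stored < keep) {
        stored <- stored + 1L
        chains[stored, ] <- c(beta, v, s2s, s2f, s2e)
        u_chain[stored, ] <- u
      }
    }
  })

  summ <- t(apply(chains, 2, function(col) {
    h <- hpd_interval(col, 0.95)
    ess <- if (sd(col) == 0) NA_real_ else effective_sample_size(col)
    c(mean = mean(col), lower_hpd95 = h[[1]], upper_hpd95 = h[[2]], ess = ess)
  }))
  structure(list(summary = as.data.frame(summ), chains = chains,
                 species_effects = u_chain,
                 transform = "log(te_length + 1)",
                 iterations = iterations, burn_in = burn_in, thin = thin,
                 priors = pr, species = species, families = fams, seed = seed),
            class = "amp_phyloreg")
}

#' @export
print.amp_phyloreg <- function(x, ...) {
  cat("Phylogenetic hierarchical regression of log gene length\n")
  cat(sprintf("  %d kept draws (%g iterations, burn-in %g, thin %g)\n",
              nrow(x$chains), x$iterations, x$burn_in, x$thin))
  print(round(x$summary, 3))
  invisible(x)
}

#' @method summary amp_phyloreg
#' @export
summary.amp_phyloreg <- function(object, ...) object$summary

#' @method coef amp_phyloreg
#' @export
coef.amp_phyloreg <- function(object, ...) {
  means <- object$summary$mean
  names(means) <- rownames(object$summary)
  means[1:4]
}
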