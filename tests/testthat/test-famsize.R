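test_that("birth-death transition probability has its boundary behaviour", {
  expect_equal(bdp_transition_prob(3, 0:6, 0.5, 0), c(0, 0, 0, 1, 0, 0, 0))
  expect_equal(bdp_transition_prob(0, 0, 0.7, 2), 1)
  expect_equal(bdp_transition_prob(0, 3, 0.7, 2), 0)
  expect_equal(bdp_transition_prob(1, 0, 0.5, 1), 1 / 3)  # a = lt/(1+lt)
  expect_error(bdp_transition_prob(-1, 0, 0.5, 1), "non-negative")
  # rows sum to one within truncation tolerance for s <= 10, lambda*t <= 2
  for (s in c(1, 5, 10)) for (lt in c(0.2, 1, 2))
    expect_lt(abs(sum(bdp_transition_prob(s, 0:400, lt, 1)) - 1), 1e-8)
  # lambda*t = 1 edge (alpha = 1/2)
  expect_lt(abs(sum(bdp_transition_prob(4, 0:400, 1, 1)) - 1), 1e-8)
})

test_that("vectorised transition matrix equals the scalar closed form", {
  for (lt in c(0.05, 0.5, 1.5)) {
    M <- ampevo:::bdp_transition_matrix(25, lt, 1)
    for (s in c(0, 1, 7, 25))
      expect_equal(M[s + 1, ], bdp_transition_prob(s, 0:25, lt, 1),
                   tolerance = 1e-9)
  }
})

test_that("discrete-gamma categories have mean one and match phangorn", {
  for (shape in c(0.5, 2, 10)) {
    m <- discrete_gamma_categories(shape, 4)
    expect_equal(mean(m), 1, tolerance = 1e-10)
    expect_equal(m, phangorn::discrete.gamma(shape, 4), tolerance = 1e-6)
  }
  expect_equal(discrete_gamma_categories(2, 1), 1)
})

test_that("family log-likelihood equals enumeration on small trees", {
  tr2 <- ape::read.tree(text = "(A:0.4,B:0.7);")
  for (cc in list(c(0L, 1L), c(2L, 3L), c(5L, 5L), c(1L, 4L))) {
    counts <- matrix(cc, 1, dimnames = list("f", c("A", "B")))
    spec <- bd_model_spec(0.45, max_count = 60)
    lhs <- family_loglik(tr2, counts, spec)
    rhs <- enum_loglik_2tip(0.4, 0.7, cc[1], cc[2], 0.45,
                            ampevo:::root_prior_states(spec, counts))
    expect_equal(lhs, rhs, tolerance = 1e-8, info = paste(cc, collapse = ","))
  }
  tr3 <- ape::read.tree(text = "((A:0.3,B:0.3):0.4,C:0.7);")
  for (cc in list(c(1L, 2L, 1L), c(3L, 0L, 2L), c(5L, 4L, 3L))) {
    counts <- matrix(cc, 1, dimnames = list("f", c("A", "B", "C")))
    spec <- bd_model_spec(0.35, max_count = 60)
    lhs <- family_loglik(tr3, counts, spec)
    rhs <- enum_loglik_3tip(0.3, 0.3, 0.4, 0.7, cc[1], cc[2], cc[3], 0.35,
                            ampevo:::root_prior_states(spec, counts))
    expect_equal(lhs, rhs, tolerance = 1e-8, info = paste(cc, collapse = ","))
  }
  # lambda = 0 with point root prior: probability-one paths
  c0 <- matrix(2L, 1, 2, dimnames = list("f", c("A", "B")))
  expect_equal(family_loglik(tr2, c0, bd_model_spec(0, root_count = 2)), 0)
  # one gamma category is the plain model
  counts <- matrix(c(2L, 3L), 1, dimnames = list("f", c("A", "B")))
  expect_equal(family_loglik(tr2, counts,
                             bd_model_spec(0.45, gamma_shape = 2,
                                           n_categories = 1L, max_count = 60)),
               family_loglik(tr2, counts, bd_model_spec(0.45, max_count = 60)),
               tolerance = 1e-10)
})

test_that("model fitting respects nesting and recovers the simulation rate", {
  tr <- simulate_species_tree(8, seed = 5)
  sim <- simulate_family_counts(tr, 0.3, 150, seed = 21)
  spec1 <- bd_model_spec(0.5, max_count = 25)
  fit1 <- fit_family_model(tr, sim$counts, spec1, n_starts = 3, seed = 1)
  expect_gt(fit1$mle[["lambda1"]], 0.2)
  expect_lt(fit1$mle[["lambda1"]], 0.4)
  # multi-lambda spec with all branches in one class: same maximum
  spec_one <- bd_model_spec(c(0.5), branch_class = rep(1L, nrow(tr$edge)),
                            max_count = 25)
  fit_one <- fit_family_model(tr, sim$counts, spec_one, n_starts = 3, seed = 1)
  expect_equal(fit_one$lnL, fit1$lnL, tolerance = 1e-6)
  # adding a rate class never decreases the maximised likelihood
  half <- as.integer(tr$edge[, 1] == (length(tr$tip.label) + 1)) + 1L
  spec2 <- bd_model_spec(c(0.5, 0.5), branch_class = half, max_count = 25)
  fit2 <- fit_family_model(tr, sim$counts, spec2, n_starts = 3, seed = 1)
  expect_gte(fit2$lnL, fit1$lnL - 1e-6)
  expect_equal(fit2$n_params, 2)
})

test_that("likelihood-ratio test reproduces the chi-squared tail", {
  res <- lrt(-648.749, -627.106, df = 2)
  expect_equal(res$statistic, 43.286)
  expect_equal(res$p_value, 3.98e-10, tolerance = 0.01)
  expect_equal(lrt(-10, -10, 1)$p_value, 1)
  expect_equal(lrt(0, 3.841 / 2, 1)$p_value, 0.05, tolerance = 1e-3)
  expect_warning(clipped <- lrt(-5, -6, 1), "clipped")
  expect_equal(clipped$statistic, 0)
  expect_error(lrt(-5, -4, 0), "df")
})

test_that("ancestral MAP counts and branch calls behave on planted signals", {
  tr <- simulate_species_tree(6, seed = 9)
  # constant families: no branch flagged
  counts <- matrix(2L, 5, 6,
                   dimnames = list(paste0("f", 1:5), tr$tip.label))
  spec <- bd_model_spec(0.2, max_count = 20, root_count = 2)
  fit <- fit_family_model(tr, counts, spec, n_starts = 2, seed = 1)
  anc <- map_ancestral_counts(fit)
  expect_true(all(anc == 2))
  # planted 10-fold expansion on one tip of otherwise constant data
  counts2 <- rbind(counts, planted = c(20L, rep(2L, 5)))
  colnames(counts2) <- tr$tip.label
  fit2 <- fit_family_model(tr, counts2, bd_model_spec(0.2, max_count = 45),
                           n_starts = 2, seed = 1)
  bc <- branch_changes(fit2, n_null_sims = 300, seed = 4)
  expect_lt(bc$family_p[["planted"]], 0.05)
  expanded <- bc$calls[bc$calls$family == "planted" &
                         bc$calls$direction == "expansion", ]
  expect_true(tr$tip.label[1] %in% expanded$child)
  expect_warning(branch_changes(fit2, n_null_sims = 50, seed = 1), "unstable")
})

test_that("null-simulated family deviances are calibrated", {
  # observed and null families drawn from the same birth-death model; the
  # per-family log-likelihood (the deviance score behind the Monte-Carlo
  # p-values) must then be exchangeable between the two sets. The
  # statistic is discrete, so ties are broken at random before the KS
  # uniformity check (the reported p-values themselves resolve ties
  # conservatively).
  tr <- simulate_species_tree(10, seed = 13)
  law <- list(name = "fixed", count = 2)
  obs <- simulate_family_counts(tr, 0.25, 1000, root_count_law = law, seed = 31)
  nul <- simulate_family_counts(tr, 0.25, 1000, root_count_law = law, seed = 32)
  spec <- bd_model_spec(0.25, max_count = 30, root_count = 2)
  l_obs <- ampevo:::per_family_loglik(tr, obs$counts, spec)
  l_nul <- ampevo:::per_family_loglik(tr, nul$counts, spec)
  set.seed(33)
  p_rand <- vapply(l_obs, function(l) {
    lo <- sum(l_nul < l); ties <- sum(l_nul == l)
    (lo + runif(1) * (ties + 1)) / (length(l_nul) + 1)
  }, numeric(1))
  ks <- suppressWarnings(stats::ks.test(p_rand, "punif"))
  expect_gt(ks$p.value, 0.01)
  # and the reported (conservative) p-values dominate the randomised ones
  fit <- structure(list(spec = spec, tree = tr, counts = obs$counts,
                        mle = c(lambda1 = 0.25), lnL = NA, n_params = 1),
                   class = "amp_famsize")
  bc <- branch_changes(fit, n_null_sims = 1000, seed = 7)
  expect_lte(mean(bc$family_p < 0.05), 0.08)
})

test_that("species-overlap duplication criterion is Jaccard at one half", {
  gt <- ape::read.tree(text = "((A_1:1,B_1:1):1,(A_2:1,B_2:1):1);")
  d <- species_overlap_duplications(gt, c(A_1 = "A", B_1 = "B",
                                          A_2 = "A", B_2 = "B"))
  root <- d[d$node == 5, ]
  expect_equal(root$support, 1.0)
  expect_true(root$is_duplication)
  gt2 <- ape::read.tree(text = "((A_1:1,B_1:1):1,(C_1:1,D_1:1):1);")
  d2 <- species_overlap_duplications(gt2, c(A_1 = "A", B_1 = "B",
                                            C_1 = "C", D_1 = "D"))
  expect_equal(d2[d2$node == 5, "support"], 0)
  expect_false(d2[d2$node == 5, "is_duplication"])
  # S1 = {A, B}, S2 = {A, C}: support 1/3, speciation
  gt3 <- ape::read.tree(text = "((a1:1,b1:1):1,(a2:1,c1:1):1);")
  d3 <- species_overlap_duplications(gt3, c(a1 = "A", b1 = "B",
                                            a2 = "A", c1 = "C"))
  expect_equal(d3[d3$node == 5, "support"], 1 / 3)
  expect_false(d3[d3$node == 5, "is_duplication"])
  expect_error(species_overlap_duplications(gt3, c(a1 = "A")), "unmapped")
})
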