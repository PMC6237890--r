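# independent BEB oracle: direct loops over the parameter grid, using the
# (separately brute-force-validated) pruning engine for class likelihoods
beb_oracle <- function(fit, ngrid) {
  tree <- pinnevo:::.reorder_labeled(fit$tree)
  fg <- foreground_edges(tree)
  n_edge <- nrow(tree$edge)
  mid <- (seq_len(ngrid) - 0.5) / ngrid
  om0_g <- mid; om2_g <- 1 + 10 * mid; pA_g <- mid; pB_g <- mid
  n_sites <- fit$aln$n_codons
  # branch lengths are fixed at their fitted (background-mixture) scale;
  # a category with ratio omega runs at mu(omega)/mubar_fit
  pf <- fit$params
  w_fit <- c(pf$p0, pf$p1,
             (1 - pf$p0 - pf$p1) * pf$p0 / (pf$p0 + pf$p1),
             (1 - pf$p0 - pf$p1) * pf$p1 / (pf$p0 + pf$p1))
  mu_of <- function(x) pinnevo:::.gy94_mean_rate(fit$freqs,
                                                 fit$params$kappa, x)
  mubar_fit <- sum(w_fit * c(mu_of(pf$omega0), mu_of(1))[c(1, 2, 1, 2)])
  cls_lik <- function(om_edge) {
    tree2 <- tree
    tree2$edge.length <- tree$edge.length *
      vapply(om_edge, mu_of, numeric(1)) / mubar_fit
    exp(pruning_loglik(tree2, fit$aln, fit$params$kappa, om_edge,
                       freqs = fit$freqs)$site_loglik)
  }
  f1 <- cls_lik(rep(1, n_edge))
  f0 <- lapply(om0_g, function(w) cls_lik(rep(w, n_edge)))
  f2a <- lapply(om0_g, function(w0) lapply(om2_g, function(w2)
    cls_lik(ifelse(fg, w2, w0))))
  f2b <- lapply(om2_g, function(w2) cls_lik(ifelse(fg, w2, 1)))
  num <- numeric(n_sites); den <- 0
  full_num <- numeric(n_sites)
  for (ia in seq_len(ngrid)) for (ib in seq_len(ngrid))
    for (i in seq_len(ngrid)) for (j in seq_len(ngrid)) {
      pA <- pA_g[ia]; pB <- pB_g[ib]
      w <- c(pA * pB, pA * (1 - pB), (1 - pA) * pB, (1 - pA) * (1 - pB))
      site_mix <- w[1] * f0[[i]] + w[2] * f1 +
        w[3] * f2a[[i]][[j]] + w[4] * f2b[[j]]
      marg <- exp(sum(log(site_mix)))
      den <- den + marg
      sel <- (w[3] * f2a[[i]][[j]] + w[4] * f2b[[j]]) / site_mix
      num <- num + marg * sel
      full_num <- full_num + marg *
        ((w[1] * f0[[i]] + w[2] * f1) / site_mix + sel)
    }
  list(posterior = num / den, total = full_num / den)
}

test_that("BEB posteriors match an exhaustive grid-sum oracle", {
  tr <- ape::read.tree(text =
    "(((seal1:0.05,seal2:0.05):0.1,dog:0.15):0.1,cow:0.25);")
  tr <- label_foreground(tr, c("seal1", "seal2"))
  spec <- sim_spec(tree = tr, n_codons = 30, model = "branch_site_A",
                   params = list(kappa = 2, p0 = 0.4, p1 = 0.4,
                                 omega0 = 0.1, omega2 = 5), seed = 41)
  sim <- simulate_alignment(spec)
  fit <- fit_codon_model(sim$codon, tr, "branch_site_alt")
  beb <- beb_site_posteriors(fit, ngrid = 4)
  oracle <- beb_oracle(fit, ngrid = 4)
  expect_equal(beb$site_posterior, oracle$posterior, tolerance = 1e-8)
  # the four class posteriors sum to one at every site
  expect_equal(oracle$total, rep(1, 30), tolerance = 1e-8)
  expect_true(all(beb$site_posterior >= 0 & beb$site_posterior <= 1))
})

test_that("invariant sites get low positive-selection posteriors", {
  spec <- sim_spec(n_codons = 80, model = "branch_site_A",
                   params = list(kappa = 2, p0 = 0.5, p1 = 0.4,
                                 omega0 = 0.05, omega2 = 6), seed = 43)
  sim <- simulate_alignment(spec)
  fit <- fit_codon_model(sim$codon, sim$tree, "branch_site_alt")
  beb <- beb_site_posteriors(fit)
  cods <- pinnevo:::.codon_states(sim$codon)
  invariant <- apply(cods, 2, function(col) length(unique(col)) == 1L)
  expect_true(any(invariant))
  expect_true(all(beb$site_posterior[invariant] < 0.5))
})

test_that("planted positively selected sites score above neutral sites", {
  spec <- sim_spec(n_codons = 200, model = "branch_site_A",
                   params = list(kappa = 2, p0 = 0.4, p1 = 0.4,
                                 omega0 = 0.1, omega2 = 8), seed = 47)
  sim <- simulate_alignment(spec)
  fit <- fit_codon_model(sim$codon, sim$tree, "branch_site_alt")
  beb <- beb_site_posteriors(fit)
  sel <- sim$truth$class %in% c("2a", "2b")
  expect_true(any(sel))
  expect_gt(mean(beb$site_posterior[sel]),
            mean(beb$site_posterior[!sel]))
})

test_that("BEB refuses wrong or unconverged fits", {
  spec <- sim_spec(n_codons = 60, model = "M0",
                   params = list(kappa = 2, omega = 0.3), seed = 2)
  sim <- simulate_alignment(spec)
  m0 <- fit_codon_model(sim$codon, sim$tree, "M0")
  expect_error(beb_site_posteriors(m0), "branch-site")
  bs <- fit_codon_model(sim$codon, sim$tree, "branch_site_alt")
  bs$converged <- FALSE
  expect_error(beb_site_posteriors(bs), "unconverged")
})
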