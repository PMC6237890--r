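test_that("per-site protein log-likelihoods sum to the tree likelihood", {
  spec <- sim_spec(n_codons = 60, model = "M0",
                   params = list(kappa = 2, omega = 0.2), seed = 5)
  sim <- simulate_alignment(spec)
  sl <- site_loglik_protein(mammal_species_tree(), sim$protein)
  expect_length(sl$site_loglik, 60)
  expect_equal(sum(sl$site_loglik), sl$loglik, tolerance = 1e-6)
})

test_that("protein site likelihood matches enumeration on a 3-taxon star", {
  aln <- protein_alignment(c(A = "MKV", B = "MRV", C = "LKV"), "g")
  tr <- toy_star_tree(c(0.2, 0.3, 0.4))
  sl <- site_loglik_protein(tr, aln, optimize_branch_lengths = FALSE)
  # oracle: explicit sum over the 20 internal states with P via expm
  fit <- pinnevo:::.protein_pml(tr, aln, optimize_branch_lengths = FALSE)
  lev <- attr(fit$data, "levels")
  # phangorn's generator is column-normalised; transpose to row convention
  Q <- t(fit$eig$vectors %*% (fit$eig$values * fit$eig$inv))
  P <- lapply(tr$edge.length, function(t) as.matrix(Matrix::expm(Q * t)))
  obs <- sapply(aln$seqs, function(s) match(strsplit(s, "")[[1]], lev))
  oracle <- sapply(1:3, function(h) {
    log(sum(sapply(1:20, function(r)
      fit$bf[r] * P[[1]][r, obs[h, 1]] * P[[2]][r, obs[h, 2]] *
        P[[3]][r, obs[h, 3]])))
  })
  expect_equal(sl$site_loglik, oracle, tolerance = 1e-6)
})

test_that("degenerate cases: single taxon and invariant columns", {
  aln1 <- protein_alignment(c(A = "MKV"), "g")
  tr1 <- structure(list(edge = matrix(c(2L, 1L), 1), tip.label = "A",
                        Nnode = 1L, edge.length = 0.1),
                   class = "phylo")
  sl1 <- site_loglik_protein(tr1, aln1)
  bf <- table(factor(c("M", "K", "V"),
                     levels = c("A", "R", "N", "D", "C", "Q", "E", "G",
                                "H", "I", "L", "K", "M", "F", "P", "S",
                                "T", "W", "Y", "V"))) / 3
  expect_equal(sl1$site_loglik, log(as.numeric(bf[c("M", "K", "V")])),
               tolerance = 1e-4)

  # invariant column on a zero-length tree: lnL = log f(residue)
  aln2 <- protein_alignment(c(A = "M", B = "M", C = "M"), "g")
  tr0 <- toy_star_tree(c(0, 0, 0))
  sl2 <- site_loglik_protein(tr0, aln2, optimize_branch_lengths = FALSE)
  f_emp <- 1 - 19e-6  # empirical frequency of M after flooring
  expect_equal(sl2$site_loglik, log(f_emp), tolerance = 1e-4)
})

test_that("deltaSSLS is zero for identical topologies, signed otherwise", {
  spec <- sim_spec(n_codons = 80, model = "M0",
                   params = list(kappa = 2, omega = 0.2), seed = 19)
  sim <- simulate_alignment(spec)
  tr <- mammal_species_tree()
  d <- delta_ssls(tr, tr, sim$protein)
  expect_equal(d$delta, rep(0, 80))
  expect_equal(d$delta, d$lnl_h0 - d$lnl_h1)

  # simulated on H0: mean delta positive; simulated on H1: negative
  d_h0 <- delta_ssls(tr, marine_monophyly_tree(), sim$protein)
  expect_gt(mean(d_h0$delta), 0)
  spec_h1 <- sim_spec(tree = marine_monophyly_tree(), n_codons = 80,
                      model = "M0", params = list(kappa = 2, omega = 0.2),
                      seed = 23)
  sim_h1 <- simulate_alignment(spec_h1)
  d_h1 <- delta_ssls(tr, marine_monophyly_tree(), sim_h1$protein)
  expect_lt(mean(d_h1$delta), 0)
  expect_error(delta_ssls(tr, toy_star_tree(), sim$protein), "reference")
})

test_that("top-fraction selection follows floor(k) and the tie-break", {
  prof <- function(g, deltas) {
    structure(data.frame(gene_id = g, site = seq_along(deltas),
                         lnl_h0 = 0, lnl_h1 = -deltas, delta = deltas),
              class = c("ssls_profile", "data.frame"))
  }
  # floor arithmetic, including the headline count
  big <- prof("g", rep(0, 100))
  expect_equal(select_top_fraction(list(big), 0.01)$k_selected, 1L)
  expect_equal(floor(0.01 * 996522), 9965)

  # ranking and deterministic tie-break by (gene, position)
  p1 <- prof("b", c(5, 1, 5))
  p2 <- prof("a", c(5, 3, 0))
  top <- select_top_fraction(list(p1, p2), 3 / 6)
  expect_equal(top$k_selected, 3L)
  expect_equal(top$sites$gene_id, c("a", "b", "b"))
  expect_equal(top$sites$site, c(1, 1, 3))
  expect_setequal(top$dsg_genes, c("a", "b"))

  # equal deltas everywhere: first k in tie-break order
  tie <- select_top_fraction(list(prof("z", rep(2, 4)),
                                  prof("y", rep(2, 4))), 0.5)
  expect_equal(tie$sites$gene_id, c("y", "y", "y", "y"))
  expect_equal(tie$sites$site, 1:4)

  expect_error(select_top_fraction(list(p1), 0), "fraction")
  expect_error(select_top_fraction(list(p1), 1.2), "fraction")
})

test_that("select_top_fraction size is exact for many n", {
  prof <- structure(data.frame(gene_id = "g", site = 1:997, lnl_h0 = 0,
                               lnl_h1 = 0, delta = stats::rnorm(997)),
                    class = c("ssls_profile", "data.frame"))
  for (f in c(0.01, 0.1, 0.33, 1)) {
    expect_equal(select_top_fraction(list(prof), f)$k_selected,
                 floor(f * 997))
  }
})
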