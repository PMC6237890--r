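test_that("spec validation catches bad inputs", {
  expect_error(sim_spec(n_codons = 50, model = "M0",
                        params = list(kappa = 2, omega = 0.2)),
               "seed")
  expect_error(sim_spec(n_codons = 50, model = "branch",
                        params = list(kappa = 2), seed = 1), "missing")
  expect_error(sim_spec(n_codons = 50, model = "branch_site_A",
                        params = list(kappa = 2, p0 = 0.8, p1 = 0.4,
                                      omega0 = 0.2, omega2 = 2),
                        seed = 1), "proportions")
  expect_error(sim_spec(n_codons = 10, model = "M0",
                        params = list(kappa = 2, omega = 0.2),
                        planted_unique_sites = list(
                          list(site = 11, residue = "V",
                               clade = "pinnipeds")),
                        seed = 1), "range")
})

test_that("zero branch lengths copy the root to every tip", {
  tr <- mammal_species_tree(within = 0, deep = 0)
  spec <- sim_spec(tree = tr, n_codons = 50, model = "M0",
                   params = list(kappa = 2, omega = 0.2), seed = 11)
  sim <- simulate_alignment(spec)
  expect_length(unique(unlist(sim$codon$seqs)), 1L)
})

test_that("empirical codon frequencies approach pi under M0", {
  spec <- sim_spec(n_codons = 3000, model = "M0",
                   params = list(kappa = 2, omega = 1), seed = 13)
  sim <- simulate_alignment(spec)
  cods <- unlist(lapply(sim$codon$seqs, function(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))))
  emp <- table(factor(cods, levels = pinnevo:::SENSE_CODONS))
  emp <- as.numeric(emp) / sum(emp)
  expect_lt(max(abs(emp - 1 / 61)), 0.01)
})

test_that("simulated alignments always pass validation and filters", {
  for (s in 1:3) {
    spec <- sim_spec(n_codons = 60, model = "branch_site_A",
                     params = list(kappa = 2, p0 = 0.4, p1 = 0.4,
                                   omega0 = 0.2, omega2 = 3), seed = s)
    sim <- simulate_alignment(spec)
    expect_s3_class(sim$codon, "codon_alignment")
    expect_true(trim_and_filter(sim$codon)$accepted)
    expect_equal(sim$protein$n_sites, 60L)
  }
})

test_that("planted pinniped-unique sites are recovered end to end", {
  spec <- sim_spec(n_codons = 80, model = "M0",
                   params = list(kappa = 2, omega = 0.2),
                   planted_unique_sites = list(
                     list(site = 10, residue = "W", clade = "pinnipeds"),
                     list(site = 40, residue = "C", clade = "pinnipeds")),
                   seed = 29)
  sim <- suppressWarnings(simulate_alignment(spec))
  expect_equal(sim$truth$planted[c(10, 40)], c("unique", "unique"))
  rec <- joint_reconstruct(mammal_species_tree(), sim$protein)
  calls <- classify_substitutions(rec)
  expect_equal(calls$category[10], "unique")
  expect_equal(calls$residue[10], "W")
  expect_equal(calls$category[40], "unique")
})

test_that("planted convergent sites appear in all marine clades", {
  spec <- sim_spec(n_codons = 60, model = "M0",
                   params = list(kappa = 2, omega = 0.2),
                   planted_convergent_sites = list(
                     list(site = 30, residue = "H", clade = "marine")),
                   seed = 37)
  sim <- suppressWarnings(simulate_alignment(spec))
  marine <- unlist(pinnevo:::.MAMMAL_TAXA)
  res30 <- vapply(marine, function(tx)
    substr(sim$protein$seqs[[match(tx, sim$protein$taxa)]], 30, 30),
    character(1))
  expect_true(all(res30 == "H"))
})

test_that("batches are reproducible and size-0 batches empty", {
  spec <- sim_spec(n_codons = 40, model = "M0",
                   params = list(kappa = 2, omega = 0.2), seed = 5)
  b1 <- simulate_null_batch(spec, 2)
  b2 <- simulate_null_batch(spec, 2)
  expect_identical(b1[[1]]$codon$seqs, b2[[1]]$codon$seqs)
  expect_identical(b1[[2]]$codon$seqs, b2[[2]]$codon$seqs)
  expect_false(identical(b1[[1]]$codon$seqs, b1[[2]]$codon$seqs))
  expect_length(simulate_null_batch(spec, 0), 0)
})

test_that("taxon exchangeability holds on equal-length star trees", {
  star <- ape::read.tree(text = "(A:0.2,B:0.2,C:0.2,D:0.2);")
  class(star) <- c("labeled_tree", class(star))
  star$foreground <- rep(FALSE, 4)
  spec <- sim_spec(tree = star, n_codons = 4000, model = "M0",
                   params = list(kappa = 2, omega = 0.5), seed = 7)
  sim <- simulate_alignment(spec)
  # pairwise difference proportions are statistically indistinguishable
  diffp <- function(a, b) {
    ca <- strsplit(sim$codon$seqs[[a]], "")[[1]]
    cb <- strsplit(sim$codon$seqs[[b]], "")[[1]]
    mean(ca != cb)
  }
  d <- c(diffp(1, 2), diffp(1, 3), diffp(2, 4), diffp(3, 4))
  expect_lt(diff(range(d)), 0.03)
})

test_that("simulate method on fitted models round-trips parameters", {
  spec <- sim_spec(n_codons = 400, model = "M0",
                   params = list(kappa = 2, omega = 0.3), seed = 53)
  sim <- simulate_alignment(spec)
  fit <- fit_codon_model(sim$codon, sim$tree, "M0")
  sim2 <- simulate(fit, seed = 54)
  refit <- fit_codon_model(sim2$codon, sim$tree, "M0")
  expect_equal(refit$params$omega, fit$params$omega, tolerance = 0.35)
})
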