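test_that("F3X4 frequencies match hand counts and handle edge cases", {
  # point mass: every codon ATG
  aln <- codon_alignment(c(A = "ATGATG", B = "ATGATG"), "g")
  fr <- build_f3x4(aln)
  expect_equal(unname(fr$pi["ATG"]), 1, tolerance = 1e-4)

  # hand-counted 2-taxon, 3-codon alignment
  aln2 <- codon_alignment(c(A = "ATGAAACCT", B = "ATGAAGCCT"), "g")
  # position 1: A,A,C / A,A,C ; position 2: T,A,C x2 ; position 3: G,A,T/G,G,T
  f1 <- c(A = 4, C = 2, G = 0, T = 0) / 6
  f2 <- c(A = 2, C = 2, G = 0, T = 2) / 6
  f3 <- c(A = 1, C = 0, G = 3, T = 2) / 6
  fr2 <- build_f3x4(aln2)
  m <- matrix(unlist(strsplit(pinnevo:::SENSE_CODONS, "")), ncol = 3,
              byrow = TRUE)
  expected <- f1[m[, 1]] * f2[m[, 2]] * f3[m[, 3]]
  expected <- expected / sum(expected)
  expect_equal(unname(fr2$pi), unname(expected), tolerance = 1e-3)

  # uniform usage -> all sense codons equal
  expect_equal(unname(uniform_codon_freqs()$pi),
               rep(1 / 61, 61))
  # gaps/N only -> degenerate input
  expect_error(build_f3x4(codon_alignment(c(A = "---NNN"), "g")),
               "countable")
})

test_that("GY94 generator has the required structure", {
  fr <- uniform_codon_freqs()
  Q <- codon_rate_matrix(fr, kappa = 3, omega = 0.5)
  expect_equal(max(abs(rowSums(Q))), 0, tolerance = 1e-12)
  # omega = 0 kills nonsynonymous rates
  Q0 <- codon_rate_matrix(fr, 3, 0, scale = FALSE)
  ns <- pinnevo:::.codon_structure$nonsyn & pinnevo:::.codon_structure$single
  expect_true(all(Q0[ns] == 0))
  # multi-nucleotide changes have rate zero
  multi <- !pinnevo:::.codon_structure$single
  diag(multi) <- FALSE
  expect_true(all(Q[multi] == 0))
  # detailed balance pi_i q_ij = pi_j q_ji
  fr2 <- build_f3x4(toy_codon_aln())
  Q2 <- codon_rate_matrix(fr2, 2, 0.3)
  flux <- fr2$pi * Q2
  expect_equal(flux, t(flux), tolerance = 1e-12)
  # scaling: expected rate 1, matching the direct summation
  mu <- -sum(fr2$pi * diag(Q2))
  expect_equal(mu, 1, tolerance = 1e-12)
  expect_error(codon_rate_matrix(fr, -1, 0.5), "kappa")
  expect_error(codon_rate_matrix(fr, 2, -0.1), "omega")
})

test_that("pruning equals brute-force enumeration on toy trees", {
  aln <- toy_codon_aln()
  # 3-taxon star (one internal node)
  tr <- toy_star_tree()
  pr <- pruning_loglik(tr, aln, 2.3, rep(0.4, 3))
  bf <- brute_force_codon_loglik(tr, aln, 2.3, rep(0.4, 3))
  expect_equal(pr$site_loglik, bf, tolerance = 1e-8)
  expect_equal(pr$loglik, sum(bf), tolerance = 1e-8)

  # rooted 3-taxon tree (two internal nodes), heterogeneous omega
  tr2 <- ape::read.tree(text = "((A:0.05,B:0.2):0.1,C:0.3);")
  om <- rep(0.2, 4); om[2] <- 1.7
  pr2 <- pruning_loglik(tr2, aln, 1.8, om)
  bf2 <- brute_force_codon_loglik(tr2, aln, 1.8, om)
  expect_equal(pr2$site_loglik, bf2, tolerance = 1e-8)
})

test_that("branch-site class mixture matches brute-force mixing", {
  aln <- toy_codon_aln()
  tr <- ape::read.tree(text = "((A:0.05,B:0.2):0.1,C:0.3);")
  tr <- label_foreground(tr, c("A", "B"))
  fg <- foreground_edges(tr)
  w <- c(0.5, 0.25, 0.15, 0.1)
  om_cols <- cbind(rep(0.1, 4), rep(1, 4),
                   ifelse(fg, 3, 0.1), ifelse(fg, 3, 1))
  pr <- pruning_loglik(tr, aln, 2, om_cols, class_weights = w)
  per_class <- sapply(1:4, function(k)
    brute_force_codon_loglik(tr, aln, 2, om_cols[, k]))
  mixed <- log(exp(per_class) %*% w)
  expect_equal(pr$site_loglik, as.vector(mixed), tolerance = 1e-8)
})

test_that("likelihood is invariant to re-rooting and sites independent", {
  aln <- toy_codon_aln()
  tr <- ape::read.tree(text = "((A:0.05,B:0.2):0.1,C:0.3);")
  l1 <- pruning_loglik(tr, aln, 2, rep(0.5, 4))$loglik
  tr2 <- ape::root(ape::unroot(tr), outgroup = "B", resolve.root = TRUE)
  l2 <- pruning_loglik(tr2, aln, 2, rep(0.5, nrow(tr2$edge)))$loglik
  expect_equal(l1, l2, tolerance = 1e-8)

  # duplicating a site doubles its contribution
  dup <- codon_alignment(c(A = "ATGATG", B = "ATGATG", C = "ATAATA"), "g")
  single <- codon_alignment(c(A = "ATG", B = "ATG", C = "ATA"), "g")
  fr <- build_f3x4(single)
  ld <- pruning_loglik(toy_star_tree(), dup, 2, rep(0.5, 3), freqs = fr)
  ls <- pruning_loglik(toy_star_tree(), single, 2, rep(0.5, 3), freqs = fr)
  expect_equal(ld$loglik, 2 * ls$loglik, tolerance = 1e-8)

  # gaps are missing data: a fully gapped taxon drops out
  gap <- codon_alignment(c(A = "ATG", B = "ATG", C = "---"), "g")
  two <- codon_alignment(c(A = "ATG", B = "ATG"), "g")
  trg <- toy_star_tree()
  l3 <- pruning_loglik(trg, gap, 2, rep(0.5, 3), freqs = fr)$loglik
  tr2t <- ape::read.tree(text = "(A:0.1,B:0.2);")
  l4 <- pruning_loglik(tr2t, two, 2, rep(0.5, 1 * nrow(tr2t$edge)),
                       freqs = fr)$loglik
  expect_equal(l3, l4, tolerance = 1e-8)
})
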