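test_that("joint reconstruction matches exhaustive search on small trees", {
  tr <- ape::read.tree(text =
    "((A:0.15,B:0.3):0.1,(C:0.2,D:0.4):0.15);")
  aln <- protein_alignment(c(A = "MKVLA", B = "MRVLG", C = "LKILG",
                             D = "MKILG"), "g")
  rec <- joint_reconstruct(tr, aln, optimize_branch_lengths = FALSE)
  fit <- pinnevo:::.protein_pml(tr, aln, optimize_branch_lengths = FALSE)
  oracle <- joint_oracle(rec$tree, fit$eig, fit$bf, aln)
  expect_equal(rec$joint_logprob, oracle[, 1], tolerance = 1e-8)
  lev <- rec$levels
  states_oracle <- matrix(lev[oracle[, -1]], ncol = aln$n_sites,
                          byrow = TRUE)
  # identical assignment (or equal joint probability already checked)
  expect_equal(unname(rec$states), states_oracle)
})

test_that("consensus columns reconstruct to the consensus everywhere", {
  aln <- protein_alignment(c(A = "AAA", B = "AAA", C = "AAA", D = "AAA"),
                           "g")
  tr <- ape::read.tree(text = "((A:0.1,B:0.1):0.1,(C:0.1,D:0.1):0.1);")
  rec <- joint_reconstruct(tr, aln, optimize_branch_lengths = FALSE)
  expect_true(all(rec$states == "A"))
})

test_that("gapped tips are uninformative and handled in oracle parity", {
  tr <- ape::read.tree(text = "((A:0.15,B:0.3):0.1,(C:0.2,D:0.4):0.15);")
  aln <- protein_alignment(c(A = "MK-", B = "MRX", C = "LK-", D = "MKI"),
                           "g")
  rec <- joint_reconstruct(tr, aln, optimize_branch_lengths = FALSE)
  fit <- pinnevo:::.protein_pml(tr, aln, optimize_branch_lengths = FALSE)
  oracle <- joint_oracle(rec$tree, fit$eig, fit$bf, aln)
  expect_equal(rec$joint_logprob, oracle[, 1], tolerance = 1e-8)
})

test_that("substitution categories follow the study definitions", {
  # template: 12-taxon alignment, one site; manipulate marine residues
  taxa <- mammal_species_tree()$tip.label
  mk_aln <- function(assign) {
    base <- stats::setNames(rep("A", length(taxa)), taxa)
    base[names(assign)] <- assign
    protein_alignment(base, "g")
  }
  tr <- mammal_species_tree()
  pin <- c("spotted_seal", "northern_fur_seal", "steller_sea_lion")
  cet <- c("dolphin", "minke_whale")

  # all pinnipeds V, everything else A -> unique
  aln_u <- mk_aln(stats::setNames(rep("V", 3), pin))
  rec <- joint_reconstruct(tr, aln_u, optimize_branch_lengths = FALSE)
  calls <- classify_substitutions(rec)
  expect_equal(calls$category, "unique")
  expect_equal(calls$residue, "V")
  expect_equal(calls$ancestral_state, "A")

  # mouse also V -> no longer unique
  aln_n <- mk_aln(stats::setNames(rep("V", 4), c(pin, "mouse")))
  rec_n <- joint_reconstruct(tr, aln_n, optimize_branch_lengths = FALSE)
  expect_equal(classify_substitutions(rec_n)$category, "none")

  # V in all three marine clades, ancestors A -> parallel
  aln_p <- mk_aln(stats::setNames(rep("V", 6), c(pin, cet, "manatee")))
  rec_p <- joint_reconstruct(tr, aln_p, optimize_branch_lengths = FALSE)
  calls_p <- classify_substitutions(rec_p)
  expect_equal(calls_p$category, "parallel")

  # gap in one pinniped is uninformative unless strict
  aln_g <- mk_aln(c(spotted_seal = "V", northern_fur_seal = "V",
                    steller_sea_lion = "-"))
  rec_g <- joint_reconstruct(tr, aln_g, optimize_branch_lengths = FALSE)
  expect_equal(classify_substitutions(rec_g)$category, "unique")
  expect_equal(classify_substitutions(rec_g, strict = TRUE)$category,
               "none")

  # input order invariance
  perm <- sample(length(taxa))
  aln_perm <- protein_alignment(unlist(aln_u$seqs)[perm], "g")
  rec_perm <- joint_reconstruct(tr, aln_perm,
                                optimize_branch_lengths = FALSE)
  expect_equal(classify_substitutions(rec_perm)$category, "unique")

  # clade map referencing unknown taxa errors
  bad_map <- default_clade_map()
  bad_map$pinnipeds$sister <- "wolf"
  expect_error(classify_substitutions(rec, bad_map), "reference")
})

test_that("a site is never both parallel and pinniped-unique", {
  spec <- sim_spec(n_codons = 150, model = "M0",
                   params = list(kappa = 2, omega = 0.4), seed = 61)
  sim <- simulate_alignment(spec)
  rec <- joint_reconstruct(mammal_species_tree(), sim$protein)
  calls <- classify_substitutions(rec)
  expect_true(all(calls$category %in% c("none", "unique", "parallel")))
  # by definition: unique requires the residue absent from cetaceans and
  # sirenians, parallel requires it present; recheck directly
  uq <- calls[calls$category == "unique", ]
  if (nrow(uq)) {
    chars <- do.call(rbind, lapply(sim$protein$seqs,
                                   function(s) strsplit(s, "")[[1]]))
    rownames(chars) <- sim$protein$taxa
    for (h in uq$site) {
      others <- chars[setdiff(sim$protein$taxa,
                              default_clade_map()$pinnipeds$taxa), h]
      expect_false(uq$residue[uq$site == h] %in% others)
    }
  }
})

test_that("intersection requires matching positions in REGs", {
  top <- structure(list(
    fraction = 0.01, k_selected = 2, n_total = 200,
    sites = data.frame(gene_id = c("g1", "g2"), site = c(10, 4),
                       delta = c(5, 4), rank = 1:2),
    dsg_genes = c("g1", "g2")), class = "top_site_set")
  calls <- data.frame(gene_id = c("g1", "g1", "g3"), site = c(10, 11, 4),
                      category = c("unique", "unique", "unique"),
                      residue = "V", ancestral_state = "A")
  res <- intersect_rdu(c("g1", "g3"), top, calls)
  expect_equal(res$final_genes, "g1")
  expect_equal(res$matches$site, 10)
  expect_equal(unname(res$unique_counts["g1"]), 2L)
  # same unique call at a different position -> empty
  calls2 <- transform(calls, site = c(11, 12, 5))
  expect_length(intersect_rdu(c("g1", "g3"), top, calls2)$final_genes, 0)
  # REG membership required
  res3 <- intersect_rdu(character(0), top, calls)
  expect_length(res3$final_genes, 0)
})
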