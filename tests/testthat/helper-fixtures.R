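# Small fixtures built in code: toy trees, toy alignments, and an
# independent brute-force likelihood oracle used across test files.

toy_codon_aln <- function() {
  codon_alignment(c(A = "ATGAAACCT", B = "ATGAAGCCT", C = "ATAAAACCC"),
                  gene_id = "toy")
}

toy_star_tree <- function(lens = c(0.1, 0.2, 0.3)) {
  tr <- ape::read.tree(text = "(A,B,C);")
  tr$edge.length <- lens
  tr
}

# brute-force codon likelihood by enumeration over internal node states,
# with transition matrices from Matrix::expm (a route independent of the
# eigendecomposition used by the package)
brute_force_codon_loglik <- function(tree, aln, kappa, omega_of_edge,
                                     freqs = NULL) {
  if (is.null(freqs)) freqs <- build_f3x4(aln)
  if (!is.matrix(omega_of_edge))
    omega_of_edge <- matrix(omega_of_edge, nrow = nrow(tree$edge))
  ntip <- length(tree$tip.label)
  states <- pinnevo:::.codon_states(aln)[tree$tip.label, , drop = FALSE]
  n_int <- tree$Nnode
  ints <- ntip + seq_len(n_int)
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    as.matrix(Matrix::expm(codon_rate_matrix(freqs, kappa,
                                             omega_of_edge[e, 1]) *
                             tree$edge.length[e])))
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  grid <- as.matrix(expand.grid(rep(list(1:61), n_int)))
  vapply(seq_len(ncol(states)), function(h) {
    tot <- 0
    for (g in seq_len(nrow(grid))) {
      asn <- integer(ntip + n_int)
      asn[seq_len(ntip)] <- states[, h] + 1L
      asn[ints] <- grid[g, ]
      pr <- freqs$pi[asn[root]]
      for (e in seq_len(nrow(tree$edge)))
        pr <- pr * P[[e]][asn[tree$edge[e, 1]], asn[tree$edge[e, 2]]]
      tot <- tot + pr
    }
    log(tot)
  }, numeric(1))
}

# deterministic small simulated gene set for pipeline tests
sim_neutral_genes <- function(n, n_codons = 120, seed = 100,
                              omega = 0.2) {
  spec <- sim_spec(n_codons = n_codons, model = "M0",
                   params = list(kappa = 2, omega = omega), seed = seed)
  batch <- simulate_null_batch(spec, n)
  lapply(batch, `[[`, "codon")
}

# exhaustive joint-reconstruction oracle: enumerate all internal-node
# assignments and maximise the joint probability directly
joint_oracle <- function(recon_tree, eig, bf, aln) {
  tr <- ape::reorder.phylo(recon_tree, "postorder")
  lev <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
           "M", "F", "P", "S", "T", "W", "Y", "V")
  ntip <- length(tr$tip.label)
  n_int <- tr$Nnode
  P <- lapply(tr$edge.length, function(t)
    t(eig$vectors %*% (exp(eig$values * t) * eig$inv)))
  obs <- do.call(rbind, lapply(aln$seqs[match(tr$tip.label, aln$taxa)],
                               function(s) match(strsplit(s, "")[[1]], lev)))
  root <- tr$edge[nrow(tr$edge), 1]
  grid <- as.matrix(expand.grid(rep(list(1:20), n_int)))
  t(sapply(seq_len(aln$n_sites), function(h) {
    best <- -Inf; barg <- NULL
    for (g in seq_len(nrow(grid))) {
      asn <- integer(ntip + n_int)
      asn[seq_len(ntip)] <- obs[, h]
      asn[ntip + seq_len(n_int)] <- grid[g, ]
      lp <- log(bf[asn[root]])
      for (e in seq_len(nrow(tr$edge))) {
        chi <- asn[tr$edge[e, 2]]
        if (is.na(chi)) next  # uninformative tip
        lp <- lp + log(P[[e]][asn[tr$edge[e, 1]], chi])
      }
      if (lp > best) { best <- lp; barg <- grid[g, ] }
    }
    c(best, barg)
  }))
}
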