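# Site-wise log-likelihood support (SSLS) under the JTT+F amino-acid
# model, and the deltaSSLS comparison between a species-tree topology
# (H0) and a marine-monophyly constraint topology (H1). The protein
# likelihood engine is phangorn's pml/optim.pml; this module owns the
# per-site extraction, the H0 - H1 contrast and the top-fraction rule.

# empirical amino-acid frequencies (+F), floored and renormalised
.empirical_aa_freqs <- function(aln, levels, floor_freq = 1e-6) {
  chars <- unlist(strsplit(unlist(aln$seqs), ""))
  counts <- table(factor(chars, levels = levels))
  f <- as.numeric(counts)
  if (sum(f) == 0) f <- rep(1, length(levels))
  f <- f / sum(f)
  f[f < floor_freq] <- floor_freq
  f / sum(f)
}

# phyDat from a protein_alignment
.as_phydat <- function(aln) {
  m <- do.call(rbind, lapply(aln$seqs, function(s) strsplit(s, "")[[1]]))
  rownames(m) <- aln$taxa
  m[m == "X"] <- "?"
  phangorn::phyDat(m, type = "AA")
}

# JTT+F fit of branch lengths on a fixed topology; returns the pml object
.protein_pml <- function(tree, aln, optimize_branch_lengths = TRUE,
                         gamma_categories = 1) {
  .check_taxa(tree, aln)
  dat <- .as_phydat(aln)
  lev <- attr(dat, "levels")
  bf <- .empirical_aa_freqs(aln, lev)
  tr <- tree
  class(tr) <- "phylo"
  tr$foreground <- NULL
  tr$edge.length <- pmax(tr$edge.length, 1e-8)
  # pml unroots the tree; harmless under a reversible model
  fit <- suppressWarnings(
    phangorn::pml(tr, dat, model = "JTT", bf = bf, k = gamma_categories,
                  shape = 1))
  if (optimize_branch_lengths || gamma_categories > 1)
    fit <- suppressWarnings(
      phangorn::optim.pml(fit, optEdge = optimize_branch_lengths,
                          optGamma = gamma_categories > 1,
                          model = "JTT", optBf = FALSE, optQ = FALSE,
                          control = phangorn::pml.control(trace = 0)))
  fit
}

#' Per-site protein log-likelihood on a fixed topology (JTT+F)
#'
#' Branch lengths are optimised for the gene on the given topology
#' (unless disabled), then per-site log-likelihoods are extracted.
#' All-gap columns contribute 0 (likelihood one).
#'
#' @param tree `phylo`/`labeled_tree` covering the alignment's taxa.
#' @param aln `protein_alignment`.
#' @param optimize_branch_lengths optimise branch lengths per gene.
#' @param gamma_categories number of discrete-gamma rate categories
#'   (1 = rate homogeneity, the default).
#' @return list with `site_loglik` (per residue), `loglik` (total) and
#'   `tree` (with optimised branch lengths).
#' @export
site_loglik_protein <- function(tree, aln, optimize_branch_lengths = TRUE,
                                gamma_categories = 1) {
  stopifnot(inherits(aln, "protein_alignment"))
  if (length(tree$tip.label) < 2) {
    # degenerate single-taxon case: site lnL is log f(residue)
    lev <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
             "M", "F", "P", "S", "T", "W", "Y", "V")
    bf <- .empirical_aa_freqs(aln, lev)
    res <- strsplit(aln$seqs[[match(tree$tip.label, aln$taxa)]], "")[[1]]
    site <- ifelse(res %in% lev, log(bf)[match(res, lev)], 0)
    return(list(site_loglik = site, loglik = sum(site), tree = tree))
  }
  fit <- .protein_pml(tree, aln, optimize_branch_lengths, gamma_categories)
  idx <- attr(fit$data, "index")
  site <- fit$siteLik[idx]
  list(site_loglik = site, loglik = sum(site), tree = fit$tree)
}

#' deltaSSLS profile between two topologies
#'
#' Computes per-residue log-likelihood under the species tree (H0) and
#' an alternative constraint topology (H1), with branch lengths
#' optimised independently under each, and returns their difference
#' `delta = lnL(H0) - lnL(H1)`. Positive values support H0 (divergence
#' of the marine clades), negative values H1 (marine monophyly /
#' convergence).
#'
#' @param tree_h0,tree_h1 topologies over the same taxon set.
#' @param aln `protein_alignment`.
#' @param ... passed to [site_loglik_protein()].
#' @return object of class `ssls_profile`: data frame with `gene_id`,
#'   `site`, `lnl_h0`, `lnl_h1`, `delta`.
#' @export
delta_ssls <- function(tree_h0, tree_h1, aln, ...) {
  if (!setequal(tree_h0$tip.label, tree_h1$tip.label))
    stop("reference error: H0 and H1 trees cover different taxa")
  h0 <- site_loglik_protein(tree_h0, aln, ...)
  h1 <- site_loglik_protein(tree_h1, aln, ...)
  out <- data.frame(gene_id = aln$gene_id,
                    site = seq_len(aln$n_sites),
                    lnl_h0 = h0$site_loglik,
                    lnl_h1 = h1$site_loglik,
                    delta = h0$site_loglik - h1$site_loglik,
                    stringsAsFactors = FALSE)
  class(out) <- c("ssls_profile", class(out))
  out
}

#' Select the top fraction of residues by deltaSSLS
#'
#' Ranks all residues by `delta` descending (ties broken by gene id then
#' position, ascending) and keeps the top `floor(fraction * N)`. Genes
#' owning at least one selected residue are flagged as divergent
#' substitution genes (DSGs).
#'
#' @param profiles an `ssls_profile` or list of them.
#' @param fraction fraction of residues to keep, in (0, 1].
#' @return object of class `top_site_set`: list with `fraction`,
#'   `k_selected`, `sites` (data frame: gene_id, site, delta, rank) and
#'   `dsg_genes`.
#' @export
select_top_fraction <- function(profiles, fraction = 0.01) {
  if (!is.numeric(fraction) || fraction <= 0 || fraction > 1)
    stop("fraction must lie in (0, 1]")
  if (inherits(profiles, "ssls_profile")) profiles <- list(profiles)
  all <- do.call(rbind, lapply(profiles, function(p)
    p[, c("gene_id", "site", "delta")]))
  if (nrow(all) == 0) stop("no residues to rank")
  k <- as.integer(floor(fraction * nrow(all)))
  ord <- order(-all$delta, all$gene_id, all$site)
  top <- all[ord[seq_len(k)], , drop = FALSE]
  if (k > 0) top$rank <- seq_len(k)
  rownames(top) <- NULL
  structure(list(fraction = fraction, k_selected = k,
                 n_total = nrow(all), sites = top,
                 dsg_genes = sort(unique(top$gene_id))),
            class = "top_site_set")
}

#' @export
print.top_site_set <- function(x, ...) {
  cat("Top ", format(100 * x$fraction), "% deltaSSLS residues: ",
      x$k_selected, " of ", x$n_total, " sites in ",
      length(x$dsg_genes), " gene(s)\n", sep = "")
  invisible(x)
}
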