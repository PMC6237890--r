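# Joint ancestral amino-acid reconstruction (max-product dynamic
# programming over the tree, Pupko-style) and classification of
# clade-unique and parallel substitutions.

#' Joint ancestral reconstruction of protein sequences
#'
#' Finds, per site, the single most probable joint assignment of
#' amino-acid states to all internal nodes under JTT+F, with branch
#' lengths optimised for the gene beforehand (unless disabled). Tips
#' with a gap or X are uninformative (they contribute no constraint).
#' Ties in the maximisation are broken by alphabetical residue order.
#'
#' @param tree rooted `phylo`/`labeled_tree` over the alignment's taxa.
#' @param aln `protein_alignment`.
#' @param optimize_branch_lengths optimise branch lengths under JTT+F
#'   before reconstructing.
#' @return object of class `ancestral_recon`: list with `states`
#'   (character matrix, internal nodes x sites, rownames `node<N>` using
#'   ape node numbers), `joint_logprob` (per site), `tree` (with the
#'   branch lengths used) and `aln`.
#' @export
joint_reconstruct <- function(tree, aln, optimize_branch_lengths = TRUE) {
  stopifnot(inherits(aln, "protein_alignment"))
  .check_taxa(tree, aln)
  fit <- .protein_pml(tree, aln, optimize_branch_lengths)
  tr <- ape::reorder.phylo(fit$tree, "postorder")
  lev <- attr(fit$data, "levels")
  ns <- length(lev)
  bf <- fit$bf
  # alphabetical preference order for deterministic tie-breaks
  pref <- order(lev)
  eig <- fit$eig
  # phangorn's eigendecomposition follows the column-generator convention
  # (columns of Q sum to zero), so P(parent -> child) is the transpose
  Pmats <- lapply(seq_len(nrow(tr$edge)), function(e) {
    P <- t(eig$vectors %*% (exp(eig$values * tr$edge.length[e]) *
                              eig$inv))
    P[P < 1e-300] <- 1e-300
    log(P)
  })

  ntip <- length(tr$tip.label)
  nnode <- tr$Nnode
  root <- tr$edge[nrow(tr$edge), 1]
  n_sites <- aln$n_sites
  chars <- do.call(rbind, lapply(aln$seqs[match(tr$tip.label, aln$taxa)],
                                 function(s) strsplit(s, "")[[1]]))
  obs <- matrix(match(chars, lev), nrow = ntip)  # NA = gap/X/missing

  children_of <- split(seq_len(nrow(tr$edge)), tr$edge[, 1])

  states <- matrix(NA_character_, nnode, n_sites)
  rownames(states) <- paste0("node", ntip + seq_len(nnode))
  joint_lp <- numeric(n_sites)

  # argmax with alphabetical tie-break
  amax <- function(v) {
    cand <- which(v == max(v))
    if (length(cand) > 1L) cand <- cand[order(match(cand, pref))][1]
    cand[1]
  }

  for (h in seq_len(n_sites)) {
    # L[[node]][s] = max log-prob of the subtree below `node` given the
    # parent sends state s down this node's stem; B[[node]][s] = argmax
    L <- vector("list", ntip + nnode)
    B <- vector("list", ntip + nnode)
    for (e in seq_len(nrow(tr$edge))) {
      chi <- tr$edge[e, 2]
      lP <- Pmats[[e]]
      if (chi <= ntip) {
        x <- obs[chi, h]
        if (is.na(x)) {
          L[[chi]] <- rep(0, ns)  # uninformative tip
          B[[chi]] <- rep(NA_integer_, ns)
        } else {
          L[[chi]] <- lP[, x]
          B[[chi]] <- rep(x, ns)
        }
      } else {
        below <- rep(0, ns)
        for (ce in children_of[[as.character(chi)]])
          below <- below + L[[tr$edge[ce, 2]]]
        tot <- sweep(lP, 2, below, "+")  # tot[s, x]
        best <- apply(tot, 1, amax)
        L[[chi]] <- tot[cbind(seq_len(ns), best)]
        B[[chi]] <- best
      }
    }
    below <- rep(0, ns)
    for (ce in children_of[[as.character(root)]])
      below <- below + L[[tr$edge[ce, 2]]]
    rootscore <- log(bf) + below
    xr <- amax(rootscore)
    joint_lp[h] <- rootscore[xr]

    # backtrack, preorder
    assign_state <- integer(ntip + nnode)
    assign_state[root] <- xr
    for (e in rev(seq_len(nrow(tr$edge)))) {
      par <- tr$edge[e, 1]; chi <- tr$edge[e, 2]
      if (chi > ntip)
        assign_state[chi] <- B[[chi]][assign_state[par]]
    }
    states[, h] <- lev[assign_state[ntip + seq_len(nnode)]]
  }

  structure(list(states = states, joint_logprob = joint_lp,
                 tree = tr, aln = aln, levels = lev),
            class = "ancestral_recon")
}

#' @export
print.ancestral_recon <- function(x, ...) {
  cat("Joint ancestral reconstruction: ", nrow(x$states),
      " internal nodes x ", ncol(x$states), " sites\n", sep = "")
  invisible(x)
}

#' Write reconstructed ancestral sequences as FASTA
#' @param recon `ancestral_recon`.
#' @param path output file.
#' @export
write_ancestral_fasta <- function(recon, path) {
  seqs <- apply(recon$states, 1, paste, collapse = "")
  .write_fasta(seqs, path)
}

# reconstructed state at the MRCA of a taxon set, per site
.mrca_states <- function(recon, taxa) {
  tr <- recon$tree
  taxa <- intersect(taxa, tr$tip.label)
  if (length(taxa) < 2)
    stop("need at least two taxa to locate an ancestral node")
  node <- ape::getMRCA(tr, taxa)
  recon$states[paste0("node", node), ]
}

#' Classify parallel and clade-unique amino-acid substitutions
#'
#' Implements the study definitions: a site carries a *unique*
#' substitution for the focal clade (pinnipeds) when all clade members
#' share a residue that is absent from the reconstructed ancestral node
#' joining the clade with its terrestrial sister taxon and from every
#' other taxon in the alignment; it carries a *parallel* substitution
#' when all three marine clades share the same residue and each clade's
#' residue differs from its own ancestral node's state. Gap/X residues
#' are uninformative unless `strict` is set, in which case every taxon
#' must be observed.
#'
#' @param recon `ancestral_recon` over the species tree.
#' @param clade_map named list of clades (`list(taxa, sister)`), as from
#'   [default_clade_map()].
#' @param focal name of the clade whose unique substitutions are sought.
#' @param strict require every taxon observed (no gap/X) at a site.
#' @return object of class `substitution_calls`: data frame with
#'   `gene_id`, `site`, `category` (`unique`/`parallel`/`none`),
#'   `residue` and `ancestral_state` (focal clade).
#' @export
classify_substitutions <- function(recon, clade_map = default_clade_map(),
                                   focal = "pinnipeds", strict = FALSE) {
  stopifnot(inherits(recon, "ancestral_recon"))
  aln <- recon$aln
  tr <- recon$tree
  for (cl in clade_map) {
    bad <- setdiff(c(cl$taxa, cl$sister), aln$taxa)
    if (length(bad))
      stop("reference error: clade map names absent taxa: ",
           paste(bad, collapse = ", "))
  }
  if (!focal %in% names(clade_map))
    stop("focal clade '", focal, "' not in clade map")

  chars <- do.call(rbind, lapply(aln$seqs, function(s) strsplit(s, "")[[1]]))
  rownames(chars) <- aln$taxa
  informative <- chars %in% AA_LETTERS
  dim(informative) <- dim(chars)
  rownames(informative) <- aln$taxa

  anc <- lapply(clade_map, function(cl)
    .mrca_states(recon, c(cl$taxa, cl$sister)))

  clade_res <- function(cl_taxa, h) {
    v <- chars[cl_taxa, h]
    ok <- informative[cl_taxa, h]
    if (strict && !all(ok)) return(NA_character_)
    v <- v[ok]
    if (!length(v) || length(unique(v)) != 1L) return(NA_character_)
    v[1]
  }

  n_sites <- aln$n_sites
  category <- rep("none", n_sites)
  residue <- rep(NA_character_, n_sites)
  anc_focal <- rep(NA_character_, n_sites)
  focal_taxa <- clade_map[[focal]]$taxa
  other_taxa <- setdiff(aln$taxa, focal_taxa)

  for (h in seq_len(n_sites)) {
    r_f <- clade_res(focal_taxa, h)
    anc_focal[h] <- anc[[focal]][h]
    if (!is.na(r_f)) {
      residue[h] <- r_f
      others <- chars[other_taxa, h]
      others_ok <- others[informative[other_taxa, h]]
      if (strict && length(others_ok) < length(other_taxa)) {
        # unresolved under strict mode
      } else if (r_f != anc[[focal]][h] && !(r_f %in% others_ok)) {
        category[h] <- "unique"
        next
      }
    }
    # parallel: same derived residue in all clades, each differing from
    # its own ancestral node
    rs <- vapply(clade_map, function(cl) clade_res(cl$taxa, h),
                 character(1))
    if (!anyNA(rs) && length(unique(rs)) == 1L) {
      derived <- all(vapply(seq_along(clade_map), function(k)
        rs[k] != anc[[k]][h], logical(1)))
      if (derived) category[h] <- "parallel"
    }
  }

  out <- data.frame(gene_id = aln$gene_id, site = seq_len(n_sites),
                    category = category, residue = residue,
                    ancestral_state = anc_focal,
                    stringsAsFactors = FALSE)
  class(out) <- c("substitution_calls", class(out))
  out
}

#' Intersect REGs with co-located top-deltaSSLS and unique substitutions
#'
#' Final candidate genes are rapidly evolving genes (REGs) that carry at
#' least one residue which is simultaneously in the top deltaSSLS
#' fraction and a clade-unique substitution, at the same position.
#'
#' @param regs character vector of REG gene ids.
#' @param top_sites `top_site_set`.
#' @param unique_calls `substitution_calls` (or a list of them / a
#'   combined data frame).
#' @return list with `final_genes`, `matches` (gene/site pairs in both
#'   sets), and `unique_counts` (unique substitutions per gene).
#' @export
intersect_rdu <- function(regs, top_sites, unique_calls) {
  if (inherits(unique_calls, "substitution_calls"))
    unique_calls <- list(unique_calls)
  if (is.list(unique_calls) && !is.data.frame(unique_calls))
    unique_calls <- do.call(rbind, unique_calls)
  uq <- unique_calls[unique_calls$category == "unique", , drop = FALSE]
  top <- top_sites$sites
  matches <- merge(uq[, c("gene_id", "site", "residue")],
                   top[, c("gene_id", "site", "delta")],
                   by = c("gene_id", "site"))
  final <- sort(intersect(regs, unique(matches$gene_id)))
  counts <- table(uq$gene_id)
  list(final_genes = final,
       matches = matches[order(matches$gene_id, matches$site), ,
                         drop = FALSE],
       unique_counts = stats::setNames(as.integer(counts), names(counts)))
}
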