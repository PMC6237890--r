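# Codon-alignment simulation along a phylogeny under M0, branch, or
# branch-site model A, with optional planted clade-unique and
# clade-convergent amino-acid substitutions at known sites.

.MAMMAL_TAXA <- list(
  pinnipeds = c("spotted_seal", "northern_fur_seal", "steller_sea_lion"),
  cetaceans = c("dolphin", "minke_whale"),
  sirenians = "manatee")

#' Default clade map for the 12-mammal analysis
#'
#' Marine clades with their terrestrial sister taxa: pinnipeds with dog,
#' cetaceans with cow, sirenians with elephant. The ancestral node used
#' when classifying substitutions for a clade is the most recent common
#' ancestor of the clade together with its sister.
#'
#' @return named list of clades, each `list(taxa, sister)`.
#' @export
default_clade_map <- function() {
  list(pinnipeds = list(taxa = .MAMMAL_TAXA$pinnipeds, sister = "dog"),
       cetaceans = list(taxa = .MAMMAL_TAXA$cetaceans, sister = "cow"),
       sirenians = list(taxa = .MAMMAL_TAXA$sirenians, sister = "elephant"))
}

# assign default branch lengths: short within marine clades, long elsewhere
.default_lengths <- function(tree, within = 0.05, deep = 0.2) {
  el <- rep(deep, nrow(tree$edge))
  for (cl in .MAMMAL_TAXA) {
    tx <- intersect(cl, tree$tip.label)
    if (!length(tx)) next
    nodes <- match(tx, tree$tip.label)
    if (length(tx) > 1) {
      mrca <- ape::getMRCA(tree, tx)
      nodes <- c(nodes, setdiff(.clade_nodes(tree, mrca), nodes))
      nodes <- unique(c(nodes, match(tx, tree$tip.label)))
    }
    el[tree$edge[, 2] %in% nodes] <- within
  }
  tree$edge.length <- el
  tree
}

#' Species tree of the 12-mammal study set
#'
#' Rooted topology over three pinnipeds, two cetaceans, one sirenian and
#' six terrestrial mammals, with pinnipeds sister to dog, cetaceans to
#' cow, manatee to elephant and opossum as outgroup. Default branch
#' lengths are 0.05 on branches inside the marine clades and 0.2
#' elsewhere (expected substitutions per codon).
#'
#' @param foreground `NULL`, a clade name (`"pinnipeds"`, `"cetaceans"`,
#'   `"sirenians"`, or `"marine"` for all three) or a character vector of
#'   tip labels to mark as foreground.
#' @param within,deep branch lengths inside marine clades / elsewhere.
#' @return `labeled_tree`.
#' @export
mammal_species_tree <- function(foreground = NULL, within = 0.05,
                                deep = 0.2) {
  nwk <- paste0(
    "(opossum,((elephant,manatee),((human,mouse),((dog,(spotted_seal,",
    "(northern_fur_seal,steller_sea_lion))),(cow,(dolphin,",
    "minke_whale))))));")
  tree <- ape::read.tree(text = nwk)
  tree <- .default_lengths(tree, within, deep)
  .apply_foreground(tree, foreground)
}

#' Marine-monophyly constraint tree (H1)
#'
#' Alternative topology in which the three marine clades form a single
#' clade, `(pinnipeds,(cetaceans,sirenians))`, attached at the pinniped
#' position (sister to dog); all other relationships as in the species
#' tree.
#'
#' @inheritParams mammal_species_tree
#' @return `labeled_tree`.
#' @export
marine_monophyly_tree <- function(foreground = NULL, within = 0.05,
                                  deep = 0.2) {
  nwk <- paste0(
    "(opossum,(elephant,((human,mouse),((dog,((spotted_seal,",
    "(northern_fur_seal,steller_sea_lion)),((dolphin,minke_whale),",
    "manatee))),cow))));")
  tree <- ape::read.tree(text = nwk)
  tree <- .default_lengths(tree, within, deep)
  .apply_foreground(tree, foreground)
}

.apply_foreground <- function(tree, foreground) {
  if (is.null(foreground)) {
    tree$foreground <- rep(FALSE, nrow(tree$edge))
    class(tree) <- c("labeled_tree", class(tree))
    return(tree)
  }
  taxa <- if (length(foreground) == 1L &&
              foreground %in% c(names(.MAMMAL_TAXA), "marine")) {
    if (foreground == "marine") unlist(.MAMMAL_TAXA)
    else .MAMMAL_TAXA[[foreground]]
  } else foreground
  if (length(foreground) == 1L && identical(foreground, "marine")) {
    # three separate clades: mark each
    out <- tree
    out$foreground <- rep(FALSE, nrow(tree$edge))
    for (cl in .MAMMAL_TAXA) {
      tmp <- label_foreground(tree, intersect(cl, tree$tip.label))
      out$foreground <- out$foreground | tmp$foreground
    }
    class(out) <- unique(c("labeled_tree", class(out)))
    return(out)
  }
  label_foreground(tree, taxa)
}

#' Simulation specification
#'
#' @param tree `labeled_tree` along which to simulate (defaults to the
#'   12-mammal species tree with pinnipeds foreground).
#' @param n_codons number of codon sites.
#' @param model `"M0"`, `"branch"` or `"branch_site_A"`.
#' @param params list of model parameters: `kappa` and, per model,
#'   `omega` (M0), `omega_bg`/`omega_fg` (branch), or
#'   `p0`, `p1`, `omega0`, `omega2` (branch-site A).
#' @param planted_unique_sites list of `list(site, residue, clade)`
#'   entries; each plants `residue` in every member of `clade` (a clade
#'   name or taxon vector) at codon `site`.
#' @param planted_convergent_sites like `planted_unique_sites` but the
#'   residue is planted in all three marine clades.
#' @param freqs `codon_freqs` for the root distribution and the
#'   generator (default uniform over sense codons).
#' @param seed mandatory integer seed.
#' @return object of class `sim_spec`.
#' @export
sim_spec <- function(tree = mammal_species_tree(foreground = "pinnipeds"),
                     n_codons = 300,
                     model = c("M0", "branch", "branch_site_A"),
                     params = list(kappa = 2, omega = 0.2),
                     planted_unique_sites = list(),
                     planted_convergent_sites = list(),
                     freqs = uniform_codon_freqs(),
                     seed) {
  model <- match.arg(model)
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  need <- switch(model,
    M0 = "omega",
    branch = c("omega_bg", "omega_fg"),
    branch_site_A = c("p0", "p1", "omega0", "omega2"))
  missing_par <- setdiff(c("kappa", need), names(params))
  if (length(missing_par))
    stop("missing params for model ", model, ": ",
         paste(missing_par, collapse = ", "))
  if (model == "branch_site_A") {
    if (params$p0 < 0 || params$p1 < 0 || params$p0 + params$p1 > 1)
      stop("invalid class proportions")
    if (params$omega0 < 0 || params$omega0 > 1)
      stop("omega0 must lie in [0, 1]")
  }
  if (model != "M0" && !any(foreground_edges(tree)))
    stop("model ", model, " requires foreground branches on the tree")
  all_sites <- vapply(c(planted_unique_sites, planted_convergent_sites),
                      function(x) x$site, numeric(1))
  if (length(all_sites) && any(all_sites < 1 | all_sites > n_codons))
    stop("planted sites out of range")
  structure(list(tree = tree, n_codons = as.integer(n_codons),
                 model = model, params = params,
                 planted_unique_sites = planted_unique_sites,
                 planted_convergent_sites = planted_convergent_sites,
                 freqs = freqs, seed = as.integer(seed)),
            class = "sim_spec")
}

# first codon (lexicographic) coding a residue
.codon_for_residue <- function(res) {
  hit <- SENSE_CODONS[GENETIC_CODE_STD[SENSE_CODONS] == res]
  if (!length(hit)) stop("no codon for residue ", res)
  hit[1]
}

# simulate states (1..61) for all tips for given per-site, per-edge
# omega and relative-rate assignments
.sim_states <- function(tree, n_sites, kappa, freqs, omega_of_edge,
                        rate_of_edge = NULL) {
  tree <- .reorder_labeled(tree)
  edge <- tree$edge
  n_edge <- nrow(edge)
  ntip <- length(tree$tip.label)
  root <- edge[n_edge, 1]
  nnode <- max(edge)
  pi <- as.numeric(freqs$pi)
  if (is.null(rate_of_edge))
    rate_of_edge <- matrix(1, n_edge, n_sites)

  om_vals <- sort(unique(as.vector(omega_of_edge)))
  eigs <- lapply(om_vals, function(w)
    .eig_reversible(codon_rate_matrix(freqs, kappa, w), pi))
  states <- matrix(0L, nnode, n_sites)
  states[root, ] <- sample.int(61, n_sites, replace = TRUE, prob = pi)
  for (e in rev(seq_len(n_edge))) {  # preorder
    par <- edge[e, 1]; chi <- edge[e, 2]
    child <- integer(n_sites)
    combo <- paste(omega_of_edge[e, ], rate_of_edge[e, ])
    for (key in unique(combo)) {
      cols <- which(combo == key)
      k <- match(omega_of_edge[e, cols[1]], om_vals)
      P <- .trans_prob(eigs[[k]],
                       tree$edge.length[e] * rate_of_edge[e, cols[1]])
      for (s in unique(states[par, cols])) {
        idx <- cols[states[par, cols] == s]
        child[idx] <- sample.int(61, length(idx), replace = TRUE,
                                 prob = P[s, ])
      }
    }
    states[chi, ] <- child
  }
  list(states = states[seq_len(ntip), , drop = FALSE], tree = tree)
}

# per-edge, per-site omega and relative-rate assignment plus site class
# labels for a spec. Branch-site sites share branch time across classes,
# so each class runs at mu(omega)/mubar relative to the nominal branch
# length, where mubar is the class-mixture mean rate on background
# branches (the fitting code uses the same convention).
.sim_class_layout <- function(spec, fg, n_edge) {
  p <- spec$params
  n <- spec$n_codons
  if (spec$model == "M0") {
    list(classes = rep("0", n),
         omega = matrix(p$omega, n_edge, n), rate = NULL)
  } else if (spec$model == "branch") {
    list(classes = rep("0", n),
         omega = matrix(ifelse(fg, p$omega_fg, p$omega_bg), n_edge, n),
         rate = NULL)
  } else {
    w <- c(p$p0, p$p1,
           (1 - p$p0 - p$p1) * p$p0 / (p$p0 + p$p1),
           (1 - p$p0 - p$p1) * p$p1 / (p$p0 + p$p1))
    cls <- sample(c("0", "1", "2a", "2b"), n, replace = TRUE, prob = w)
    om <- matrix(1, n_edge, n)
    om[, cls == "0"] <- p$omega0
    om[fg, cls == "2a"] <- p$omega2
    om[!fg, cls == "2a"] <- p$omega0
    om[fg, cls == "2b"] <- p$omega2
    mu_of <- function(x) .gy94_mean_rate(spec$freqs, p$kappa, x)
    mu <- c(`0` = mu_of(p$omega0), `1` = mu_of(1), `2` = mu_of(p$omega2))
    mubar <- sum(w * mu[c(1, 2, 1, 2)])
    rate <- matrix(mu["1"], n_edge, n)
    rate[, cls == "0"] <- mu["0"]
    rate[fg, cls == "2a"] <- mu["2"]
    rate[!fg, cls == "2a"] <- mu["0"]
    rate[fg, cls == "2b"] <- mu["2"]
    list(classes = cls, omega = om, rate = rate / mubar)
  }
}

.resolve_clade <- function(clade, tree) {
  if (length(clade) == 1L && clade %in% names(.MAMMAL_TAXA))
    intersect(.MAMMAL_TAXA[[clade]], tree$tip.label)
  else if (length(clade) == 1L && clade == "marine")
    intersect(unlist(.MAMMAL_TAXA), tree$tip.label)
  else {
    bad <- setdiff(clade, tree$tip.label)
    if (length(bad)) stop("unknown taxa in planted clade: ",
                          paste(bad, collapse = ", "))
    clade
  }
}

#' Simulate a codon alignment with known truth
#'
#' Draws root codons from the stationary distribution and evolves them
#' along the tree under the spec's model; for branch-site model A, site
#' classes are drawn first and foreground branches use omega2 in the
#' positively selected classes. Planted substitutions are applied after
#' simulation by overwriting the target clade's codons; a column whose
#' background already carries the planted residue is re-simulated (with a
#' warning) so the plant stays clade-exclusive.
#'
#' @param spec a `sim_spec`.
#' @return list with `codon` (`codon_alignment`), `protein`
#'   (`protein_alignment`), `truth` (per-site data frame with the site
#'   class and planting annotation) and `tree`.
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(spec$seed)
  tree <- .reorder_labeled(spec$tree)
  fg <- foreground_edges(tree)
  layout <- .sim_class_layout(spec, fg, nrow(tree$edge))
  sim <- .sim_states(tree, spec$n_codons, spec$params$kappa, spec$freqs,
                     layout$omega, layout$rate)
  states <- sim$states
  taxa <- sim$tree$tip.label

  truth <- data.frame(site = seq_len(spec$n_codons),
                      class = layout$classes,
                      planted = NA_character_,
                      planted_residue = NA_character_,
                      stringsAsFactors = FALSE)

  # group plant instructions by site so that several entries at one site
  # (e.g. a clade-unique residue plus engineered background states) are
  # applied atomically after any column regeneration
  entries <- c(lapply(spec$planted_unique_sites, function(e)
    c(e, kind = "unique")),
    lapply(spec$planted_convergent_sites, function(e)
      c(e, kind = "convergent")))
  for (site in unique(vapply(entries, function(e) e$site, numeric(1)))) {
    here <- Filter(function(e) e$site == site, entries)
    target_rows <- integer(0)
    target_state <- integer(0)
    residues <- character(0)
    for (e in here) {
      tx <- if (e$kind == "convergent") .resolve_clade("marine", tree)
            else .resolve_clade(e$clade, tree)
      rows <- match(tx, taxa)
      target_rows <- c(target_rows, rows)
      target_state <- c(target_state,
                        rep(match(.codon_for_residue(e$residue),
                                  SENSE_CODONS), length(rows)))
      residues <- c(residues, e$residue)
    }
    other <- setdiff(seq_along(taxa), target_rows)
    for (attempt in 1:25) {
      other_res <- GENETIC_CODE_STD[SENSE_CODONS[states[other, site]]]
      if (!any(other_res %in% residues, na.rm = TRUE)) break
      warning("planted residue matches wild type at site ", site,
              "; regenerating column", call. = FALSE)
      col <- .sim_states(tree, 1L, spec$params$kappa, spec$freqs,
                         layout$omega[, site, drop = FALSE],
                         if (is.null(layout$rate)) NULL else
                           layout$rate[, site, drop = FALSE])
      states[, site] <- col$states[, 1]
    }
    states[cbind(target_rows, site)] <- target_state
    kinds <- vapply(here, function(e) e$kind, character(1))
    truth$planted[site] <- if (any(kinds == "unique")) "unique"
                           else "convergent"
    truth$planted_residue[site] <-
      here[[which(kinds == truth$planted[site])[1]]]$residue
  }

  seqs <- apply(states, 1, function(row)
    paste(SENSE_CODONS[row], collapse = ""))
  names(seqs) <- taxa
  codon <- codon_alignment(seqs, gene_id = "sim")
  list(codon = codon, protein = translate_alignment(codon),
       truth = truth, tree = sim$tree)
}

#' Simulate a batch of independent genes
#'
#' Per-gene seeds are derived deterministically from the spec's master
#' seed, so a batch is reproducible and individual genes can be
#' regenerated in isolation.
#'
#' @param spec `sim_spec` shared by all genes.
#' @param n_genes number of genes (0 gives an empty list).
#' @param gene_prefix gene identifier prefix.
#' @return list of `simulate_alignment()` results, names `g1`, `g2`, ...
#' @export
simulate_null_batch <- function(spec, n_genes, gene_prefix = "g") {
  if (n_genes == 0) return(list())
  out <- vector("list", n_genes)
  for (i in seq_len(n_genes)) {
    gspec <- spec
    gspec$seed <- as.integer((spec$seed + 104729 * i) %% .Machine$integer.max)
    res <- simulate_alignment(gspec)
    gid <- paste0(gene_prefix, i)
    res$codon$gene_id <- gid
    res$protein$gene_id <- gid
    out[[i]] <- res
  }
  names(out) <- paste0(gene_prefix, seq_len(n_genes))
  out
}

#' Simulate alignments from a fitted codon model
#'
#' @param object `codon_fit`.
#' @param nsim number of alignments.
#' @param seed integer seed.
#' @param ... unused.
#' @return list of `simulate_alignment()` results.
#' @export
simulate.codon_fit <- function(object, nsim = 1, seed = 1, ...) {
  p <- object$params
  model <- switch(object$model,
                  M0 = "M0", branch = "branch",
                  branch_site_alt = "branch_site_A",
                  branch_site_null = "branch_site_A")
  params <- switch(object$model,
    M0 = list(kappa = p$kappa, omega = p$omega),
    branch = list(kappa = p$kappa, omega_bg = p$omega_bg,
                  omega_fg = p$omega_fg),
    list(kappa = p$kappa, p0 = p$p0, p1 = p$p1, omega0 = p$omega0,
         omega2 = p$omega2))
  spec <- sim_spec(tree = object$tree, n_codons = object$n_codons,
                   model = model, params = params, freqs = object$freqs,
                   seed = seed)
  out <- simulate_null_batch(spec, nsim, gene_prefix = object$gene_id)
  if (nsim == 1) out[[1]] else out
}
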