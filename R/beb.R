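# Bayes empirical Bayes site posteriors for branch-site model A.
# Empirical-Bayes averaging over a discrete grid on (p0, p1, omega0,
# omega2) with kappa and branch lengths fixed at their MLEs, in the
# spirit of the Yang-Wong-Nielsen scheme.

#' BEB posterior probabilities of positive selection per site
#'
#' For a converged branch-site alternative fit, computes the posterior
#' probability that each site belongs to the positively selected classes
#' (2a + 2b), averaging over a uniform discrete grid on the mixture
#' proportions (via `pA = p0 + p1`, `pB = p0/(p0+p1)`), `omega0` in
#' (0, 1) and `omega2` in (1, 11). Kappa and branch lengths are fixed at
#' their maximum-likelihood estimates.
#'
#' @param fit converged `codon_fit` of model `branch_site_alt`.
#' @param ngrid grid points per parameter dimension (default 10).
#' @param threshold posterior threshold for calling a site selected.
#' @return object of class `beb_result`: list with `site_posterior`
#'   (per-site probability of classes 2a+2b), `selected_sites` (1-based
#'   site indices with posterior > threshold), `threshold`, `ngrid`.
#' @export
beb_site_posteriors <- function(fit, ngrid = 10, threshold = 0.95) {
  stopifnot(inherits(fit, "codon_fit"))
  if (fit$model != "branch_site_alt")
    stop("BEB requires a branch-site alternative model fit")
  if (!fit$converged)
    stop("refusing BEB on an unconverged fit")

  tree <- .reorder_labeled(fit$tree)
  fg <- foreground_edges(tree)
  aln <- fit$aln
  if (is.null(aln))
    stop("fit does not carry its alignment; refit with a current version")
  states <- .codon_states(aln)[tree$tip.label, , drop = FALSE]
  pat <- .site_patterns(states)
  pi <- as.numeric(fit$freqs$pi)
  kappa <- fit$params$kappa

  mid <- (seq_len(ngrid) - 0.5) / ngrid
  om0_g <- mid                 # omega0 in (0, 1)
  om2_g <- 1 + 10 * mid        # omega2 in (1, 11)
  pA_g <- mid
  pB_g <- mid

  # categories: 1..ngrid omega0 values, then omega1 = 1, then omega2 values
  cats <- c(om0_g, 1, om2_g)
  eigs <- lapply(cats, function(w)
    .eig_reversible(codon_rate_matrix(pi, kappa, w), pi))
  i0 <- seq_len(ngrid); i1 <- ngrid + 1L; i2 <- ngrid + 1L + seq_len(ngrid)

  # relative rates: branch lengths are fixed at their MLE meaning
  # (background-mixture substitutions per codon), so each grid category
  # runs at mu(omega)/mubar_fit relative to them
  pf <- fit$params
  w_fit <- c(pf$p0, pf$p1,
             (1 - pf$p0 - pf$p1) * pf$p0 / (pf$p0 + pf$p1),
             (1 - pf$p0 - pf$p1) * pf$p1 / (pf$p0 + pf$p1))
  mu_fit <- vapply(c(pf$omega0, 1), function(x)
    .gy94_mean_rate(pi, kappa, x), numeric(1))
  mubar_fit <- sum(w_fit * mu_fit[c(1, 2, 1, 2)])
  rmult <- vapply(cats, function(x)
    .gy94_mean_rate(pi, kappa, x), numeric(1)) / mubar_fit

  n_edge <- nrow(tree$edge)
  cols <- list()
  # class 0 per omega0; class 1; class 2a per (omega0, omega2); class 2b
  # per omega2
  for (i in seq_len(ngrid)) cols[[length(cols) + 1L]] <-
    rep(i0[i] - 1L, n_edge)
  cols[[length(cols) + 1L]] <- rep(i1 - 1L, n_edge)
  for (i in seq_len(ngrid)) for (j in seq_len(ngrid))
    cols[[length(cols) + 1L]] <- ifelse(fg, i2[j] - 1L, i0[i] - 1L)
  for (j in seq_len(ngrid)) cols[[length(cols) + 1L]] <-
    ifelse(fg, i2[j] - 1L, i1 - 1L)
  catmap <- do.call(cbind, cols)
  storage.mode(catmap) <- "integer"

  cls <- .pruning_loglik_cpp(pat$states, tree$edge,
                             outer(tree$edge.length, rmult),
                             length(tree$tip.label), eigs, catmap, pi)
  npat <- nrow(cls)
  f0 <- cls[, seq_len(ngrid), drop = FALSE]
  f1 <- cls[, ngrid + 1L]
  f2a <- array(cls[, ngrid + 1L + seq_len(ngrid^2)], c(npat, ngrid, ngrid))
  f2b <- cls[, ngrid + 1L + ngrid^2 + seq_len(ngrid), drop = FALSE]

  # mixture weights for every (pA, pB) combination: rows = grid points
  Wt <- matrix(0, ngrid^2, 4)
  k <- 1L
  for (ia in seq_len(ngrid)) for (ib in seq_len(ngrid)) {
    pA <- pA_g[ia]; pB <- pB_g[ib]
    Wt[k, ] <- c(pA * pB, pA * (1 - pB),
                 (1 - pA) * pB, (1 - pA) * (1 - pB))
    k <- k + 1L
  }

  # pass 1: log marginal of the data at every grid point
  wpat <- pat$weight
  ln_marg <- matrix(NA_real_, ngrid^2, ngrid^2)  # (pA,pB) x (om0,om2)
  ij <- 1L
  Es <- vector("list", ngrid^2); shifts <- vector("list", ngrid^2)
  for (i in seq_len(ngrid)) for (j in seq_len(ngrid)) {
    Fm <- rbind(f0[, i], f1, f2a[, j, i], f2b[, j])   # 4 x npat, log scale
    s <- apply(Fm, 2, max)
    E <- exp(sweep(Fm, 2, s))
    M <- Wt %*% E                                     # (pA,pB) x npat
    ln_marg[, ij] <- as.vector((log(M) + rep(s, each = nrow(M))) %*% wpat)
    Es[[ij]] <- E; shifts[[ij]] <- s
    ij <- ij + 1L
  }
  lm <- as.vector(ln_marg)
  post_w <- exp(lm - max(lm))
  post_w <- post_w / sum(post_w)
  dim(post_w) <- dim(ln_marg)

  # pass 2: accumulate P(class 2a or 2b | data) per site
  post_pat <- numeric(npat)
  ij <- 1L
  for (i in seq_len(ngrid)) for (j in seq_len(ngrid)) {
    E <- Es[[ij]]
    M <- Wt %*% E
    sel <- (Wt[, 3, drop = FALSE] %*% E[3, , drop = FALSE] +
            Wt[, 4, drop = FALSE] %*% E[4, , drop = FALSE]) / M
    post_pat <- post_pat + as.vector(post_w[, ij] %*% sel)
    ij <- ij + 1L
  }
  post <- post_pat[pat$index]

  structure(list(site_posterior = post,
                 selected_sites = which(post > threshold),
                 threshold = threshold, ngrid = ngrid,
                 gene_id = fit$gene_id),
            class = "beb_result")
}

#' @export
print.beb_result <- function(x, ...) {
  cat("BEB site posteriors, gene '", x$gene_id, "': ",
      length(x$site_posterior), " sites, ", length(x$selected_sites),
      " above ", x$threshold, "\n", sep = "")
  if (length(x$selected_sites))
    cat("  selected: ", paste(utils::head(x$selected_sites, 20),
                              collapse = ", "),
        if (length(x$selected_sites) > 20) " ..." else "", "\n", sep = "")
  invisible(x)
}

#' Plot BEB posteriors along the gene
#' @param x `beb_result`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.beb_result <- function(x, ...) {
  graphics::plot(seq_along(x$site_posterior), x$site_posterior,
                 type = "h", xlab = "codon site",
                 ylab = "P(positive selection | data)",
                 ylim = c(0, 1), ...)
  graphics::abline(h = x$threshold, lty = 2, col = "red3")
  invisible(x)
}
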