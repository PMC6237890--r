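# Per-branch dN and dS from the Goldman-Yang decomposition of the scaled
# generator into synonymous and nonsynonymous expected substitutions,
# normalised by the neutral (omega = 1) proportions of synonymous and
# nonsynonymous sites.

# fraction of substitutions that are synonymous under Q(omega), at
# stationarity, for the fit's kappa and frequencies
.syn_fraction <- function(freqs, kappa, omega) {
  Q <- codon_rate_matrix(freqs, kappa, omega, scale = TRUE)
  st <- .codon_structure
  syn <- st$single & !st$nonsyn
  pi <- if (inherits(freqs, "codon_freqs")) freqs$pi else freqs
  flux <- pi * Q  # pi_i q_ij
  tot <- sum(flux[st$single])
  if (tot <= 0) return(NA_real_)
  sum(flux[syn]) / tot
}

#' Per-branch dN, dS and dN/dS from a fitted codon model
#'
#' For each branch, the expected substitutions per codon (the fitted
#' branch length) are split into synonymous and nonsynonymous parts
#' under that branch's omega (for branch-site fits, the site-class
#' mixture average), then normalised by the proportions of synonymous /
#' nonsynonymous sites computed at omega = 1. Zero-length branches get
#' dN = dS = 0 with an undefined (NA) ratio.
#'
#' @param fit converged `codon_fit`.
#' @return object of class `branch_rates`: data frame with one row per
#'   branch (`child` labels tips by name, internal nodes by number) and
#'   columns `t`, `omega`, `dN`, `dS`, `dNdS`, `foreground`.
#' @export
branch_rates <- function(fit) {
  stopifnot(inherits(fit, "codon_fit"))
  if (!fit$converged)
    stop("branch rates require a converged fit")
  tree <- fit$tree
  fg <- foreground_edges(tree)
  p <- fit$params
  kappa <- p$kappa

  if (fit$model == "M0") {
    om_edge <- rep(p$omega, nrow(tree$edge))
    syn_edge <- rep(.syn_fraction(fit$freqs, kappa, p$omega),
                    nrow(tree$edge))
  } else if (fit$model == "branch") {
    om_edge <- ifelse(fg, p$omega_fg, p$omega_bg)
    sf <- vapply(unique(om_edge), function(w)
      .syn_fraction(fit$freqs, kappa, w), numeric(1))
    syn_edge <- sf[match(om_edge, unique(om_edge))]
  } else {
    # branch-site model A: site classes share branch time, so expected
    # substitutions on an edge average the unscaled class rates; the
    # synonymous flux is omega-free and identical across classes
    w <- c(p$p0, p$p1, (1 - p$p0 - p$p1) * p$p0 / (p$p0 + p$p1),
           (1 - p$p0 - p$p1) * p$p1 / (p$p0 + p$p1))
    om_bg <- c(p$omega0, 1, p$omega0, 1)
    om_fg <- c(p$omega0, 1, p$omega2, p$omega2)
    mu_of <- function(x) .gy94_mean_rate(fit$freqs, kappa, x)
    mubar_bg <- sum(w * vapply(om_bg, mu_of, numeric(1)))
    mubar_fg <- sum(w * vapply(om_fg, mu_of, numeric(1)))
    mu_edge <- ifelse(fg, mubar_fg, mubar_bg)
    rho_s <- mu_of(1) * .syn_fraction(fit$freqs, kappa, 1)
    syn_edge <- rho_s / mu_edge
    om_edge <- ifelse(fg, sum(w * om_fg), sum(w * om_bg))
    # branch lengths are background-mixture subs/codon (tau = t/mubar_bg);
    # rescale so each edge's split uses its true total flux tau * mu_edge
    tree$edge.length <- tree$edge.length * mu_edge / mubar_bg
  }

  s1 <- .syn_fraction(fit$freqs, kappa, 1)
  t <- tree$edge.length
  dS <- ifelse(t > 0, t * syn_edge / (3 * s1), 0)
  dN <- ifelse(t > 0, t * (1 - syn_edge) / (3 * (1 - s1)), 0)
  ratio <- ifelse(t > 0 & dS > 0, dN / dS, NA_real_)

  ntip <- length(tree$tip.label)
  child <- tree$edge[, 2]
  lab <- ifelse(child <= ntip, tree$tip.label[child],
                paste0("node", child))
  out <- data.frame(child = lab, t = t, omega = om_edge, dN = dN, dS = dS,
                    dNdS = ratio, foreground = fg,
                    stringsAsFactors = FALSE)
  class(out) <- c("branch_rates", class(out))
  out
}

#' @export
print.branch_rates <- function(x, ...) {
  cat("Per-branch substitution rates (", nrow(x), " branches):\n", sep = "")
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
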