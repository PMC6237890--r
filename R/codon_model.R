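# Goldman-Yang codon substitution machinery: genetic code tables, F3X4
# frequencies, the 61x61 GY94 generator, and the pruning log-likelihood.

NUC <- c("A", "C", "G", "T")

# standard genetic code, codons enumerated in TCAG base order
.code_string <- "FFLLSSSSYY**CC*WLLLLPPPPHHQQRRRRIIIMTTTTNNKKSSRRVVVVAAAADDEEGGGG"

.build_code <- function() {
  b <- c("T", "C", "A", "G")
  codons <- as.vector(t(outer(
    as.vector(t(outer(b, b, paste0))), b, paste0)))
  aa <- strsplit(.code_string, "")[[1]]
  names(aa) <- codons
  aa[order(codons)]
}

GENETIC_CODE_STD <- .build_code()
SENSE_CODONS <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD != "*"]
STOP_CODONS <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD == "*"]
AA_LETTERS <- sort(unique(GENETIC_CODE_STD[GENETIC_CODE_STD != "*"]))

#' Translate a codon string to amino acids
#'
#' Gap codons (`---`) become `-`; codons containing `N` or partial gaps
#' become `X`; stop codons become `*`.
#'
#' @param codon_str character string of concatenated codons (length
#'   divisible by 3).
#' @return single amino-acid string.
#' @keywords internal
translate_codons <- function(codon_str) {
  stopifnot(nchar(codon_str) %% 3 == 0)
  if (nchar(codon_str) == 0L) return("")
  cods <- substring(codon_str, seq(1, nchar(codon_str), 3),
                    seq(3, nchar(codon_str), 3))
  aa <- ifelse(cods == "---", "-",
               ifelse(cods %in% names(GENETIC_CODE_STD),
                      GENETIC_CODE_STD[cods], "X"))
  paste(aa, collapse = "")
}

# pairwise structure of the 61-codon state space, computed once at load
.codon_structure <- local({
  n <- length(SENSE_CODONS)
  mat <- matrix(unlist(strsplit(SENSE_CODONS, "")), ncol = 3, byrow = TRUE)
  ndiff <- matrix(0L, n, n)
  for (k in 1:3) ndiff <- ndiff + outer(mat[, k], mat[, k], "!=")
  pos <- matrix(0L, n, n)
  for (k in 1:3) pos[outer(mat[, k], mat[, k], "!=") & ndiff == 1L] <- k
  is_ts <- matrix(FALSE, n, n)
  for (k in 1:3) {
    a <- mat[, k]
    ts_pair <- outer(a, a, function(x, y)
      (x == "A" & y == "G") | (x == "G" & y == "A") |
      (x == "C" & y == "T") | (x == "T" & y == "C"))
    is_ts <- is_ts | (ts_pair & ndiff == 1L &
                        pos == k)
  }
  aa <- GENETIC_CODE_STD[SENSE_CODONS]
  nonsyn <- outer(aa, aa, "!=")
  list(single = ndiff == 1L, transition = is_ts, nonsyn = nonsyn,
       target_nuc = lapply(1:3, function(k) mat[, k]))
})

#' Position-specific (F3X4) codon frequencies
#'
#' Estimates nucleotide frequencies at each of the three codon positions
#' from an alignment (gaps and ambiguous bases excluded), floors zero
#' frequencies at `floor_freq` and renormalises, then forms codon
#' frequencies as the product over positions restricted to the 61 sense
#' codons.
#'
#' @param aln a `codon_alignment`.
#' @param floor_freq lower floor applied to position-specific nucleotide
#'   frequencies before renormalisation (avoids zero-probability codons).
#' @return object of class `codon_freqs`: list with `pi` (named
#'   61-vector summing to 1) and `position_freqs` (3 x 4 matrix).
#' @export
build_f3x4 <- function(aln, floor_freq = 1e-6) {
  stopifnot(inherits(aln, "codon_alignment"))
  chars <- lapply(aln$seqs, function(s) strsplit(s, "")[[1]])
  pf <- matrix(0, 3, 4, dimnames = list(NULL, NUC))
  total <- 0
  for (v in chars) {
    posidx <- rep(1:3, length.out = length(v))
    keep <- v %in% NUC
    total <- total + sum(keep)
    tab <- table(factor(posidx[keep], 1:3), factor(v[keep], NUC))
    pf <- pf + as.matrix(tab)
  }
  if (total == 0) stop("alignment has no countable nucleotides")
  pf <- pf / rowSums(pf)
  pf[pf < floor_freq] <- floor_freq
  pf <- pf / rowSums(pf)
  m <- matrix(unlist(strsplit(SENSE_CODONS, "")), ncol = 3, byrow = TRUE)
  pi <- pf[1, m[, 1]] * pf[2, m[, 2]] * pf[3, m[, 3]]
  pi <- pi / sum(pi)
  names(pi) <- SENSE_CODONS
  structure(list(pi = pi, position_freqs = pf), class = "codon_freqs")
}

#' Uniform codon frequencies over the 61 sense codons
#' @return `codon_freqs` with every sense codon at 1/61.
#' @export
uniform_codon_freqs <- function() {
  pi <- rep(1 / length(SENSE_CODONS), length(SENSE_CODONS))
  names(pi) <- SENSE_CODONS
  structure(list(pi = pi,
                 position_freqs = matrix(0.25, 3, 4,
                                         dimnames = list(NULL, NUC))),
            class = "codon_freqs")
}

#' GY94 codon rate matrix
#'
#' Instantaneous rates are zero for changes at more than one codon
#' position; otherwise proportional to the target codon frequency, times
#' `kappa` for transitions and `omega` for nonsynonymous changes. The
#' generator is scaled so the expected number of substitutions per codon
#' per unit time equals one at the stationary distribution (unless
#' `scale = FALSE`).
#'
#' @param freqs `codon_freqs` (or bare 61-vector of frequencies).
#' @param kappa transition/transversion rate ratio, > 0.
#' @param omega nonsynonymous/synonymous rate ratio, >= 0.
#' @param scale normalise the mean rate to 1.
#' @return 61 x 61 generator matrix with rows summing to zero.
#' @export
codon_rate_matrix <- function(freqs, kappa, omega, scale = TRUE) {
  if (inherits(freqs, "codon_freqs")) freqs <- freqs$pi
  if (!is.numeric(kappa) || length(kappa) != 1L || !is.finite(kappa) ||
      kappa <= 0) stop("kappa must be a positive finite scalar")
  if (!is.numeric(omega) || length(omega) != 1L || !is.finite(omega) ||
      omega < 0) stop("omega must be a non-negative finite scalar")
  st <- .codon_structure
  n <- length(SENSE_CODONS)
  Q <- matrix(0, n, n, dimnames = list(SENSE_CODONS, SENSE_CODONS))
  Q[st$single] <- rep(freqs, each = n)[st$single]
  Q[st$single & st$transition] <- Q[st$single & st$transition] * kappa
  Q[st$single & st$nonsyn] <- Q[st$single & st$nonsyn] * omega
  diag(Q) <- -rowSums(Q)
  if (scale) {
    mu <- -sum(freqs * diag(Q))
    if (mu > 0) Q <- Q / mu
  }
  Q
}

# expected substitutions per codon per unit time of the unscaled GY94
# generator (used to set relative rates across site classes)
.gy94_mean_rate <- function(freqs, kappa, omega) {
  pi <- if (inherits(freqs, "codon_freqs")) freqs$pi else freqs
  Q <- codon_rate_matrix(freqs, kappa, omega, scale = FALSE)
  -sum(pi * diag(Q))
}

# eigendecomposition of a reversible generator via symmetrisation;
# returns the pieces the C++ pruning kernel consumes
.eig_reversible <- function(Q, pi) {
  s <- sqrt(pi)
  B <- sweep(sweep(Q, 1, s, "*"), 2, s, "/")  # s_i q_ij / s_j
  B <- (B + t(B)) / 2  # symmetric up to round-off
  e <- eigen(B, symmetric = TRUE)
  list(values = e$values,
       U = e$vectors / s,
       Uinv = t(e$vectors) * rep(s, each = length(pi)))
}

#' Transition probability matrix exp(Q t)
#' @param eig result of the internal reversible eigendecomposition, or a
#'   generator matrix `Q` (then `pi` must be its stationary distribution).
#' @param t branch length.
#' @param pi stationary frequencies when `eig` is a raw generator.
#' @keywords internal
.trans_prob <- function(eig, t, pi = NULL) {
  if (is.matrix(eig)) eig <- .eig_reversible(eig, pi)
  P <- eig$U %*% (exp(eig$values * t) * eig$Uinv)
  P[P < 0] <- 0
  P
}

# map codon alignment to 0-based state matrix (ntaxa x nsites), -1 missing
.codon_states <- function(aln) {
  n_cod <- aln$n_codons
  out <- matrix(-1L, length(aln$taxa), n_cod)
  for (i in seq_along(aln$taxa)) {
    s <- aln$seqs[[i]]
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    idx <- match(cods, SENSE_CODONS)
    out[i, ] <- ifelse(is.na(idx), -1L, idx - 1L)
  }
  rownames(out) <- aln$taxa
  out
}

# compress columns of a state matrix into unique patterns with weights
.site_patterns <- function(states) {
  key <- apply(states, 2, paste, collapse = ",")
  u <- !duplicated(key)
  idx <- match(key, key[u])
  list(states = states[, u, drop = FALSE],
       weight = as.vector(table(factor(idx, seq_len(sum(u))))),
       index = idx)
}

#' Pruning log-likelihood of a codon alignment on a tree
#'
#' Felsenstein's pruning algorithm under a (possibly branch-heterogeneous)
#' GY94 model. `omega_of_edge` gives, per site class, the omega applying
#' to each edge; class likelihoods are mixed with `class_weights` at the
#' site level. Gaps and ambiguous codons are treated as missing data.
#'
#' @param tree a `phylo` (or `labeled_tree`) whose tip labels match the
#'   alignment taxa; edge lengths are expected substitutions per codon.
#' @param aln a `codon_alignment`.
#' @param kappa transition/transversion ratio.
#' @param omega_of_edge numeric matrix, edges x classes, of omega values
#'   (a plain vector is treated as a single class).
#' @param class_weights mixing proportions over site classes.
#' @param freqs `codon_freqs`; defaults to F3X4 from the alignment.
#' @return list with `loglik` (total), `site_loglik` (per codon site) and
#'   `class_site_loglik` (pattern-expanded per-class log-likelihoods).
#' @export
pruning_loglik <- function(tree, aln, kappa, omega_of_edge,
                           class_weights = 1, freqs = NULL) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (!all(tree$tip.label %in% aln$taxa))
    stop("tree tips absent from alignment: ",
         paste(setdiff(tree$tip.label, aln$taxa), collapse = ", "))
  if (is.null(freqs)) freqs <- build_f3x4(aln)
  if (!is.matrix(omega_of_edge))
    omega_of_edge <- matrix(omega_of_edge, nrow = nrow(tree$edge), ncol = 1)
  if (nrow(omega_of_edge) != nrow(tree$edge))
    stop("omega_of_edge must have one row per edge")
  # reorder to postorder, keeping the per-edge omega assignment aligned
  key_in <- paste(tree$edge[, 1], tree$edge[, 2])
  tree <- .reorder_labeled(tree)
  omega_of_edge <- omega_of_edge[match(paste(tree$edge[, 1], tree$edge[, 2]),
                                       key_in), , drop = FALSE]
  n_class <- ncol(omega_of_edge)
  if (length(class_weights) != n_class)
    stop("class_weights length must match the number of site classes")
  if (abs(sum(class_weights) - 1) > 1e-8)
    stop("class_weights must sum to 1")

  om_vals <- sort(unique(as.vector(omega_of_edge)))
  eigs <- lapply(om_vals, function(w)
    .eig_reversible(codon_rate_matrix(freqs, kappa, w), freqs$pi))
  catmap <- matrix(match(omega_of_edge, om_vals) - 1L,
                   nrow = nrow(tree$edge))

  states <- .codon_states(aln)[tree$tip.label, , drop = FALSE]
  pat <- .site_patterns(states)
  el_mat <- matrix(tree$edge.length, nrow(tree$edge), length(om_vals))
  cls <- .pruning_loglik_cpp(pat$states, tree$edge, el_mat,
                             length(tree$tip.label), eigs, catmap,
                             as.numeric(freqs$pi))
  # mix classes per site in log space
  m <- apply(cls, 1, max)
  mix <- m + log(as.vector(exp(sweep(cls, 1, m, "-")) %*% class_weights))
  site <- mix[pat$index]
  list(loglik = sum(site), site_loglik = site,
       class_site_loglik = cls[pat$index, , drop = FALSE])
}
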