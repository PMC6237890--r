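# Maximum-likelihood fitting of GY94 codon models: one-ratio (M0), branch
# (two-omega), and branch-site model A (alternative and omega2 = 1 null).
# Optimisation is bounded quasi-Newton (L-BFGS-B) on log/logit-transformed
# parameters, with optional multi-start.

.OMEGA_MAX <- 50
.KAPPA_BOUNDS <- c(0.05, 50)
.SCALE_BOUNDS <- c(1e-3, 100)
.EDGE_BOUNDS <- c(1e-6, 20)

.codon_models <- c("M0", "branch", "branch_site_alt", "branch_site_null")

# parameter pack/unpack per model; theta is the transformed vector
.param_spec <- function(model, bl_mode, n_edge) {
  nm <- switch(model,
    M0 = c("lkappa", "lomega"),
    branch = c("lkappa", "lomega_bg", "lomega_fg"),
    branch_site_alt = c("lkappa", "qpA", "qpB", "qomega0", "lomega2"),
    branch_site_null = c("lkappa", "qpA", "qpB", "qomega0"))
  lower <- c(lkappa = log(.KAPPA_BOUNDS[1]), lomega = log(1e-4),
             lomega_bg = log(1e-4), lomega_fg = log(1e-4),
             qpA = stats::qlogis(1e-4), qpB = stats::qlogis(1e-4),
             qomega0 = stats::qlogis(1e-6), lomega2 = 0)[nm]
  upper <- c(lkappa = log(.KAPPA_BOUNDS[2]), lomega = log(.OMEGA_MAX),
             lomega_bg = log(.OMEGA_MAX), lomega_fg = log(.OMEGA_MAX),
             qpA = stats::qlogis(1 - 1e-4), qpB = stats::qlogis(1 - 1e-4),
             qomega0 = stats::qlogis(1 - 1e-6),
             lomega2 = log(.OMEGA_MAX))[nm]
  if (bl_mode == "scale") {
    nm <- c(nm, "lscale")
    lower <- c(lower, lscale = log(.SCALE_BOUNDS[1]))
    upper <- c(upper, lscale = log(.SCALE_BOUNDS[2]))
  } else if (bl_mode == "free") {
    enm <- paste0("ledge", seq_len(n_edge))
    nm <- c(nm, enm)
    lower <- c(lower, stats::setNames(rep(log(.EDGE_BOUNDS[1]), n_edge), enm))
    upper <- c(upper, stats::setNames(rep(log(.EDGE_BOUNDS[2]), n_edge), enm))
  }
  list(names = nm, lower = unname(lower), upper = unname(upper))
}

# natural-scale parameter list from transformed theta
.unpack_params <- function(theta, model, bl_mode, el0) {
  pn <- attr(theta, "pnames")
  th <- stats::setNames(as.numeric(theta),
                        if (is.null(pn)) names(theta) else pn)
  get <- function(n) unname(th[n])
  p <- list(kappa = exp(get("lkappa")))
  if (model == "M0") {
    p$omega <- exp(get("lomega"))
  } else if (model == "branch") {
    p$omega_bg <- exp(get("lomega_bg"))
    p$omega_fg <- exp(get("lomega_fg"))
  } else {
    pA <- stats::plogis(get("qpA"))
    pB <- stats::plogis(get("qpB"))
    p$p0 <- pA * pB
    p$p1 <- pA * (1 - pB)
    p$omega0 <- stats::plogis(get("qomega0"))
    p$omega2 <- if (model == "branch_site_alt") exp(get("lomega2")) else 1
  }
  p$el <- switch(bl_mode,
    scale = exp(get("lscale")) * el0,
    free = exp(th[grep("^ledge", names(th))]),
    fixed = el0)
  p$scale <- if (bl_mode == "scale") exp(get("lscale")) else NA_real_
  p
}

# class structure: omega values (categories), per-edge category per class,
# class weights, and relative rates per category.
#
# Single-class models use per-edge normalised generators (each branch
# length is expected substitutions per codon on that branch, under its
# own omega). Branch-site mixtures share branch lengths across classes,
# so classes must keep their *relative* rates: categories are given rate
# multipliers mu(omega)/mu(1); the overall scale is absorbed by the
# branch-length scale parameter, and reported branch lengths are
# converted to the background-mixture average after fitting.
.class_structure <- function(model, p, fg, freqs) {
  n_edge <- length(fg)
  if (model == "M0") {
    list(om = p$omega, catmap = matrix(0L, n_edge, 1), w = 1, rmult = 1)
  } else if (model == "branch") {
    list(om = c(p$omega_bg, p$omega_fg),
         catmap = matrix(ifelse(fg, 1L, 0L), n_edge, 1), w = 1,
         rmult = c(1, 1))
  } else {
    # model A classes 0, 1, 2a, 2b; categories: 1 = omega0, 2 = 1, 3 = omega2
    cm <- cbind(rep(0L, n_edge), rep(1L, n_edge),
                ifelse(fg, 2L, 0L), ifelse(fg, 2L, 1L))
    w <- c(p$p0, p$p1, (1 - p$p0 - p$p1) * p$p0 / (p$p0 + p$p1),
           (1 - p$p0 - p$p1) * p$p1 / (p$p0 + p$p1))
    mu <- vapply(c(p$omega0, 1, p$omega2), function(x)
      .gy94_mean_rate(freqs, p$kappa, x), numeric(1))
    list(om = c(p$omega0, 1, p$omega2), catmap = cm, w = w,
         rmult = mu / mu[2], mu = mu)
  }
}

# build the fast negative log-likelihood over transformed parameters
.make_objective <- function(tree, aln, model, freqs, bl_mode) {
  tree <- .reorder_labeled(tree)
  fg <- foreground_edges(tree)
  states <- .codon_states(aln)[tree$tip.label, , drop = FALSE]
  pat <- .site_patterns(states)
  el0 <- tree$edge.length
  ntip <- length(tree$tip.label)
  pi <- as.numeric(freqs$pi)
  edge <- tree$edge

  site_mix <- function(cls, w) {
    if (length(w) == 1L) return(cls[, 1])
    m <- do.call(pmax, as.data.frame(cls))
    m + log(as.vector(exp(cls - m) %*% w))
  }
  # cache of per-class pattern log-likelihoods: a change in the mixture
  # proportions alone costs nothing, and a change in a single omega only
  # recomputes the site classes that use it (a large saving inside the
  # finite-difference gradient)
  cache <- new.env(parent = emptyenv())
  class_loglik <- function(p, st) {
    el <- as.numeric(p$el)
    el_mat <- outer(el, st$rmult)
    # classes whose per-edge omega assignments coincide (e.g. classes 1
    # and 2b when omega2 = 1) are computed once
    omap <- matrix(st$om[st$catmap + 1L], nrow(st$catmap))
    ckey <- apply(omap, 2, paste, collapse = ",")
    uniq <- !duplicated(ckey)
    expand <- match(ckey, ckey[uniq])
    reusable <- !is.null(cache$cls_u) && cache$kappa == p$kappa &&
      length(cache$el) == length(el) && all(cache$el == el) &&
      length(cache$om) == length(st$om) &&
      identical(cache$expand, expand)
    if (reusable && all(cache$om == st$om))
      return(cache$cls_u[, cache$expand, drop = FALSE])
    eig_for <- function(k) {
      if (reusable && cache$om[k] == st$om[k]) return(cache$eigs[[k]])
      .eig_reversible(codon_rate_matrix(pi, p$kappa, st$om[k]), pi)
    }
    eigs <- lapply(seq_along(st$om), eig_for)
    if (reusable) {
      changed_cat <- which(cache$om != st$om)
      affected <- which(uniq & vapply(seq_len(ncol(st$catmap)), function(j)
        any((st$catmap[, j] + 1L) %in% changed_cat), logical(1)))
      cls_u <- cache$cls_u
      if (length(affected))
        cls_u[, match(affected, which(uniq))] <- .pruning_loglik_cpp(
          pat$states, edge, el_mat, ntip, eigs,
          st$catmap[, affected, drop = FALSE], pi)
    } else {
      cls_u <- .pruning_loglik_cpp(pat$states, edge, el_mat, ntip, eigs,
                                   st$catmap[, uniq, drop = FALSE], pi)
    }
    cls <- cls_u[, expand, drop = FALSE]
    cache$cls_u <- cls_u; cache$expand <- expand
    cache$kappa <- p$kappa; cache$el <- el
    cache$om <- st$om; cache$eigs <- eigs
    cls
  }
  eval_ll <- function(theta, per_site = FALSE) {
    p <- .unpack_params(theta, model, bl_mode, el0)
    st <- .class_structure(model, p, fg, pi)
    cls <- class_loglik(p, st)
    mix <- site_mix(cls, st$w)
    if (per_site)
      return(list(site = mix[pat$index], cls = cls, p = p, st = st))
    sum(mix * pat$weight)
  }
  list(negll = function(theta) {
         v <- tryCatch(-eval_ll(theta), error = function(e) NA_real_)
         if (!is.finite(v)) 1e10 else v
       },
       detail = eval_ll, tree = tree, fg = fg, el0 = el0, pat = pat)
}

# default (fixed) transformed start per model
.fixed_start <- function(spec, model, el0) {
  st <- c(lkappa = log(2), lomega = log(0.5), lomega_bg = log(0.5),
          lomega_fg = log(0.5), qpA = stats::qlogis(0.85),
          qpB = stats::qlogis(0.5), qomega0 = stats::qlogis(0.2),
          lomega2 = log(2), lscale = 0)
  out <- st[spec$names]
  free <- grepl("^ledge", spec$names)
  if (any(free)) out[free] <- log(pmax(el0, 1e-4))
  names(out) <- spec$names
  out
}

.random_start <- function(spec, el0) {
  draw <- c(lkappa = log(stats::runif(1, 0.5, 8)),
            lomega = log(stats::runif(1, 0.05, 3)),
            lomega_bg = log(stats::runif(1, 0.05, 3)),
            lomega_fg = log(stats::runif(1, 0.05, 5)),
            qpA = stats::qlogis(stats::runif(1, 0.4, 0.98)),
            qpB = stats::qlogis(stats::runif(1, 0.1, 0.9)),
            qomega0 = stats::qlogis(stats::runif(1, 0.02, 0.9)),
            lomega2 = log(stats::runif(1, 1.05, 8)),
            lscale = log(stats::runif(1, 0.3, 3)))
  out <- draw[spec$names]
  free <- grepl("^ledge", spec$names)
  if (any(free))
    out[free] <- log(pmax(el0, 1e-4)) + stats::rnorm(sum(free), 0, 0.3)
  names(out) <- spec$names
  out
}

# L-BFGS-B with a forward-difference gradient that reuses f(x)
.optimize_theta <- function(negll, start, spec, control) {
  memo <- new.env(parent = emptyenv())
  fn <- function(x) {
    v <- negll(x)
    memo$x <- x; memo$f <- v
    v
  }
  h <- control$ndeps %||% 1e-5
  gr <- function(x) {
    f0 <- if (!is.null(memo$x) && isTRUE(all.equal(memo$x, x,
                                                   tolerance = 0)))
      memo$f else negll(x)
    vapply(seq_along(x), function(i) {
      xi <- x
      hi <- if (xi[i] + h <= spec$upper[i]) h else -h
      xi[i] <- xi[i] + hi
      (negll(xi) - f0) / hi
    }, numeric(1))
  }
  stats::optim(start, fn, gr, method = "L-BFGS-B",
               lower = spec$lower, upper = spec$upper,
               control = list(maxit = control$maxit %||% 200,
                              factr = control$factr %||% 1e9))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Fit a GY94 codon model by maximum likelihood
#'
#' Fits one of four codon substitution models to an in-frame codon
#' alignment on a labeled tree: `"M0"` (one ratio), `"branch"` (separate
#' foreground/background omega), `"branch_site_alt"` (branch-site model A:
#' site classes with 0 <= omega0 <= 1, omega1 = 1, and omega2 >= 1 on
#' foreground branches) or `"branch_site_null"` (model A with omega2
#' fixed at 1). Codon frequencies are F3X4 from the alignment unless
#' supplied. Optimisation is bounded quasi-Newton on transformed
#' parameters with an optional fixed start, warm start, and random
#' restarts; the best of all starts is returned.
#'
#' @param aln `codon_alignment`.
#' @param tree `labeled_tree` (foreground marks required for branch and
#'   branch-site models); edge lengths in expected substitutions/codon.
#' @param model one of `"M0"`, `"branch"`, `"branch_site_alt"`,
#'   `"branch_site_null"`.
#' @param freqs optional `codon_freqs`.
#' @param branch_lengths `"scale"` (default; a single rate multiplier of
#'   the input branch lengths is estimated), `"free"` (every edge length
#'   free) or `"fixed"`.
#' @param start optional named transformed-parameter vector (as found in
#'   `fit$theta`) used as an additional warm start.
#' @param use_fixed_start include the fixed default start (kappa = 2,
#'   omega = 0.5) among the optimisation starts.
#' @param n_restarts number of additional random restarts.
#' @param control list: `maxit`, `factr`, `ndeps` passed to the optimiser.
#' @return object of class `codon_fit`.
#' @export
fit_codon_model <- function(aln, tree,
                            model = c("M0", "branch", "branch_site_alt",
                                      "branch_site_null"),
                            freqs = NULL,
                            branch_lengths = c("scale", "free", "fixed"),
                            start = NULL, use_fixed_start = TRUE,
                            n_restarts = 0, control = list()) {
  model <- match.arg(model)
  bl_mode <- match.arg(branch_lengths)
  stopifnot(inherits(aln, "codon_alignment"))
  .check_taxa(tree, aln)
  if (model != "M0" && !any(foreground_edges(tree)))
    stop("model '", model, "' requires at least one foreground branch")
  if (model != "M0" && all(foreground_edges(tree)))
    stop("at least one background branch is required")
  if (is.null(freqs)) freqs <- build_f3x4(aln)

  obj <- .make_objective(tree, aln, model, freqs, bl_mode)
  spec <- .param_spec(model, bl_mode, length(obj$el0))

  starts <- if (use_fixed_start || is.null(start))
    list(.fixed_start(spec, model, obj$el0)) else list()
  if (!is.null(start)) {
    s <- .fixed_start(spec, model, obj$el0)
    s[intersect(names(start), names(s))] <-
      start[intersect(names(start), names(s))]
    starts <- c(starts, list(s))
  }
  if (n_restarts > 0)
    starts <- c(starts, replicate(n_restarts, .random_start(spec, obj$el0),
                                  simplify = FALSE))

  best <- NULL
  for (s0 in starts) {
    s0 <- pmin(pmax(s0, spec$lower), spec$upper)
    res <- .optimize_theta(obj$negll, s0, spec, control)
    if (is.null(best) || res$value < best$value) best <- res
  }
  theta <- best$par
  attr(theta, "pnames") <- spec$names
  det <- obj$detail(theta, per_site = TRUE)
  p <- det$p

  fitted_tree <- obj$tree
  el_report <- as.numeric(p$el)
  if (grepl("branch_site", model)) {
    # report branch lengths as expected substitutions per codon averaged
    # over site classes on background branches
    st <- det$st
    mubar <- sum(st$w * st$mu[c(1, 2, 1, 2)])
    el_report <- el_report * mubar / st$mu[2]
  }
  fitted_tree$edge.length <- el_report

  params <- p[setdiff(names(p), c("el"))]
  out <- list(model = model, gene_id = aln$gene_id,
              params = params, tree = fitted_tree,
              loglik = sum(det$site), site_loglik = det$site,
              theta = stats::setNames(as.numeric(theta), spec$names),
              converged = best$convergence == 0,
              n_restarts_used = length(starts) - 1L,
              np = length(spec$names),
              n_codons = aln$n_codons, aln = aln,
              freqs = freqs, branch_lengths = bl_mode,
              optim = list(value = best$value, counts = best$counts,
                           message = best$message))
  class(out) <- "codon_fit"
  out
}

#' @export
print.codon_fit <- function(x, ...) {
  cat("GY94 codon model fit (", x$model, "), gene '", x$gene_id, "'\n",
      sep = "")
  cat("  lnL = ", format(x$loglik, digits = 10), " over ", x$n_codons,
      " codons; converged: ", x$converged, "\n", sep = "")
  pr <- x$params[vapply(x$params, function(v) length(v) == 1L, logical(1))]
  cat("  ", paste(names(pr), "=", vapply(pr, function(v)
    format(v, digits = 4), character(1)), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' @export
summary.codon_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.codon_fit")
}

#' @export
print.summary.codon_fit <- function(x, ...) {
  print(x$fit)
  f <- x$fit
  if (grepl("branch_site", f$model)) {
    p <- f$params
    cat("  site class proportions: p0 =", format(p$p0, digits = 4),
        " p1 =", format(p$p1, digits = 4),
        " p2a+p2b =", format(1 - p$p0 - p$p1, digits = 4), "\n")
  }
  cat("  branch length mode:", f$branch_lengths)
  if (!is.na(f$params$scale))
    cat(" (tree scale ", format(f$params$scale, digits = 4), ")", sep = "")
  cat("\n  per-site lnL: range ",
      paste(format(range(f$site_loglik), digits = 4), collapse = " .. "),
      "\n", sep = "")
  invisible(x)
}

#' @export
coef.codon_fit <- function(object, ...) {
  p <- object$params
  unlist(p[vapply(p, function(v) length(v) == 1L && is.finite(v),
                  logical(1))])
}

#' @export
logLik.codon_fit <- function(object, ...) {
  structure(object$loglik, df = object$np, nobs = object$n_codons,
            class = "logLik")
}
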