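# Likelihood-ratio testing and multiple-testing correction, plus the two
# paired fit-and-test drivers (branch test, branch-site test).

#' Likelihood-ratio test between nested codon model fits
#'
#' Statistic is `2 * (lnL_alt - lnL_null)`, clamped at zero, compared to
#' a chi-square upper tail with `df` degrees of freedom. Numeric
#' log-likelihoods may be given directly in place of fits.
#'
#' @param fit_null,fit_alt `codon_fit` objects or bare log-likelihoods.
#' @param df degrees of freedom (default 1).
#' @param tol tolerance on `lnL_alt < lnL_null` before an optimisation
#'   failure is declared.
#' @return object of class `lrt_result`: list with `statistic`, `df`,
#'   `p_value` and (initially `NA`) `p_adjusted`.
#' @export
lrt <- function(fit_null, fit_alt, df = 1, tol = 1e-4) {
  ll0 <- if (inherits(fit_null, "codon_fit")) fit_null$loglik
         else as.numeric(fit_null)
  ll1 <- if (inherits(fit_alt, "codon_fit")) fit_alt$loglik
         else as.numeric(fit_alt)
  if (df < 1) stop("df must be >= 1")
  stat <- 2 * (ll1 - ll0)
  if (stat < -tol)
    stop("optimization failure: alternative lnL (", ll1,
         ") below null lnL (", ll0, ")")
  stat <- max(stat, 0)
  structure(list(statistic = stat, df = df,
                 p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                 p_adjusted = NA_real_),
            class = "lrt_result")
}

#' @export
print.lrt_result <- function(x, ...) {
  cat("LRT: statistic = ", format(x$statistic, digits = 7), ", df = ",
      x$df, ", p = ", format(x$p_value, digits = 4), sep = "")
  if (!is.na(x$p_adjusted))
    cat(", adjusted p = ", format(x$p_adjusted, digits = 4), sep = "")
  cat("\n")
  invisible(x)
}

#' Bonferroni correction
#'
#' @param p_values numeric p-values in \[0, 1\].
#' @param n_tests number of tests corrected for; must be at least
#'   `length(p_values)`.
#' @return adjusted p-values, `min(1, p * n_tests)`.
#' @export
bonferroni <- function(p_values, n_tests = length(p_values)) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE))
    stop("p-values must lie in [0, 1]")
  if (n_tests < length(p_values))
    stop("n_tests must be >= number of p-values")
  pmin(1, p_values * n_tests)
}

#' Branch test of lineage-specific rate acceleration
#'
#' Fits the one-ratio (M0) null and the two-ratio branch model
#' (foreground vs background omega) and performs the LRT. The
#' alternative is warm-started from the null solution so its
#' log-likelihood can never fall below the null's.
#'
#' @inheritParams fit_codon_model
#' @param df LRT degrees of freedom (default 1).
#' @param ... passed to [fit_codon_model()].
#' @return list with `fit_null`, `fit_alt` and `lrt`.
#' @export
branch_test <- function(aln, tree, df = 1, ...) {
  fit0 <- fit_codon_model(aln, tree, model = "M0", ...)
  warm <- c(fit0$theta["lkappa"],
            lomega_bg = unname(fit0$theta["lomega"]),
            lomega_fg = unname(fit0$theta["lomega"]))
  if ("lscale" %in% names(fit0$theta))
    warm <- c(warm, fit0$theta["lscale"])
  if (any(grepl("^ledge", names(fit0$theta))))
    warm <- c(warm, fit0$theta[grep("^ledge", names(fit0$theta))])
  fit1 <- fit_codon_model(aln, tree, model = "branch", start = warm,
                          use_fixed_start = FALSE, ...)
  if (fit1$loglik < fit0$loglik - 1e-6) {
    retry <- fit_codon_model(aln, tree, model = "branch", n_restarts = 2, ...)
    if (retry$loglik > fit1$loglik) fit1 <- retry
  }
  list(fit_null = fit0, fit_alt = fit1,
       lrt = lrt(fit0, fit1, df = df))
}

#' Branch-site test of positive selection
#'
#' Fits branch-site model A and its omega2 = 1 null. The alternative is
#' optimised from two starts: the null solution with omega2 at its
#' boundary value 1 (guaranteeing a non-negative LRT statistic) and the
#' null solution pushed to an interior point (class-0/1 mass 0.85,
#' omega2 = 2.5), which protects against the boundary local optimum in
#' the (p0 + p1, omega2) profile.
#'
#' @inheritParams fit_codon_model
#' @param df LRT degrees of freedom (default 1).
#' @param ... passed to [fit_codon_model()].
#' @return list with `fit_null`, `fit_alt` and `lrt`.
#' @export
branch_site_test <- function(aln, tree, df = 1, ...) {
  fit0 <- fit_codon_model(aln, tree, model = "branch_site_null", ...)
  warm <- fit0$theta
  warm <- c(warm, lomega2 = 0)  # omega2 = 1, boundary of the alternative
  fit1a <- fit_codon_model(aln, tree, model = "branch_site_alt",
                           start = warm, use_fixed_start = FALSE, ...)
  warm2 <- warm
  warm2["qpA"] <- stats::qlogis(0.85)
  warm2["lomega2"] <- log(2.5)
  fit1b <- fit_codon_model(aln, tree, model = "branch_site_alt",
                           start = warm2, use_fixed_start = FALSE, ...)
  fit1 <- if (fit1b$loglik > fit1a$loglik) fit1b else fit1a
  list(fit_null = fit0, fit_alt = fit1,
       lrt = lrt(fit0, fit1, df = df))
}
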