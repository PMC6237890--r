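# Orchestration of the full analysis: alignment filters -> branch-model
# REGs -> deltaSSLS DSGs -> unique-substitution USGs -> final
# intersection; and, separately, the branch-site scan with BEB site
# posteriors.

#' Pipeline run configuration
#'
#' @param tree_h0 species tree (`labeled_tree`/`phylo`); used for the
#'   selection tests (with the configured foreground) and as the H0
#'   topology for deltaSSLS.
#' @param tree_h1 marine-monophyly constraint topology for deltaSSLS.
#' @param foreground foreground spec for the branch (REG) test: clade
#'   name or taxon vector (default `"marine"`: all three marine clades).
#' @param bs_foreground foreground for the branch-site test (default
#'   `"pinnipeds"`).
#' @param clade_map clade definitions for substitution classification.
#' @param df LRT degrees of freedom.
#' @param n_tests Bonferroni denominator override (`NULL`: the number of
#'   genes entering each analysis after filtering).
#' @param fraction top deltaSSLS fraction (default 0.01).
#' @param min_len_nt,max_ds,max_dnds,min_lrt alignment and post-fit
#'   filter thresholds (defaults: 100 nt, dS 3, dN/dS 5, LRT 0).
#' @param beb_threshold BEB posterior threshold (default 0.95).
#' @param sig_level significance level on Bonferroni-adjusted p.
#' @param seed integer seed fixed at the start of every run.
#' @param fit_args list of extra arguments passed to the model fits
#'   (e.g. `branch_lengths`, `n_restarts`, `control`).
#' @return object of class `run_config`.
#' @export
run_config <- function(tree_h0 = mammal_species_tree(),
                       tree_h1 = marine_monophyly_tree(),
                       foreground = "marine",
                       bs_foreground = "pinnipeds",
                       clade_map = default_clade_map(),
                       df = 1, n_tests = NULL, fraction = 0.01,
                       min_len_nt = 100, max_ds = 3, max_dnds = 5,
                       min_lrt = 0, beb_threshold = 0.95,
                       sig_level = 0.05, seed = 1, fit_args = list()) {
  stopifnot(min_len_nt > 0, max_ds > 0, max_dnds > 0,
            fraction > 0, fraction <= 1,
            beb_threshold > 0, beb_threshold < 1,
            sig_level > 0, sig_level < 1)
  structure(list(tree_h0 = tree_h0, tree_h1 = tree_h1,
                 foreground = foreground, bs_foreground = bs_foreground,
                 clade_map = clade_map, df = df, n_tests = n_tests,
                 fraction = fraction, min_len_nt = min_len_nt,
                 max_ds = max_ds, max_dnds = max_dnds, min_lrt = min_lrt,
                 beb_threshold = beb_threshold, sig_level = sig_level,
                 seed = as.integer(seed), fit_args = fit_args),
            class = "run_config")
}

#' Post-fit gene filters on branch rates and LRT
#'
#' A gene is removed when its maximum branch dS exceeds `max_ds`, its
#' maximum branch dN/dS exceeds `max_dnds`, or its LRT statistic falls
#' below `min_lrt`.
#'
#' @param stats data frame with columns `gene_id`, `max_ds`, `max_dnds`,
#'   `lrt_stat` (as built by the pipeline from [branch_rates()] and
#'   [lrt()]).
#' @param max_ds,max_dnds,min_lrt thresholds (defaults 3, 5, 0).
#' @return the data frame with a logical `retained` column added.
#' @export
apply_post_fit_filters <- function(stats, max_ds = 3, max_dnds = 5,
                                   min_lrt = 0) {
  need <- c("gene_id", "max_ds", "max_dnds", "lrt_stat")
  if (!all(need %in% names(stats)))
    stop("missing columns: ", paste(setdiff(need, names(stats)),
                                    collapse = ", "))
  stats$retained <- !(stats$max_ds > max_ds |
                        stats$max_dnds > max_dnds |
                        stats$lrt_stat < min_lrt)
  stats
}

# internal: trim/filter a list of codon alignments, with reasons
.filter_genes <- function(codon_alns, config) {
  res <- lapply(codon_alns, trim_and_filter,
                min_len_nt = config$min_len_nt)
  names(res) <- vapply(codon_alns, function(a) a$gene_id, character(1))
  res
}

#' Run the full divergence/uniqueness analysis
#'
#' Stages: (1) alignment trimming and length/stop filters; (2) branch
#' test with the configured (marine) foreground, followed by the
#' post-fit dS / dN/dS / LRT filters and Bonferroni correction, giving
#' the rapidly evolving genes (REGs); (3) deltaSSLS between the species
#' tree and the marine-monophyly tree with top-fraction selection,
#' giving divergent substitution genes (DSGs); (4) joint ancestral
#' reconstruction and substitution classification, giving unique
#' substitution genes (USGs); (5) intersection of REGs with genes whose
#' top-deltaSSLS residues coincide with unique substitutions.
#'
#' @param codon_alns list of `codon_alignment` objects (one per gene).
#' @param config `run_config`.
#' @param verbose print per-stage progress.
#' @param out_dir optional directory: each stage's table is written there
#'   as TSV (`branch_tests.tsv`, `top_sites.tsv`,
#'   `substitution_calls.tsv`, `final_genes.tsv`), so stages can be
#'   inspected or re-used without re-running the pipeline.
#' @return object of class `pipeline_report`.
#' @export
run_full <- function(codon_alns, config = run_config(), verbose = FALSE,
                     out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  say <- function(...) if (verbose) message(...)
  persist <- function(obj, name) {
    if (is.null(out_dir)) return(invisible())
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(obj, file.path(out_dir, paste0(name, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  t_h0 <- .apply_foreground(config$tree_h0, config$foreground)

  say("stage 1/5: alignment filters")
  filt <- .filter_genes(codon_alns, config)
  kept <- Filter(function(x) x$accepted, filt)
  rejected <- data.frame(
    gene_id = names(filt)[!vapply(filt, `[[`, logical(1), "accepted")],
    reason = vapply(filt[!vapply(filt, `[[`, logical(1), "accepted")],
                    `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  if (length(kept) == 0) stop("stage alignment-filter: no genes retained")

  say("stage 2/5: branch test (", length(kept), " genes)")
  per_gene <- lapply(names(kept), function(g) {
    aln <- kept[[g]]$alignment
    bt <- do.call(branch_test,
                  c(list(aln = aln, tree = t_h0, df = config$df),
                    config$fit_args))
    rates <- branch_rates(bt$fit_alt)
    list(gene_id = g, aln = aln, test = bt, rates = rates)
  })
  names(per_gene) <- names(kept)

  stats <- do.call(rbind, lapply(per_gene, function(x) {
    data.frame(gene_id = x$gene_id,
               n_codons = x$aln$n_codons,
               lnl_h0 = x$test$fit_null$loglik,
               lnl_h1 = x$test$fit_alt$loglik,
               lrt_stat = x$test$lrt$statistic,
               p_value = x$test$lrt$p_value,
               fg_omega = x$test$fit_alt$params$omega_fg,
               bg_omega = x$test$fit_alt$params$omega_bg,
               delta_dnds = x$test$fit_alt$params$omega_fg -
                 x$test$fit_alt$params$omega_bg,
               max_ds = max(x$rates$dS),
               max_dnds = max(x$rates$dNdS, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(stats) <- NULL
  stats <- apply_post_fit_filters(stats, config$max_ds, config$max_dnds,
                                  config$min_lrt)
  n_tests <- config$n_tests %||% sum(stats$retained)
  stats$p_adjusted <- NA_real_
  stats$p_adjusted[stats$retained] <-
    bonferroni(stats$p_value[stats$retained], n_tests)
  stats$reg <- stats$retained & !is.na(stats$p_adjusted) &
    stats$p_adjusted < config$sig_level
  regs <- stats$gene_id[stats$reg]
  persist(stats, "branch_tests")

  say("stage 3/5: deltaSSLS (", sum(stats$retained), " genes)")
  retained_ids <- stats$gene_id[stats$retained]
  prots <- lapply(per_gene[retained_ids], function(x)
    translate_alignment(x$aln))
  profiles <- lapply(prots, function(p)
    delta_ssls(config$tree_h0, config$tree_h1, p))
  top <- select_top_fraction(profiles, config$fraction)
  persist(top$sites, "top_sites")

  say("stage 4/5: ancestral reconstruction and substitution calls")
  calls <- lapply(prots, function(p) {
    recon <- joint_reconstruct(config$tree_h0, p)
    classify_substitutions(recon, config$clade_map,
                           focal = config$bs_foreground)
  })
  call_df <- do.call(rbind, calls)
  rownames(call_df) <- NULL
  usgs <- sort(unique(call_df$gene_id[call_df$category == "unique"]))
  persist(call_df[call_df$category != "none", , drop = FALSE],
          "substitution_calls")

  say("stage 5/5: intersection")
  inter <- intersect_rdu(regs, top, call_df)

  stats$max_delta_ssls <- vapply(stats$gene_id, function(g) {
    if (!g %in% names(profiles)) return(NA_real_)
    max(profiles[[g]]$delta)
  }, numeric(1))
  stats$dsg <- stats$gene_id %in% top$dsg_genes
  stats$usg <- stats$gene_id %in% usgs
  stats$n_unique_subs <- vapply(stats$gene_id, function(g) {
    n <- inter$unique_counts[g]
    if (is.na(n)) 0L else as.integer(n)
  }, integer(1))
  stats$final <- stats$gene_id %in% inter$final_genes

  summary_counts <- c(n_input = length(codon_alns),
                      n_filtered = length(kept),
                      n_retained = sum(stats$retained),
                      n_reg = length(regs),
                      n_dsg = length(top$dsg_genes),
                      n_usg = length(usgs),
                      n_overlap = sum(stats$reg & stats$dsg),
                      n_final = length(inter$final_genes))
  if (length(inter$final_genes))
    persist(data.frame(gene_id = inter$final_genes), "final_genes")

  structure(list(gene_table = stats, rejected = rejected,
                 top_sites = top, substitution_calls = call_df,
                 intersection = inter, regs = regs, usgs = usgs,
                 summary = summary_counts, config = config,
                 n_tests = n_tests),
            class = "pipeline_report")
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Pipeline report\n")
  s <- x$summary
  cat(sprintf(
    "  genes: %d in, %d past alignment filters, %d past post-fit filters\n",
    s["n_input"], s["n_filtered"], s["n_retained"]))
  cat(sprintf("  REGs: %d  DSGs: %d  USGs: %d  final: %d\n",
              s["n_reg"], s["n_dsg"], s["n_usg"], s["n_final"]))
  if (length(x$intersection$final_genes))
    cat("  final genes:", paste(x$intersection$final_genes,
                                collapse = ", "), "\n")
  invisible(x)
}

#' Run the branch-site scan with BEB site posteriors
#'
#' Per gene: alignment filters, branch-site test (model A alternative vs
#' omega2 = 1 null) with the configured foreground, post-fit filters,
#' Bonferroni correction, and BEB site identification for significant
#' genes.
#'
#' @param codon_alns list of `codon_alignment` objects.
#' @param config `run_config` (`bs_foreground` sets the foreground).
#' @param verbose print progress.
#' @return object of class `branch_site_report`: per-gene table plus
#'   per-gene BEB results for significant genes.
#' @export
run_branch_site <- function(codon_alns, config = run_config(),
                            verbose = FALSE) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  say <- function(...) if (verbose) message(...)
  tree <- .apply_foreground(config$tree_h0, config$bs_foreground)

  filt <- .filter_genes(codon_alns, config)
  kept <- Filter(function(x) x$accepted, filt)
  rejected <- data.frame(
    gene_id = names(filt)[!vapply(filt, `[[`, logical(1), "accepted")],
    reason = vapply(filt[!vapply(filt, `[[`, logical(1), "accepted")],
                    `[[`, character(1), "reason"),
    stringsAsFactors = FALSE)
  if (length(kept) == 0) stop("stage alignment-filter: no genes retained")

  say("branch-site test on ", length(kept), " genes")
  per_gene <- lapply(names(kept), function(g) {
    aln <- kept[[g]]$alignment
    bst <- do.call(branch_site_test,
                   c(list(aln = aln, tree = tree, df = config$df),
                     config$fit_args))
    rates <- branch_rates(bst$fit_alt)
    list(gene_id = g, aln = aln, test = bst, rates = rates)
  })
  names(per_gene) <- names(kept)

  stats <- do.call(rbind, lapply(per_gene, function(x) {
    p <- x$test$fit_alt$params
    data.frame(gene_id = x$gene_id,
               n_codons = x$aln$n_codons,
               fg_omega2 = p$omega2,
               prop_2b = (1 - p$p0 - p$p1) * p$p1 / (p$p0 + p$p1),
               lnl_h0 = x$test$fit_null$loglik,
               lnl_h1 = x$test$fit_alt$loglik,
               lrt_stat = x$test$lrt$statistic,
               p_value = x$test$lrt$p_value,
               max_ds = max(x$rates$dS),
               max_dnds = max(x$rates$dNdS, na.rm = TRUE),
               stringsAsFactors = FALSE)
  }))
  rownames(stats) <- NULL
  stats <- apply_post_fit_filters(stats, config$max_ds, config$max_dnds,
                                  config$min_lrt)
  n_tests <- config$n_tests %||% sum(stats$retained)
  stats$p_adjusted <- NA_real_
  stats$p_adjusted[stats$retained] <-
    bonferroni(stats$p_value[stats$retained], n_tests)
  stats$significant <- stats$retained & !is.na(stats$p_adjusted) &
    stats$p_adjusted < config$sig_level

  beb <- list()
  for (g in stats$gene_id[stats$significant]) {
    say("BEB for ", g)
    beb[[g]] <- beb_site_posteriors(per_gene[[g]]$test$fit_alt,
                                    threshold = config$beb_threshold)
  }
  stats$n_selected_sites <- vapply(stats$gene_id, function(g)
    if (g %in% names(beb)) length(beb[[g]]$selected_sites) else 0L,
    integer(1))

  structure(list(gene_table = stats, rejected = rejected, beb = beb,
                 config = config, n_tests = n_tests),
            class = "branch_site_report")
}

#' @export
print.branch_site_report <- function(x, ...) {
  cat("Branch-site scan: ", nrow(x$gene_table), " genes tested, ",
      sum(x$gene_table$significant), " significant (adjusted p < ",
      x$config$sig_level, ")\n", sep = "")
  invisible(x)
}

#' Write a pipeline or branch-site report to TSV (+ JSON summary)
#'
#' @param report `pipeline_report` or `branch_site_report`.
#' @param path base path; writes `<path>.tsv` and `<path>.json`.
#' @return invisibly, the paths written.
#' @export
write_report <- function(report, path) {
  tsv <- paste0(path, ".tsv")
  json <- paste0(path, ".json")
  utils::write.table(report$gene_table, tsv, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  summ <- if (inherits(report, "pipeline_report"))
    as.list(report$summary)
  else list(n_tested = nrow(report$gene_table),
            n_significant = sum(report$gene_table$significant))
  summ$n_tests_bonferroni <- report$n_tests
  jsonlite::write_json(summ, json, auto_unbox = TRUE, digits = NA)
  invisible(c(tsv, json))
}
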