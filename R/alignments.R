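# Alignment containers and FASTA plumbing. Codon alignments are in-frame
# nucleotide alignments (gap-aware, alphabet A/C/G/T/-/N); protein
# alignments use the 20-letter alphabet plus gap and X.

#' Construct a codon alignment
#'
#' @param seqs named character vector or list of aligned in-frame
#'   nucleotide strings (equal lengths, divisible by 3).
#' @param gene_id identifier carried into reports.
#' @return object of class `codon_alignment` with fields `gene_id`,
#'   `taxa`, `seqs` and `n_codons`.
#' @export
codon_alignment <- function(seqs, gene_id = "gene") {
  seqs <- vapply(seqs, toupper, character(1))
  taxa <- names(seqs)
  if (is.null(taxa) || anyNA(taxa) || any(taxa == ""))
    stop("all sequences must be named")
  if (anyDuplicated(taxa)) stop("duplicate taxon names")
  len <- nchar(seqs)
  if (length(unique(len)) != 1L)
    stop("ragged alignment: sequence lengths differ")
  if (len[1] %% 3 != 0)
    stop("frame error: alignment length ", len[1], " not divisible by 3")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad))
    stop("invalid characters in sequences: ",
         paste(taxa[bad], collapse = ", "))
  structure(list(gene_id = gene_id, taxa = taxa, seqs = as.list(seqs),
                 n_codons = as.integer(len[1] / 3)),
            class = "codon_alignment")
}

#' Construct a protein alignment
#'
#' @param seqs named character vector/list of aligned amino-acid strings.
#' @param gene_id identifier carried into reports.
#' @return object of class `protein_alignment` with fields `gene_id`,
#'   `taxa`, `seqs` and `n_sites`.
#' @export
protein_alignment <- function(seqs, gene_id = "gene") {
  seqs <- vapply(seqs, toupper, character(1))
  taxa <- names(seqs)
  if (is.null(taxa) || anyNA(taxa) || any(taxa == ""))
    stop("all sequences must be named")
  if (anyDuplicated(taxa)) stop("duplicate taxon names")
  len <- nchar(seqs)
  if (length(unique(len)) != 1L)
    stop("ragged alignment: sequence lengths differ")
  bad <- grepl(paste0("[^", paste(AA_LETTERS, collapse = ""), "X*-]"), seqs)
  if (any(bad))
    stop("invalid residues in sequences: ", paste(taxa[bad], collapse = ", "))
  structure(list(gene_id = gene_id, taxa = taxa, seqs = as.list(seqs),
                 n_sites = as.integer(len[1])),
            class = "protein_alignment")
}

#' @export
print.codon_alignment <- function(x, ...) {
  cat("Codon alignment '", x$gene_id, "': ", length(x$taxa), " taxa, ",
      x$n_codons, " codons\n", sep = "")
  invisible(x)
}

#' @export
print.protein_alignment <- function(x, ...) {
  cat("Protein alignment '", x$gene_id, "': ", length(x$taxa), " taxa, ",
      x$n_sites, " sites\n", sep = "")
  invisible(x)
}

# minimal FASTA reader/writer (plain text, no wrapping requirements)
.read_fasta <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  hdr <- grepl("^>", lines)
  if (!any(hdr) || !hdr[1]) stop("not a FASTA file: ", path)
  id <- sub("^>\\s*", "", lines[hdr])
  id <- sub("\\s.*$", "", id)
  grp <- cumsum(hdr)
  seqs <- vapply(split(lines[!hdr], grp[!hdr]),
                 function(x) gsub("\\s", "", paste(x, collapse = "")),
                 character(1))
  names(seqs) <- id
  seqs
}

.write_fasta <- function(seqs, path, width = 70) {
  con <- file(path, "w")
  on.exit(close(con))
  for (nm in names(seqs)) {
    writeLines(paste0(">", nm), con)
    s <- seqs[[nm]]
    starts <- seq(1, nchar(s), width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read an aligned FASTA file
#'
#' @param path FASTA file of aligned sequences.
#' @param kind `"codon"` for an in-frame nucleotide alignment, `"protein"`
#'   for amino acids.
#' @param gene_id identifier; defaults to the file base name.
#' @return `codon_alignment` or `protein_alignment`.
#' @export
read_alignment <- function(path, kind = c("codon", "protein"),
                           gene_id = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("no such file: ", path)
  if (is.null(gene_id))
    gene_id <- sub("\\.[^.]*$", "", basename(path))
  seqs <- .read_fasta(path)
  if (kind == "codon") codon_alignment(seqs, gene_id)
  else protein_alignment(seqs, gene_id)
}

#' Write an alignment to FASTA
#' @param aln `codon_alignment` or `protein_alignment`.
#' @param path output file.
#' @export
write_alignment <- function(aln, path) {
  .write_fasta(stats::setNames(unlist(aln$seqs), aln$taxa), path)
}

#' Translate a codon alignment
#'
#' @param aln `codon_alignment`.
#' @return the paired `protein_alignment` (gap codons become `-`,
#'   ambiguous codons `X`, stops `*`).
#' @export
translate_alignment <- function(aln) {
  stopifnot(inherits(aln, "codon_alignment"))
  prot <- vapply(aln$seqs, translate_codons, character(1))
  names(prot) <- aln$taxa
  prot <- gsub("*", "X", prot, fixed = TRUE)  # container has no stop letter
  protein_alignment(prot, aln$gene_id)
}

#' Back-translate a protein alignment using unaligned coding sequences
#'
#' Each coding sequence must translate, under the standard genetic code,
#' to its taxon's ungapped protein row; gap residues expand to `---` so
#' residue i corresponds to codon i.
#'
#' @param protein_aln `protein_alignment`.
#' @param cds named character vector/list of unaligned CDS (no gaps).
#' @return `codon_alignment` consistent with the protein alignment.
#' @export
back_translate <- function(protein_aln, cds) {
  stopifnot(inherits(protein_aln, "protein_alignment"))
  cds <- vapply(cds, toupper, character(1))
  missing_taxa <- setdiff(protein_aln$taxa, names(cds))
  if (length(missing_taxa))
    stop("no CDS for taxa: ", paste(missing_taxa, collapse = ", "))
  out <- character(length(protein_aln$taxa))
  for (i in seq_along(protein_aln$taxa)) {
    tx <- protein_aln$taxa[i]
    p <- strsplit(protein_aln$seqs[[i]], "")[[1]]
    s <- cds[[tx]]
    if (nchar(s) %% 3 != 0)
      stop("frame error: CDS length of ", tx, " not divisible by 3")
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    aa <- vapply(cods, function(co)
      if (co %in% names(GENETIC_CODE_STD)) GENETIC_CODE_STD[[co]] else "X",
      character(1))
    if (length(cods) && any(aa[-length(aa)] == "*"))
      stop("frame error: internal stop codon in CDS of ", tx)
    ungapped <- p[p != "-"]
    aa_cmp <- aa[aa != "*"]  # tolerate a trailing stop codon
    if (length(aa_cmp) != length(ungapped) ||
        any(aa_cmp != ungapped & ungapped != "X"))
      stop("consistency error: CDS of ", tx,
           " does not translate to its protein row")
    cods <- cods[aa != "*"]
    row <- character(length(p))
    row[p == "-"] <- "---"
    row[p != "-"] <- cods
    out[i] <- paste(row, collapse = "")
  }
  names(out) <- protein_aln$taxa
  codon_alignment(out, protein_aln$gene_id)
}

#' Trim gapped columns and apply the length / internal-stop filters
#'
#' Codon columns containing a gap or ambiguous codon in any taxon are
#' removed (optional), then the alignment is rejected when the trimmed
#' length falls below `min_len_nt` nucleotides or when any row contains
#' an internal stop codon (stop before the final codon).
#'
#' @param aln `codon_alignment`.
#' @param min_len_nt minimum alignment length in nucleotides (default 100).
#' @param trim drop codon columns with a gap or N in any row.
#' @param length_after_trim apply the length threshold after trimming
#'   (`TRUE`) or to the input alignment (`FALSE`).
#' @return list with `accepted` (logical), `alignment` (trimmed
#'   `codon_alignment`, also present when rejected) and `reason`
#'   (`NA` when accepted).
#' @export
trim_and_filter <- function(aln, min_len_nt = 100, trim = TRUE,
                            length_after_trim = TRUE) {
  stopifnot(inherits(aln, "codon_alignment"))
  if (aln$n_codons == 0L)
    return(list(accepted = FALSE, alignment = aln,
                reason = sprintf("alignment shorter than %d nt (0 nt)",
                                 min_len_nt)))
  cods <- lapply(aln$seqs, function(s)
    substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3)))
  cmat <- do.call(rbind, cods)  # taxa x codon columns
  pre_len <- 3L * aln$n_codons

  keep <- rep(TRUE, aln$n_codons)
  if (trim && aln$n_codons > 0)
    keep <- apply(cmat, 2, function(col) all(!grepl("[-N]", col)))
  trimmed <- cmat[, keep, drop = FALSE]
  new_seqs <- vapply(seq_along(aln$taxa), function(i)
    paste(trimmed[i, ], collapse = ""), character(1))
  names(new_seqs) <- aln$taxa
  out <- codon_alignment(new_seqs, aln$gene_id)

  len_checked <- if (length_after_trim) 3L * out$n_codons else pre_len
  reason <- NA_character_
  if (len_checked < min_len_nt) {
    reason <- sprintf("alignment shorter than %d nt (%d nt)",
                      min_len_nt, len_checked)
  } else if (out$n_codons > 1) {
    internal <- trimmed[, -ncol(trimmed), drop = FALSE]
    if (any(internal %in% STOP_CODONS))
      reason <- "internal stop codon"
  }
  list(accepted = is.na(reason), alignment = out, reason = reason)
}
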