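#' Load the cis-regulatory element motif catalog
#'
#' Reads a two-column TSV (`name iupac`) of promoter motif consensus
#' sequences. The catalog shipped with the package covers the
#' drought-associated plant elements ABRE, DRE core, MBS, MYC, ARE,
#' W-box, as-1 and G-box; edit a copy to extend it. Motifs are validated
#' against the IUPAC nucleotide alphabet at load time.
#'
#' @param path TSV path; default is the catalog shipped in `extdata`.
#' @return `data.frame` `name iupac`.
#' @export
load_cre_motifs <- function(path = system.file("extdata", "cre_motifs.tsv",
                                               package = "mqtlkit")) {
  df <- read_tsv_checked(path, required = c("name", "iupac"))
  df$name <- as.character(df$name)
  df$iupac <- toupper(as.character(df$iupac))
  bad <- grepl("[^ACGTRYSWKMBDHVN]", df$iupac)
  if (any(bad))
    mq_value_error(sprintf("invalid IUPAC motif(s): %s",
                           paste(df$name[bad], collapse = ", ")))
  df
}

#' Scan a sequence for IUPAC motifs
#'
#' Exact degenerate matching of each motif at every offset, optionally on
#' both strands. Reverse-complement hits are reported with strand `"-"`
#' and the plus-strand start of the matched window. An `N` in the subject
#' sequence never matches any motif position.
#'
#' @param sequence `DNAString` or character over `A C G T N`.
#' @param motifs Motif catalog ([load_cre_motifs()]).
#' @param both_strands Scan the reverse complement too (default `TRUE`).
#' @return `data.frame` `motif start strand` (`start` 1-based on the
#'   supplied sequence).
#' @export
scan_cres <- function(sequence, motifs, both_strands = TRUE) {
  subject <- if (is(sequence, "DNAString")) sequence else
    Biostrings::DNAString(as.character(sequence))
  out <- list()
  has_n <- function(starts, w) {
    if (length(starts) == 0) return(logical(0))
    vapply(starts, function(st)
      Biostrings::countPattern(
        "N", Biostrings::subseq(subject, st, st + w - 1L)) > 0,
      logical(1))
  }
  for (i in seq_len(nrow(motifs))) {
    pat <- Biostrings::DNAString(motifs$iupac[i])
    w <- length(pat)
    if (w > length(subject)) next
    fwd <- Biostrings::start(
      Biostrings::matchPattern(pat, subject, fixed = "subject"))
    fwd <- fwd[!has_n(fwd, w)]
    if (length(fwd) > 0)
      out[[length(out) + 1L]] <- data.frame(
        motif = motifs$name[i], start = fwd, strand = "+",
        stringsAsFactors = FALSE)
    if (both_strands) {
      rcp <- Biostrings::reverseComplement(pat)
      rev <- Biostrings::start(
        Biostrings::matchPattern(rcp, subject, fixed = "subject"))
      rev <- rev[!has_n(rev, w)]
      if (length(rev) > 0)
        out[[length(out) + 1L]] <- data.frame(
          motif = motifs$name[i], start = rev, strand = "-",
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(motif = character(0), start = integer(0),
                      strand = character(0), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$motif, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Presence/enrichment screen of motifs across promoters
#'
#' Reports, per motif, the number of promoters containing at least one
#' hit, and a one-sided binomial test of that count against a background
#' rate estimated from dinucleotide-preserving shuffles of the same
#' promoters.
#'
#' @param promoters Named `DNAStringSet`.
#' @param motifs Motif catalog.
#' @param n_shuffle Shuffled promoters used to estimate the background
#'   per-promoter hit probability.
#' @param seed Seed for the shuffling.
#' @return `data.frame` `motif n_with_hit n_promoters background_rate
#'   p_value`.
#' @export
cre_enrichment <- function(promoters, motifs, n_shuffle = 50, seed = 1) {
  set.seed(seed)
  n <- length(promoters)
  hit_mat <- vapply(seq_len(n), function(i) {
    h <- scan_cres(promoters[[i]], motifs)
    motifs$name %in% h$motif
  }, logical(nrow(motifs)))
  hit_mat <- matrix(hit_mat, nrow = nrow(motifs))
  idx <- sample(n, n_shuffle, replace = TRUE)
  bg_mat <- vapply(idx, function(i) {
    s <- as.character(promoters[[i]])
    shuf <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    h <- scan_cres(shuf, motifs)
    motifs$name %in% h$motif
  }, logical(nrow(motifs)))
  bg_mat <- matrix(bg_mat, nrow = nrow(motifs))
  bg <- pmin(pmax(rowMeans(bg_mat), 1 / (2 * n_shuffle)),
             1 - 1 / (2 * n_shuffle))
  pv <- vapply(seq_len(nrow(motifs)), function(i)
    binom.test(sum(hit_mat[i, ]), n, bg[i],
               alternative = "greater")$p.value, numeric(1))
  data.frame(motif = motifs$name, n_with_hit = rowSums(hit_mat),
             n_promoters = n, background_rate = bg, p_value = pv,
             stringsAsFactors = FALSE)
}

#' Screen signature-cluster genes for the required promoter element
#'
#' Final funnel stage: a gene becomes a candidate iff it belongs to the
#' signature cluster and its promoter carries at least one hit of the
#' required motif (default ABRE). The returned table carries the full
#' evidence trail.
#'
#' @param signature_genes Gene ids in the signature cluster.
#' @param promoters Named `DNAStringSet` covering those genes.
#' @param motifs Motif catalog.
#' @param required_motif Motif name that must be present (default
#'   `"ABRE"`).
#' @param gene_windows Gene-to-window map ([genes_in_windows()]).
#' @param deg_stats DE statistics (for the contrast evidence).
#' @param cluster_id Signature cluster id (recorded in the output).
#' @return `data.frame` `gene_id mqtl_id deg_contrasts cluster_id
#'   n_required_hits cre_hits` (hits as `motif@start(strand)` strings).
#' @export
screen_decgs <- function(signature_genes, promoters, motifs,
                         required_motif = "ABRE", gene_windows = NULL,
                         deg_stats = NULL, cluster_id = NA_integer_) {
  if (!required_motif %in% motifs$name)
    mq_value_error(sprintf("required motif '%s' not in catalog",
                           required_motif))
  rows <- list()
  for (g in signature_genes) {
    if (!g %in% names(promoters)) next
    hits <- scan_cres(promoters[[g]], motifs)
    req <- hits[hits$motif == required_motif, , drop = FALSE]
    if (nrow(req) == 0) next
    mq <- if (!is.null(gene_windows))
      paste(unique(gene_windows$mqtl_id[gene_windows$gene_id == g]),
            collapse = ",") else NA_character_
    ctr <- if (!is.null(deg_stats))
      paste(unique(deg_stats$contrast[deg_stats$gene_id == g]),
            collapse = ",") else NA_character_
    rows[[length(rows) + 1L]] <- data.frame(
      gene_id = g, mqtl_id = mq, deg_contrasts = ctr,
      cluster_id = cluster_id, n_required_hits = nrow(req),
      cre_hits = paste(sprintf("%s@%d(%s)", hits$motif, hits$start,
                               hits$strand), collapse = ";"),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0)
    return(data.frame(gene_id = character(0), mqtl_id = character(0),
                      deg_contrasts = character(0), cluster_id = integer(0),
                      n_required_hits = integer(0), cre_hits = character(0),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
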