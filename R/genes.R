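#' Read gene models from a GFF3 file
#'
#' Reads `gene` features (attribute `ID`) and, when present,
#' `five_prime_UTR` features (attribute `Parent`) whose total width gives
#' the 5'UTR length. The transcription start site is the strand-aware gene
#' start and the translation start (ATG) lies `utr5_len` bp downstream of
#' it.
#'
#' @param path GFF3 file path.
#' @return `data.frame` `gene_id chr start_bp end_bp strand tss_bp atg_bp
#'   utr5_len`.
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  genes <- gr[gr$type == "gene"]
  if (length(genes) == 0) mq_format_error("no gene features in GFF3")
  utr <- gr[gr$type == "five_prime_UTR"]
  utr_len <- setNames(rep(0, length(genes)), genes$ID)
  if (length(utr) > 0) {
    parents <- as.character(unlist(utr$Parent))
    widths <- tapply(GenomicRanges::width(utr), parents, sum)
    utr_len[names(widths)] <- widths
  }
  strand <- as.character(GenomicRanges::strand(genes))
  start <- GenomicRanges::start(genes)
  end <- GenomicRanges::end(genes)
  tss <- ifelse(strand == "+", start, end)
  atg <- ifelse(strand == "+", start + utr_len[genes$ID],
                end - utr_len[genes$ID])
  data.frame(gene_id = genes$ID,
             chr = as.integer(as.character(GenomicRanges::seqnames(genes))),
             start_bp = start, end_bp = end, strand = strand,
             tss_bp = as.numeric(tss), atg_bp = as.numeric(atg),
             utr5_len = as.numeric(utr_len[genes$ID]),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Map genes to MQTL physical windows
#'
#' A gene matches a window iff both are on the same chromosome and the
#' gene body overlaps the window by at least 1 bp (`containment = "any"`)
#' or lies entirely inside it (`"full"`). Genes may match several windows.
#'
#' @param genes Gene-model table ([read_gene_models()]).
#' @param windows Physical windows ([anchor_mqtls()]).
#' @param containment Overlap rule, `"any"` (default) or `"full"`.
#' @return `data.frame` `gene_id mqtl_id` (one row per match).
#' @export
genes_in_windows <- function(genes, windows,
                             containment = c("any", "full")) {
  containment <- match.arg(containment)
  if (nrow(genes) == 0 || nrow(windows) == 0)
    return(data.frame(gene_id = character(0), mqtl_id = character(0)))
  gg <- GenomicRanges::GRanges(as.character(genes$chr),
                               IRanges::IRanges(genes$start_bp,
                                                genes$end_bp))
  gw <- GenomicRanges::GRanges(as.character(windows$chr),
                               IRanges::IRanges(windows$start_bp,
                                                windows$end_bp))
  ov <- GenomicRanges::findOverlaps(
    gg, gw, type = if (containment == "full") "within" else "any")
  data.frame(gene_id = genes$gene_id[S4Vectors::queryHits(ov)],
             mqtl_id = windows$mqtl_id[S4Vectors::subjectHits(ov)],
             stringsAsFactors = FALSE)
}

#' Extract a gene's promoter sequence
#'
#' The promoter is the sequence from 2000 bp upstream of the translation
#' start (ATG) down to the transcription start site; when the 5'UTR
#' exceeds 100 bp the region is instead 1500 bp upstream of the ATG down
#' to the 5'UTR start. Minus-strand promoters are reverse-complemented so
#' the returned sequence reads in transcription orientation. Regions
#' extending beyond the chromosome are clipped with a warning.
#'
#' @param gene One-row gene-model `data.frame`.
#' @param genome Named `Biostrings::DNAStringSet` (names = chromosome).
#' @param upstream_long,upstream_short Upstream extents (bp) for the
#'   short-UTR and long-UTR branches.
#' @param utr_cutoff 5'UTR length above which the short extent is used.
#' @return `Biostrings::DNAString` with attribute `"region"`
#'   (`c(start, end)` genomic, 1-based inclusive).
#' @export
extract_promoter <- function(gene, genome, upstream_long = 2000,
                             upstream_short = 1500, utr_cutoff = 100) {
  chr <- as.character(gene$chr)
  if (!chr %in% names(genome))
    mq_value_error(sprintf("chromosome %s absent from genome", chr))
  seqlen <- length(genome[[chr]])
  up <- if (gene$utr5_len > utr_cutoff) upstream_short else upstream_long
  if (gene$strand == "+") {
    lo <- gene$atg_bp - up; hi <- gene$tss_bp
  } else {
    lo <- gene$tss_bp; hi <- gene$atg_bp + up
  }
  if (lo < 1 || hi > seqlen) {
    warning(sprintf("promoter of %s clipped at chromosome edge",
                    gene$gene_id))
    lo <- max(1, lo); hi <- min(seqlen, hi)
  }
  if (lo > hi) mq_value_error(
    sprintf("degenerate promoter region for %s", gene$gene_id))
  s <- Biostrings::subseq(genome[[chr]], lo, hi)
  if (gene$strand == "-") s <- Biostrings::reverseComplement(s)
  attr(s, "region") <- c(start = lo, end = hi)
  s
}

#' Extract promoters for a set of genes
#'
#' @param genes Gene-model table.
#' @param genome Named `DNAStringSet`.
#' @param ... Passed to [extract_promoter()].
#' @return Named `DNAStringSet` (one promoter per gene).
#' @export
extract_promoters <- function(genes, genome, ...) {
  seqs <- lapply(seq_len(nrow(genes)), function(i)
    extract_promoter(genes[i, ], genome, ...))
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- genes$gene_id
  out
}
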