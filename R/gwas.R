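#' Read a marker physical-anchor table
#'
#' @param path TSV with columns `marker chr position_bp`.
#' @return `data.frame` `marker chr position_bp`.
#' @export
read_marker_anchors <- function(path) {
  df <- read_tsv_checked(path, required = c("marker", "chr", "position_bp"))
  out <- data.frame(marker = as.character(df$marker),
                    chr = as.integer(df$chr),
                    position_bp = as.numeric(df$position_bp),
                    stringsAsFactors = FALSE)
  if (any(out$position_bp < 1)) mq_value_error("position_bp must be >= 1")
  out
}

#' Read a GWAS marker-trait association table
#'
#' @param path TSV with columns
#'   `snp_id chr position_bp neg_log10_p trait panel_id`.
#' @return `data.frame` with those columns.
#' @export
read_mta_table <- function(path) {
  df <- read_tsv_checked(path, required = c("snp_id", "chr", "position_bp",
                                            "neg_log10_p"))
  out <- data.frame(snp_id = as.character(df$snp_id),
                    chr = as.integer(df$chr),
                    position_bp = as.numeric(df$position_bp),
                    neg_log10_p = as.numeric(df$neg_log10_p),
                    trait = if ("trait" %in% names(df))
                      as.character(df$trait) else NA_character_,
                    panel_id = if ("panel_id" %in% names(df))
                      as.character(df$panel_id) else NA_character_,
                    stringsAsFactors = FALSE)
  if (any(out$position_bp < 1)) mq_value_error("position_bp must be >= 1")
  if (any(out$neg_log10_p < 0)) mq_value_error("neg_log10_p must be >= 0")
  out
}

#' Anchor MQTLs to physical windows
#'
#' Each MQTL's physical window is its anchor position +/- `half_window` bp,
#' clipped at 1 and at the chromosome length when provided. The anchor is
#' chosen among the member QTLs' flanking markers that have a physical
#' coordinate on the MQTL's chromosome: markers of higher-membership
#' members are preferred, and within a member the marker whose consensus
#' genetic position is closest to the MQTL peak. MQTLs with no anchorable
#' marker are excluded with a warning.
#'
#' @param mqtls MQTL table from [run_meta_analysis()].
#' @param membership Membership table from the same run.
#' @param qtls The standardized QTL table (for flanking-marker names).
#' @param anchors Marker anchor table ([read_marker_anchors()]).
#' @param consensus Consensus map (optional, used to pick the marker
#'   closest to the peak; membership order alone is used without it).
#' @param half_window Half window width in bp (default 500000, i.e. a
#'   peak +/- 0.5 Mbp window).
#' @param chrom_lengths_bp Optional named vector (names = chromosome) of
#'   chromosome lengths for right-edge clipping.
#' @return `data.frame` `mqtl_id chr start_bp end_bp anchor_marker
#'   anchor_bp`; unanchored MQTLs recorded in `attr(result, "unanchored")`.
#' @export
anchor_mqtls <- function(mqtls, membership, qtls, anchors, consensus = NULL,
                         half_window = 500000,
                         chrom_lengths_bp = NULL) {
  rows <- list(); unanchored <- character(0)
  for (i in seq_len(nrow(mqtls))) {
    m <- mqtls[i, ]
    mem <- membership[membership$mqtl_id == m$mqtl_id, , drop = FALSE]
    mem <- mem[order(-mem$membership), , drop = FALSE]
    qsub <- qtls[match(mem$qtl_id, qtls$qtl_id), , drop = FALSE]
    cand <- unlist(lapply(seq_len(nrow(qsub)), function(j)
      c(qsub$marker_left[j], qsub$marker_right[j])))
    cand <- cand[!is.na(cand)]
    anch <- anchors[anchors$chr == m$chr, , drop = FALSE]
    cand <- cand[cand %in% anch$marker]
    if (length(cand) == 0) {
      unanchored <- c(unanchored, m$mqtl_id)
      next
    }
    pick <- cand[1]
    if (!is.null(consensus)) {
      con <- consensus[consensus$chr == m$chr, , drop = FALSE]
      pos <- con$position_cm[match(cand, con$marker)]
      if (any(!is.na(pos))) {
        ok <- which(!is.na(pos))
        pick <- cand[ok][which.min(abs(pos[ok] - m$peak_cm))]
      }
    }
    bp <- anch$position_bp[match(pick, anch$marker)]
    hi <- bp + half_window
    if (!is.null(chrom_lengths_bp)) {
      len <- chrom_lengths_bp[as.character(m$chr)]
      if (!is.na(len)) hi <- min(hi, len)
    }
    rows[[length(rows) + 1L]] <- data.frame(
      mqtl_id = m$mqtl_id, chr = m$chr,
      start_bp = max(1, bp - half_window), end_bp = hi,
      anchor_marker = pick, anchor_bp = bp, stringsAsFactors = FALSE)
  }
  out <- if (length(rows) > 0) do.call(rbind, rows) else
    data.frame(mqtl_id = character(0), chr = integer(0),
               start_bp = numeric(0), end_bp = numeric(0),
               anchor_marker = character(0), anchor_bp = numeric(0))
  if (length(unanchored) > 0)
    warning(sprintf("%d MQTL(s) had no anchorable marker and were excluded: %s",
                    length(unanchored), paste(unanchored, collapse = ", ")))
  attr(out, "unanchored") <- unanchored
  out
}

#' Co-localize MQTL windows with GWAS associations
#'
#' An MTA supports a window iff it is on the same chromosome, its position
#' lies inside the window (both boundaries inclusive) and its
#' `-log10(p)` is at least `threshold` (inclusive). A window with at least
#' one supporting MTA is validated.
#'
#' @param windows Physical windows from [anchor_mqtls()].
#' @param mtas MTA table ([read_mta_table()]).
#' @param threshold Significance threshold on `-log10(p)`, default 5.0.
#' @return List: `hits` (`data.frame` of window/MTA pairs), `summary`
#'   (per-window `n_mtas` and `validated` flag), `validated_fraction`.
#' @export
colocalize <- function(windows, mtas, threshold = 5.0) {
  sig <- mtas[mtas$neg_log10_p >= threshold, , drop = FALSE]
  if (nrow(windows) > 0 && nrow(sig) > 0) {
    gw <- GenomicRanges::GRanges(
      seqnames = as.character(windows$chr),
      ranges = IRanges::IRanges(start = windows$start_bp,
                                end = windows$end_bp))
    gs <- GenomicRanges::GRanges(
      seqnames = as.character(sig$chr),
      ranges = IRanges::IRanges(start = sig$position_bp, width = 1L))
    ov <- GenomicRanges::findOverlaps(gw, gs)
    hits <- data.frame(
      mqtl_id = windows$mqtl_id[S4Vectors::queryHits(ov)],
      snp_id = sig$snp_id[S4Vectors::subjectHits(ov)],
      chr = sig$chr[S4Vectors::subjectHits(ov)],
      position_bp = sig$position_bp[S4Vectors::subjectHits(ov)],
      neg_log10_p = sig$neg_log10_p[S4Vectors::subjectHits(ov)],
      panel_id = sig$panel_id[S4Vectors::subjectHits(ov)],
      stringsAsFactors = FALSE)
  } else {
    hits <- data.frame(mqtl_id = character(0), snp_id = character(0),
                       chr = integer(0), position_bp = numeric(0),
                       neg_log10_p = numeric(0), panel_id = character(0))
  }
  n_mtas <- vapply(windows$mqtl_id,
                   function(id) sum(hits$mqtl_id == id), integer(1))
  summary <- data.frame(mqtl_id = windows$mqtl_id, chr = windows$chr,
                        n_mtas = unname(n_mtas),
                        validated = unname(n_mtas) >= 1L,
                        stringsAsFactors = FALSE)
  list(hits = hits, summary = summary,
       validated_fraction = if (nrow(summary) > 0)
         mean(summary$validated) else NA_real_)
}
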