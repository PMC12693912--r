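#' Read genetic maps from a TSV file
#'
#' @param path TSV with columns `map_id chr marker position_cM`.
#' @return `data.frame` with columns `map_id chr marker position_cm`,
#'   sorted by map, chromosome and position.
#' @export
read_genetic_maps <- function(path) {
  df <- read_tsv_checked(path, required = c("map_id", "chr", "marker",
                                            "position_cM"))
  out <- data.frame(map_id = as.character(df$map_id),
                    chr = as.integer(df$chr),
                    marker = as.character(df$marker),
                    position_cm = as.numeric(df$position_cM),
                    stringsAsFactors = FALSE)
  out <- out[order(out$map_id, out$chr, out$position_cm), ]
  rownames(out) <- NULL
  validate_genetic_maps(out)
  out
}

validate_genetic_maps <- function(maps) {
  dup <- duplicated(maps[, c("map_id", "marker")])
  if (any(dup))
    mq_value_error(sprintf("duplicated marker(s) within a map: %s",
                           paste(head(unique(maps$marker[dup]), 5),
                                 collapse = ", ")))
  if (any(!is.finite(maps$position_cm)))
    mq_value_error("non-finite map position")
  invisible(maps)
}

#' Write a consensus map
#'
#' @param consensus Consensus map from [merge_maps()].
#' @param path Output TSV path (columns `map_id chr marker position_cM
#'   n_maps`).
#' @return The path, invisibly.
#' @export
write_consensus_map <- function(consensus, path) {
  out <- data.frame(map_id = "consensus", chr = consensus$chr,
                    marker = consensus$marker,
                    position_cM = consensus$position_cm,
                    n_maps = consensus$n_maps)
  write_tsv(out, path)
}

#' Merge genetic maps into a consensus map
#'
#' Per chromosome, the map with the most markers is taken as the reference
#' frame. Every other map (in decreasing marker count) is rescaled onto the
#' accumulating consensus by a linear fit through shared markers, and each
#' marker's consensus position is the arithmetic mean of its rescaled
#' observations. Order conflicts are resolved by majority: within the
#' incoming map, the largest subset of shared markers whose rescaled
#' positions respect the consensus order is kept, and the conflicting
#' markers' incoming observations are dropped with a warning. A map sharing
#' fewer than two markers with the consensus on some chromosome is skipped
#' there with a warning.
#'
#' @param maps `data.frame` as from [read_genetic_maps()].
#' @return Consensus `data.frame` with columns
#'   `chr marker position_cm n_maps`, ordered by position within
#'   chromosome.
#' @export
merge_maps <- function(maps) {
  validate_genetic_maps(maps)
  if (nrow(maps) == 0) mq_value_error("no maps supplied")
  res <- list()
  for (ch in sort(unique(maps$chr))) {
    sub <- maps[maps$chr == ch, , drop = FALSE]
    counts <- sort(table(sub$map_id), decreasing = TRUE)
    ref_id <- names(counts)[1]
    ref <- sub[sub$map_id == ref_id, , drop = FALSE]
    cons <- data.frame(marker = ref$marker, pos = ref$position_cm,
                       n = 1L, stringsAsFactors = FALSE)
    for (mid in names(counts)[-1]) {
      inc <- sub[sub$map_id == mid, , drop = FALSE]
      shared <- intersect(cons$marker, inc$marker)
      if (length(shared) < 2) {
        warning(sprintf(
          "map '%s' shares <2 markers with the consensus on chr %d; skipped",
          mid, ch))
        next
      }
      cp <- cons$pos[match(shared, cons$marker)]
      ip <- inc$position_cm[match(shared, inc$marker)]
      # robust linear rescale (Theil-Sen) of the incoming map onto the
      # consensus frame: a discordant shared marker must not distort it
      fit <- theil_sen(ip, cp)
      inc$rescaled <- fit$icept + fit$slope * inc$position_cm
      # order-conflict resolution: keep the largest order-consistent subset
      ord <- order(cp)
      keep_idx <- lis_indices(ip[ord])
      conflicted <- shared[ord][-keep_idx]
      if (length(conflicted) > 0 && length(keep_idx) < length(shared))
        warning(sprintf(
          "map '%s' conflicts with consensus marker order on chr %d; dropped: %s",
          mid, ch, paste(conflicted, collapse = ", ")))
      use <- !(inc$marker %in% conflicted)
      inc <- inc[use, , drop = FALSE]
      old <- inc$marker %in% cons$marker
      j <- match(inc$marker[old], cons$marker)
      cons$pos[j] <- (cons$pos[j] * cons$n[j] + inc$rescaled[old]) /
        (cons$n[j] + 1L)
      cons$n[j] <- cons$n[j] + 1L
      if (any(!old))
        cons <- rbind(cons, data.frame(marker = inc$marker[!old],
                                       pos = inc$rescaled[!old], n = 1L))
    }
    cons <- cons[order(cons$pos), ]
    res[[as.character(ch)]] <- data.frame(chr = ch, marker = cons$marker,
                                          position_cm = cons$pos,
                                          n_maps = cons$n,
                                          stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

# affine transform of a position through the (L,R) -> (L2,R2) interval
project_point <- function(p, l, r, l2, r2) {
  if (r == l) return(l2)
  l2 + (p - l) * (r2 - l2) / (r - l)
}

#' Project QTLs onto a consensus map
#'
#' Each QTL's peak and CI bounds are mapped from its source map onto the
#' consensus by linear interpolation between the nearest shared markers
#' bracketing the peak; outside the shared-marker span the nearest
#' interval's transform is extended, up to `extrapolation_limit` cM beyond
#' the span, after which the QTL is excluded with a warning. The projected
#' positional standard deviation is `(ci_high - ci_low)/3.92` (two-sided
#' Gaussian 95% convention).
#'
#' @param qtls Standardized QTL table ([standardize_qtls()]); every row must
#'   have CI bounds.
#' @param maps Per-study maps ([read_genetic_maps()]); each QTL's `map_id`
#'   must be present.
#' @param consensus Consensus map from [merge_maps()].
#' @param extrapolation_limit Maximum distance (cM) a peak may lie outside
#'   the shared-marker span before the QTL is excluded.
#' @return `data.frame`: the input columns plus `position_cm`, `sd_cm` and
#'   projected `ci_low_cm`/`ci_high_cm`. Excluded QTLs are recorded in
#'   `attr(result, "failed")` (qtl_id + reason).
#' @export
project_qtls <- function(qtls, maps, consensus, extrapolation_limit = 5) {
  if (any(is.na(qtls$ci_low_cm) | is.na(qtls$ci_high_cm)))
    mq_value_error("QTLs must be standardized (CI bounds present) before projection")
  rows <- vector("list", nrow(qtls))
  failed <- list()
  for (i in seq_len(nrow(qtls))) {
    q <- qtls[i, ]
    src <- maps[maps$map_id == q$map_id & maps$chr == q$chr, , drop = FALSE]
    con <- consensus[consensus$chr == q$chr, , drop = FALSE]
    shared <- intersect(src$marker, con$marker)
    if (length(shared) < 2) {
      failed[[length(failed) + 1L]] <-
        data.frame(qtl_id = q$qtl_id, reason = "fewer than 2 shared markers")
      next
    }
    sp <- src$position_cm[match(shared, src$marker)]
    cp <- con$position_cm[match(shared, con$marker)]
    o <- order(sp); sp <- sp[o]; cp <- cp[o]
    pk <- q$peak_cm
    if (pk < sp[1] - extrapolation_limit ||
        pk > sp[length(sp)] + extrapolation_limit) {
      failed[[length(failed) + 1L]] <-
        data.frame(qtl_id = q$qtl_id,
                   reason = sprintf("peak %.2f cM beyond shared span by > %g cM",
                                    pk, extrapolation_limit))
      next
    }
    # bracketing interval; nearest interval when outside the span
    j <- findInterval(pk, sp)
    j <- min(max(j, 1L), length(sp) - 1L)
    l <- sp[j]; r <- sp[j + 1L]; l2 <- cp[j]; r2 <- cp[j + 1L]
    q$position_cm <- project_point(pk, l, r, l2, r2)
    lo <- project_point(q$ci_low_cm, l, r, l2, r2)
    hi <- project_point(q$ci_high_cm, l, r, l2, r2)
    q$ci_low_cm <- min(lo, hi)
    q$ci_high_cm <- max(lo, hi)
    q$sd_cm <- (q$ci_high_cm - q$ci_low_cm) / 3.92
    if (!is.finite(q$sd_cm) || q$sd_cm <= 0) {
      failed[[length(failed) + 1L]] <-
        data.frame(qtl_id = q$qtl_id, reason = "degenerate projected interval")
      next
    }
    rows[[i]] <- q
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out))
    out <- cbind(qtls[0, ], position_cm = numeric(0), sd_cm = numeric(0))
  rownames(out) <- NULL
  failed_df <- if (length(failed) > 0) do.call(rbind, failed) else
    data.frame(qtl_id = character(0), reason = character(0))
  if (nrow(failed_df) > 0)
    warning(sprintf("%d QTL(s) could not be projected and were excluded",
                    nrow(failed_df)))
  attr(out, "failed") <- failed_df
  out
}
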