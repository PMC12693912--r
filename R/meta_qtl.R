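#' Summarize one meta-QTL from its member QTLs
#'
#' Responsibility-weighted inverse-variance pooling: the MQTL peak is
#' `sum(r x / s^2) / sum(r / s^2)`, its variance `1 / sum(r / s^2)`, and
#' the 95% CI `peak +/- 1.96 sd`.
#'
#' @param positions Member peak positions (cM).
#' @param sds Member positional standard deviations (cM).
#' @param resp Member responsibilities (defaults to 1).
#' @return List with `peak_cm`, `sd_cm`, `ci_low_cm`, `ci_high_cm`,
#'   `n_members`.
#' @export
mqtl_summary <- function(positions, sds, resp = rep(1, length(positions))) {
  if (length(positions) < 1) mq_value_error("at least one member required")
  w <- resp / sds^2
  peak <- sum(w * positions) / sum(w)
  sd <- sqrt(1 / sum(w))
  list(peak_cm = peak, sd_cm = sd,
       ci_low_cm = peak - 1.96 * sd, ci_high_cm = peak + 1.96 * sd,
       n_members = length(positions))
}

#' Assign QTLs to mixture components
#'
#' A QTL joins a component iff its membership probability for that
#' component exceeds `threshold` (strictly) AND its peak lies within the
#' component's 95% CI (computed by [mqtl_summary()] over the component's
#' members). The peak-in-CI check is iterated to a fixpoint: members whose
#' peaks fall outside the pooled CI are removed and the CI re-pooled, so a
#' distant outlier cannot drag the consensus peak. Each QTL joins at most
#' one component; the rest are reported as unassigned, never dropped.
#'
#' @param fit A `mixture_fit`.
#' @param positions,sds The observations the fit was made on.
#' @param qtl_ids Identifiers, one per observation.
#' @param threshold Membership threshold (strict), default 0.60.
#' @return List: `assignments` (`data.frame` `qtl_id component membership`),
#'   `unassigned` (character vector of ids), `components` (per-component
#'   summary list from [mqtl_summary()], `NULL` for empty components).
#' @export
assign_members <- function(fit, positions, sds, qtl_ids,
                           threshold = 0.60) {
  r <- fit$responsibilities
  n <- length(positions)
  if (nrow(r) != n || length(qtl_ids) != n)
    mq_value_error("responsibilities, positions and ids must agree in length")
  best_k <- max.col(r, ties.method = "first")
  best_r <- r[cbind(seq_len(n), best_k)]
  provisional <- best_r > threshold
  comp_of <- ifelse(provisional, best_k, NA_integer_)
  components <- vector("list", fit$k)
  keep <- rep(FALSE, n)
  for (k in seq_len(fit$k)) {
    idx <- which(comp_of == k)
    # refine to a fixpoint: while some peak lies outside the pooled CI,
    # trim the farthest one and re-pool (one at a time, so an outlier is
    # removed before it can drag the consensus peak off every member)
    while (length(idx) > 0) {
      sm <- mqtl_summary(positions[idx], sds[idx], best_r[idx])
      dist <- abs(positions[idx] - sm$peak_cm)
      inside <- positions[idx] >= sm$ci_low_cm &
        positions[idx] <= sm$ci_high_cm
      if (all(inside)) break
      idx <- idx[-which.max(dist + ifelse(inside, -Inf, 0))]
    }
    if (length(idx) == 0) next
    keep[idx] <- TRUE
    components[[k]] <- mqtl_summary(positions[idx], sds[idx], best_r[idx])
    components[[k]]$member_idx <- idx
  }
  assignments <- data.frame(qtl_id = qtl_ids[keep],
                            component = comp_of[keep],
                            membership = best_r[keep],
                            stringsAsFactors = FALSE)
  list(assignments = assignments,
       unassigned = qtl_ids[!keep],
       components = components)
}

#' Meta-analyze one chromosome's projected QTLs
#'
#' Fits mixtures for a candidate range of component counts, applies
#' five-criterion majority selection, assigns members and summarizes the
#' resulting MQTLs. With `n <= 10` QTLs, candidate counts are
#' `1..min(4, n)` (small-sample regime); with `n > 10`,
#' `1..min(ceiling(n/2), kmax_cap)`.
#'
#' @param projected Projected QTLs for one chromosome ([project_qtls()]).
#' @param kmax_cap Cap on the candidate component count for large `n`.
#' @param threshold Membership threshold for [assign_members()].
#' @param n_starts,tol,seed Passed to [fit_mixture()].
#' @return List: `k` (selected count), `fit` (chosen `mixture_fit`),
#'   `criteria` (stacked criterion table with `chosen` flag), `mqtls`
#'   (`data.frame` `mqtl_id chr peak_cm ci_low_cm ci_high_cm sd_cm
#'   n_members member_ids`), `membership` (assignment table with
#'   `mqtl_id`), `unassigned` (ids). Empty input gives `NULL` components.
#' @export
run_chromosome <- function(projected, kmax_cap = 12, threshold = 0.60,
                           n_starts = 20, tol = 1e-8, seed = NULL) {
  n <- nrow(projected)
  if (n == 0)
    return(list(k = 0L, fit = NULL, criteria = NULL,
                mqtls = empty_mqtl_table(), membership = NULL,
                unassigned = character(0)))
  stopifnot(length(unique(projected$chr)) == 1)
  ch <- projected$chr[1]
  x <- projected$position_cm
  s <- projected$sd_cm
  ks <- if (n <= 10) seq_len(min(4L, n)) else
    seq_len(min(ceiling(n / 2), kmax_cap))
  fits <- lapply(ks, function(k)
    fit_mixture(x, s, k, n_starts = n_starts, tol = tol,
                seed = if (is.null(seed)) NULL else seed + k))
  criteria <- do.call(rbind, lapply(fits, information_criteria, n_obs = n))
  k_sel <- as.integer(select_model(criteria))
  criteria$chosen <- criteria$k == k_sel
  fit <- fits[[match(k_sel, ks)]]
  asg <- assign_members(fit, x, s, projected$qtl_id, threshold = threshold)
  comp <- asg$components
  occupied <- which(!vapply(comp, is.null, logical(1)))
  # rank by position along the chromosome for naming
  occupied <- occupied[order(vapply(comp[occupied], `[[`, numeric(1),
                                    "peak_cm"))]
  mqtls <- lapply(seq_along(occupied), function(i) {
    k <- occupied[i]
    sm <- comp[[k]]
    ids <- projected$qtl_id[sm$member_idx]
    data.frame(mqtl_id = sprintf("MQTL%d.%d", ch, i), chr = ch,
               peak_cm = sm$peak_cm, ci_low_cm = sm$ci_low_cm,
               ci_high_cm = sm$ci_high_cm, sd_cm = sm$sd_cm,
               n_members = sm$n_members,
               member_ids = paste(ids, collapse = ","),
               stringsAsFactors = FALSE)
  })
  mqtls <- if (length(mqtls) > 0) do.call(rbind, mqtls) else empty_mqtl_table()
  membership <- asg$assignments
  membership$mqtl_id <- NA_character_
  for (i in seq_along(occupied))
    membership$mqtl_id[membership$component == occupied[i]] <-
      sprintf("MQTL%d.%d", ch, i)
  membership <- membership[!is.na(membership$mqtl_id), , drop = FALSE]
  list(k = k_sel, fit = fit, criteria = cbind(chr = ch, criteria),
       mqtls = mqtls, membership = membership, unassigned = asg$unassigned)
}

empty_mqtl_table <- function() {
  data.frame(mqtl_id = character(0), chr = integer(0), peak_cm = numeric(0),
             ci_low_cm = numeric(0), ci_high_cm = numeric(0),
             sd_cm = numeric(0), n_members = integer(0),
             member_ids = character(0), stringsAsFactors = FALSE)
}

#' Meta-analyze all chromosomes
#'
#' Runs [run_chromosome()] per chromosome and stacks the results.
#'
#' @inheritParams run_chromosome
#' @param projected Projected QTL table (any number of chromosomes).
#' @param bin_width_cm Bin width for the per-chromosome overview index.
#' @return List: `mqtls`, `model_selection`, `membership`, `unassigned`,
#'   `overview` (stacked [overview_index()] tables), `per_chromosome`
#'   (raw results).
#' @export
run_meta_analysis <- function(projected, kmax_cap = 12, threshold = 0.60,
                              n_starts = 20, tol = 1e-8, seed = NULL,
                              bin_width_cm = 0.5) {
  chroms <- sort(unique(projected$chr))
  per <- lapply(chroms, function(ch) {
    sub <- projected[projected$chr == ch, , drop = FALSE]
    res <- run_chromosome(sub, kmax_cap = kmax_cap, threshold = threshold,
                          n_starts = n_starts, tol = tol,
                          seed = if (is.null(seed)) NULL else seed + 100L * ch)
    res$overview <- overview_index(sub, bin_width_cm = bin_width_cm)
    res
  })
  names(per) <- as.character(chroms)
  list(
    mqtls = do.call(rbind, c(lapply(per, `[[`, "mqtls"),
                             list(make.row.names = FALSE))),
    model_selection = do.call(rbind, c(lapply(per, `[[`, "criteria"),
                                       list(make.row.names = FALSE))),
    membership = do.call(rbind, c(lapply(per, `[[`, "membership"),
                                  list(make.row.names = FALSE))),
    unassigned = unlist(lapply(per, `[[`, "unassigned"), use.names = FALSE),
    overview = do.call(rbind, c(lapply(per, `[[`, "overview"),
                                list(make.row.names = FALSE))),
    per_chromosome = per)
}

#' QTL-overview index along a chromosome
#'
#' Tiles the chromosome span into `bin_width_cm` bins and accumulates each
#' QTL's Gaussian positional probability mass per bin, normalized by the
#' number of QTLs: the contribution of QTL `i` to bin `[a, b)` is
#' `pnorm((b - x_i)/s_i) - pnorm((a - x_i)/s_i)`, and the bin's index is
#' the mean contribution.
#'
#' @param projected Projected QTLs for one chromosome.
#' @param span `c(start, end)` of the chromosome in cM; default covers all
#'   member CIs from 0.
#' @param bin_width_cm Bin width in cM (default 0.5).
#' @return `data.frame` `chr start_cm end_cm index`.
#' @export
overview_index <- function(projected, span = NULL, bin_width_cm = 0.5) {
  if (bin_width_cm <= 0) mq_value_error("bin_width_cm must be > 0")
  if (nrow(projected) == 0) {
    span <- span %||% c(0, bin_width_cm)
  } else {
    span <- span %||% c(0, max(projected$ci_high_cm))
  }
  edges <- seq(span[1], span[2] + bin_width_cm * 0.999, by = bin_width_cm)
  if (edges[length(edges)] < span[2]) edges <- c(edges, span[2])
  starts <- edges[-length(edges)]
  ends <- edges[-1]
  idx <- numeric(length(starts))
  n <- nrow(projected)
  if (n > 0) {
    for (i in seq_len(n)) {
      x <- projected$position_cm[i]; s <- projected$sd_cm[i]
      idx <- idx + (pnorm((ends - x) / s) - pnorm((starts - x) / s))
    }
    idx <- idx / n
  }
  ch <- if (n > 0) projected$chr[1] else NA_integer_
  data.frame(chr = ch, start_cm = starts, end_cm = ends, index = idx)
}
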