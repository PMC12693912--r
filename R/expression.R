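#' FPKM from fragment counts
#'
#' `FPKM = 10^6 C / (N L / 10^3) = 10^9 C / (N L)`, where `C` is the
#' fragment count on the gene, `N` the number of mapped fragments and `L`
#' the gene length in bp.
#'
#' @param c_frags Fragment count(s), >= 0.
#' @param n_mapped Mapped-fragment total(s), > 0.
#' @param l_bp Gene length(s) in bp, > 0.
#' @return FPKM value(s).
#' @examples
#' compute_fpkm(100, 1e6, 1000)  # 100
#' @export
compute_fpkm <- function(c_frags, n_mapped, l_bp) {
  if (any(c_frags < 0)) mq_value_error("fragment count must be >= 0")
  if (any(n_mapped <= 0) || any(l_bp <= 0))
    mq_value_error("n_mapped and l_bp must be > 0")
  1e9 * c_frags / (n_mapped * l_bp)
}

#' Read per-gene DE statistics
#'
#' @param path TSV with columns `gene_id log2fc fdr contrast`.
#' @return `data.frame` with those columns.
#' @export
read_deg_stats <- function(path) {
  df <- read_tsv_checked(path, required = c("gene_id", "log2fc", "fdr"))
  out <- data.frame(gene_id = as.character(df$gene_id),
                    log2fc = as.numeric(df$log2fc),
                    fdr = as.numeric(df$fdr),
                    contrast = if ("contrast" %in% names(df))
                      as.character(df$contrast) else "contrast1",
                    stringsAsFactors = FALSE)
  if (any(out$fdr < 0 | out$fdr > 1, na.rm = TRUE))
    mq_value_error("fdr must lie in [0, 1]")
  out
}

#' Filter differentially expressed genes
#'
#' A gene passes in a contrast iff `|log2FC| >= lfc_min` (inclusive) and
#' `FDR < fdr_max` (strict); the union over contrasts is returned.
#'
#' @param stats DE statistics ([read_deg_stats()]).
#' @param lfc_min Absolute log2 fold-change threshold, default 1.
#' @param fdr_max FDR threshold (strict), default 0.05.
#' @return Character vector of unique passing gene ids.
#' @export
filter_degs <- function(stats, lfc_min = 1.0, fdr_max = 0.05) {
  keep <- abs(stats$log2fc) >= lfc_min & stats$fdr < fdr_max
  unique(stats$gene_id[keep & !is.na(keep)])
}

#' Read an expression time-course table
#'
#' @param path TSV with columns `gene_id genotype timepoint replicate fpkm`.
#' @return `data.frame` with those columns.
#' @export
read_expression_table <- function(path) {
  df <- read_tsv_checked(path, required = c("gene_id", "genotype",
                                            "timepoint", "replicate", "fpkm"))
  out <- data.frame(gene_id = as.character(df$gene_id),
                    genotype = as.character(df$genotype),
                    timepoint = as.numeric(df$timepoint),
                    replicate = as.integer(df$replicate),
                    fpkm = as.numeric(df$fpkm), stringsAsFactors = FALSE)
  if (any(out$fpkm < 0)) mq_value_error("fpkm must be >= 0")
  out
}

#' Replicate-averaged genotype x timepoint expression profiles
#'
#' @param expr Long expression table ([read_expression_table()]).
#' @param genotypes Genotype order for the concatenated profile.
#' @return Matrix genes x (genotype, timepoint) of mean FPKM, with column
#'   names `<genotype>_t<timepoint>`; attribute `"layout"` records
#'   genotype and timepoint per column.
#' @export
expression_profiles <- function(expr,
                                genotypes = c("mutant", "wildtype")) {
  tps <- sort(unique(expr$timepoint))
  cols <- expand.grid(timepoint = tps, genotype = genotypes,
                      stringsAsFactors = FALSE)[, c("genotype", "timepoint")]
  agg <- stats::aggregate(fpkm ~ gene_id + genotype + timepoint, data = expr,
                          FUN = mean)
  genes <- sort(unique(agg$gene_id))
  m <- matrix(NA_real_, length(genes), nrow(cols),
              dimnames = list(genes, sprintf("%s_t%g", cols$genotype,
                                             cols$timepoint)))
  for (j in seq_len(nrow(cols))) {
    sub <- agg[agg$genotype == cols$genotype[j] &
                 agg$timepoint == cols$timepoint[j], ]
    m[match(sub$gene_id, genes), j] <- sub$fpkm
  }
  attr(m, "layout") <- cols
  m
}

#' Standardize expression profiles
#'
#' Centers and scales each gene's profile to zero mean, unit variance
#' (the Mfuzz convention). Genes with zero variance are removed.
#'
#' @param profiles Genes x conditions matrix.
#' @return Standardized matrix (zero-variance rows dropped; ids in
#'   `attr(, "dropped")`).
#' @export
standardize_profiles <- function(profiles) {
  sds <- apply(profiles, 1L, stats::sd)
  dropped <- rownames(profiles)[sds == 0 | !is.finite(sds)]
  keep <- profiles[!(rownames(profiles) %in% dropped), , drop = FALSE]
  out <- t(scale(t(keep)))
  attr(out, "dropped") <- dropped
  attr(out, "layout") <- attr(profiles, "layout")
  out
}

#' Fuzzy c-means clustering of expression profiles
#'
#' Classic fuzzy c-means (Bezdek): memberships
#' `u_ij = 1 / sum_l (d_ij/d_il)^(2/(m-1))`, centers
#' `v_j = sum_i u_ij^m x_i / sum_i u_ij^m`, iterated until the maximum
#' membership change falls below `tol`. A profile coinciding with a center
#' receives membership 1 for it (singular-distance convention). Profiles
#' are expected to be standardized ([standardize_profiles()]).
#'
#' @param profiles Genes x conditions numeric matrix with row names.
#' @param c Number of clusters (default 9).
#' @param m Fuzzifier > 1 (default 2).
#' @param tol Convergence tolerance on memberships.
#' @param max_iter Iteration cap.
#' @param init `"kmeans"` (default) seeds the centers with a k-means
#'   pass, which is robust for well-separated temporal shapes; `"random"`
#'   starts from random memberships.
#' @param seed Optional seed for the initialization.
#' @return Object of class `fuzzy_cmeans`: list with `c`, `m`, `centers`
#'   (c x conditions), `memberships` (genes x c, rows summing to 1),
#'   `objective` (per-iteration values, non-increasing), `n_iter`.
#' @export
fuzzy_cmeans <- function(profiles, c = 9, m = 2.0, tol = 1e-6,
                         max_iter = 500, init = c("kmeans", "random"),
                         seed = NULL) {
  x <- as.matrix(profiles)
  n <- nrow(x)
  init <- match.arg(init)
  if (c < 1) mq_value_error("c must be >= 1")
  if (c > n) mq_value_error("more clusters than profiles")
  if (m <= 1) mq_value_error("fuzzifier m must be > 1")
  if (!is.null(seed)) set.seed(seed)
  if (init == "kmeans" && c > 1 && n > c) {
    km <- suppressWarnings(stats::kmeans(x, centers = c, nstart = 10))
    u <- matrix(1e-6, n, c)
    u[cbind(seq_len(n), km$cluster)] <- 1
    u <- u / rowSums(u)
  } else {
    u <- matrix(runif(n * c), n, c)
    u <- u / rowSums(u)
  }
  obj <- numeric(0)
  expo <- 2 / (m - 1)
  for (it in seq_len(max_iter)) {
    um <- u^m
    centers <- (t(um) %*% x) / colSums(um)
    d2 <- outer(rowSums(x^2), rep(1, c)) - 2 * x %*% t(centers) +
      outer(rep(1, n), rowSums(centers^2))
    d2 <- pmax(d2, 0)
    obj <- c(obj, sum(um * d2))
    singular <- d2 < 1e-12
    u_new <- matrix(0, n, c)
    any_sing <- rowSums(singular) > 0
    if (any(any_sing))
      u_new[any_sing, ] <- singular[any_sing, , drop = FALSE] /
        rowSums(singular[any_sing, , drop = FALSE])
    if (any(!any_sing)) {
      dm <- d2[!any_sing, , drop = FALSE]^(expo / 2)
      u_new[!any_sing, ] <- (1 / dm) / rowSums(1 / dm)
    }
    delta <- max(abs(u_new - u))
    u <- u_new
    if (delta < tol) break
  }
  um <- u^m
  centers <- (t(um) %*% x) / colSums(um)
  dimnames(u) <- list(rownames(x), sprintf("cluster%d", seq_len(c)))
  rownames(centers) <- sprintf("cluster%d", seq_len(c))
  structure(list(c = c, m = m, centers = centers, memberships = u,
                 objective = obj, n_iter = it),
            class = "fuzzy_cmeans")
}

#' Hard cluster assignment from fuzzy memberships
#'
#' @param result A `fuzzy_cmeans` object.
#' @param membership_min Minimum max-membership for a gene to be assigned.
#' @return Named integer vector (cluster per gene); unassigned genes get
#'   `NA`.
#' @export
cluster_assignments <- function(result, membership_min = 0.5) {
  u <- result$memberships
  best <- max.col(u, ties.method = "first")
  val <- u[cbind(seq_len(nrow(u)), best)]
  out <- ifelse(val >= membership_min, best, NA_integer_)
  names(out) <- rownames(u)
  out
}

#' Select the mutant-up / wild-type-down signature cluster
#'
#' For each cluster, genes assigned by maximum membership (at least
#' `membership_min`) define per-genotype mean temporal profiles; the
#' least-squares slope over the timepoints is computed per genotype. The
#' selected cluster maximizes (mutant slope - wildtype slope) subject to
#' mutant slope > 0 and wildtype slope < 0 — the mutant-specific
#' drought-induced signature. If no cluster satisfies the sign
#' constraints, an empty result is returned with a warning.
#'
#' @param result A `fuzzy_cmeans` object fitted on concatenated
#'   genotype x timepoint profiles.
#' @param profiles The (standardized) profile matrix the fit used; its
#'   `"layout"` attribute identifies genotype/timepoint per column.
#' @param genotypes `c(mutant, wildtype)` genotype labels.
#' @param membership_min Assignment threshold (default 0.5).
#' @return List: `cluster` (integer or `NA`), `genes` (character),
#'   `slopes` (`data.frame` cluster x genotype slopes).
#' @export
select_signature_cluster <- function(result, profiles,
                                     genotypes = c("mutant", "wildtype"),
                                     membership_min = 0.5) {
  layout <- attr(profiles, "layout")
  if (is.null(layout))
    mq_value_error("profiles must carry a 'layout' attribute (see expression_profiles)")
  asg <- cluster_assignments(result, membership_min)
  slopes <- data.frame(cluster = seq_len(result$c),
                       mutant_slope = NA_real_, wildtype_slope = NA_real_,
                       n_genes = 0L)
  for (k in seq_len(result$c)) {
    genes <- names(asg)[!is.na(asg) & asg == k]
    slopes$n_genes[k] <- length(genes)
    if (length(genes) == 0) next
    for (g in seq_along(genotypes)) {
      cols <- which(layout$genotype == genotypes[g])
      prof <- colMeans(profiles[genes, cols, drop = FALSE])
      sl <- ls_slope(layout$timepoint[cols], prof)
      if (g == 1) slopes$mutant_slope[k] <- sl else
        slopes$wildtype_slope[k] <- sl
    }
  }
  ok <- which(slopes$mutant_slope > 0 & slopes$wildtype_slope < 0 &
                slopes$n_genes > 0)
  if (length(ok) == 0) {
    warning("no cluster shows the mutant-up/wildtype-down signature")
    return(list(cluster = NA_integer_, genes = character(0), slopes = slopes))
  }
  sep <- slopes$mutant_slope[ok] - slopes$wildtype_slope[ok]
  k <- ok[which.max(sep)]
  list(cluster = k, genes = names(asg)[!is.na(asg) & asg == k],
       slopes = slopes)
}
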