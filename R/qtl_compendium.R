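#' Population-class to CI-formula mapping
#'
#' The width of a QTL's 95% confidence interval shrinks with population size
#' N and the phenotypic variance explained R^2, with a proportionality that
#' depends on the population structure. Three formulas are used:
#' `530/(N R^2)` for early-generation crosses, `163/(N R^2)` for inbred-line
#' populations and `97.462/(N R^2)^0.835` for doubled haploids. This mapping
#' assigns each population type to one of the three; pass a modified copy to
#' [estimate_ci_width()] to remap.
#'
#' @return Named character vector mapping population types (`F2`, `F2:3`,
#'   `BC`, `BIL`, `RIL`, `DH`) to formula classes (`"f2"`, `"ril"`, `"dh"`).
#' @export
ci_formula_map <- function() {
  c(F2 = "f2", `F2:3` = "f2", BC = "f2",
    RIL = "ril", BIL = "ril",
    DH = "dh")
}

#' Population-specific 95% confidence-interval width
#'
#' Computes the expected 95% CI width (in cM) of a QTL from the mapping
#' population's size and the fraction of phenotypic variance the QTL
#' explains:
#' \deqn{CI = 530/(N R^2) \quad \textrm{(F2, F2:3, BC)}}
#' \deqn{CI = 163/(N R^2) \quad \textrm{(RIL, BIL)}}
#' \deqn{CI = 97.462/(N R^2)^{0.835} \quad \textrm{(DH)}}
#'
#' @param population_type Character vector of population types; must be
#'   names of `mapping`.
#' @param n Population size(s), integer >= 2.
#' @param r2 Phenotypic variance explained as a fraction in (0, 1].
#' @param mapping Population-to-formula mapping, see [ci_formula_map()].
#' @return Numeric vector of CI widths in cM.
#' @examples
#' estimate_ci_width("F2", 530, 1.0)   # 1 cM
#' estimate_ci_width("DH", 100, 0.1)   # 97.462 / 10^0.835
#' @export
estimate_ci_width <- function(population_type, n, r2,
                              mapping = ci_formula_map()) {
  if (any(!population_type %in% names(mapping)))
    mq_value_error(sprintf(
      "unknown population type(s): %s",
      paste(unique(setdiff(population_type, names(mapping))), collapse = ", ")))
  if (any(!is.finite(n)) || any(n < 2))
    mq_value_error("population size n must be finite and >= 2")
  if (any(!is.finite(r2)) || any(r2 <= 0) || any(r2 > 1))
    mq_value_error("r2 must lie in (0, 1]")
  nr2 <- n * r2
  if (any(nr2 == 0)) mq_value_error("n * r2 must be positive")
  cls <- unname(mapping[population_type])
  out <- numeric(length(cls))
  out[cls == "f2"]  <- 530 / nr2[cls == "f2"]
  out[cls == "ril"] <- 163 / nr2[cls == "ril"]
  out[cls == "dh"]  <- 97.462 / nr2[cls == "dh"]^0.835
  out
}

qtl_table_columns <- c(
  "qtl_id", "study_id", "trait", "chr", "peak_cm", "ci_low_cm", "ci_high_cm",
  "lod", "pve", "pop_type", "pop_size", "marker_left", "marker_right",
  "map_id", "condition")

validate_qtl_table <- function(df) {
  bad_chr <- which(!is.finite(df$chr) | df$chr < 1 | df$chr > 12 |
                     df$chr != round(df$chr))
  if (length(bad_chr) > 0)
    mq_value_error(sprintf("chromosome outside 1-12 at row(s) %s",
                           paste(head(bad_chr, 5), collapse = ", ")))
  bad_pve <- which(!is.finite(df$pve) | df$pve <= 0 | df$pve > 1)
  if (length(bad_pve) > 0)
    mq_value_error(sprintf("pve outside (0,1] at row(s) %s",
                           paste(head(bad_pve, 5), collapse = ", ")))
  bad_lod <- which(!is.na(df$lod) & df$lod < 0)
  if (length(bad_lod) > 0)
    mq_value_error(sprintf("negative lod at row(s) %s",
                           paste(head(bad_lod, 5), collapse = ", ")))
  bad_n <- which(!is.finite(df$pop_size) | df$pop_size < 2)
  if (length(bad_n) > 0)
    mq_value_error(sprintf("population size < 2 at row(s) %s",
                           paste(head(bad_n, 5), collapse = ", ")))
  has_ci <- !is.na(df$ci_low_cm) & !is.na(df$ci_high_cm)
  bad_ci <- which(has_ci & !(df$ci_low_cm <= df$peak_cm &
                               df$peak_cm <= df$ci_high_cm))
  if (length(bad_ci) > 0)
    mq_value_error(sprintf("peak outside reported CI at row(s) %s",
                           paste(head(bad_ci, 5), collapse = ", ")))
  invisible(df)
}

#' Read a QTL compendium table
#'
#' Reads a UTF-8 TSV with one published QTL per row. Rows whose `condition`
#' column is present and differs from `"drought"` (loci detected under
#' well-watered controls) are dropped. Records are returned sorted by
#' chromosome, then peak position.
#'
#' @param path Path to the TSV file. Expected columns: `qtl_id study_id
#'   trait chr peak_cM ci_low_cM ci_high_cM lod pve pop_type pop_size
#'   marker_left marker_right map_id condition`; missing optional values are
#'   empty strings.
#' @param dialect Optional list adapting other layouts: `columns`, a named
#'   character vector mapping canonical names (lower-case, e.g. `peak_cm`)
#'   to the file's column names; `pve_percent`, logical, `TRUE` when the
#'   `pve` column is expressed in percent (divided by 100 on read);
#'   `keep_condition`, character, the condition value retained (default
#'   `"drought"`).
#' @return `data.frame` with canonical columns (`peak_cm` etc. in cM,
#'   `pve` as a fraction).
#' @export
read_qtl_table <- function(path, dialect = list()) {
  file_cols <- c(qtl_id = "qtl_id", study_id = "study_id", trait = "trait",
                 chr = "chr", peak_cm = "peak_cM", ci_low_cm = "ci_low_cM",
                 ci_high_cm = "ci_high_cM", lod = "lod", pve = "pve",
                 pop_type = "pop_type", pop_size = "pop_size",
                 marker_left = "marker_left", marker_right = "marker_right",
                 map_id = "map_id", condition = "condition")
  if (!is.null(dialect$columns))
    file_cols[names(dialect$columns)] <- dialect$columns
  required <- file_cols[c("qtl_id", "study_id", "trait", "chr", "peak_cm",
                          "pve", "pop_type", "pop_size")]
  raw <- read_tsv_checked(path, required = unname(required))
  df <- data.frame(row.names = NULL, stringsAsFactors = FALSE,
                   matrix(nrow = nrow(raw), ncol = 0))
  for (canon in names(file_cols)) {
    col <- file_cols[[canon]]
    df[[canon]] <- if (col %in% names(raw)) raw[[col]] else NA
  }
  num_cols <- c("chr", "peak_cm", "ci_low_cm", "ci_high_cm", "lod", "pve",
                "pop_size")
  pct <- isTRUE(dialect$pve_percent)
  for (cc in num_cols) {
    v <- df[[cc]]
    if (is.character(v)) v <- suppressWarnings(as.numeric(sub("%$", "", v)))
    df[[cc]] <- as.numeric(v)
  }
  if (pct) df$pve <- df$pve / 100
  keep_cond <- dialect$keep_condition %||% "drought"
  if (!all(is.na(df$condition)))
    df <- df[is.na(df$condition) | df$condition == keep_cond, , drop = FALSE]
  df$condition <- keep_cond
  validate_qtl_table(df)
  df <- df[order(df$chr, df$peak_cm), , drop = FALSE]
  rownames(df) <- NULL
  df[, qtl_table_columns]
}

#' Write a QTL compendium table
#'
#' Inverse of [read_qtl_table()] for the canonical dialect; missing optional
#' values are written as empty strings.
#'
#' @param qtls QTL `data.frame` with canonical columns.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_qtl_table <- function(qtls, path) {
  out <- qtls[, qtl_table_columns]
  names(out) <- c("qtl_id", "study_id", "trait", "chr", "peak_cM",
                  "ci_low_cM", "ci_high_cM", "lod", "pve", "pop_type",
                  "pop_size", "marker_left", "marker_right", "map_id",
                  "condition")
  write_tsv(out, path)
}

#' Standardize QTL confidence intervals
#'
#' Fills in missing (or, optionally, all) 95% CI bounds using the
#' population-specific width from [estimate_ci_width()], placed
#' symmetrically about the peak.
#'
#' @param qtls QTL `data.frame` from [read_qtl_table()].
#' @param policy `"prefer_reported"` keeps reported bounds when both are
#'   present and fills the rest by formula; `"always_formula"` recomputes
#'   every interval.
#' @param mapping Population-to-formula mapping, see [ci_formula_map()].
#' @return The table with `ci_low_cm`/`ci_high_cm` filled for every row.
#' @export
standardize_qtls <- function(qtls,
                             policy = c("prefer_reported", "always_formula"),
                             mapping = ci_formula_map()) {
  policy <- match.arg(policy)
  validate_qtl_table(qtls)
  width <- estimate_ci_width(qtls$pop_type, qtls$pop_size, qtls$pve,
                             mapping = mapping)
  recompute <- if (policy == "always_formula") {
    rep(TRUE, nrow(qtls))
  } else {
    is.na(qtls$ci_low_cm) | is.na(qtls$ci_high_cm)
  }
  qtls$ci_low_cm[recompute]  <- qtls$peak_cm[recompute] - width[recompute] / 2
  qtls$ci_high_cm[recompute] <- qtls$peak_cm[recompute] + width[recompute] / 2
  qtls
}
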