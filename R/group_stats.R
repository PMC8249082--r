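star_label <- function(p) {
  if (is.na(p)) "" else if (p < 0.001) "**" else if (p < 0.05) "*" else ""
}

#' Two-sided Mann-Whitney-Wilcoxon rank-sum test
#'
#' Compares two pooled ssGPDC samples.  The exact null distribution is
#' enumerated when the smaller sample has at most 8 values and there are
#' no ties; otherwise the normal approximation with midranks and the
#' variance tie correction is used.  Star annotation follows the
#' profile-figure convention: `"*"` for p < 0.05 and `"**"` for
#' p < 0.001.
#'
#' @param sample_a,sample_b Numeric vectors.
#' @param label_a,label_b Group labels for reporting.
#' @param unit Optional description of the compared unit (interaction /
#'   band).
#' @return Object of class `comparison_result`: `unit`, `group_a`,
#'   `group_b`, `n_a`, `n_b`, `u_statistic`, `p_value`, `stars`,
#'   `testable`, `exact`.  An empty sample yields `testable = FALSE`
#'   with `NA` statistics (mirroring interactions with too few ssGPDC
#'   values to compare).
#' @export
mann_whitney <- function(sample_a, sample_b, label_a = "A", label_b = "B",
                         unit = NULL) {
  sample_a <- as.numeric(sample_a); sample_b <- as.numeric(sample_b)
  na <- length(sample_a); nb <- length(sample_b)
  if (na == 0 || nb == 0)
    return(structure(list(unit = unit, group_a = label_a, group_b = label_b,
                          n_a = na, n_b = nb, u_statistic = NA_real_,
                          p_value = NA_real_, stars = "", testable = FALSE,
                          exact = NA),
                     class = "comparison_result"))
  ties <- anyDuplicated(c(sample_a, sample_b)) > 0
  use_exact <- min(na, nb) <= 8 && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(sample_a, sample_b, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  structure(list(unit = unit, group_a = label_a, group_b = label_b,
                 n_a = na, n_b = nb,
                 u_statistic = unname(wt$statistic),
                 p_value = unname(wt$p.value),
                 stars = star_label(wt$p.value), testable = TRUE,
                 exact = use_exact),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  if (!x$testable) {
    cat(sprintf("<comparison> %s vs %s: not testable (n = %d, %d)\n",
                x$group_a, x$group_b, x$n_a, x$n_b))
  } else {
    cat(sprintf("<comparison> %s (n=%d) vs %s (n=%d): U = %g, p = %.4g %s\n",
                x$group_a, x$n_a, x$group_b, x$n_b, x$u_statistic,
                x$p_value, x$stars))
  }
  invisible(x)
}

#' Per-band group comparison for one interaction
#'
#' Runs one two-sided rank-sum test per retained band on the pooled
#' ssGPDC values of the two groups.  No multiplicity correction is
#' applied (per-band reporting convention); [stats::p.adjust()] can be
#' applied to the returned column when a corrected view is wanted.
#'
#' @param cs_a,cs_b `connectivity_set`s for the two groups (e.g. WT and
#'   KO recordings).  Lists of connectivity sets are pooled per group.
#' @param from_organ,to_organ Ordered organ pair.
#' @param bands A [define_bands()] grid.
#' @param label_a,label_b Group labels.
#' @return Data frame with one row per retained band: `low`, `high`,
#'   `n_a`, `n_b`, `median_a`, `median_b`, `u_statistic`, `p_value`,
#'   `stars`, `testable`.
#' @export
compare_groups_per_band <- function(cs_a, cs_b, from_organ, to_organ,
                                    bands = define_bands(),
                                    label_a = "A", label_b = "B") {
  pool_group <- function(cs, lo, hi) {
    if (inherits(cs, "connectivity_set")) cs <- list(cs)
    unlist(lapply(cs, function(s)
      as.numeric(pool_organ_pair(s, from_organ, to_organ, band = c(lo, hi)))))
  }
  rows <- list()
  for (b in seq_len(nrow(bands))) {
    if (bands$excluded[b]) next
    va <- pool_group(cs_a, bands$low[b], bands$high[b])
    vb <- pool_group(cs_b, bands$low[b], bands$high[b])
    cr <- mann_whitney(va, vb, label_a, label_b)
    rows[[length(rows) + 1L]] <- data.frame(
      from = toupper(from_organ), to = toupper(to_organ),
      low = bands$low[b], high = bands$high[b],
      n_a = cr$n_a, n_b = cr$n_b,
      median_a = if (cr$n_a > 0) stats::median(va) else NA_real_,
      median_b = if (cr$n_b > 0) stats::median(vb) else NA_real_,
      u_statistic = cr$u_statistic, p_value = cr$p_value,
      stars = cr$stars, testable = cr$testable)
  }
  do.call(rbind, rows)
}

#' Pairwise comparison of interaction strengths within one group
#'
#' Rank-sum tests between the full-spectrum ssGPDC pools of every
#' unordered pair of the six inter-organ interactions.
#'
#' @param cs A `connectivity_set` (or list thereof) for one group.
#' @param bands A [define_bands()] grid (for harmonic exclusion).
#' @return 6 x 6 symmetric matrix of p-values (diagonal `NA`;
#'   untestable pairs `NA`), row/column names `FROM->TO`.
#' @export
compare_interaction_pairs <- function(cs, bands = define_bands()) {
  if (inherits(cs, "connectivity_set")) cs <- list(cs)
  prs <- organ_pairs()
  pools <- lapply(seq_len(nrow(prs)), function(q)
    unlist(lapply(cs, function(s)
      fullband_average(s, prs[q, "from"], prs[q, "to"], bands)$values)))
  names(pools) <- rownames(prs)
  m <- matrix(NA_real_, 6, 6, dimnames = list(rownames(prs), rownames(prs)))
  for (a in 1:5) for (b in (a + 1):6) {
    cr <- mann_whitney(pools[[a]], pools[[b]],
                       rownames(prs)[a], rownames(prs)[b])
    m[a, b] <- m[b, a] <- cr$p_value
  }
  m
}

#' Most discriminative frequency band for one interaction
#'
#' Selects, from a per-band comparison table, the retained band with the
#' minimum rank-sum p-value (the band at which the two groups' ssGPDC
#' profiles differ most); ties break toward the lower-frequency band.
#'
#' @param comparisons Output of [compare_groups_per_band()].
#' @return The selected row (single-row data frame).
#' @export
select_discriminative_band <- function(comparisons) {
  ok <- comparisons[comparisons$testable & !is.na(comparisons$p_value), ,
                    drop = FALSE]
  if (nrow(ok) == 0) stop("no testable band")
  pm <- min(ok$p_value)
  cand <- ok[ok$p_value == pm, , drop = FALSE]
  cand[which.min(cand$low), , drop = FALSE]
}
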