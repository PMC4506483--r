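# Developmental-induction statistics: exterior-splice assignment, depth
# normalization, age-weighted z scores, JRPKM, two-timepoint binomial CI
# comparisons, and the tissue-outlier residual analysis.

#' Assign linear junctions to the exterior category
#'
#' Linear expression of a gene must be quantified independently of its
#' circles, so only linear splice junctions outside the genomic boundaries of
#' the gene's expressed circles are used. A linear junction is exterior to a
#' circle when at least one of its two splice sites lies outside the circle's
#' genomic span; junctions with both splice sites interior to any circle
#' expressed at `k_min` or more counts are excluded. For genes with multiple
#' qualifying circles the exterior set is the intersection over circles.
#'
#' @param linear_junctions Tibble with `junction_id`, `gene_id`, `pos5`,
#'   `pos3` (the two splice-site genomic positions).
#' @param circles Tibble with `gene_id`, `lo`, `hi` (circle genomic span) and
#'   `count`.
#' @param k_min Minimum circle read count to define a boundary (default 10;
#'   use 0 for shallow libraries).
#' @return The exterior subset of `linear_junctions`.
#' @export
assign_exterior <- function(linear_junctions, circles, k_min = 10) {
  qual <- dplyr::filter(circles, .data$count >= k_min)
  if (nrow(qual) == 0) return(linear_junctions)
  interior <- linear_junctions |>
    dplyr::inner_join(qual, by = "gene_id", relationship = "many-to-many") |>
    dplyr::filter(.data$pos5 >= .data$lo, .data$pos5 <= .data$hi,
                  .data$pos3 >= .data$lo, .data$pos3 <= .data$hi) |>
    dplyr::distinct(.data$junction_id)
  dplyr::anti_join(linear_junctions, interior, by = "junction_id")
}

#' Per-sample junctional depth normalization constants
#'
#' Each sample's constant is the median count among all junctions exceeding
#' five counts in that sample, under the simplifying assumption that summed
#' over all genes junctional expression is comparable across samples
#' (conceptually similar to RPKM normalization).
#'
#' @param counts A long tibble with `junction_id`, `sample_id`, `count`.
#' @return A tibble with `sample_id` and `c` (the normalization constant).
#' @export
normalization_constants <- function(counts) {
  out <- counts |>
    dplyr::group_by(.data$sample_id) |>
    dplyr::summarise(c = median(.data$count[.data$count > 5]), .groups = "drop")
  bad <- out$sample_id[is.na(out$c)]
  abort_if(length(bad) > 0,
           paste0("no junction exceeds five counts in sample ", bad[1]))
  out
}

#' Age-weighted induction z score for one junction
#'
#' Tests whether a junction's depth-normalized counts `x_i = r_i / c_i`
#' change consistently with sample age. The contrast vector `o` is
#' proportional to the ages, centered to sum zero and scaled to unit
#' Euclidean norm. Under a Poisson model `var(x_i)` is estimated by
#' `x_i / c_i`, so the age contrast `sum(o * (x - mean(x)))` has variance
#' `sum(o^2 * x / c)`, and
#' `z = sum(o * (x - mean(x))) / sqrt(sum(o^2 * x / c))` is approximately
#' standard normal when counts are exchangeable across samples; it is
#' maximized when counts increase linearly with age. (Dropping the `o^2`
#' weighting from the variance, as a unit-norm shortcut would, deflates the
#' z scores by roughly the square root of the sample count; the weighted
#' form is the one that calibrates to N(0,1).)
#'
#' @param r Raw counts across samples.
#' @param c Per-sample normalization constants (same order).
#' @param ages Sample ages (e.g. gestational weeks).
#' @return The z score, or `NA` when all counts are zero.
#' @export
induction_zscore <- function(r, c, ages) {
  abort_if(length(r) < 3, "need at least three samples")
  abort_if(length(r) != length(c) || length(r) != length(ages),
           "counts, constants and ages must have equal length")
  o <- ages - mean(ages)
  nrm <- sqrt(sum(o^2))
  abort_if(nrm == 0, "ages are constant: the age contrast is undefined")
  o <- o / nrm
  x <- r / c
  v <- sum(o^2 * x / c)
  if (v <= 0) return(NA_real_)
  sum(o * (x - mean(x))) / sqrt(v)
}

#' Induction z scores for a junction count table
#'
#' Applies [induction_zscore()] to every junction of a long count table,
#' deriving normalization constants with [normalization_constants()].
#'
#' @param counts Long tibble with `junction_id`, `sample_id`, `count`.
#' @param samples Sample sheet with `sample_id` and `age_weeks`.
#' @return A tibble with `junction_id` and `z`.
#' @export
induction_zscores <- function(counts, samples) {
  cc <- normalization_constants(counts)
  counts |>
    dplyr::inner_join(cc, by = "sample_id") |>
    dplyr::inner_join(samples[, c("sample_id", "age_weeks")], by = "sample_id") |>
    dplyr::group_by(.data$junction_id) |>
    dplyr::summarise(z = induction_zscore(.data$count, .data$c, .data$age_weeks),
                     .groups = "drop")
}

#' Junctional reads per kilobase of junction window per million mapped reads
#'
#' JRPKM expresses a junction count on an RPKM-like scale. With 100-nt reads
#' and a 10-nt minimum boundary overlap, a junction can be hit by reads
#' starting in a window of `2 * (read_len - min_overlap)` = 180 nt, so the
#' count is divided by `total_linear_mapped / ((180 / 1000) * 1e6)`.
#'
#' @param count Junction read count(s).
#' @param total_linear_mapped Total reads mapped to linear junctions in the
#'   sample.
#' @param read_len Read length (default 100).
#' @param min_overlap Minimum boundary overlap (default 10).
#' @return JRPKM value(s).
#' @export
jrpkm <- function(count, total_linear_mapped, read_len = 100, min_overlap = 10) {
  abort_if(any(total_linear_mapped <= 0), "total mapped reads must be positive")
  window <- 2 * (read_len - min_overlap)
  count / (total_linear_mapped / ((window / 1000) * 1e6))
}

#' Compare a gene's circle fraction between two timepoints
#'
#' For each sample the circle fraction `p = n_c / (n_c + n_l)` (circular
#' count over circular plus maximum exterior linear count) gets a 95%
#' binomial confidence interval; because both counts share the sample's
#' depth, the fraction intrinsically normalizes for sequencing depth. If the
#' early and late intervals do not overlap, the gene is called as an
#' increase or decrease in circular proportion.
#'
#' @param early,late Length-2 vectors `c(n_c, n_l)`.
#' @param level Confidence level (default 0.95).
#' @param method `"wilson"` (default) or `"clopper-pearson"`.
#' @return `"increase"`, `"decrease"`, or `"none"`.
#' @export
two_timepoint_test <- function(early, late, level = 0.95,
                               method = c("wilson", "clopper-pearson")) {
  method <- match.arg(method)
  ne <- sum(early); nl <- sum(late)
  if (ne == 0 || nl == 0) return("none")
  ci_e <- binom_ci(early[1], ne, level, method)
  ci_l <- binom_ci(late[1], nl, level, method)
  if (ci_e["upper"] < ci_l["lower"]) return("increase")
  if (ci_l["upper"] < ci_e["lower"]) return("decrease")
  "none"
}

#' Tissue-outlier analysis of circle fractions
#'
#' For each gene, tests whether individual samples express a circle out of
#' proportion to the gene's linear expression. Per sample, the circle
#' fraction `p = n_c / n` (with `n = n_c + n_l`) is compared with (a) the
#' pooled MLE (`z_n`, binomial standardization) and (b) an ordinary
#' least-squares prediction of `p` from depth-normalized linear counts
#' (`z_o`, the reported statistic). To absorb Poisson overdispersion, every
#' `z_o` is divided by the median across genes of the per-gene standard
#' deviation of `z_o`; the corrected statistic is referred to a t
#' distribution with `n_samples - 2` degrees of freedom, and outliers are
#' flagged at a BH FDR of 0.001.
#'
#' @param tbl Tibble with `gene_id`, `sample_id`, `n_c`, `n_l`,
#'   `linear_norm` (linear count normalized for depth), and optionally
#'   `tissue`.
#' @param fdr_level Outlier FDR threshold (default 0.001).
#' @param eps Clamp for OLS-predicted fractions outside (0, 1).
#' @return The input tibble plus `p_hat`, `z_n`, `z_o`, `z_corrected`,
#'   `p_value`, `fdr`, `outlier`; the per-gene sd median is attached as
#'   attribute `"sd_median"`, and a tissue-consistency summary as attribute
#'   `"tissue_summary"` when a `tissue` column is present.
#' @export
outlier_analysis <- function(tbl, fdr_level = 0.001, eps = 1e-6) {
  counts_ok <- tbl |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::filter(dplyr::n() >= 4) |>
    dplyr::ungroup()
  abort_if(nrow(counts_ok) == 0, "need at least four samples per gene")

  out <- counts_ok |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::group_modify(function(g, key) {
      n <- g$n_c + g$n_l
      p_hat <- g$n_c / n
      p_mle <- sum(g$n_c) / sum(n)
      z_n <- (p_hat - p_mle) * sqrt(n) / sqrt(p_mle * (1 - p_mle))
      ols <- lm(p_hat ~ linear_norm, data = data.frame(p_hat, linear_norm = g$linear_norm))
      p_ols <- unname(fitted(ols))
      if (any(p_ols <= 0 | p_ols >= 1)) {
        warning("OLS-predicted circle fraction outside (0, 1); clamping",
                call. = FALSE)
        p_ols <- clamp01(p_ols, eps)
      }
      z_o <- (p_hat - p_ols) * sqrt(n) / sqrt(p_ols * (1 - p_ols))
      dplyr::bind_cols(g, tibble::tibble(
        p_hat = p_hat, z_n = z_n, z_o = z_o, sd_zo = sd(z_o)))
    }) |>
    dplyr::ungroup()

  sd_med <- median(out$sd_zo[!duplicated(out$gene_id)])
  abort_if(!is.finite(sd_med) || sd_med < 0,
           "median per-gene sd of z_o is not finite")
  if (sd_med == 0) {
    # every gene's residuals are exactly zero-dispersed (degenerate input);
    # skip the overdispersion correction rather than divide by zero
    warning("median per-gene sd of z_o is zero; overdispersion correction skipped",
            call. = FALSE)
    sd_med <- 1
  }
  out <- out |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::mutate(
      z_corrected = .data$z_o / sd_med,
      p_value = 2 * pt(-abs(.data$z_corrected), df = dplyr::n() - 2)) |>
    dplyr::ungroup() |>
    dplyr::mutate(fdr = bh_fdr(.data$p_value),
                  outlier = .data$fdr <= fdr_level) |>
    dplyr::select(-"sd_zo")
  attr(out, "sd_median") <- sd_med

  if ("tissue" %in% names(out)) {
    ts <- out |>
      dplyr::filter(.data$outlier) |>
      dplyr::group_by(.data$gene_id, .data$tissue) |>
      dplyr::summarise(n_outlier_samples = dplyr::n(), .groups = "drop")
    total <- out |>
      dplyr::group_by(.data$gene_id, .data$tissue) |>
      dplyr::summarise(n_samples = dplyr::n(), .groups = "drop")
    attr(out, "tissue_summary") <- ts |>
      dplyr::left_join(total, by = c("gene_id", "tissue")) |>
      dplyr::mutate(tissue_consistent = .data$n_outlier_samples == .data$n_samples &
                      .data$n_samples >= 2)
  }
  out
}

#' Plot induction z-score distributions for circular vs linear junctions
#'
#' @param z Tibble with `z` and a grouping column `role` (e.g. `"circular"`
#'   vs `"exterior_linear"`).
#' @return A ggplot.
#' @export
plot_induction_z <- function(z) {
  ggplot2::ggplot(z, ggplot2::aes(x = .data$z, colour = .data$role)) +
    ggplot2::geom_density() +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "induction z score", y = "density", colour = NULL) +
    ggplot2::theme_minimal()
}
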