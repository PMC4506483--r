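test_that("exterior assignment excludes junctions interior to expressed circles", {
  lin <- tibble::tibble(
    junction_id = c("in", "shares_donor", "outside"),
    gene_id = "g1",
    pos5 = c(3500, 5200, 5600), pos3 = c(4000, 5800, 6200))
  circles <- tibble::tibble(gene_id = "g1", lo = 3000, hi = 5200, count = 50)
  out <- assign_exterior(lin, circles, k_min = 10)
  # both sites inside -> excluded; a junction sharing the circle's donor but
  # splicing downstream keeps one site outside -> exterior
  expect_setequal(out$junction_id, c("shares_donor", "outside"))

  # circles below the count threshold impose no boundary
  expect_equal(nrow(assign_exterior(lin, dplyr::mutate(circles, count = 5),
                                    k_min = 10)), 3)

  # with two circles, exterior is the intersection: a junction interior to
  # only circle A is still excluded
  two <- dplyr::bind_rows(circles,
                          tibble::tibble(gene_id = "g1", lo = 8000, hi = 9000,
                                         count = 60))
  lin2 <- tibble::tibble(junction_id = "inA_outB", gene_id = "g1",
                         pos5 = 3500, pos3 = 4000)
  expect_equal(nrow(assign_exterior(lin2, two, k_min = 10)), 0)
})

test_that("exterior assignment never excludes a junction with an outside site", {
  set.seed(51)
  for (rep in 1:20) {
    circles <- tibble::tibble(
      gene_id = "g", lo = sort(sample(1000:5000, 3)),
      count = sample(0:40, 3, TRUE))
    circles$hi <- circles$lo + sample(500:2000, 3, TRUE)
    lin <- tibble::tibble(
      junction_id = sprintf("j%02d", 1:30), gene_id = "g",
      pos5 = sample(500:8000, 30), pos3 = sample(500:8000, 30))
    out <- assign_exterior(lin, circles, k_min = 10)
    qual <- circles[circles$count >= 10, ]
    has_outside_site <- vapply(seq_len(nrow(lin)), function(i) {
      all(vapply(seq_len(nrow(qual)), function(k) {
        lin$pos5[i] < qual$lo[k] || lin$pos5[i] > qual$hi[k] ||
          lin$pos3[i] < qual$lo[k] || lin$pos3[i] > qual$hi[k]
      }, logical(1)))
    }, logical(1))
    expect_setequal(out$junction_id, lin$junction_id[has_outside_site])
  }
})

test_that("normalization constants are medians of counts above five", {
  counts <- tibble::tibble(
    junction_id = sprintf("j%d", 1:5), sample_id = "s1",
    count = c(1, 2, 6, 8, 100))
  expect_equal(normalization_constants(counts)$c, 8)
  flat <- dplyr::mutate(counts, count = 10)
  expect_equal(normalization_constants(flat)$c, 10)
  # scaling all counts scales c (x = r / c is unchanged) as long as no
  # borderline count crosses the fixed >5 threshold
  counts2 <- dplyr::mutate(counts, count = c(0, 1, 7, 9, 101))
  expect_equal(normalization_constants(counts2)$c, 9)
  scaled <- dplyr::mutate(counts2, count = count * 3)
  expect_equal(normalization_constants(scaled)$c, 27)
  low <- dplyr::mutate(counts, count = c(1, 2, 3, 4, 5))
  expect_error(normalization_constants(low), "no junction exceeds five.*s1")
})

test_that("the induction z score is zero for flat profiles and scale-invariant", {
  ages <- c(10, 12, 15, 18, 21)
  expect_equal(induction_zscore(rep(20, 5), rep(2, 5), ages), 0)
  r <- c(10, 14, 22, 30, 41)
  z <- induction_zscore(r, rep(2, 5), ages)
  # the normalized profile x = r / c is scale-free, and tripling the
  # sequencing depth shrinks the Poisson noise so |z| grows by sqrt(3)
  expect_equal(induction_zscore(3 * r, 3 * rep(2, 5), ages), sqrt(3) * z)
  # z is invariant to the units of the age vector
  expect_equal(induction_zscore(r, rep(2, 5), ages * 7), z)
  expect_true(is.na(induction_zscore(rep(0, 5), rep(2, 5), ages)))
  expect_error(induction_zscore(r[1:2], rep(2, 2), ages[1:2]), "three samples")
  expect_error(induction_zscore(r, rep(2, 5), rep(15, 5)), "constant")
})

test_that("the age-aligned arrangement of counts maximizes z", {
  ages <- c(10, 12, 15, 18, 21)
  r <- c(5, 9, 14, 20, 27)   # increasing with age
  # enumerate all 120 arrangements of the same counts
  allperm <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in allperm(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  zs <- vapply(allperm(r), function(p) {
    induction_zscore(p, rep(2, 5), ages)
  }, numeric(1))
  expect_equal(max(zs), induction_zscore(r, rep(2, 5), ages))
})

test_that("JRPKM uses the effective junction window", {
  # 100-nt reads with 10-nt minimum overlap: 180-nt window
  expect_equal(jrpkm(10, 1.8e6), 1.0)
  expect_equal(jrpkm(10, 3.6e6), 0.5)       # doubling depth halves JRPKM
  expect_equal(jrpkm(10, 1.8e6, read_len = 60, min_overlap = 10),
               10 / (1.8e6 / (100 / 1000 * 1e6)))
  expect_error(jrpkm(10, 0), "positive")
})

test_that("two-timepoint calls come from non-overlapping binomial intervals", {
  expect_equal(two_timepoint_test(c(30, 70), c(30, 70)), "none")
  expect_equal(two_timepoint_test(c(2, 98), c(60, 40)), "increase")
  expect_equal(two_timepoint_test(c(60, 40), c(2, 98)), "decrease")
  expect_equal(two_timepoint_test(c(0, 0), c(10, 10)), "none")
  # Clopper-Pearson intervals are available as an alternative
  expect_equal(two_timepoint_test(c(2, 98), c(60, 40),
                                  method = "clopper-pearson"), "increase")
})

test_that("two-timepoint type-I error is controlled under a binomial null", {
  set.seed(52)
  n <- 150
  hits <- replicate(2000, {
    e <- rbinom(1, n, 0.3)
    l <- rbinom(1, n, 0.3)
    two_timepoint_test(c(e, n - e), c(l, n - l)) != "none"
  })
  # two non-overlapping independent 95% CIs: type-I well below 0.05
  expect_lte(mean(hits), 0.05)
})

test_that("outlier analysis flags planted outliers and matches hand formulas", {
  # hand-computed z_n on a constructed table
  tb <- tibble::tibble(
    gene_id = "g", sample_id = sprintf("s%d", 1:4),
    n_c = c(10, 20, 30, 40), n_l = c(90, 80, 70, 60),
    linear_norm = c(0.9, 0.8, 0.7, 0.6))
  out <- suppressWarnings(outlier_analysis(tb))
  n <- tb$n_c + tb$n_l
  p_hat <- tb$n_c / n
  p_mle <- sum(tb$n_c) / sum(n)
  expect_equal(out$z_n, (p_hat - p_mle) * sqrt(n) / sqrt(p_mle * (1 - p_mle)))
  # p_hat here is exactly linear in linear_norm, so OLS residuals vanish
  expect_equal(out$z_o, rep(0, 4), tolerance = 1e-10)

  # identical samples: no outliers
  flat <- tibble::tibble(gene_id = rep(sprintf("g%d", 1:5), each = 4),
                         sample_id = rep(sprintf("s%d", 1:4), 5),
                         n_c = 20, n_l = 80, linear_norm = 0.8)
  out_flat <- suppressWarnings(outlier_analysis(flat))
  expect_false(any(out_flat$outlier))
  expect_equal(out_flat$z_o, rep(0, 20), tolerance = 1e-10)

  # a sample far above an otherwise flat trend is flagged at FDR 0.001
  set.seed(53)
  tb2 <- tidyr::expand_grid(gene_id = sprintf("g%02d", 1:25),
                            sample_id = sprintf("s%02d", 1:12))
  tb2$n_l <- rpois(nrow(tb2), 300)
  tb2$n_c <- rpois(nrow(tb2), 60)
  planted <- tb2$gene_id == "g01" & tb2$sample_id == "s01"
  tb2$n_c[planted] <- 600
  tb2$linear_norm <- tb2$n_l / 1000
  out2 <- outlier_analysis(tb2)
  expect_true(out2$outlier[out2$gene_id == "g01" & out2$sample_id == "s01"])
  expect_lte(sum(out2$outlier), 3)
  expect_gt(attr(out2, "sd_median"), 0)
})

test_that("induction z scores are calibrated and detect planted slopes", {
  ct <- simulate_count_table(n_circular = 0, n_linear = 3000,
                             circular_slope = 0, seed = 54)
  z <- induction_zscores(ct$counts, ct$samples)$z
  expect_lt(abs(mean(z, na.rm = TRUE)), 0.05)
  expect_gt(sd(z, na.rm = TRUE), 0.9)
  expect_lt(sd(z, na.rm = TRUE), 1.1)

  ct2 <- simulate_count_table(n_circular = 150, n_linear = 600, seed = 55)
  z2 <- dplyr::inner_join(induction_zscores(ct2$counts, ct2$samples),
                          ct2$truth, by = "junction_id")
  test <- wilcox.test(z2$z[z2$role == "circular"],
                      z2$z[z2$role == "exterior_linear"],
                      alternative = "greater")
  expect_lt(test$p.value, 0.01)
})
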