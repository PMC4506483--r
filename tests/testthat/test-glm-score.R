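test_that("junction posterior matches the closed form and its symmetries", {
  # direct product evaluation
  expect_equal(junction_posterior(c(0.9, 0.9)), 0.81 / (0.81 + 0.01))
  expect_equal(junction_posterior(0.73), 0.73)  # single read: identity
  expect_equal(junction_posterior(c(0.5, 0.5, 0.5)), 0.5)
  # balanced evidence: half q, half 1 - q, for any q
  for (q in c(0.05, 0.2, 0.45)) {
    expect_equal(junction_posterior(c(rep(q, 3), rep(1 - q, 3))), 0.5)
  }
  # permutation invariance and strict monotonicity in each read
  set.seed(31)
  p <- runif(7, 0.05, 0.95)
  expect_equal(junction_posterior(p), junction_posterior(sample(p)))
  expect_gt(junction_posterior(c(p, 0.6)), junction_posterior(p))
  expect_lt(junction_posterior(c(p, 0.4)), junction_posterior(p))
  # log-space evaluation survives read counts that would underflow naively
  expect_gt(junction_posterior(rep(0.9, 500)), 1 - 1e-12)
  expect_error(junction_posterior(numeric(0)), "no reads")
})

test_that("linear junction p-values are centered and signed correctly", {
  nm <- list(mu = 0, var1 = 1)
  # reads at the null mean log-odds give p = 0.5
  expect_equal(linear_junction_pvalue(rep(0.5, 4), nm$mu, nm$var1), 0.5)
  # reads all above the dataset mean probability -> z < 0, p < 0.5
  expect_lt(linear_junction_pvalue(rep(0.8, 4), nm$mu, nm$var1), 0.5)
  expect_gt(linear_junction_pvalue(rep(0.2, 4), nm$mu, nm$var1), 0.5)
  expect_error(linear_junction_pvalue(0.5, 0, 0), "variance")

  # moments come from the pooled decoy + linear reads
  set.seed(32)
  p <- plogis(rnorm(500))
  nm <- estimate_null_moments(p)
  l <- log((1 - p) / p)
  expect_equal(nm$mu, mean(l))
  expect_equal(nm$var1, var(l))
})

test_that("circular junction p-values follow the printed artifact null", {
  one <- circular_junction_pvalue(1)
  expect_equal(one$z, -2)
  expect_equal(one$p_value, pnorm(-2), tolerance = 1e-12)
  # z = -2 sqrt(n): four reads give z = -4, and p decreases monotonically
  expect_equal(circular_junction_pvalue(4)$z, -4)
  n <- 1:20
  p <- circular_junction_pvalue(n)$p_value
  expect_equal(circular_junction_pvalue(n)$z, -2 * sqrt(n))
  expect_true(all(diff(p) < 0))
  expect_error(circular_junction_pvalue(0), "at least one read")
})

test_that("BH adjustment matches a hand-rolled step-up oracle", {
  expect_equal(bh_fdr(0.03), 0.03)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(numeric(0)), numeric(0))

  # independent step-up implementation
  bh_oracle <- function(p) {
    m <- length(p)
    o <- order(p)
    adj <- rev(cummin(rev(p[o] * m / seq_len(m))))
    pmin(1, adj)[order(o)]
  }
  set.seed(33)
  p <- runif(1000)
  expect_equal(bh_fdr(p), bh_oracle(p), tolerance = 1e-12)
  p_ties <- round(runif(200, 0, 0.2), 2)
  expect_equal(bh_fdr(p_ties), bh_oracle(p_ties), tolerance = 1e-12)
})

test_that("the naive Poisson test matches exact pmf summation", {
  expect_equal(naive_mismatch_pvalue(0, 1000), 1)
  expect_equal(naive_mismatch_pvalue(5, 100), 0.00365984682734371,
               tolerance = 1e-10)
  # oracle: direct upper-tail pmf summation to a far cutoff
  tail_oracle <- function(m, bases, rate = 0.01) {
    lambda <- rate * bases
    k <- m:(m + 2000)
    sum(exp(-lambda + k * log(lambda) - lgamma(k + 1)))
  }
  set.seed(34)
  for (i in 1:50) {
    m <- rpois(1, 3)
    bases <- sample(50:5000, 1)
    expect_equal(naive_mismatch_pvalue(m, bases), tail_oracle(m, bases),
                 tolerance = 1e-10)
  }
  expect_error(naive_mismatch_pvalue(-1, 100), "mismatches")
})

test_that("the two-step fit balances classes and downweights conflicted reads", {
  tr <- tiny_training(n = 200, seed = 35)
  fit <- suppressWarnings(fit_two_step_glm(tr))
  d <- fit$data
  # class weight totals are equal after step-2 reweighting
  expect_equal(sum(d$weight[d$category == "linear"]),
               sum(d$weight[d$category == "decoy"]), tolerance = 1e-12)
  expect_true(all(d$p_lo <= d$p_hat & d$p_hat <= d$p_hi))
  expect_true(all(d$p_hat > 0 & d$p_hat < 1))

  # a linear-labeled read whose features match the decoy profile carries less
  # weight than one matching the linear profile
  probe <- dplyr::bind_rows(
    tibble::tibble(category = "linear", offset = 12, alignment_score = -18,
                   mapq = 1, read_id = "probe_decoyish", junction_id = "jx",
                   cls = "linear"),
    tibble::tibble(category = "linear", offset = 40, alignment_score = 0,
                   mapq = 42, read_id = "probe_linearish", junction_id = "jx",
                   cls = "linear"))
  fit2 <- suppressWarnings(fit_two_step_glm(dplyr::bind_rows(tr, probe)))
  w <- fit2$data[match(c("probe_decoyish", "probe_linearish"),
                       fit2$data$read_id), "weight", drop = TRUE]
  expect_lt(w[1], w[2])

  # class preconditions
  expect_error(fit_two_step_glm(dplyr::filter(tr, category == "linear")),
               "both a linear and a decoy class")
  expect_error(fit_two_step_glm(tr[c(1:30, 201:205), ]), "at least 10")
})

test_that("indistinguishable classes yield an uninformative classifier", {
  ft <- simulate_feature_table(n_linear = 1500, n_decoy = 1500,
                               scenario = "null", seed = 36)
  fit <- suppressWarnings(fit_two_step_glm(ft))
  g <- glance(fit)
  expect_gt(g$auc, 0.45)
  expect_lt(g$auc, 0.55)
  td <- tidy(fit, step = 1)
  expect_true(all(td$p.value[td$term != "(Intercept)"] > 0.001))
})

test_that("conservative prediction uses the CI end nearer 0.5, never past it", {
  # a synthetic single-predictor fit with known coefficients and covariance
  fit <- structure(list(beta = c(`(Intercept)` = 0, x = 1),
                        vcov = matrix(c(0.04, 0, 0, 0), 2, 2,
                                      dimnames = list(c("(Intercept)", "x"),
                                                      c("(Intercept)", "x"))),
                        predictors = "x"), class = "circ_glm")
  sc <- predict_conservative(fit, tibble::tibble(x = c(2, -2)))
  # class-1 read: lower bound; class-2 read: upper bound
  expect_equal(sc$p_used[1], plogis(2 - qnorm(0.975) * 0.2))
  expect_equal(sc$p_used[2], plogis(-2 + qnorm(0.975) * 0.2))
  # degenerate zero-width interval returns p_hat itself
  fit0 <- structure(list(beta = c(`(Intercept)` = 0, x = 1),
                         vcov = matrix(0, 2, 2), predictors = "x"),
                    class = "circ_glm")
  sc0 <- predict_conservative(fit0, tibble::tibble(x = 1.3))
  expect_equal(sc0$p_used, sc0$p_hat)
  # an interval wide enough to cross 0.5 is truncated there, not inverted
  fitw <- structure(list(beta = c(`(Intercept)` = 0, x = 1),
                         vcov = matrix(c(25, 0, 0, 0), 2, 2),
                         predictors = "x"), class = "circ_glm")
  scw <- predict_conservative(fitw, tibble::tibble(x = c(2, -2)))
  expect_equal(scw$p_used, c(0.5, 0.5))
})

test_that("report filtering applies the posterior and read-count thresholds", {
  calls <- tibble::tibble(
    junction_id = c("a", "b", "c"), cls = "scrambled",
    n_reads = c(3L, 1L, 10L), decoy_count = 0L,
    posterior = c(0.95, 0.95, 0.89),
    p_value = 0.01, fdr = 0.02, verdict = "pass")
  kept <- report_calls(calls, posterior_threshold = 0.9, n_min = 2)
  expect_equal(kept$junction_id, "a")
  # n_min = 1 admits single-read junctions (shallow-library setting)
  expect_setequal(report_calls(calls, n_min = 1)$junction_id, c("a", "b"))
})

test_that("scoring separates real from artifact junctions on feature tables", {
  ft <- simulate_feature_table(seed = 37)
  calls <- suppressWarnings(score_junctions(ft))
  truth <- dplyr::distinct(ft[ft$category == "circular",
                              c("junction_id", "true_status")])
  m <- dplyr::inner_join(calls, truth, by = "junction_id")
  real2 <- m$true_status == "real" & m$n_reads >= 2
  expect_gte(mean(m$posterior[real2] >= 0.9), 0.95)
  expect_lte(mean(m$posterior[m$true_status == "artifact"] >= 0.9), 0.05)
  # decoy counts surface in the calls for diagnostics
  expect_true(any(m$decoy_count[m$true_status == "artifact"] > 0))
  # naive mode scores junctions without a posterior
  naive <- score_junctions(dplyr::mutate(ft, mismatches = 0L), mode = "naive")
  expect_true(all(is.na(naive$posterior)))
  expect_true(all(naive$p_value == 1))
})
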