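test_that("wilcoxon signed-rank matches sign-pattern enumeration at small n", {
  # independent oracle: enumerate all 2^n sign assignments of the ranked
  # absolute differences and accumulate the exact two-sided tail probability
  enum_p <- function(d) {
    d <- d[d != 0]
    n <- length(d)
    r <- rank(abs(d))
    W <- sum(r[d > 0])
    mu <- sum(r) / 2
    grid <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
    Ws <- grid %*% r
    mean(abs(Ws - mu) >= abs(W - mu) - 1e-9)
  }
  # five one-signed differences: exact two-sided p = 2/32
  d5 <- c(-1.3, -0.4, -2.2, -0.9, -3.1)
  res <- wilcoxon_signed_rank(d5)
  expect_equal(res$p, 0.0625)
  expect_equal(res$p, enum_p(d5))
  # assorted cases with ties and mixed signs
  set.seed(42)
  for (i in 1:20) {
    d <- round(rnorm(sample(4:10, 1)), sample(0:1, 1))
    d <- d[d != 0]
    if (length(d) < 2) next
    expect_equal(wilcoxon_signed_rank(d)$p, enum_p(d), tolerance = 1e-12)
  }
})

test_that("wilcoxon handles symmetry, zeros and degenerate input", {
  # perfectly symmetric differences sit at the null centre: p = 1
  expect_equal(wilcoxon_signed_rank(c(-2, 2, -1, 1, 3, -3))$p, 1)
  # zeros are dropped before ranking
  expect_equal(wilcoxon_signed_rank(c(0, 0, -1, -2, -3, -4, -5))$p, 0.0625)
  expect_error(wilcoxon_signed_rank(c(0, 0, 0)), "nonzero")
})

test_that("wilcoxon agrees with the base R exact test when there are no ties", {
  set.seed(7)
  for (i in 1:10) {
    d <- rnorm(sample(6:20, 1))
    ours <- wilcoxon_signed_rank(d)$p
    ref <- wilcox.test(d, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
})

test_that("exact and normal-approximate wilcoxon agree at n = 25", {
  set.seed(11)
  for (i in 1:50) {
    d <- rnorm(25, mean = runif(1, -0.5, 0.5))
    pe <- wilcoxon_signed_rank(d, exact_max = 25)$p
    pa <- wilcoxon_signed_rank(d, exact_max = 0)$p
    expect_lt(abs(pe - pa), 0.01)
  }
})

test_that("wilcoxon p is invariant under permutation of the input", {
  set.seed(3)
  d <- rnorm(12)
  p0 <- wilcoxon_signed_rank(d)$p
  for (i in 1:5) expect_equal(wilcoxon_signed_rank(sample(d))$p, p0)
})

test_that("spearman matches a brute-force rank-Pearson oracle", {
  brute <- function(x, y) {
    rk <- function(v) {
      # average ranks computed from scratch
      sapply(seq_along(v), function(i)
        sum(v < v[i]) + (sum(v == v[i]) + 1) / 2)
    }
    rx <- rk(x); ry <- rk(y)
    sum((rx - mean(rx)) * (ry - mean(ry))) /
      sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  }
  set.seed(5)
  for (i in 1:25) {
    n <- sample(4:12, 1)
    x <- round(rnorm(n), 1)   # induce ties
    y <- round(rnorm(n), 1)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(spearman_cor(x, y)$rho, brute(x, y), tolerance = 1e-12)
  }
})

test_that("spearman endpoints, invariances and missing-data handling", {
  x <- c(1, 2, 5, 7, 9, 12)
  expect_equal(spearman_cor(x, x^3)$rho, 1)
  expect_equal(spearman_cor(x, -exp(x / 5))$rho, -1)
  # invariant under strictly monotone transforms
  set.seed(9)
  a <- rnorm(15); b <- rnorm(15)
  r0 <- spearman_cor(a, b)$rho
  expect_equal(spearman_cor(exp(a), b)$rho, r0)
  expect_equal(spearman_cor(a, qnorm(pnorm(b)))$rho, r0, tolerance = 1e-12)
  # pairwise deletion mirrors the missing-rhinometry bookkeeping
  b[3] <- NA
  expect_equal(spearman_cor(a, b)$n, 14)
  expect_error(spearman_cor(rep(1, 5), rnorm(5)), "constant")
})

test_that("spearman small-n p agrees with the base R exact test", {
  set.seed(13)
  for (i in 1:8) {
    x <- rnorm(7); y <- rnorm(7)   # no ties
    ours <- spearman_cor(x, y)
    ref <- cor.test(x, y, method = "spearman", exact = TRUE)
    expect_equal(ours$rho, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-9)
  }
})

test_that("median_iqr uses linear interpolation between order statistics", {
  expect_equal(unname(median_iqr(c(1, 2, 3))["median"]), 2)
  expect_equal(unname(median_iqr(c(1, 2, 3, 4))["median"]), 2.5)
  # independent sorted-interpolation oracle
  interp_q <- function(x, p) {
    x <- sort(x); n <- length(x)
    h <- (n - 1) * p + 1
    lo <- floor(h)
    x[lo] + (h - lo) * (x[min(lo + 1, n)] - x[lo])
  }
  set.seed(21)
  for (i in 1:100) {
    x <- rnorm(sample(3:40, 1))
    m <- median_iqr(x)
    expect_equal(unname(m["iq25"]), interp_q(x, 0.25), tolerance = 1e-12)
    expect_equal(unname(m["iq75"]), interp_q(x, 0.75), tolerance = 1e-12)
  }
})

test_that("change scores subtract pre from post with the clinical sign convention", {
  tab <- data.frame(id = rep(c("a", "b"), each = 2),
                    timepoint = rep(c("pre", "post"), 2),
                    force = c(3.22e-4, 1.62e-4, 2e-4, 2e-4))
  ch <- change_scores(tab)
  # improvement (smaller post force) gives a negative change
  expect_equal(ch$force[ch$id == "a"], -1.60e-4)
  expect_equal(ch$force[ch$id == "b"], 0)
  expect_error(change_scores(tab[-4, ]), "exactly one pre and one post")
})

test_that("type-I error of the wilcoxon test is calibrated under the null", {
  set.seed(101)
  reject <- logical(2000)
  for (i in seq_along(reject)) {
    d <- rnorm(25)
    reject[i] <- wilcoxon_signed_rank(d)$p < 0.05
  }
  rate <- mean(reject)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("cohort report carries the pooled and paired sample sizes", {
  set.seed(33)
  co <- generate_cohort(25, coupling_params(target_rho = 0.9), seed = 4)
  tab <- co$subjects
  tab$roi_force <- tab$force_surrogate
  tab$roi_heat <- 0.5 + 0.05 * rnorm(nrow(tab))
  tab$roi_volume <- tab$v25
  tab$pressure_loss <- 20 * tab$force_surrogate / max(tab$force_surrogate)
  rep <- build_report(tab)
  expect_equal(rep$n_subjects, 25)
  expect_equal(rep$n_pooled, 50)
  expect_true(all(rep$pooled_cor$n == 50))
  expect_true(all(rep$change_cor$n == 25))
  # one subject missing rhinometry -> pooled 48, change 24
  tab2 <- tab
  tab2$v25[tab2$id == "S003"] <- NA
  rep2 <- build_report(tab2)
  expect_equal(rep2$pooled_cor$n[rep2$pooled_cor$y == "v25"][1], 48)
  expect_equal(rep2$change_cor$n[rep2$change_cor$y == "v25"][1], 24)
  # strong coupling: dVAS ~ d(roi force) positive and significant
  vs <- rep$change_cor[rep$change_cor$x == "roi_force" &
                         rep$change_cor$y == "vas", ]
  expect_gt(vs$rho, 0)
  expect_lt(vs$p, 0.05)
})
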