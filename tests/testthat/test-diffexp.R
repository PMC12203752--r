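make_counts <- function(m, genes = sprintf("G%03d", seq_len(nrow(m))),
                        samples = sprintf("s%d", seq_len(ncol(m)))) {
  dimnames(m) <- list(genes, samples)
  storage.mode(m) <- "integer"
  m
}

test_that("size factors recover exact library scaling", {
  a <- c(10L, 40L, 100L, 7L)
  m <- make_counts(cbind(a, 2L * a))
  sf <- size_factors(m)
  expect_equal(unname(sf), c(1 / sqrt(2), sqrt(2)))
  expect_equal(unname(sf[2] / sf[1]), 2)
  # identical samples give unit factors
  m2 <- make_counts(cbind(a, a, a))
  expect_equal(unname(size_factors(m2)), c(1, 1, 1))
})

test_that("size factors match the brute-force median-of-ratios oracle", {
  set.seed(101)
  m <- make_counts(matrix(rnbinom(50 * 6, mu = 60, size = 5), 50, 6))
  expect_equal(unname(size_factors(m)), size_factor_oracle(m), tolerance = 1e-12)
})

test_that("size factors fail when no gene is expressed everywhere", {
  m <- make_counts(matrix(c(0L, 5L, 5L, 0L), 2, 2))
  expect_error(size_factors(m), class = "metadeg_normalization")
})

test_that("dispersion floors Poisson-like and constant genes, recovers true alpha", {
  grp <- rep(c("a", "b"), each = 200)
  set.seed(7)
  pois <- matrix(rpois(400, 50), 1)
  const <- matrix(rep(30, 400), 1)
  expect_equal(estimate_dispersion(pois, grp), 1e-8)
  expect_equal(estimate_dispersion(const, grp), 1e-8)
  # method-of-moments consistency at alpha = 0.2, n = 200 per group
  hits <- 0
  for (r in 1:100) {
    y <- matrix(rnbinom(400, mu = 100, size = 1 / 0.2), 1)
    a <- estimate_dispersion(y, grp)
    hits <- hits + (a >= 0.1 && a <= 0.3)
  }
  expect_gte(hits, 90)
})

test_that("Wald test gives exact null for identical counts and flags degenerate genes", {
  m <- make_counts(rbind(rep(20L, 8), rep(0L, 8), c(0L, 0L, 0L, 0L, 9L, 7L, 11L, 8L),
                         c(15L, 18L, 22L, 25L, 30L, 35L, 41L, 50L)))
  ctr <- contrast(paste0("s", 5:8), paste0("s", 1:4))
  r <- nb_wald_test(m, ctr, sf = setNames(rep(1, 8), colnames(m)))
  expect_equal(r$log2fc[1], 0)
  expect_equal(r$p[1], 1)
  expect_equal(r$status[2], "all_zero")
  expect_true(is.na(r$p[2]))
  expect_equal(r$status[3], "failed_fit")   # one side all zero: unbounded fold change
  # BH denominator counts tested genes only
  tested <- r$status == "tested"
  expect_equal(r$adj_p[tested], bh_oracle(r$p[tested]))
})

test_that("NB fit matches an independent fixed-dispersion GLM", {
  set.seed(42)
  n <- 12
  sf <- runif(n, 0.6, 1.5)
  grp <- rep(c(1, 0), each = 6)
  alpha <- 0.15
  for (rep_i in 1:5) {
    y <- rnbinom(n, mu = sf * exp(3 + 0.8 * grp), size = 1 / alpha)
    m <- make_counts(matrix(y, 1, n))
    r <- nb_wald_test(m, contrast(paste0("s", 1:6), paste0("s", 7:12)),
                      sf = setNames(sf, colnames(m)), alpha = alpha)
    fit <- suppressWarnings(
      glm(y ~ grp + offset(log(sf)),
          family = MASS::negative.binomial(theta = 1 / alpha)))
    expect_equal(r$log2fc * log(2), unname(coef(fit)[2]), tolerance = 1e-6)
    expect_equal(r$se * log(2),
                 unname(summary(fit, dispersion = 1)$coefficients[2, 2]),
                 tolerance = 1e-6)
  }
})

test_that("swapping contrast sides negates fold changes and preserves p-values", {
  set.seed(5)
  m <- make_counts(matrix(rnbinom(200 * 10, mu = 50, size = 8), 200, 10))
  sf <- size_factors(m)
  a <- paste0("s", 1:5); b <- paste0("s", 6:10)
  r1 <- nb_wald_test(m, contrast(a, b), sf = sf)
  r2 <- nb_wald_test(m, contrast(b, a), sf = sf)
  t12 <- r1$status == "tested" & r2$status == "tested"
  expect_equal(r1$log2fc[t12], -r2$log2fc[t12], tolerance = 1e-9)
  expect_equal(r1$p[t12], r2$p[t12], tolerance = 1e-9)
})

test_that("Wald test has power on strong planted fold changes", {
  set.seed(31)
  mu <- outer(rep(100, 100), c(rep(4, 10), rep(1, 10)))
  y <- matrix(rnbinom(length(mu), mu = mu, size = 1 / 0.1), nrow(mu))
  m <- make_counts(y)
  # unit size factors: the planted change affects every gene, so data-driven
  # normalization would absorb it
  r <- nb_wald_test(m, contrast(paste0("s", 1:10), paste0("s", 11:20)),
                    sf = setNames(rep(1, 20), colnames(m)))
  hits <- sum(r$adj_p <= 0.01 & r$log2fc > 0, na.rm = TRUE)
  expect_gte(hits, 95)
})

test_that("null NB simulation keeps the raw p-value rate calibrated", {
  set.seed(77)
  m <- make_counts(matrix(rnbinom(5000 * 16, mu = 80, size = 1 / 0.15), 5000, 16))
  r <- nb_wald_test(m, contrast(paste0("s", 1:8), paste0("s", 9:16)))
  frac <- mean(r$p < 0.05, na.rm = TRUE)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.08)
})

test_that("BH adjustment follows the step-up formula and stays monotone", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_error(bh_adjust(c(0.5, 1.2)), class = "metadeg_pvalue")
  expect_error(bh_adjust(c(0.5, NA)), class = "metadeg_pvalue")
  set.seed(12)
  for (i in 1:25) {
    p <- runif(sample(1:300, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, bh_oracle(p))
    o <- order(p)
    expect_true(all(diff(adj[o]) >= -1e-15))
  }
})

test_that("DEG calling respects the inclusive boundary and partitions by sign", {
  res <- data.frame(gene_id = sprintf("G%02d", 1:20),
                    base_mean = 50,
                    log2fc = rep(c(2, -1, 0.5, -0.2), 5),
                    se = 0.1,
                    p = seq_len(20) / 60,
                    adj_p = seq_len(20) / 50,
                    status = "tested", stringsAsFactors = FALSE)
  class(res) <- c("de_result", "data.frame")
  degs <- call_degs(res, alpha = 0.1)
  expect_equal(nrow(degs), sum(res$adj_p <= 0.1))
  expect_true("G05" %in% degs$gene_id)  # adj_p = 0.1 exactly: included
  strict <- call_degs(res, alpha = 0.1, strict = TRUE)
  expect_false("G05" %in% strict$gene_id)
  expect_equal(sum(degs$direction > 0), sum(res$adj_p <= 0.1 & res$log2fc > 0))
  expect_equal(sum(degs$direction < 0), sum(res$adj_p <= 0.1 & res$log2fc < 0))
  # a significant zero fold change is an impossible state
  res$log2fc[1] <- 0
  expect_error(call_degs(res, alpha = 0.1), class = "metadeg_impossible_state")
})
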