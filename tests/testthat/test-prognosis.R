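surv_fixture <- function(n = 60, seed = 42, beta = log(2), missing_gleason = 0) {
  labs <- setNames(rep(c("high", "low"), length.out = n), sprintf("S%04d", seq_len(n)))
  rec <- simulate_survival(labs, beta = beta, censoring_fraction = 0.25,
                           missing_gleason = missing_gleason, seed = seed)
  list(records = rec, labels = labs)
}

test_that("third-quartile stratification uses the interpolated quantile", {
  v <- setNames(as.numeric(1:8), letters[1:8])
  labs <- stratify_by_q3(v)                      # Q3 = 6.25
  expect_equal(names(labs)[labs == "high"], c("g", "h"))
  expect_equal(sum(labs == "low"), 6)
  expect_error(stratify_by_q3(rep(3, 10)), class = "metadeg_degenerate_stratification")
  expect_error(stratify_by_q3(c(1, 2, 3)), class = "metadeg_stratification")
  # partition property on continuous data
  set.seed(1)
  x <- rnorm(200)
  l <- stratify_by_q3(x)
  expect_equal(sum(l == "high") + sum(l == "low"), 200)
  expect_equal(sum(l == "high"), 50)
})

test_that("Kaplan-Meier estimates follow the product-limit formula", {
  rec <- data.frame(sample_id = sprintf("s%d", 1:6),
                    time = c(1, 2, 3, 10, 20, 30), event = 1,
                    age = 60, psa = 5, gleason = 7, pt_stage = "pT2a")
  labs <- setNames(rep(c("A", "B"), each = 3), rec$sample_id)
  km <- km_logrank(rec, labs)
  a <- km$surv[km$surv$group == "A", ]
  expect_equal(a$survival, c(2 / 3, 1 / 3, 0))
  expect_equal(a$n_risk, c(3, 2, 1))
  # with no censoring the estimate equals the empirical survival function
  b <- km$surv[km$surv$group == "B", ]
  expect_equal(b$survival, c(2 / 3, 1 / 3, 0))
})

test_that("log-rank test is null for identical groups and undefined without events", {
  rec <- data.frame(sample_id = sprintf("s%d", 1:8),
                    time = rep(c(3, 5, 9, 14), 2), event = rep(c(1, 0, 1, 1), 2),
                    age = 60, psa = 5, gleason = 7, pt_stage = "pT2a")
  labs <- setNames(rep(c("high", "low"), 4), rec$sample_id)
  labs[] <- c("high", "high", "low", "low", "high", "high", "low", "low")
  rec2 <- rec; rec2$time <- c(3, 5, 9, 14, 3, 5, 9, 14)
  labs2 <- setNames(rep(c("high", "low"), each = 4), rec$sample_id)
  km <- km_logrank(rec2, labs2)
  expect_equal(km$chisq, 0, tolerance = 1e-12)
  expect_equal(km$p, 1)
  rec3 <- rec; rec3$event <- 0
  expect_error(km_logrank(rec3, labs), class = "metadeg_undefined_test")
})

test_that("covariate coding matches the published group boundaries", {
  rec <- data.frame(sample_id = sprintf("s%d", 1:8),
                    time = 10, event = 1,
                    age = c(62, 63, 50, 70, 62, 62, 62, 62),
                    psa = c(10, 15, 20, 9.9, 19.9, 25, 10, 3),
                    gleason = c(6, 7, 8, 9, NA, 7, 6, 7),
                    pt_stage = c("pT2a", "pT2b", "pT3a", "pT3b",
                                 "pT2a", "pT2a", "pT2a", "pT2a"))
  enc <- encode_covariates(rec)
  expect_equal(as.character(enc$age_group[1:4]), c("low", "high", "low", "high"))
  expect_equal(as.character(enc$psa_group[1:6]),
               c("low", "intermediate", "high", "low", "intermediate", "high"))
  expect_equal(as.character(enc$gs_group[1:4]), c("low", "intermediate", "high", "high"))
  expect_equal(as.character(enc$pt_group[1:4]), c("low", "low", "high", "high"))
  expect_false(enc$complete[5])  # missing Gleason flagged
  expect_true(all(enc$complete[-5]))
  bad <- rec; bad$pt_stage[1] <- "pT4"
  expect_error(encode_covariates(bad), class = "metadeg_vocabulary")
})

test_that("Cox fit matches an independent Newton-Raphson partial likelihood", {
  fx <- surv_fixture(n = 60, seed = 42)
  expect_equal(anyDuplicated(fx$records$time[fx$records$event == 1]), 0) # untied
  cf <- cox_multivariate(fx$records, fx$labels)
  X <- stats::model.matrix(
    ~ expression + age_group + psa_group + gs_group + pt_group,
    data = cbind(encode_covariates(fx$records),
                 expression = factor(fx$labels[fx$records$sample_id],
                                     levels = c("low", "high"))))[, -1]
  ref <- cox_nr_oracle(X, fx$records$time, fx$records$event)
  expect_equal(cf$terms$beta, unname(ref), tolerance = 1e-6)
  expect_equal(cf$n_excluded, 0)
  expect_true(cf$converged)
  # confidence intervals bracket the relative risk
  expect_true(all(cf$terms$lower <= cf$terms$rr & cf$terms$rr <= cf$terms$upper))
})

test_that("missing Gleason records are excluded from Cox with a count", {
  fx <- surv_fixture(n = 80, seed = 43, missing_gleason = 0.1)
  cf <- cox_multivariate(fx$records, fx$labels)
  expect_equal(cf$n_excluded, 8)
  expect_equal(cf$n_used, 72)
})

test_that("constant covariates are dropped with a warning, not an error", {
  fx <- surv_fixture(n = 50, seed = 44)
  rec <- fx$records
  rec$pt_stage <- "pT3a"
  expect_warning(cf <- cox_multivariate(rec, fx$labels),
                 class = "metadeg_degenerate_design")
  expect_false("pt_grouphigh" %in% cf$terms$term)
  expect_true("expressionhigh" %in% cf$terms$term)
})

test_that("score test at zero equals the log-rank statistic and RR inverts on relabeling", {
  fx <- surv_fixture(n = 70, seed = 45)
  rec <- fx$records
  labs <- fx$labels
  sc <- survival::coxph(survival::Surv(rec$time, rec$event) ~ I(labs == "high"))
  km <- km_logrank(rec, labs)
  expect_equal(unname(sc$score), km$chisq, tolerance = 1e-6)
  cf <- cox_multivariate(rec, labs, covariates = character(0))
  swapped <- setNames(ifelse(labs == "high", "low", "high"), names(labs))
  cf2 <- cox_multivariate(rec, swapped, covariates = character(0))
  expect_equal(cf$terms$rr, 1 / cf2$terms$rr, tolerance = 1e-8)
  expect_equal(cf$terms$p, cf2$terms$p, tolerance = 1e-8)
})

test_that("prognostic screen recovers planted genes and skips degenerate ones", {
  detected <- integer(0)
  for (s in 1:4) {
    prog <- data.frame(gene_id = sprintf("PG%d", 1:5), loghr = log(2))
    sim <- simulate_prognostic_cohort(sprintf("BG%02d", 1:95), prog, n = 200,
                                      missing_gleason = 0, seed = 400 + s)
    scr <- prognostic_screen(rownames(sim$expression), sim$expression, sim$records)
    detected <- c(detected, sum(prog$gene_id %in% scr$significant))
  }
  expect_gte(mean(detected >= 4), 0.75)
  # a constant-expression gene is reported as skipped, never fatal
  prog <- data.frame(gene_id = "PG1", loghr = log(2))
  sim <- simulate_prognostic_cohort(c("BG1", "FLAT"), prog, n = 60, seed = 9)
  sim$expression["FLAT", ] <- 7
  scr <- prognostic_screen(rownames(sim$expression), sim$expression, sim$records)
  expect_true("FLAT" %in% scr$skipped$gene_id)
  expect_error(
    prognostic_screen("PG1", sim$expression,
                      transform(sim$records, sample_id = paste0("X", sample_id))),
    class = "metadeg_config")
})

test_that("null genes reach log-rank significance at roughly the alpha rate", {
  hits <- 0; total <- 0
  for (s in 1:2) {
    sim <- simulate_prognostic_cohort(sprintf("BG%03d", 1:200),
                                      data.frame(gene_id = character(), loghr = numeric()),
                                      n = 150, missing_gleason = 0, seed = 500 + s)
    scr <- prognostic_screen(rownames(sim$expression), sim$expression, sim$records)
    hits <- hits + length(scr$significant)
    total <- total + nrow(scr$km)
  }
  expect_gte(hits / total, 0.015)
  expect_lte(hits / total, 0.10)
})
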