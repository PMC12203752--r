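deg_call_for <- function(gene_ids, direction, log2fc = direction * 2,
                         adj_p = 1e-4) {
  out <- data.frame(gene_id = gene_ids, direction = direction,
                    log2fc = log2fc, adj_p = adj_p, stringsAsFactors = FALSE)
  class(out) <- c("deg_call", "data.frame")
  out
}

test_that("the opposing-direction rule removes only significant sign -d controls", {
  opp <- metadeg:::control_opposes
  # up in mets (d = +1): removed only when the control change is significant
  # AND negative (higher baseline in the control tissue)
  expect_true(opp(1, -2, 1e-5, 0.01))
  expect_false(opp(1, -2, 0.5, 0.01))     # not significant
  expect_false(opp(1, 3, 1e-6, 0.01))     # opposes the metastasis direction
  expect_false(opp(1, -2, 0.02, 0.01))    # strict threshold
  expect_true(opp(-1, 2, 1e-4, 0.01))     # symmetric for down-regulated DEGs
  expect_false(opp(1, -2, NA, 0.01))      # untested control gene never removes
})

test_that("tissue filters remove planted tissue-signature genes with named reasons", {
  # cohort whose only planted structure is strong liver-specific expression
  cfg <- sim_config(n_genes = 300, n_met_up = 0, n_met_down = 0,
                    n_tissue_specific = c(liver = 12), tissue_lfc = 6,
                    n_prognostic = 0, sigma_patient = 0.3, seed = 21)
  co <- simulate_cohort(cfg)
  liver_up <- co$truth$tissue_specific$gene_id[co$truth$tissue_specific$direction > 0]
  degs <- deg_call_for(liver_up, direction = 1)

  dec <- tissue_baseline_filter(degs, co$counts, co$samples, alpha = 0.01)
  expect_true(all(!dec$kept))
  expect_true(all(grepl("baseline expression in liver", dec$reason)))

  dec_p <- pooled_tissue_filter(degs, co$counts, co$samples, alpha = 0.01)
  expect_gte(mean(!dec_p$kept), 0.8)  # pooled contrast dilutes but still catches most
})

test_that("per-tissue filter skips undersized control tissues with a warning", {
  cfg <- sim_config(n_genes = 120, n_met_up = 5, n_met_down = 0,
                    n_normals = c(liver = 4, adrenal = 1),
                    n_tissue_specific = c(liver = 0), n_prognostic = 0, seed = 22)
  co <- simulate_cohort(cfg)
  degs <- deg_call_for(co$truth$met_deg$gene_id, 1)
  expect_warning(tissue_baseline_filter(degs, co$counts, co$samples),
                 class = "metadeg_config")
})

test_that("pairwise filter applies the more-than-two-patients boundary exactly", {
  samples <- matched_design(6)
  genes <- c("Gdiv3", "Gdiv2", "Gtie")
  nc <- matrix(100, length(genes), nrow(samples),
               dimnames = list(genes, samples$sample_id))
  set_patient <- function(nc, g, pat, delta) {
    nc[g, sprintf("%s_met1", pat)] <- 100 + delta
    nc[g, sprintf("%s_met2", pat)] <- 100 + delta
    nc
  }
  # gene up in mets globally; divergent (negative within-patient change) in
  # exactly 3 of 6 patients -> removed; in exactly 2 -> kept
  for (p in sprintf("P%02d", 1:3)) nc <- set_patient(nc, "Gdiv3", p, -10)
  for (p in sprintf("P%02d", 4:6)) nc <- set_patient(nc, "Gdiv3", p, +10)
  for (p in sprintf("P%02d", 1:2)) nc <- set_patient(nc, "Gdiv2", p, -10)
  for (p in sprintf("P%02d", 3:6)) nc <- set_patient(nc, "Gdiv2", p, +10)
  # ties (zero difference) count as concordant
  for (p in sprintf("P%02d", 1:2)) nc <- set_patient(nc, "Gtie", p, 0)
  for (p in sprintf("P%02d", 3:6)) nc <- set_patient(nc, "Gtie", p, +10)

  degs <- deg_call_for(genes, direction = 1)
  dec <- pairwise_concordance_filter(degs, nc, samples, max_divergent = 2)
  expect_equal(dec$kept[dec$gene_id == "Gdiv3"], FALSE)
  expect_equal(dec$kept[dec$gene_id == "Gdiv2"], TRUE)
  expect_equal(dec$kept[dec$gene_id == "Gtie"], TRUE)
  expect_match(dec$reason[dec$gene_id == "Gdiv3"], "divergent in 3 of 6")
})

test_that("a two-primary patient is divergent if any comparison diverges", {
  samples <- matched_design(3)
  extra <- data.frame(sample_id = "P01_pri2", patient_id = "P01",
                      category = "primary", tissue = "prostate")
  samples <- rbind(samples, extra)
  nc <- matrix(100, 1, nrow(samples), dimnames = list("G1", samples$sample_id))
  # metastases above primary 1 but below primary 2
  nc["G1", c("P01_met1", "P01_met2")] <- 110
  nc["G1", "P01_pri1"] <- 100
  nc["G1", "P01_pri2"] <- 130
  degs <- deg_call_for("G1", 1)
  dec_any <- pairwise_concordance_filter(degs, nc, samples, max_divergent = 0,
                                         two_primary_rule = "any")
  expect_false(dec_any$kept)
  # averaging the primaries makes the within-patient change negative too,
  # but mean rule collapses to a single comparison
  dec_mean <- pairwise_concordance_filter(degs, nc, samples, max_divergent = 0,
                                          two_primary_rule = "mean")
  expect_false(dec_mean$kept)  # mean primary 115 > met 110: still divergent
  nc["G1", "P01_pri2"] <- 112  # mean 106 < 110: concordant under mean rule
  dec_mean2 <- pairwise_concordance_filter(degs, nc, samples, max_divergent = 0,
                                           two_primary_rule = "mean")
  expect_true(dec_mean2$kept)
  dec_any2 <- pairwise_concordance_filter(degs, nc, samples, max_divergent = 0,
                                          two_primary_rule = "any")
  expect_false(dec_any2$kept)  # pri2 = 112 still above the metastases
})

test_that("discovery preconditions fail before any computation", {
  co <- simulate_cohort(small_sim_config(n_genes = 100, seed = 23))
  s <- co$samples
  expect_error(run_discovery(co$counts, s[s$category != "normal", ]),
               class = "metadeg_config")
  expect_error(run_discovery(co$counts, s[s$category != "bph", ]),
               class = "metadeg_config")
  no_match <- s[!(s$category == "primary"), ]
  expect_error(run_discovery(co$counts, no_match), class = "metadeg_config")
})

test_that("discovery report shrinks monotonically with a complete audit trail", {
  co <- simulate_cohort(small_sim_config(seed = 24))
  rep <- run_discovery(co$counts, co$samples)
  sc <- rep$stage_counts
  expect_equal(sc$stage, c("de", "tissue_per", "tissue_pooled", "bph", "pairwise"))
  # kept set shrinks and counts reconcile between consecutive stages
  expect_true(all(diff(sc$n_kept) <= 0))
  expect_equal(sc$n_in[-1], sc$n_kept[-nrow(sc)])
  expect_true(all(rep$final$gene_id %in% rep$degs$gene_id))
  expect_equal(nrow(rep$final), sc$n_kept[nrow(sc)])
  # every initial DEG has exactly one terminal decision; no decisions after removal
  dec <- rep$decisions[rep$decisions$stage != "de", ]
  for (g in rep$degs$gene_id) {
    dg <- dec[dec$gene_id == g, ]
    if (any(!dg$kept)) {
      expect_equal(sum(!dg$kept), 1)
      expect_false(dg$kept[nrow(dg)])  # removal is the last decision
    } else {
      expect_equal(nrow(dg), 4)        # survived all four filter stages
    }
  }
})

test_that("per-gene decisions do not depend on gene order", {
  co <- simulate_cohort(small_sim_config(n_genes = 400, seed = 25))
  rep1 <- run_discovery(co$counts, co$samples)
  perm <- sample(nrow(co$counts))
  rep2 <- run_discovery(co$counts[perm, ], co$samples)
  expect_setequal(rep1$final$gene_id, rep2$final$gene_id)
})
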