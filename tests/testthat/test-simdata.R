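test_that("config invariants are enforced with the offending field named", {
  expect_error(sim_config(n_pos_signature = 30, n_neg_signature = 20,
                          n_genes = 40), "n_pos_signature")
  expect_error(sim_config(covariate_range = c(10, 5)), "covariate_range")
  expect_error(sim_config(frac_absent = 1.2), "frac_absent")
  expect_error(sim_config(target_r_pos = c(0.9, 0.5)), "target_r_pos")
})

test_that("same seed + config gives identical output, different seed differs", {
  cfg <- sim_config(n_genes = 200, n_samples = 10, n_pos_signature = 5,
                    n_neg_signature = 2, seed = 42)
  s1 <- generate_expression_study(cfg)
  s2 <- generate_expression_study(cfg)
  expect_identical(s1$values, s2$values)
  expect_identical(s1$detected, s2$detected)
  expect_identical(s1$clinical, s2$clinical)
  expect_identical(attr(s1, "truth"), attr(s2, "truth"))
  cfg2 <- sim_config(n_genes = 200, n_samples = 10, n_pos_signature = 5,
                     n_neg_signature = 2, seed = 43)
  expect_false(identical(generate_expression_study(cfg2)$values, s1$values))
})

test_that("pure-null config plants nothing and matches the null r law", {
  cfg <- sim_config(n_genes = 400, n_samples = 12, n_pos_signature = 0,
                    n_neg_signature = 0, frac_absent = 0, seed = 11)
  study <- generate_expression_study(cfg)
  expect_identical(nrow(attr(study, "truth")), 0L)
  pr <- pearson_per_gene(study)
  # under the null, r^2 ~ Beta(1/2, (n-2)/2): check mean within MC error
  expect_lt(abs(mean(pr$pearson_r^2) - 1 / (12 - 1)), 3 * 0.12 / sqrt(400))
})

test_that("planted correlations land in the target bands on average", {
  # Monte-Carlo check of the slope calibration over seeds
  devs <- sapply(1:25, function(s) {
    cfg <- sim_config(n_genes = 300, n_pos_signature = 74, n_neg_signature = 9,
                      frac_absent = 0, seed = s)
    study <- generate_expression_study(cfg)
    truth <- attr(study, "truth")
    pr <- pearson_per_gene(study)
    r <- pr$pearson_r[match(truth$gene_id, pr$gene_id)]
    mean(abs(r)) - mean(truth$target_r)
  })
  expect_lt(abs(mean(devs)), 0.1)
  # and the band midpoints themselves
  cfg <- sim_config(n_genes = 300, frac_absent = 0, seed = 1)
  mid_pos <- mean(cfg$target_r_pos)
  rbar <- mean(sapply(1:25, function(s) {
    cfg <- sim_config(n_genes = 300, frac_absent = 0, seed = s)
    study <- generate_expression_study(cfg)
    truth <- attr(study, "truth")
    pr <- pearson_per_gene(study)
    mean(abs(pr$pearson_r[match(truth$gene_id[truth$direction == "positive"],
                                pr$gene_id)]))
  }))
  expect_lt(abs(rbar - mid_pos), 0.1)
})

test_that("planted-effect monotonicity: higher target |r| -> higher realized |r|", {
  realized <- sapply(c(0.3, 0.6, 0.85), function(rt) {
    mean(sapply(1:10, function(s) {
      cfg <- sim_config(n_genes = 100, n_pos_signature = 20,
                        n_neg_signature = 0, target_r_pos = c(rt, rt),
                        frac_absent = 0, seed = s)
      study <- generate_expression_study(cfg)
      truth <- attr(study, "truth")
      pr <- pearson_per_gene(study)
      mean(abs(pr$pearson_r[match(truth$gene_id, pr$gene_id)]))
    }))
  })
  expect_true(all(diff(realized) > 0))
})

test_that("covariate spans the configured range and carries the cohort labels", {
  cfg <- sim_config(n_genes = 500, seed = 3)
  study <- generate_expression_study(cfg)
  wl <- study$clinical$weight_loss_pct
  expect_equal(min(wl), -0.5)
  expect_equal(max(wl), 43.8)
  expect_identical(study$clinical$wl_label, ifelse(wl >= 5, "WL", "WS"))
  expect_identical(study$clinical$si_flag, study$clinical$crp >= 5)
  expect_identical(sum(wl == 0), 3L)   # control subjects
})

test_that("absent flags hit the configured fraction, independent of truth", {
  cfg <- sim_config(n_genes = 1000, n_pos_signature = 74, n_neg_signature = 9,
                    frac_absent = 0.2, seed = 9)
  study <- generate_expression_study(cfg)
  all_absent <- rowSums(study$detected) == 0
  expect_identical(sum(all_absent), 200L)
  filtered <- filter_all_absent(study)
  expect_identical(nrow(filtered$values), 800L)
})

test_that("promoter planting respects rates, lengths and null exchangeability", {
  motifs <- panel_motifs()
  wm <- motifs$MSYN07_FKHDlong
  # realized insertion rate ~ Poisson(0.8) per fg promoter over seeds
  rate_hat <- mean(sapply(1:5, function(s) {
    cfg <- sim_config(n_fg_promoters = 60, n_bg_promoters = 10,
                      promoter_length = 300,
                      planted_motif_rates = list(MSYN07_FKHDlong = c(0.8, 0.2)),
                      seed = s)
    sets <- generate_promoter_sets(cfg, motifs[c("MSYN07_FKHDlong")])
    profile_set(sets$fg, wm)$total_hits / 60
  }))
  # planted occurrences nearly always exceed the threshold; background rate
  # at 300 bp is small, so the realized hit rate tracks the planting rate
  expect_lt(abs(rate_hat - 0.8), 3 * sqrt(0.8 / 300))
  # motif longer than promoter is rejected
  cfg_bad <- sim_config(promoter_length = 5,
                        planted_motif_rates = list(MSYN07_FKHDlong = c(1, 0)))
  expect_error(generate_promoter_sets(cfg_bad, motifs), "longer than")
  # promoter_length == motif length: insertion occupies the whole sequence
  cfg_eq <- sim_config(n_fg_promoters = 20, n_bg_promoters = 5,
                       promoter_length = ncol(wm$counts),
                       planted_motif_rates = list(MSYN07_FKHDlong = c(3, 0)),
                       seed = 2)
  sets <- generate_promoter_sets(cfg_eq, motifs["MSYN07_FKHDlong"])
  expect_true(all(nchar(sets$fg) == ncol(wm$counts)))
  # null planting: determinism + fg/bg generated from the same law
  cfg0 <- sim_config(n_fg_promoters = 20, n_bg_promoters = 20,
                     promoter_length = 100, seed = 7)
  a <- generate_promoter_sets(cfg0, motifs)
  b <- generate_promoter_sets(cfg0, motifs)
  expect_identical(a, b)
})

test_that("Ct tables have the stated structure and recover planted signs", {
  cfg <- sim_config(n_genes = 100, n_samples = 12, n_pos_signature = 3,
                    n_neg_signature = 0, frac_absent = 0, seed = 21)
  study <- generate_expression_study(cfg)
  truth <- attr(study, "truth")
  expect_error(generate_ct_table(cfg, study, "NOPE"), "unknown gene")
  ct <- generate_ct_table(cfg, study, truth$gene_id)
  expect_true(all(table(ct$sample_id, ct$gene_id) == 3))
  # zero replicate noise -> identical triplicates
  cfg0 <- sim_config(n_genes = 100, n_samples = 12, n_pos_signature = 3,
                     n_neg_signature = 0, frac_absent = 0, ct_rep_sd = 0,
                     seed = 21)
  st0 <- generate_expression_study(cfg0)
  ct0 <- generate_ct_table(cfg0, st0, attr(st0, "truth")$gene_id)
  sds <- tapply(ct0$ct, paste(ct0$sample_id, ct0$gene_id), sd)
  expect_true(all(sds == 0))
  # -deltaCt correlates positively with the covariate for planted-positive
  # genes in nearly all seeds
  signs <- sapply(1:40, function(s) {
    cfgs <- sim_config(n_genes = 60, n_samples = 12, n_pos_signature = 1,
                       n_neg_signature = 0, frac_absent = 0, seed = s)
    st <- generate_expression_study(cfgs)
    g <- attr(st, "truth")$gene_id
    dct <- delta_ct(generate_ct_table(cfgs, st, g))
    dct <- dct[match(st$clinical$sample_id, dct$sample_id), ]
    cor(-dct$delta_ct, st$clinical$weight_loss_pct) > 0
  })
  expect_gte(mean(signs), 0.95)
})
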