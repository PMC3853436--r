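test_that("invalid configurations are rejected with the offending field named", {
  expect_error(synthetic_config(n_mirna = 0), "n_mirna")
  expect_error(synthetic_config(rho = 1), "rho")
  expect_error(synthetic_config(rho = -0.1), "rho")
  expect_error(synthetic_config(noise_sd = 0), "noise_sd")
  expect_error(synthetic_config(n_mirna = 10, n_hubs = 3, module_size = 5),
               "module_size")
  expect_error(synthetic_config(de_fraction = 1.5), "de_fraction")
  expect_error(synthetic_config(hazard_ratio = 0), "hazard_ratio")
})

test_that("identical config and seed give bit-identical datasets", {
  cfg <- synthetic_config(n_mirna = 40, n_hubs = 3, module_size = 4,
                          n_genes = 150, seed = 99)
  s1 <- generate_dual_dataset(cfg)
  s2 <- generate_dual_dataset(cfg)
  expect_identical(s1$mirna, s2$mirna)
  expect_identical(s1$mrna, s2$mrna)
  expect_identical(s1$targets, s2$targets)
  expect_identical(s1$survival, s2$survival)
  expect_identical(s1$truth, s2$truth)
  s3 <- generate_dual_dataset(synthetic_config(n_mirna = 40, n_hubs = 3,
                                               module_size = 4,
                                               n_genes = 150, seed = 100))
  expect_false(identical(s1$mirna, s3$mirna))
})

test_that("null configuration produces pairwise-independent features and empty truth", {
  cfg <- synthetic_config(n_class_a = 100, n_class_b = 100, n_mirna = 30,
                          n_hubs = 1, module_size = 1, rho = 0,
                          de_fraction = 0, coupling = 0, seed = 5)
  sim <- generate_dual_dataset(cfg)
  expect_equal(nrow(sim$truth$de_ids), 0)
  C <- cor(t(sim$mirna))
  expect_lt(max(abs(C[upper.tri(C)])), 0.35)  # n=200 null correlations
  # targeted genes carry no miRNA signal when coupling = 0
  g1 <- sim$targets[[1]][1]
  expect_lt(abs(cor(sim$mrna[g1, ], sim$mirna[1, ])), 0.35)
})

test_that("planted module correlations match the latent-factor closed forms", {
  # hub = shared factor, members load rho: hub-member r = rho,
  # member-member r = rho^2
  rho <- 0.9
  hm <- mm <- c()
  for (s in 1:3) {
    cfg <- synthetic_config(n_class_a = 100, n_class_b = 100, n_mirna = 60,
                            n_hubs = 3, module_size = 5, rho = rho,
                            de_fraction = 0, seed = s)
    sim <- generate_dual_dataset(cfg)
    for (h in sim$truth$hub_ids) {
      mem <- sim$truth$module_members[[h]]
      C <- cor(t(sim$mirna[c(h, mem), ]))
      hm <- c(hm, C[1, -1])
      mm <- c(mm, C[-1, -1][upper.tri(C[-1, -1])])
    }
  }
  expect_lt(abs(mean(hm) - rho), 0.05)
  expect_lt(abs(mean(mm) - rho^2), 0.05)
})

test_that("marginal variance stays near 1 without class shifts", {
  cfg <- synthetic_config(n_class_a = 120, n_class_b = 120, n_mirna = 80,
                          n_hubs = 5, module_size = 5, de_fraction = 0,
                          seed = 11)
  sim <- generate_dual_dataset(cfg)
  v <- apply(sim$mirna, 1, var)
  expect_true(all(v > 0.7 & v < 1.3))
})

test_that("planted class shifts are detectable at the designed power", {
  # d = 2 at n = 15 + 41: two-sample t-test power at alpha = 0.01 is ~1;
  # every planted feature across 5 seeds should reject
  rejections <- c()
  for (s in 1:5) {
    cfg <- synthetic_config(de_fraction = 0.2, effect_size = 2, n_mirna = 50,
                            n_hubs = 2, module_size = 3, n_genes = 100,
                            seed = s)
    sim <- generate_dual_dataset(cfg)
    lab <- sample_labels(sim$mirna)
    a <- lab == "basal_like"
    for (id in sim$truth$de_ids$mirna) {
      p <- t.test(sim$mirna[id, a], sim$mirna[id, !a])$p.value
      rejections <- c(rejections, p < 0.01)
    }
  }
  expect_gt(mean(rejections), 0.9)
})

test_that("regression on a targeted gene recovers the coupling coefficient", {
  cfg <- synthetic_config(n_class_a = 100, n_class_b = 100, n_mirna = 20,
                          n_hubs = 1, module_size = 2, de_fraction = 0,
                          n_genes = 100, coupling = -0.8, noise_sd = 0.5,
                          seed = 21)
  sim <- generate_dual_dataset(cfg)
  cm <- sim$truth$coupling_map
  # pick genes targeted by exactly one miRNA so the coefficient is direct
  single <- names(which(table(cm$gene) == 1))
  row <- cm[match(single[1:5], cm$gene), ]
  for (i in seq_len(nrow(row))) {
    fit <- lm(sim$mrna[row$gene[i], ] ~ sim$mirna[row$mirna[i], ])
    est <- coef(summary(fit))[2, ]
    expect_lt(abs(est["Estimate"] - row$coefficient[i]),
              3 * est["Std. Error"])
  }
})

test_that("survival times respect the planted hazard ratio and censoring rule", {
  cfg <- synthetic_config(n_class_a = 150, n_class_b = 150, n_mirna = 10,
                          n_hubs = 1, module_size = 1, n_genes = 50,
                          hazard_ratio = 4, seed = 31)
  sim <- generate_dual_dataset(cfg)
  expect_equal(mean(sim$survival$event), 0.75, tolerance = 0.01)
  lab <- sample_labels(sim$mirna)
  b <- lab[sim$survival$sample_id] == "luminal_A"
  # class-B events come 4x faster: median uncensored time much smaller
  expect_lt(median(sim$survival$time[b]), median(sim$survival$time[!b]))
  fit <- survival::coxph(survival::Surv(time, event) ~ b, data = sim$survival)
  expect_equal(unname(exp(coef(fit))), 4, tolerance = 0.35)
})

test_that("every coupled gene appears in the emitted target map", {
  sim <- generate_dual_dataset(synthetic_config(n_mirna = 25, n_hubs = 2,
                                                module_size = 3,
                                                n_genes = 80, seed = 41))
  cm <- sim$truth$coupling_map
  for (i in sample(nrow(cm), 20))
    expect_true(cm$gene[i] %in% sim$targets[[cm$mirna[i]]])
  expect_true(all(sim$truth$hub_ids %in% rownames(sim$mirna)))
})
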