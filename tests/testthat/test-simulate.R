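test_that("configuration validation rejects inconsistent settings", {
  expect_error(sim_config(true_weights = c(0.7, 0.7)), "simplex")
  expect_error(sim_config(true_weights = c(-0.2, 1.2)), "simplex")
  expect_error(sim_config(ld_rho = 1), "\\[0, 1\\)")
  expect_error(sim_config(expr_h2 = 1), "\\[0, 1\\)")
  expect_error(sim_config(expr_h2 = 0.5, n_causal_eqtl = 0), "causal")
  expect_error(sim_config(maf_range = c(0.005, 0.4)), "MAF")
  expect_error(sim_config(panel_sizes = 100), "one entry per ancestry")
  expect_error(simulate_genotypes(sim_config(), 3), "1..n_ancestries")
})

test_that("default panels have the study-scale shapes and dosage bounds", {
  cfg <- sim_config(n_snps = 8, seed = 2)
  p1 <- simulate_genotypes(cfg, 1)
  p2 <- simulate_genotypes(cfg, 2)
  expect_identical(dim(p1$genotypes), c(1032L, 8L))
  expect_identical(dim(p2$genotypes), c(801L, 8L))
  expect_true(all(p1$genotypes %in% 0:2))
  expect_true(all(p1$allele_freqs > 0.01 & p1$allele_freqs <= 0.5))
})

test_that("uncorrelated haplotypes give near-independent dosages", {
  cfg <- sim_config(panel_sizes = c(1000, 1000), n_snps = 10, ld_rho = 0,
                    seed = 5)
  G <- simulate_genotypes(cfg, 1)$genotypes
  C <- cor(G)
  expect_lt(max(abs(C[upper.tri(C)])), 0.1)
})

test_that("AR(1) dosage LD matches a direct latent-MVN oracle", {
  skip_if_not_installed("MASS")
  rho <- 0.5; p <- 10; n <- 2000
  acc <- matrix(0, p, p)
  n_seeds <- 20
  for (s in seq_len(n_seeds)) {
    cfg <- sim_config(panel_sizes = c(n, n), n_snps = p, ld_rho = rho,
                      maf_range = c(0.2, 0.4), seed = 100 + s)
    acc <- acc + cor(simulate_genotypes(cfg, 1)$genotypes)
  }
  emp <- acc / n_seeds
  # oracle: same thresholding applied to exact MVN haplotypes at 10x n
  set.seed(77)
  Sigma <- rho^abs(outer(1:p, 1:p, "-"))
  f <- runif(p, 0.2, 0.4); thr <- qnorm(1 - f)
  H <- function() sweep(MASS::mvrnorm(10 * n, rep(0, p), Sigma), 2, thr, ">")
  Gor <- H() + H()
  expect_lt(max(abs(emp - cor(Gor))), 0.05)
})

test_that("identical seed and config reproduce bit-identical panels", {
  cfg <- quick_config(seed = 9)
  a <- simulate_expression(simulate_genotypes(cfg, 1), cfg)
  b <- simulate_expression(simulate_genotypes(cfg, 1), cfg)
  expect_identical(a, b)
  cfg2 <- quick_config(seed = 10)
  expect_false(identical(simulate_genotypes(cfg2, 1)$genotypes,
                         a$genotypes))
})

test_that("panels with identical parameters are exchangeable in distribution", {
  means1 <- means2 <- numeric(20)
  for (s in 1:20) {
    cfg <- sim_config(panel_sizes = c(400, 400), n_snps = 10, seed = 300 + s)
    means1[s] <- mean(simulate_genotypes(cfg, 1)$genotypes)
    means2[s] <- mean(simulate_genotypes(cfg, 2)$genotypes)
  }
  expect_gt(stats::t.test(means1, means2)$p.value, 1e-3)
  expect_lt(abs(sd(means1) - sd(means2)), 0.1)
})

test_that("expression follows the variance decomposition of the eQTL model", {
  # null architecture: unit variance, no strong SNP association
  cfg0 <- sim_config(panel_sizes = c(1000, 1000), n_snps = 20,
                     n_causal_eqtl = 0, expr_h2 = 0, seed = 21)
  pan0 <- simulate_expression(simulate_genotypes(cfg0, 1), cfg0)
  expect_equal(var(pan0$expression), 1, tolerance = 1e-8)
  expect_true(all(pan0$true_betas == 0))
  r <- abs(cor(pan0$expression, pan0$genotypes))
  expect_lt(max(r), 6 / sqrt(1000))   # noise-level associations only

  # heritable architecture: mean genetic R^2 near the target h2
  r2 <- vapply(1:40, function(s) {
    cfg <- sim_config(panel_sizes = c(500, 500), n_snps = 20,
                      expr_h2 = 0.5, seed = 400 + s)
    pan <- simulate_expression(simulate_genotypes(cfg, 1), cfg)
    g <- metrotwas:::standardize_columns(pan$genotypes) %*% pan$true_betas
    cor(g, pan$expression)^2
  }, numeric(1))
  expect_gt(mean(r2), 0.45)
  expect_lt(mean(r2), 0.55)

  # expression length matches the panel and is unit-variance
  cfg <- quick_config(seed = 31)
  pan <- simulate_expression(simulate_genotypes(cfg, 1), cfg)
  expect_length(pan$expression, nrow(pan$genotypes))
  expect_equal(var(pan$expression), 1, tolerance = 1e-8)
})

test_that("noiseless expression equals the genetic component exactly", {
  cfg <- sim_config(panel_sizes = c(200, 200), n_snps = 10,
                    expr_h2 = 1 - 1e-9, seed = 8)
  pan <- simulate_expression(simulate_genotypes(cfg, 1), cfg)
  g <- drop(metrotwas:::standardize_columns(pan$genotypes) %*% pan$true_betas)
  expect_equal(as.numeric(scale(g)), pan$expression, tolerance = 1e-3)
})

test_that("null GWAS z-scores have unit chi-square mean and exact LD diagonal", {
  z2 <- numeric(0)
  for (s in 1:200) {
    cfg <- sim_config(panel_sizes = c(50, 50), n_snps = 5, n_gwas = 500,
                      true_alpha = 0, seed = 600 + s)
    gw <- simulate_gwas_summary(cfg)
    z2 <- c(z2, gw$z^2)
  }
  expect_gt(mean(z2), 0.9)
  expect_lt(mean(z2), 1.1)
  gw <- simulate_gwas_summary(quick_config(seed = 3, true_alpha = 0))
  expect_identical(unname(diag(gw$ld)), rep(1, length(gw$z)))
  expect_identical(gw$ld, t(gw$ld))
  # shrinkage guarantees positive definiteness
  ev <- eigen(metrotwas:::shrink_ld(gw$ld), only.values = TRUE)$values
  expect_gt(min(ev), 0)
})

test_that("a causal SNP's expected chi-square matches its non-centrality", {
  # one causal SNP explaining q = alpha^2 = 0.01 of trait variance at n = 5000
  z2 <- vapply(1:200, function(s) {
    cfg <- sim_config(panel_sizes = c(50, 50), n_snps = 4, n_gwas = 5000,
                      n_causal_eqtl = 1, true_alpha = 0.1, ld_rho = 0,
                      seed = 900 + s)
    beta <- c(1, 0, 0, 0)
    simulate_gwas_summary(cfg, composite_beta = beta)$z[1]^2
  }, numeric(1))
  expect_gt(mean(z2), 1 + 5000 * 0.01 * 0.85)
  expect_lt(mean(z2), 1 + 5000 * 0.01 * 1.15)
})

test_that("a GReX effect with no eQTL signal warns", {
  cfg <- quick_config(seed = 4)
  expect_warning(simulate_gwas_summary(cfg, composite_beta = numeric(20)),
                 "no genetic signal")
})

test_that("simulated regions have the declared causal structure", {
  cfg <- sim_config(n_gwas = 1500, n_snps = 12, n_causal_eqtl = 3, seed = 13)
  expect_error(simulate_region(cfg, 3, causal_gene = 4), "1..n_genes")

  # degenerate single-gene region carries signal in expectation
  reg <- simulate_region(cfg, 1, causal_gene = 1)
  z1 <- twas_zscores(reg$scenario$true_weights, reg$gwas)
  expect_gt(abs(z1$z), 2)

  # null region: gene-level Z scores null-distributed over replicates
  zs <- unlist(lapply(1:40, function(s) {
    cfg_s <- sim_config(n_gwas = 800, n_snps = 10, n_causal_eqtl = 2,
                        seed = 1300 + s)
    reg <- simulate_region(cfg_s, 3, causal_gene = NULL)
    twas_zscores(reg$scenario$true_weights, reg$gwas)$z
  }))
  expect_lt(abs(mean(zs)), 0.15)
  expect_gt(sd(zs), 0.8); expect_lt(sd(zs), 1.2)

  # overlapping cis-windows induce GReX correlation between neighbours,
  # checked directly on simulated GReX vectors drawn from the region's law
  cfg5 <- sim_config(n_gwas = 3000, n_snps = 20, n_causal_eqtl = 5, seed = 17)
  reg5 <- simulate_region(cfg5, 5, causal_gene = NULL, overlap = 0.5)
  set.seed(18)
  p_tot <- nrow(reg5$scenario$true_weights)
  f <- runif(p_tot, 0.05, 0.5); thr <- qnorm(1 - f)
  G <- (sweep(metrotwas:::latent_ar1(5000, p_tot, 0.5), 2, thr, ">") +
        sweep(metrotwas:::latent_ar1(5000, p_tot, 0.5), 2, thr, ">")) * 1
  grex <- metrotwas:::standardize_columns(G) %*% reg5$scenario$true_weights
  emp <- cor(grex)
  expect_gt(max(abs(emp[cbind(1:4, 2:5)])), 0.05)
})
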