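test_that("z_from_p matches the inverse-normal oracle at all scales", {
  expect_identical(z_from_p(1), 0)
  # frozen oracle values (high-precision inverse normal CDF)
  expect_equal(z_from_p(0.05), 1.9599639845400545, tolerance = 1e-10)
  expect_equal(z_from_p(5.44e-12, -1), -6.893594374032168, tolerance = 1e-9)
  # log-scale path keeps extreme p-values finite and monotone
  expect_true(is.finite(z_from_p(1e-320)))
  expect_gt(z_from_p(1e-320), z_from_p(1e-300))
  expect_error(z_from_p(0), "\\(0, 1\\]")
  expect_error(z_from_p(-0.1), "\\(0, 1\\]")
  expect_error(z_from_p(0.5, 0), "nonzero")
})

test_that("genes are partitioned into half-open LD blocks", {
  genes <- tibble::tibble(gene_id = c("a", "b", "c"), chr = 1,
                          tss = c(100, 200, 250))
  one <- tibble::tibble(chr = 1, start = 0, end = 1000)
  expect_identical(unique(assign_blocks(genes, one)$block_id), "block_001")

  # TSS exactly at a block end belongs to the following block
  two <- tibble::tibble(chr = 1, start = c(0, 200), end = c(200, 400))
  out <- assign_blocks(genes, two)
  expect_identical(out$block_id, c("block_001", "block_002", "block_002"))

  expect_error(assign_blocks(genes, tibble::tibble(chr = 1,
                                                   start = c(0, 100),
                                                   end = c(150, 300))),
               "overlap")
  far <- tibble::tibble(gene_id = "zz", chr = 2, tss = 5)
  expect_warning(out2 <- assign_blocks(far, two), "outside")
  expect_match(out2$block_id, "singleton")
})

test_that("random gene/block layouts match a brute-force containment scan", {
  set.seed(101)
  for (rep in 1:5) {
    starts <- sort(sample(0:500, 6)) * 10
    blocks <- tibble::tibble(chr = 1, start = starts[c(1, 3, 5)],
                             end = starts[c(2, 4, 6)])
    genes <- tibble::tibble(gene_id = sprintf("g%02d", 1:30), chr = 1,
                            tss = sample(0:6000, 30))
    got <- suppressWarnings(assign_blocks(genes, blocks))
    oracle <- vapply(genes$tss, function(x) {
      j <- NA_character_
      for (k in seq_len(nrow(blocks)))
        if (blocks$start[k] <= x && x < blocks$end[k])
          j <- sprintf("block_%03d", k)
      j
    }, character(1))
    matched <- !is.na(oracle)
    expect_identical(got$block_id[matched], oracle[matched])
    expect_true(all(grepl("singleton", got$block_id[!matched])))
  }
})

test_that("GReX correlation matches its quadratic form and an MC oracle", {
  # identical weight vectors correlate exactly
  b <- c(1, 0.5, 0, -0.2)
  W <- cbind(g1 = b, g2 = b)
  R <- metrotwas:::shrink_ld(diag(4), 0)
  expect_equal(gene_correlation(W, R)["g1", "g2"], 1, tolerance = 1e-4)
  # disjoint supports under independent SNPs are uncorrelated
  W2 <- cbind(g1 = c(1, 1, 0, 0), g2 = c(0, 0, 1, 1))
  expect_equal(gene_correlation(W2, diag(4))["g1", "g2"], 0,
               tolerance = 1e-12)
  expect_error(gene_correlation(cbind(g1 = b, g2 = rep(0, 4)), diag(4)),
               "zero-norm.*g2")

  # Monte-Carlo oracle: empirical correlation of simulated GReX at n = 50000
  cfg <- sim_config(n_gwas = 2000, n_snps = 16, n_causal_eqtl = 4,
                    seed = 115)
  reg <- simulate_region(cfg, 4, causal_gene = NULL, overlap = 0.5)
  set.seed(116)
  p_tot <- nrow(reg$scenario$true_weights)
  f <- runif(p_tot, 0.05, 0.5); thr <- qnorm(1 - f)
  G <- (sweep(metrotwas:::latent_ar1(50000, p_tot, 0.5), 2, thr, ">") +
        sweep(metrotwas:::latent_ar1(50000, p_tot, 0.5), 2, thr, ">")) * 1
  grex <- metrotwas:::standardize_columns(G) %*% reg$scenario$true_weights
  sig <- gene_correlation(reg$scenario$true_weights, cor(G))
  expect_lt(max(abs(cor(grex) - sig)), 0.02)
})

test_that("posterior enumeration matches an exhaustive independent oracle", {
  skip_if_not_installed("mvtnorm")
  set.seed(120)
  for (rep in 1:5) {
    k <- 3
    A <- matrix(rnorm(k * k), k)
    sigma <- stats::cov2cor(crossprod(A) + diag(k))
    z <- rnorm(k, sd = 2)
    got <- focus_pip(tibble::tibble(gene_id = letters[1:k], z = z),
                     sigma, prior_causal = 0.2, prior_var = 30,
                     max_causal = 3)
    want <- oracle_pip(z, sigma, prior_causal = 0.2, prior_var = 30)
    expect_equal(got$genes$pip, want$pip, tolerance = 1e-8)
    expect_equal(got$null_posterior, want$null_posterior, tolerance = 1e-8)
    expect_equal(sum(got$configs$posterior), 1, tolerance = 1e-8)
  }
  # k = 4 with restricted configuration size still matches the same
  # enumeration truncated to |c| <= 2
  k <- 4
  sigma <- diag(k)
  z <- c(3, -1, 0.5, 2)
  got <- focus_pip(tibble::tibble(gene_id = letters[1:k], z = z), sigma,
                   prior_causal = 0.15, prior_var = 20, max_causal = 4)
  want <- oracle_pip(z, sigma, 0.15, 20)
  expect_equal(got$genes$pip, want$pip, tolerance = 1e-8)
})

test_that("fine-mapping has the expected limits", {
  # overwhelming single-gene evidence
  one <- focus_pip(tibble::tibble(gene_id = "g", z = 10), matrix(1, 1, 1))
  expect_gt(one$genes$pip, 0.99)
  # perfectly correlated genes with equal z are exchangeable
  sig <- matrix(c(1, 1 - 1e-6, 1 - 1e-6, 1), 2)
  two <- focus_pip(tibble::tibble(gene_id = c("a", "b"), z = c(4, 4)), sig)
  expect_lt(abs(two$genes$pip[1] - two$genes$pip[2]), 1e-6)
  # no evidence: the null model dominates all configurations
  nul <- focus_pip(tibble::tibble(gene_id = letters[1:3], z = rep(0, 3)),
                   diag(3))
  expect_identical(nul$configs$config[which.max(nul$configs$posterior)],
                   "<null>")
  expect_true("<null>" %in% nul$credible_set)
})

test_that("credible sets take the minimal posterior-ranked prefix", {
  fake <- structure(
    list(genes = tibble::tibble(gene_id = c("g1", "g2", "g3"),
                                z = c(5, 4, 3),
                                pip = c(0.5, 0.3, 0.15)),
         null_posterior = 0.05,
         credible_level = 0.9),
    class = "finemap_result")
  expect_identical(credible_set(fake, 0.9), c("g1", "g2", "g3"))
  expect_identical(credible_set(fake, 0.7), c("g1", "g2"))
  expect_identical(credible_set(fake, 1.0), c("g1", "g2", "g3", "<null>"))
  # monotone in the level
  sizes <- vapply(seq(0.1, 1, by = 0.1),
                  function(l) length(credible_set(fake, l)), numeric(1))
  expect_true(all(diff(sizes) >= 0))
  oner <- structure(
    list(genes = tibble::tibble(gene_id = "g1", z = 6, pip = 0.95),
         null_posterior = 0.05, credible_level = 0.9),
    class = "finemap_result")
  expect_identical(credible_set(oner, 0.9), "g1")
})

test_that("region fine-mapping identifies a strongly causal gene", {
  cfg <- sim_config(n_gwas = 4000, n_snps = 16, n_causal_eqtl = 3,
                    true_alpha = 0.12, seed = 130)
  reg <- simulate_region(cfg, 5, causal_gene = 3)
  fr <- finemap_region(reg)
  expect_identical(
    fr$genes$gene_id[which.max(fr$genes$pip)],
    reg$scenario$genes$gene_id[3])
  expect_true(all(fr$genes$pip >= 0 & fr$genes$pip <= 1))
  expect_equal(sum(fr$configs$posterior), 1, tolerance = 1e-8)
  gl <- glance(fr)
  expect_identical(gl$credible_level, 0.9)
})
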