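# Shared fixtures and independent oracles used across the suite.

# Small two-ancestry configuration for fast end-to-end runs.
quick_config <- function(seed = 1, ...) {
  sim_config(panel_sizes = c(300, 300), n_snps = 20, n_gwas = 2000,
             seed = seed, ...)
}

# Two fitted ridge models plus a matched GWAS under the configured truth.
quick_pipeline <- function(cfg, alpha = cfg$true_alpha) {
  panels <- lapply(seq_len(cfg$n_ancestries), function(m)
    simulate_expression(simulate_genotypes(cfg, m), cfg))
  models <- lapply(panels, fit_expression_model, method = "ridge")
  beta <- Reduce(`+`, Map(function(p, w) w * p$true_betas,
                          panels, cfg$true_weights))
  cfg$true_alpha <- alpha
  gwas <- simulate_gwas_summary(cfg, composite_beta = beta)
  list(panels = panels, models = models, gwas = gwas, beta = beta)
}

# Independent fine-mapping oracle: full 2^k enumeration scored with
# mvtnorm's density, no shared code with focus_pip().
oracle_pip <- function(z, sigma, prior_causal, prior_var) {
  k <- length(z)
  scores <- numeric(2^k)
  members <- vector("list", 2^k)
  for (mask in 0:(2^k - 1)) {
    cfg <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0)
    V <- sigma
    if (length(cfg)) {
      Sc <- sigma[, cfg, drop = FALSE]
      V <- V + prior_var * Sc %*% t(Sc)
    }
    scores[mask + 1] <- mvtnorm::dmvnorm(z, sigma = V, log = TRUE) +
      length(cfg) * log(prior_causal) +
      (k - length(cfg)) * log(1 - prior_causal)
    members[[mask + 1]] <- cfg
  }
  post <- exp(scores - max(scores)); post <- post / sum(post)
  list(
    pip = vapply(seq_len(k), function(i)
      sum(post[vapply(members, function(m) i %in% m, logical(1))]),
      numeric(1)),
    null_posterior = post[1]
  )
}

# Set-algebra oracle for Venn regions: intersection of the members minus the
# union of the non-members.
oracle_venn <- function(sets) {
  nm <- names(sets)
  out <- list()
  for (size in seq_along(sets)) {
    for (idx in utils::combn(length(sets), size, simplify = FALSE)) {
      inter <- Reduce(intersect, sets[idx])
      others <- unlist(sets[-idx])
      out[[paste(nm[idx], collapse = "&")]] <-
        length(setdiff(inter, others))
    }
  }
  out
}

# Combinatorial upper-tail hypergeometric sum.
oracle_hyper <- function(overlap, set_size, universe, query) {
  i <- overlap:min(set_size, query)
  sum(choose(set_size, i) * choose(universe - set_size, query - i)) /
    choose(universe, query)
}
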