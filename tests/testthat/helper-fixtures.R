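# shared fixtures and oracles for the test suite

# small simulated panel, standardized, with phenotype and split
make_panel <- function(n = 120, p = 60, seed = 7,
                       maf_range = c(0.1, 0.45), ...) {
  # common-variant range so small test panels have no monomorphic columns
  cfg <- simulation_config(n_individuals = n, n_snps = p, seed = seed,
                           maf_range = maf_range, ...)
  G <- simulate_genotypes(cfg)
  Gstd <- standardize_genotypes(G)
  ph <- simulate_phenotype(Gstd, cfg)
  sp <- split_data(n, cfg$train_fraction, seed = seed)
  list(cfg = cfg, G = G, Gstd = Gstd, ph = ph, sp = sp)
}

# hand-construct a genotype_matrix from a dosage matrix
toy_genotypes <- function(values) {
  ldrisk:::new_genotype_matrix(
    values,
    snp_ids = paste0("s", seq_len(ncol(values))),
    sample_ids = paste0("i", seq_len(nrow(values))))
}

# central-difference gradient check of a built model against backprop;
# returns the worst relative error over sampled parameters and inputs
gradcheck_model <- function(model, x, n_checks = 10, eps = 1e-5, seed = 99) {
  set.seed(seed)
  fw <- ldrisk:::model_forward(model, x, training = FALSE)
  tgt <- array(rnorm(length(fw$out)), dim(fw$out))
  loss_at <- function(m, xx) {
    out <- ldrisk:::model_forward(m, xx, training = FALSE)$out
    mean((out - tgt)^2)
  }
  dout <- 2 * (fw$out - tgt) / length(fw$out)
  grads <- ldrisk:::model_backward(model, fw$caches, dout)
  worst <- 0
  for (k in seq_along(model$layers)) {
    for (nm in names(model$layers[[k]]$params)) {
      p <- model$layers[[k]]$params[[nm]]
      for (i in sample(length(p), min(n_checks, length(p)))) {
        m2 <- model
        m2$layers[[k]]$params[[nm]][i] <- p[i] + eps
        lp <- loss_at(m2, x)
        m2$layers[[k]]$params[[nm]][i] <- p[i] - eps
        lm <- loss_at(m2, x)
        num <- (lp - lm) / (2 * eps)
        ana <- grads[[k]][[nm]][i]
        worst <- max(worst, abs(num - ana) / max(1e-4, abs(num) + abs(ana)))
      }
    }
  }
  worst
}

var_pop <- function(v) mean((v - mean(v))^2)
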