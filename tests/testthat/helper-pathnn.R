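# shared fixtures, built in code at test time

tiny_vocab <- function(n = 4) class_vocabulary(paste0("c", seq_len(n)))

# a small deterministic variant table
tiny_table <- function(vocab = tiny_vocab()) {
  variant_table(data.frame(
    sample_id = c("s1", "s1", "s1", "s2", "s2", "s3"),
    gene_id = c("g1", "g1", "g2", "g1", "g3", "g2"),
    functional_class = c("c1", "c1", "c2", "c3", "c1", "c4")), vocab)
}

# random variant table for property tests
random_table <- function(n_rec = 200, n_samples = 6, n_genes = 5,
                         vocab = tiny_vocab(), seed = 1) {
  set.seed(seed)
  variant_table(data.frame(
    sample_id = sample(paste0("s", seq_len(n_samples)), n_rec, TRUE),
    gene_id = sample(paste0("g", seq_len(n_genes)), n_rec, TRUE),
    functional_class = sample(unclass(vocab), n_rec, TRUE)), vocab)
}

# quick standardized tensor + labels with an additive signal
toy_data <- function(n = 300, G = 10, C = 4, seed = 1, beta = 1.5,
                     n_signal = 3, noise = 0.5, prevalence = 0.5) {
  cfg <- sim_config(n, G, n_pathways = 3, classes = tiny_vocab(C),
                    rate = 0.3, prevalence = prevalence,
                    additive = data.frame(gene = seq_len(n_signal),
                                          beta = beta),
                    noise_sd = noise, seed = seed)
  simulate_cohort(cfg)
}

default_gm <- function(C = 4, h = 4) gene_module_spec(C, h)

train_quick <- function(model, X, y, epochs = 5, seed = 1, ...) {
  train(model, X, y, train_config(epochs = epochs, seed = seed, ...))
}

logit <- function(p) log(p / (1 - p))
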