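#!/usr/bin/env Rscript
# Build the synthetic study inputs: the LamB-like reference amplicon, the
# ground-truth fitness model, and the two error-prone PCR libraries (high
# mutagenesis for the phage-lambda selection, low for the maltodextrin
# selection). Reports the mutational loads and writes the ground truth.

library(lambscan)
dir.create("results", showWarnings = FALSE)
seed <- 1L

ref <- synthetic_reference()
print(ref)

model <- fitness_model(ref, seed = derive_seed(seed, "model"))
print(model)
truth <- single_mutant_truth(model)
write_tsv(truth, "results/ground_truth_single_mutants.tsv",
          header = sprintf("seed=%d", seed))

cfg <- experiment_config(seed = seed)
hi <- generate_library(ref, library_spec(cfg$lambda_n_variants, cfg$lambda_rate,
  seed = derive_seed(seed, "library_lambda")))
lo <- generate_library(ref, library_spec(cfg$malt_n_variants, cfg$malt_rate,
  seed = derive_seed(seed, "library_malt")))
print(hi)
print(lo)
cat(sprintf(
  "high-rate library: %.2f mutations/variant (expected %.2f)\n",
  mutation_load(hi), cds_length(ref) * cfg$lambda_rate))
cat(sprintf(
  "low-rate library:  %.3f mutations/variant (expected %.3f)\n",
  mutation_load(lo), cds_length(ref) * cfg$malt_rate))

fit_hi <- variant_fitness(hi, model)
write_library_truth(hi, fit_hi,
                    "results/ground_truth_lambda_library.tsv",
                    header = sprintf("seed=%d", seed))
cat(sprintf(
  "fraction of high-rate variants still lambda-sensitive (f >= 0.5): %.2f\n",
  mean(fit_hi$f_lambda_sensitivity >= 0.5)))
write_tsv(data.frame(
  library = c("lambda", "malt"),
  n_variants = c(hi$n_variants, lo$n_variants),
  per_base_rate = c(cfg$lambda_rate, cfg$malt_rate),
  mutations_per_variant = c(mutation_load(hi), mutation_load(lo))
), "results/library_summary.tsv", header = sprintf("seed=%d", seed))
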