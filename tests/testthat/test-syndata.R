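test_that("zero mutagenesis rate yields a wild-type library", {
  ref <- small_reference()
  lib <- generate_library(ref, library_spec(50, 0, seed = 1))
  expect_equal(nrow(lib$mutations), 0L)
  expect_equal(mutation_load(lib), 0)
  expect_equal(sum(lib$abundance), 1)
})

test_that("mutational load matches the Poisson-binomial expectation", {
  ref <- synthetic_reference()
  L <- cds_length(ref)
  for (rate in c(0.0052, 0.00063)) {
    n <- 5000
    lib <- generate_library(ref, library_spec(n, rate, seed = 11))
    expected <- L * rate
    se <- sqrt(L * rate * (1 - rate) / n)
    expect_lt(abs(mutation_load(lib) - expected), 3 * se)
    # per-variant positions unique, alt always differs from ref
    expect_equal(anyDuplicated(lib$mutations[, c("variant_id", "pos")]), 0L)
    expect_false(any(lib$mutations$ref == lib$mutations$alt))
  }
})

test_that("library generation is deterministic under a fixed seed", {
  ref <- small_reference()
  a <- generate_library(ref, library_spec(500, 0.005, seed = 3))
  b <- generate_library(ref, library_spec(500, 0.005, seed = 3))
  expect_identical(a$mutations, b$mutations)
  d <- generate_library(ref, library_spec(500, 0.005, seed = 4))
  expect_false(identical(a$mutations, d$mutations))
})

test_that("trait fitness follows the multiplicative rule with nonsense override", {
  ref <- small_reference()
  model <- fitness_model(ref, seed = 2)
  wt <- trait_fitness(data.frame(pos = integer(0), ref = character(0),
                                 alt = character(0)), model, ref)
  expect_equal(unname(wt), c(1, 1))

  eff <- model$effects
  # single missense with no loop/pore effect: both traits = 1 - stability_cost
  mis <- eff[eff$effect_class == "missense" & eff$lambda_binding_effect == 0 &
               eff$malt_pore_effect == 0, ][1, ]
  f <- trait_fitness(data.frame(pos = mis$pos, ref = mis$ref, alt = mis$alt),
                     model, ref)
  expect_equal(unname(f), rep(1 - mis$stability_cost, 2))

  # hand evaluation: a 0.5-cost mutation in a model with forced effects
  model2 <- model
  model2$effects$stability_cost[1] <- 0.5
  model2$effects$lambda_binding_effect[1] <- 0
  model2$effects$malt_pore_effect[1] <- 0
  k <- model2$effects[1, ]
  expect_equal(
    unname(trait_fitness(data.frame(pos = k$pos, ref = k$ref, alt = k$alt),
                         model2, ref)),
    c(0.5, 0.5)
  )

  non <- eff[eff$effect_class == "nonsense", ][1, ]
  f0 <- trait_fitness(data.frame(pos = non$pos, ref = non$ref, alt = non$alt),
                      model, ref)
  expect_equal(unname(f0), c(0, 0))

  expect_error(
    trait_fitness(data.frame(pos = cds_length(ref) + 5, ref = "A", alt = "C"),
                  model, ref),
    "outside"
  )
})

test_that("synonymous mutations carry no fitness effects", {
  ref <- small_reference()
  model <- fitness_model(ref, seed = 7)
  syn <- model$effects[model$effects$effect_class == "synonymous", ]
  expect_true(all(syn$stability_cost == 0))
  expect_true(all(syn$lambda_binding_effect == 0))
  expect_true(all(syn$malt_pore_effect == 0))
  tr <- single_mutant_truth(model)
  expect_true(all(tr$f_lambda_sensitivity >= 0 & tr$f_lambda_sensitivity <= 1))
  expect_true(all(tr$f_lambda_sensitivity[tr$effect_class == "nonsense"] == 0))
  expect_true(all(tr$f_malt[tr$effect_class == "synonymous"] == 1))
})

test_that("selection reweights by 2^(g*w) and conserves total frequency", {
  lib2 <- list(abundance = c(0.5, 0.5))
  fit2 <- data.frame(f_lambda_sensitivity = c(0, 1), f_malt = c(1, 0))
  # resistant (w = 1) vs sensitive (w = 0) over 3 generations: 8/9 vs 1/9
  post <- simulate_selection(lib2, fit2, "lambda", generations = 3,
                             bottleneck = Inf)
  expect_equal(post, c(8 / 9, 1 / 9))

  # neutral selection leaves frequencies unchanged
  fit_eq <- data.frame(f_lambda_sensitivity = c(0.4, 0.4), f_malt = c(1, 1))
  expect_equal(
    simulate_selection(lib2, fit_eq, "lambda", generations = 5, bottleneck = Inf),
    c(0.5, 0.5)
  )
  expect_equal(
    simulate_selection(lib2, fit2, "control", generations = 5, bottleneck = Inf),
    c(0.5, 0.5)
  )

  # a nonsense-only variant gains frequency relative to wild type under lambda
  fit_non <- data.frame(f_lambda_sensitivity = c(1, 0), f_malt = c(1, 0))
  post_non <- simulate_selection(lib2, fit_non, "lambda", generations = 4,
                                 bottleneck = Inf)
  expect_gt(post_non[2], 0.5)

  # finite bottleneck: still sums to 1, deterministic under seed
  p1 <- simulate_selection(lib2, fit2, "lambda", 3, bottleneck = 1e4, seed = 9)
  p2 <- simulate_selection(lib2, fit2, "lambda", 3, bottleneck = 1e4, seed = 9)
  expect_identical(p1, p2)
  expect_equal(sum(p1), 1)

  expect_error(simulate_selection(lib2, fit2, "lambda", generations = -1),
               "non-negative")
  expect_error(simulate_selection(lib2, fit2, "lambda", 3, bottleneck = 0),
               "positive")
})

test_that("simulated reads reflect fragments, duplication and errors", {
  ref <- small_reference()
  lib <- generate_library(ref, library_spec(100, 0.005, seed = 21))

  # error-free, fixed duplication of 5: every fragment appears as >= 5
  # identical pairs and survives the downstream raw-count filter
  sp <- sequencing_spec(n_fragments = 400, per_base_error = 0,
                        dup_min = 5, dup_mean_extra = 0,
                        frag_len_max = 200, seed = 31)
  sim <- simulate_reads(lib, lib$abundance, ref, sp)
  expect_equal(nrow(sim$reads), 2000L)
  pairs <- collapse_and_filter(sim$reads, min_raw = 5)
  expect_true(all(pairs$raw_count >= 5))
  expect_equal(sum(pairs$raw_count), 2000L)

  # wild-type-only library with no errors: every read matches the reference
  wt <- generate_library(ref, library_spec(10, 0, seed = 1))
  simwt <- simulate_reads(wt, wt$abundance, ref, sp)
  hits <- vapply(simwt$reads$r1, function(r) grepl(r, ref$sequence, fixed = TRUE),
                 logical(1))
  expect_true(all(hits))

  # far fewer unique (start, end) events than raw read pairs
  big <- simulate_reads(lib, lib$abundance, ref,
    sequencing_spec(n_fragments = 5000, per_base_error = 0, frag_len_max = 200,
                    seed = 41))
  n_unique_events <- nrow(unique(big$truth[, c("variant_id", "start", "end")]))
  expect_lt(n_unique_events, nrow(big$reads) / 3)

  # determinism
  sim2 <- simulate_reads(lib, lib$abundance, ref, sp)
  expect_identical(sim$reads, sim2$reads)
  expect_identical(sim$truth, sim2$truth)
})

test_that("fragment construction agrees with materialised variant sequences", {
  ref <- small_reference()
  lib <- generate_library(ref, library_spec(80, 0.01, seed = 13))
  sp <- sequencing_spec(n_fragments = 500, per_base_error = 0,
                        frag_len_max = 150, seed = 17)
  direct <- simulate_reads(lib, lib$abundance, ref, sp)
  cached <- simulate_reads(lib, lib$abundance, ref, sp,
                           variant_seqs = build_variant_sequences(lib, ref))
  expect_identical(direct$reads, cached$reads)
})

test_that("paired FASTQ round-trips", {
  ref <- small_reference()
  lib <- generate_library(ref, library_spec(20, 0.005, seed = 2))
  sim <- simulate_reads(lib, lib$abundance, ref,
    sequencing_spec(n_fragments = 50, dup_min = 1, dup_mean_extra = 0,
                    frag_len_max = 150, seed = 3))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_pair(sim$reads, f1, f2)
  back <- read_fastq_pair(f1, f2)
  expect_equal(back$r1, sim$reads$r1)
  expect_equal(back$r2, sim$reads$r2)
  expect_true(all(grepl("^I+$", back$q1)))
})
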