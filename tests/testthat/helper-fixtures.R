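# Shared synthetic-genome fixtures, generated once per test run. Three
# compositionally distinct genomes at the generator's default divergence:
# one target and two contaminant species (the benchmark's 3:1 split pair).
fx <- local({
  list(
    target = c(target_genome = synthetic_genome(60000, divergence = 0.5, seed = 301)),
    contam1 = c(contam1_genome = synthetic_genome(60000, divergence = 0.5, seed = 302)),
    contam2 = c(contam2_genome = synthetic_genome(60000, divergence = 0.5, seed = 303))
  )
})

# Small contaminated dataset + matching control, for end-to-end tests
make_benchmark <- function(rate = 0.3, total = 120, seed = 9000) {
  design <- mix_design(total, rate, species = c("contam1", "contam2"))
  tf <- sample_fragments(fx$target, design$target_count, seed = seed + 1, prefix = "t")
  c1 <- sample_fragments(fx$contam1, design$contaminant_counts[["contam1"]],
                         seed = seed + 2, prefix = "c1")
  c2 <- sample_fragments(fx$contam2, design$contaminant_counts[["contam2"]],
                         seed = seed + 3, prefix = "c2")
  ds <- mix_datasets(tf$contigs, list(contam1 = c1$contigs, contam2 = c2$contigs),
                     design, seed = seed + 4)
  ctl1 <- sample_fragments(fx$contam1, round(0.75 * total), seed = seed + 5, prefix = "n1")
  ctl2 <- sample_fragments(fx$contam2, round(0.25 * total), seed = seed + 6, prefix = "n2")
  list(dataset = ds, control = c(ctl1$contigs, ctl2$contigs))
}
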