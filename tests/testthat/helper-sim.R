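# Shared small simulated dataset, built once per test run.

small_cfg <- function(...) {
  sim_config(genome_length = 8000L, n_mirs = 10L, n_known = 6L,
             n_pirna_loci = 8L, read_total = 20000L, seed = 7L, ...)
}

.shared <- new.env(parent = emptyenv())

small_sim <- function() {
  if (is.null(.shared$sim)) {
    cfg <- small_cfg()
    sim <- sim_genome(cfg)
    reads <- sim_reads(sim, cfg)
    .shared$sim <- list(cfg = cfg, sim = sim, reads = reads$reads,
                        truth = reads$truth,
                        refset = sim_reference_sets(sim))
  }
  .shared$sim
}

small_run <- function() {
  if (is.null(.shared$run)) {
    s <- small_sim()
    pp <- preprocess_reads(s$reads, s$cfg$adaptor, s$sim$contaminants)
    ann <- annotate_tags(pp$tags, s$refset)
    .shared$run <- list(pp = pp, ann = ann)
  }
  .shared$run
}

random_rna <- function(n, len) random_seq(n, len, c("A", "C", "G", "U"))

worked_ct <- function() {
  # miRNA Ct 18 / U6 15 at MI vs miRNA 20 / U6 15 at GV => fold 4
  tidyr::expand_grid(individual = c("i1", "i2", "i3"),
                     stage = c("GV", "MI"), target = c("m", "U6"),
                     rep = 1:3) |>
    dplyr::mutate(ct = dplyr::case_when(
      target == "U6" ~ 15,
      stage == "GV" ~ 20,
      TRUE ~ 18
    ))
}

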