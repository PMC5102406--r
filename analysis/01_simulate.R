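#!/usr/bin/env Rscript

# Step 1: generate the synthetic study — a known sparse regulatory network
# over transcripts and metabolites, sampled across cDNA pools, then pushed
# down to probe/spot level with two strain lineages and background noise.
# Everything downstream works from the files written here.

suppressPackageStartupMessages(library(fragnet))
dir.create("results", showWarnings = FALSE)

cfg <- sim_config(n_nodes = 12, n_samples = 48, edge_density = 0.2,
                  fraction_conditional = 0.2, probes_per_node = 3,
                  n_lineages = 2, censor_fraction = 0.15,
                  metabolite_fraction = 0.25, seed = 2026L)

truth <- generate_dag(cfg)
message("ground truth: ", length(truth$nodes), " nodes, ",
        nrow(truth$edges), " edges (",
        sum(truth$edges$class != "plain"), " conditional)")
write_ground_truth(truth, "results/ground_truth.graphml",
                   "results/ground_truth_edges.json")

sim <- simulate_samples(truth, cfg)
write_variable_table(sim$data, "results/latent_variables.tsv")

probe <- emit_probe_level(sim$data, cfg)
write_spot_table(probe$spots, "results/spots.tsv")
write.table(probe$annotation, "results/probe_annotation.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
message("wrote ", nrow(probe$spots), " spot records for ",
        nrow(probe$annotation), " probes (",
        cfg$n_spots, " spots per probe, ", cfg$n_lineages, " lineages)")
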