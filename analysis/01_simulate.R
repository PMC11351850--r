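#!/usr/bin/env Rscript
# Stage 1 — generate the synthetic two-species diel study.
#
# Emulates the study design: two closely related species with opposite
# activity niches (AN diurnal, DR nocturnal), heads sampled at midday and
# midnight, three replicates per species and phase, ~2000 reference-anchored
# genes with planted sign-flips, concordant genes, single-species genes,
# co-expression modules, GO enrichment, and a protein family with conserved
# blocks. Every later stage regenerates this study deterministically from
# the same seed, so the written files are for inspection, not plumbing.

library(dielortho)

SEED <- 42
out <- "results/01_simulated_study"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

study <- simulate_study(sim_config(seed = SEED))

for (sp in study$config$species) {
  write_counts(study$counts[[sp]],
               file.path(out, paste0("counts_", sp, ".tsv")),
               file.path(out, paste0("samples_", sp, ".tsv")),
               file.path(out, paste0("lengths_", sp, ".tsv")))
  write_fasta(study$orthology$proteomes[[sp]],
              file.path(out, paste0("proteome_", sp, ".faa")))
}
write_fasta(study$orthology$proteomes$ref, file.path(out, "proteome_ref.faa"))
write.table(study$go, file.path(out, "go.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(data.frame(go_id = names(study$category_map),
                       category = unname(study$category_map)),
            file.path(out, "go_categories.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write.table(study$truth, file.path(out, "truth.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE)
write_fasta(study$family$msa, file.path(out, "family.afa"))

cat("simulated study (seed", SEED, ")\n")
cat("genes:", study$config$n_ref_genes, "| samples per species:",
    nrow(study$counts[[1]]$design), "\n")
print(table(study$truth$de_class))
cat("planted modules:", sum(!is.na(study$truth$module_id)), "genes in",
    length(unique(na.omit(study$truth$module_id))), "modules\n")
cat("key candidate gene:",
    study$truth$reference_gene[study$truth$is_key_gene], "\n")
cat("outputs in", out, "\n")
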