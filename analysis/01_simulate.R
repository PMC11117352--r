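#!/usr/bin/env Rscript
# Stage 1: generate the benchmark genome.
#
# One synthetic contig (~900 kb background) carrying three full copies of
# each of the nine family templates at insertion ages 0.5, 2 and 4 My, a
# truncated and a solo-LTR V-clade decoy, and two copies of an undersized
# decoy element (3.5 kb) that the 4-10 kb element-length filter must remove.
# Three copies per family keep the per-column majority of the cluster
# consensus well-defined (with two members every disagreeing column is a
# tie) and exercise the size>=3 LTR-refinement path.  Ground truth
# (intervals, classes, ages, realized substitution counts) is written next
# to the genome.

suppressPackageStartupMessages(library(tetraltr))

seed <- 20240601L
out <- "results/synthetic"

templates <- family_templates(include_short = TRUE)
plans <- lapply(setdiff(names(templates), "Short1"), function(nm) {
  list(template = nm, n_full = 3L, ages_My = c(0.5, 2, 4))
})
plans[[which(vapply(plans, `[[`, "", "template") == "V-clade1")]] <-
  list(template = "V-clade1", n_full = 3L, n_truncated = 1L, n_solo = 1L,
       ages_My = c(0.5, 2, 4, 2, 2))
plans <- c(plans, list(list(template = "Short1", n_full = 2L, ages_My = 1)))

run <- implant(900000L, gc = 0.45, plans = plans, seed = seed)
write_synth_run(run, out)

cat("genome length:", nchar(run$genome[[1L]]), "bp\n")
cat("implants by class:\n")
print(table(run$truth$class))
cat("implants by template:\n")
print(table(run$truth$template))
cat("written to", out, "\n")
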