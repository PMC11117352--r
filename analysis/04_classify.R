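#!/usr/bin/env Rscript
# Stage 4: greedy 50%-identity clustering, consensus building, LTR boundary
# refinement, family/superfamily assignment against the bundled synthetic
# reference panel, and a neighbor-joining tree of cluster Pol proteins with
# the panel as classification support.

suppressPackageStartupMessages(library(tetraltr))

genome <- read_fasta("results/synthetic/genome.fa")
cands <- utils::read.delim("results/detect/candidates.tsv")
elements <- utils::read.delim("results/annotate/elements.tsv")
models <- load_domain_models()
panel <- default_panel()
dir.create("results/classify", showWarnings = FALSE, recursive = TRUE)

g <- genome[[1L]]
ids <- sprintf("cand%02d", seq_len(nrow(cands)))
seqs <- stats::setNames(substring(g, cands$start + 1L, cands$end), ids)

cl <- greedy_cluster(seqs, threshold = 50)
cat("clusters:", length(cl), "from", length(seqs), "elements\n")

refined <- refine_ltr_boundaries(cl, seqs)
rows <- list()
pols <- character(0)
for (i in seq_along(cl)) {
  c <- cl[[i]]
  cons <- refined$consensus[i]
  pol <- consensus_pol(cons, models)
  layout <- elements$layout[match(c$centroid, elements$cand)]
  fa <- if (is.null(pol)) {
    data.frame(family = "unclassified", superfamily = "unclassified",
               best_identity = NA_real_, best_hit = NA_character_,
               support = "none")
  } else {
    suppressMessages(assign_family(pol, panel, layout = layout))
  }
  if (!is.null(pol)) pols[paste0("cluster", i, "_", fa$family)] <- pol
  rows[[i]] <- data.frame(cluster = paste0("cluster", i),
                          centroid = c$centroid, size = length(c$members),
                          members = paste(c$members, collapse = ","),
                          family = fa$family, superfamily = fa$superfamily,
                          best_identity = round(fa$best_identity, 1),
                          support = fa$support,
                          ltr_length = refined$ltr_length[i],
                          ltr_method = refined$method[i])
}
fam <- do.call(rbind, rows)
print(fam[, c("cluster", "size", "family", "superfamily", "best_identity",
              "support", "ltr_length")])

utils::write.table(fam, "results/classify/families.tsv", sep = "\t",
                   quote = FALSE, row.names = FALSE)
write_fasta(stats::setNames(refined$consensus, fam$cluster),
            "results/classify/consensus.fa")

# NJ tree over cluster Pol proteins + panel entries, distance (100-id)/100
taxa <- c(pols, stats::setNames(panel$protein, panel$id))
n <- length(taxa)
dm <- matrix(0, n, n, dimnames = list(names(taxa), names(taxa)))
for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
  dm[i, j] <- dm[j, i] <-
    (100 - pairwise_identity(taxa[[i]], taxa[[j]], type = "protein")) / 100
}
tree <- nj_tree(dm)
ape::write.tree(tree, "results/classify/tree.nwk")
cat("NJ tree over", n, "Pol proteins written to results/classify/tree.nwk\n")
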