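test_that("pairwise identity matches hand-computed cases", {
  expect_equal(pairwise_identity("ACGTACGT", "ACGTACGT"), 100)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0)
  expect_equal(pairwise_identity("ACGTACGT", "ACGAACGT"), 87.5)
  expect_error(pairwise_identity("", "ACGT"), "empty")
})

test_that("greedy clustering follows the longest-first threshold rule", {
  seqs <- c(A = strrep("A", 30), B = strrep("A", 20), C = strrep("A", 10))
  ident <- matrix(0, 3, 3, dimnames = list(names(seqs), names(seqs)))
  ident["A", "B"] <- ident["B", "A"] <- 60
  ident["A", "C"] <- ident["C", "A"] <- 30
  ident["B", "C"] <- ident["C", "B"] <- 28
  idf <- function(i, j) ident[i, j]
  cl <- greedy_cluster(seqs, threshold = 50, identity_fun = idf)
  expect_identical(length(cl), 2L)
  expect_setequal(cl[[1L]]$members, c("A", "B"))
  expect_identical(cl[[2L]]$members, "C")
  # boundary: exactly-threshold identity joins
  ident["A", "C"] <- ident["C", "A"] <- 50
  cl2 <- greedy_cluster(seqs, threshold = 50, identity_fun = idf)
  expect_identical(length(cl2), 1L)
  # single sequence -> singleton
  cl3 <- greedy_cluster(seqs["A"], threshold = 50, identity_fun = idf)
  expect_identical(length(cl3), 1L)
  expect_identical(cl3[[1L]]$members, "A")
})

test_that("greedy clustering equals the reference rule on a random suite", {
  set.seed(2024)
  for (rep in 1:30) {
    n <- sample(2:6, 1L)
    ids <- paste0("s", seq_len(n))
    lens <- sample(50:500, n)
    ident <- matrix(stats::runif(n * n, 0, 100), n, n,
                    dimnames = list(ids, ids))
    ident[lower.tri(ident)] <- t(ident)[lower.tri(ident)]
    diag(ident) <- 100
    seqs <- stats::setNames(vapply(lens, function(l) strrep("A", l), ""), ids)
    idf <- function(i, j) ident[i, j]
    cl <- greedy_cluster(seqs, threshold = 50, identity_fun = idf)
    got <- attr(cl, "assignment")[ids]
    want <- reference_greedy(ids, lens, ident, 50)[ids]
    expect_identical(got, want)
    # partition: every id appears in exactly one cluster, and members meet
    # the threshold against their centroid
    all_members <- unlist(lapply(cl, `[[`, "members"))
    expect_setequal(all_members, ids)
    expect_identical(anyDuplicated(all_members), 0L)
    for (c in cl) {
      for (m in setdiff(c$members, c$centroid)) {
        expect_gte(ident[c$centroid, m], 50)
      }
    }
  }
})

test_that("center-star consensus takes the per-column majority", {
  expect_identical(build_consensus(c(a = "ACGT", b = "ACGT", c = "ACGT")),
                   "ACGT")
  expect_identical(build_consensus(c(a = "ACGT", b = "ACGA", c = "ACGT")),
                   "ACGT")
  # 2 A vs 2 C columns resolve to the lexicographically smallest base
  expect_identical(build_consensus(c(a = "AAAA", b = "AAAA", c = "CCCC",
                                     d = "CCCC")), "AAAA")
  expect_identical(build_consensus(c(solo = "TTGACA")), "TTGACA")
})

test_that("consensus of mutated copies converges back to the template", {
  tl <- family_templates()
  cons <- build_template_consensus(tl[["Mag1"]], seed = 30L)
  copies <- stats::setNames(lapply(1:5, function(i) {
    mutate_copy(cons$seq, 2, seed = i, ltr5 = cons$ltr5, ltr3 = cons$ltr3,
                orfs = cons$orfs)$seq
  }), paste0("m", 1:5))
  rebuilt <- build_consensus(unlist(copies))
  expect_gte(pairwise_identity(rebuilt, cons$seq), 99)
})

test_that("LTR boundaries are re-called on consensus and adopted by singletons", {
  tl <- family_templates()
  cons <- build_template_consensus(tl[["Mag1"]], seed = 44L)
  copies <- stats::setNames(vapply(1:4, function(i) {
    mutate_copy(cons$seq, 1.5, seed = i, ltr5 = cons$ltr5, ltr3 = cons$ltr3,
                orfs = cons$orfs)$seq
  }, ""), paste0("m", 1:4))
  set.seed(99)
  unrelated <- paste(sample(c("A", "C", "G", "T"), 4700, replace = TRUE),
                     collapse = "")
  clusters <- list(list(centroid = "m1", members = c("m1", "m2", "m3")),
                   list(centroid = "m4", members = "m4"),
                   list(centroid = "bg", members = "bg"))
  out <- refine_ltr_boundaries(clusters, c(copies, bg = unrelated))
  expect_identical(out$method[1L], "consensus_repeat")
  expect_lte(abs(out$ltr_length[1L] - tl[["Mag1"]]$ltr_length), 10L)
  expect_identical(out$method[2L], "adopted")
  expect_lte(abs(out$ltr_length[2L] - tl[["Mag1"]]$ltr_length), 25L)
  expect_true(out$flagged[3L])
})

test_that("family assignment uses panel identity with structural overrides", {
  panel <- default_panel()
  tl <- family_templates()
  # a Gmr-derived protein with fused layout: similarity and structure agree
  gmr_prot <- family_proteins(tl[["Gmr1"]])$gagpol
  fa <- assign_family(gmr_prot, panel, layout = "gag_pol_fused")
  expect_identical(fa$family, "Gmr")
  expect_identical(fa$superfamily, "Gypsy")
  expect_identical(fa$support, "both")
  expect_gte(fa$best_identity, 90)
  # env layout overrides a non-ERV best hit
  vcl_prot <- family_proteins(tl[["V-clade1"]])$pol
  expect_message(fa2 <- assign_family(vcl_prot, panel, layout = "gag_pol_env"),
                 "overrides")
  expect_identical(fa2$superfamily, "ERV")
  expect_identical(fa2$support, "structural")
  # no RT-bearing protein -> precondition error
  expect_error(assign_family(NULL, panel, "gag_pol"), "RT-bearing")
  # nothing close in the panel -> unclassified
  set.seed(3)
  junk <- paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]], 400,
                       replace = TRUE), collapse = "")
  fa3 <- assign_family(junk, panel, layout = "pol_only", floor = 35)
  expect_identical(fa3$family, "unclassified")
})

test_that("clusters of implanted families are pure and correctly assigned", {
  bench <- bench_run()
  models <- bench_models()
  run <- bench$run
  cands <- bench$cands
  g <- run$genome[[1L]]
  seqs <- stats::setNames(substring(g, cands$start + 1L, cands$end),
                          sprintf("el%02d", seq_len(nrow(cands))))
  tmpl <- vapply(seq_len(nrow(cands)), function(i) {
    run$truth$template[which.max(reciprocal_overlap(cands$start[i],
                                                    cands$end[i], run$truth))]
  }, "")
  names(tmpl) <- names(seqs)
  cl <- greedy_cluster(seqs, threshold = 50)
  expect_identical(length(cl), length(unique(tmpl)))
  for (c in cl) {
    expect_identical(length(unique(tmpl[c$members])), 1L)
  }
  panel <- default_panel()
  tlist <- family_templates()
  for (c in cl) {
    cons <- build_consensus(seqs[c$members])
    pol <- consensus_pol(cons, models)
    true_t <- tlist[[tmpl[[c$centroid]]]]
    layout <- switch(true_t$layout, gag_pol_fused = "gag_pol_fused",
                     gag_pol_env = "gag_pol_env", pol_only = "pol_only",
                     "gag_pol")
    fa <- assign_family(pol, panel, layout = layout)
    expect_identical(fa$family, true_t$family)
    expect_identical(fa$superfamily, true_t$superfamily)
  }
})

test_that("neighbor joining recovers additive trees and validates input", {
  # 3 taxa: closed-form branch lengths
  d3 <- matrix(c(0, 2, 3, 2, 0, 4, 3, 4, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  tr3 <- nj_tree(d3)
  expect_setequal(tr3$tip.label, c("a", "b", "c"))
  co <- ape::cophenetic.phylo(tr3)[c("a", "b", "c"), c("a", "b", "c")]
  expect_equal(unname(co), unname(d3), tolerance = 1e-9)
  # non-symmetric input rejected
  bad <- d3; bad[1, 2] <- 5
  expect_error(nj_tree(bad), "symmetric")
  bad2 <- d3; diag(bad2) <- 1
  expect_error(nj_tree(bad2), "diagonal")
  # equal distances still give a valid tree over all leaves
  deq <- matrix(1, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(deq) <- 0
  treq <- nj_tree(deq)
  expect_setequal(treq$tip.label, letters[1:4])
  expect_true(all(treq$edge.length >= 0))
})

test_that("NJ groups superfamily leaves when within-identity exceeds between", {
  fams <- c(g1 = "Gypsy", g2 = "Gypsy", g3 = "Gypsy", e1 = "ERV", e2 = "ERV",
            b1 = "BEL-PAO")
  n <- length(fams)
  ident <- matrix(20, n, n, dimnames = list(names(fams), names(fams)))
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (fams[i] == fams[j]) ident[i, j] <- 70
  }
  diag(ident) <- 100
  tr <- nj_tree((100 - ident) / 100)
  # the Gypsy triplet forms a clade in the unrooted tree: pruning it leaves
  # a subtree whose MRCA has no non-Gypsy descendants
  rooted <- ape::root(tr, outgroup = "b1", resolve.root = TRUE)
  g_mrca <- ape::getMRCA(rooted, c("g1", "g2", "g3"))
  desc <- ape::extract.clade(rooted, g_mrca)$tip.label
  expect_setequal(desc, c("g1", "g2", "g3"))
})
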