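test_that("scan_orfs finds the template pol ORF and maps its interval", {
  tl <- family_templates()
  cons <- build_template_consensus(tl[["V-clade1"]], seed = 4L)
  orfs <- scan_orfs(cons$seq, min_aa = 500L)
  # exactly one qualifying ORF: the 1119 aa pol (the maximal stop-to-stop
  # run may start a few codons upstream of its ATG)
  expect_identical(nrow(orfs), 1L)
  expect_gte(orfs$aa_len[1L], 1119L)
  expect_true(grepl(cons$orfs$protein[cons$orfs$name == "pol"],
                    orfs$protein[1L], fixed = TRUE))
  pol <- cons$orfs[cons$orfs$name == "pol", ]
  expect_lte(orfs$start[1L], pol$start)
  expect_identical(orfs$end[1L], pol$end - 3L)  # stop codon excluded
  expect_identical(3L * orfs$aa_len[1L], orfs$end[1L] - orfs$start[1L])
})

test_that("the >500 aa threshold is strict", {
  set.seed(6)
  aa <- c("GCT", "GAA", "TGG", "CAT")  # A, E, W, H codons
  mk <- function(n_codons) {
    paste0("TAA", paste(sample(aa, n_codons, replace = TRUE), collapse = ""),
           "TAA")
  }
  # the stop-bracketed frame-0 run of exactly 500 aa is excluded, 501 kept
  # (other frames of this synthetic stretch may hold unrelated long runs)
  orfs500 <- scan_orfs(mk(500L), min_aa = 500L)
  expect_identical(sum(orfs500$frame == 0L), 0L)
  orfs <- scan_orfs(mk(501L), min_aa = 500L)
  expect_identical(orfs$aa_len[orfs$frame == 0L], 501L)
})

test_that("random short sequence has no long ORFs", {
  for (seed in 1:5) {
    set.seed(seed)
    x <- paste(sample(c("A", "C", "G", "T"), 2000L, replace = TRUE),
               collapse = "")
    expect_identical(nrow(scan_orfs(x, min_aa = 500L)), 0L)
  }
})

test_that("reverse-frame ORFs map onto plus-strand coordinates", {
  tl <- family_templates()
  cons <- build_template_consensus(tl[["CsRN1-1"]], seed = 15L)
  rc <- reverse_complement(cons$seq)
  fw <- scan_orfs(cons$seq, min_aa = 500L)
  rv <- scan_orfs(rc, min_aa = 500L)
  n <- nchar(cons$seq)
  expect_identical(nrow(rv), nrow(fw))
  expect_setequal(rv$strand, "-")
  expect_identical(sort(n - rv$end), sort(fw$start))
})

test_that("domain scan hits an embedded consensus and rejects shuffles", {
  models <- bench_models()
  set.seed(23)
  filler <- function(n) paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]],
                                     n, replace = TRUE), collapse = "")
  prot <- paste0(filler(200), models$RT$consensus, filler(150))
  hits <- scan_domains(prot, models["RT"])
  expect_identical(nrow(hits), 1L)
  span <- hits$prot_end - hits$prot_start
  expect_gte(span, 0.9 * models$RT$length)
  expect_identical(hits$prot_start, 200L)
  for (i in 1:20) {
    shuf <- paste(sample(strsplit(prot, "")[[1L]]), collapse = "")
    expect_identical(nrow(scan_domains(shuf, models["RT"])), 0L)
  }
  expect_identical(nrow(scan_domains(prot, list())), 0L)
})

test_that("domain hits stay inside their ORFs on annotated elements", {
  bench <- bench_run()
  models <- bench_models()
  recs <- annotate_elements(bench$run$genome, bench$cands[1:4, ], models)
  for (r in recs) {
    for (i in seq_len(nrow(r$hits))) {
      orf <- r$orfs[r$orfs$orf == r$hits$orf[i], ]
      expect_gte(r$hits$prot_start[i], 0L)
      expect_lte(r$hits$prot_end[i], orf$aa_len)
    }
  }
})

test_that("DDE triads are canonical at spacing 35 and non-canonical at 42", {
  models <- bench_models()
  tl <- family_templates()
  for (nm in c("V-clade1", "Gmr1", "Epsilon2", "Copia1")) {
    prots <- family_proteins(tl[[nm]], models)
    pol <- if (!is.null(prots$pol)) prots$pol else prots$gagpol
    h <- scan_domains(pol, models["INT"])
    expect_gte(nrow(h), 1L)
    dde <- locate_dde(pol, h[1L, ], models$INT)
    expect_false(is.null(dde))
    expect_identical(dde$spacing_d2_e, 35L)
    expect_true(dde$canonical)
    chars <- strsplit(pol, "")[[1L]]
    expect_identical(chars[c(dde$d1, dde$d2, dde$e) + 1L], c("D", "D", "E"))
    # triad lies within (or just at the fringe of) the INT hit
    expect_gte(dde$d1, h$prot_start[1L] - 8L)
    expect_lte(dde$e, h$prot_end[1L] - 1L + 8L)
  }
  # BEL-PAO heterogeneity: spacing 42, canonical FALSE
  protsB <- family_proteins(tl[["BEL1"]], models)
  hB <- scan_domains(protsB$pol, models["INT"])
  ddeB <- locate_dde(protsB$pol, hB[1L, ], models$INT)
  expect_identical(ddeB$spacing_d2_e, 42L)
  expect_false(ddeB$canonical)
})

test_that("triad-free integrase windows return absent", {
  models <- bench_models()
  cons <- models$INT$consensus
  noD <- gsub("D", "N", gsub("E", "Q", cons))
  hit <- data.frame(model = "INT", prot_start = 0L, prot_end = nchar(noD),
                    model_start = 0L, model_end = nchar(noD), bits = 30)
  expect_null(locate_dde(noD, hit, models$INT))
  # ordering violated: no E after the second D
  chars <- strsplit(cons, "")[[1L]]
  chars[chars == "E"] <- "Q"
  noE <- paste(chars, collapse = "")
  expect_null(locate_dde(noE, hit, models$INT))
})

test_that("layout typing follows the gag/pol/env hit pattern", {
  mk <- function(model, orf) data.frame(model = model, orf = orf,
                                        stringsAsFactors = FALSE)
  expect_identical(type_layout(mk(c("GAG", "RT", "ENV"),
                                  c("orf1", "orf2", "orf3"))), "gag_pol_env")
  expect_identical(type_layout(mk(c("GAG", "POL", "RT"),
                                  c("orf1", "orf1", "orf1"))), "gag_pol_fused")
  expect_identical(type_layout(mk(c("POL", "RT"), c("orf1", "orf1"))),
                   "pol_only")
  expect_identical(type_layout(mk(c("GAG", "RT"), c("orf1", "orf2"))),
                   "gag_pol")
  expect_identical(type_layout(mk(character(0), character(0))), "none")
})

test_that("full-length verdict is the conjunction of the three criteria", {
  v <- full_length_verdict(TRUE, 501L, TRUE)
  expect_true(v$full_length)
  expect_identical(v$reasons, character(0))
  expect_false(full_length_verdict(TRUE, 500L, TRUE)$full_length)
  v2 <- full_length_verdict(FALSE, 800L, FALSE)
  expect_false(v2$full_length)
  expect_identical(v2$reasons, c("LTR missing", "no RT domain"))
})

test_that("layouts of annotated benchmark elements match their templates", {
  bench <- bench_run()
  models <- bench_models()
  truth <- bench$run$truth
  cands <- bench$cands
  tmpl <- vapply(seq_len(nrow(cands)), function(i) {
    truth$template[which.max(reciprocal_overlap(cands$start[i], cands$end[i],
                                                truth))]
  }, "")
  recs <- annotate_elements(bench$run$genome, cands, models)
  expected <- c("V-clade1" = "gag_pol", "Gmr1" = "gag_pol_fused",
                "Epsilon2" = "gag_pol_env", "CsRN1-1" = "pol_only",
                "BEL1" = "pol_only")
  got <- vapply(recs, `[[`, "", "layout")
  expect_identical(unname(got), unname(expected[tmpl]))
})
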