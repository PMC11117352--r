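test_that("template consensus has the requested geometry with identical LTRs", {
  tl <- family_templates()
  cons <- build_template_consensus(tl[["V-clade1"]], seed = 42L)
  expect_identical(nchar(cons$seq), 5558L)
  expect_identical(cons$ltr5, c(0L, 538L))
  expect_identical(cons$ltr3, c(5020L, 5558L))
  expect_identical(substr(cons$seq, 1, 538), substr(cons$seq, 5021, 5558))
  expect_setequal(cons$orfs$name, c("gag", "pol"))
  expect_identical(cons$orfs$aa_len[cons$orfs$name == "pol"], 1119L)
  expect_identical(cons$orfs$aa_len[cons$orfs$name == "gag"], 371L)
  # ORF intervals encode the protein (start codon ATG, length 3*aa + stop)
  pol <- cons$orfs[cons$orfs$name == "pol", ]
  expect_identical(pol$end - pol$start, 3L * 1119L + 3L)
  expect_identical(substr(cons$seq, pol$start + 1L, pol$start + 3L), "ATG")
})

test_that("template construction is deterministic and validates geometry", {
  tl <- family_templates()
  a <- build_template_consensus(tl[["Gmr1"]], seed = 9L)
  b <- build_template_consensus(tl[["Gmr1"]], seed = 9L)
  expect_identical(a$seq, b$seq)
  bad <- tl[["Gmr1"]]
  bad$ltr_length <- 0L
  expect_error(build_template_consensus(bad, 1L), "positive")
  bad2 <- tl[["Gmr1"]]
  bad2$consensus_length <- 4000L
  expect_error(build_template_consensus(bad2, 1L), "exceed")
})

test_that("every default template yields ORFs free of internal stops", {
  for (t in family_templates()) {
    cons <- build_template_consensus(t, seed = 3L)
    for (i in seq_len(nrow(cons$orfs))) {
      dna <- substr(cons$seq, cons$orfs$start[i] + 1L, cons$orfs$end[i])
      aa <- translate_frame(dna, 0L)
      expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
      expect_false(grepl("*", substr(aa, 1L, nchar(aa) - 1L), fixed = TRUE))
      expect_identical(substr(aa, 1L, nchar(aa) - 1L), cons$orfs$protein[i])
    }
  }
})

test_that("mutate_copy realises the expected K2P substitution load", {
  set.seed(31)
  s <- paste(sample(c("A", "C", "G", "T"), 10000, replace = TRUE),
             collapse = "")
  # 1 My at r = 1e-8 -> d = 0.02; with multiple hits the expected number of
  # changed sites is n * (p_ts + p_tv) at distance d, slightly below n*d
  d <- 0.02
  kappa <- 2
  bt <- d / (kappa + 2); at <- kappa * bt
  p_change <- (0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))) +
    (0.5 - 0.5 * exp(-4 * bt))
  counts <- vapply(1:1000, function(i) {
    mutate_copy(s, age_My = 1, rate_r = 1e-8, kappa = kappa, seed = i)$n_changed
  }, numeric(1))
  se <- stats::sd(counts) / sqrt(length(counts))
  expect_lt(abs(mean(counts) - 10000 * p_change), 3 * se)
  expect_lt(abs(mean(counts) - 200) / 200, 0.02)
})

test_that("mutation limits behave: zero age, infinite kappa", {
  set.seed(5)
  s <- paste(sample(c("A", "C", "G", "T"), 5000, replace = TRUE), collapse = "")
  m0 <- mutate_copy(s, age_My = 0, seed = 1L)
  expect_identical(m0$seq, s)
  expect_identical(m0$n_changed, 0L)
  minf <- mutate_copy(s, age_My = 5, kappa = 1e9, seed = 2L)
  expect_identical(minf$transversions, 0L)
  expect_gt(minf$transitions, 0L)
})

test_that("ORF-preserving mutation never introduces premature stops", {
  tl <- family_templates()
  cons <- build_template_consensus(tl[["V-clade1"]], seed = 8L)
  for (i in 1:5) {
    m <- mutate_copy(cons$seq, age_My = 5, seed = i, ltr5 = cons$ltr5,
                     ltr3 = cons$ltr3, orfs = cons$orfs)
    for (j in seq_len(nrow(cons$orfs))) {
      dna <- substr(m$seq, cons$orfs$start[j] + 1L, cons$orfs$end[j])
      aa <- translate_frame(dna, 0L)
      expect_false(grepl("*", substr(aa, 1, nchar(aa) - 1L), fixed = TRUE))
      expect_identical(substr(aa, nchar(aa), nchar(aa)), "*")
    }
  }
})

test_that("implant bookkeeping matches the plan and the emitted sequence", {
  plans <- list(
    list(template = "V-clade1", n_full = 3, n_truncated = 2, n_solo = 2,
         ages_My = 1),
    list(template = "Mag1", n_full = 2, ages_My = c(0.5, 2)))
  run <- implant(150000L, plans = plans, seed = 77L)
  expect_identical(sum(run$truth$class == "full"), 5L)
  expect_identical(sum(run$truth$class == "truncated"), 2L)
  expect_identical(sum(run$truth$class == "solo_ltr"), 2L)
  expect_identical(nchar(run$genome[[1L]]),
                   150000L + sum(run$truth$length_bp) +
                     9L * run$config$tsd_len)
  # extracting a truth interval reproduces the mutated copy exactly:
  # element length and LTR sub-intervals are consistent
  g <- run$genome[[1L]]
  for (i in seq_len(nrow(run$truth))) {
    tr <- run$truth[i, ]
    expect_identical(nchar(substr(g, tr$start + 1L, tr$end)), tr$length_bp)
    if (tr$class == "full") {
      expect_false(is.na(tr$ltr5_start) || is.na(tr$ltr3_start))
      expect_true(tr$ltr5_end <= tr$ltr3_start)
    }
    if (tr$class == "solo_ltr") {
      expect_true(is.na(tr$ltr3_start))
      expect_identical(tr$end - tr$start, tr$ltr5_end - tr$ltr5_start)
    }
  }
  # determinism
  run2 <- implant(150000L, plans = plans, seed = 77L)
  expect_identical(run2$genome, run$genome)
  expect_identical(run2$truth, run$truth)
})

test_that("implant with no plans returns pure background and empty truth", {
  run <- implant(20000L, plans = list(), seed = 3L)
  expect_identical(nchar(run$genome[[1L]]), 20000L)
  expect_identical(nrow(run$truth), 0L)
})

test_that("truth GFF3 and manifest round-trip through the writers", {
  plans <- list(list(template = "CsRN1-1", n_full = 2, ages_My = 1))
  run <- implant(60000L, plans = plans, seed = 12L)
  dir <- withr::local_tempdir()
  write_synth_run(run, dir)
  gff <- read_gff3(file.path(dir, "truth.gff3"))
  expect_identical(nrow(gff), 2L)
  expect_identical(gff$start, run$truth$start)
  expect_identical(gff$end, run$truth$end)
  fa <- read_fasta(file.path(dir, "genome.fa"))
  expect_identical(as.character(fa), unname(run$genome))
})

test_that("inter-LTR divergence of generated copies recovers the age clock", {
  tl <- family_templates()
  cons <- build_template_consensus(tl[["Barthez1"]], seed = 21L)
  L <- tl[["Barthez1"]]$ltr_length
  age <- 3
  est <- vapply(1:60, function(i) {
    m <- mutate_copy(cons$seq, age, seed = i, ltr5 = cons$ltr5,
                     ltr3 = cons$ltr3, orfs = cons$orfs)
    n <- nchar(m$seq)
    estimate_age("inter_ltr", ltr5 = substr(m$seq, 1, L),
                 ltr3 = substr(m$seq, n - L + 1L, n))$t_My
  }, numeric(1))
  se <- stats::sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - age), 3 * se)
})
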