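# Shared fixtures, built once per test run.  Everything is generated in code
# from fixed seeds; nothing is read from outside the package.

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, envir = .fixture_env, inherits = FALSE)) {
    assign(name, builder(), envir = .fixture_env)
  }
  get(name, envir = .fixture_env, inherits = FALSE)
}

# A mid-sized benchmark genome: 20 full copies across 5 families at ages
# 0.5-4 My, plus truncated and solo decoys.  Used by detection, annotation
# and acceptance tests.
bench_run <- function() {
  fixture("bench_run", function() {
    plans <- list(
      list(template = "V-clade1", n_full = 5, n_truncated = 1, n_solo = 1,
           ages_My = c(0.5, 1, 2, 3, 4, 1, 1)),
      list(template = "Gmr1", n_full = 4, ages_My = c(0.5, 1, 2, 4)),
      list(template = "Epsilon2", n_full = 4, n_solo = 1,
           ages_My = c(1, 2, 3, 4, 2)),
      list(template = "CsRN1-1", n_full = 4, n_truncated = 1,
           ages_My = c(0.5, 1, 2, 3, 2)),
      list(template = "BEL1", n_full = 3, ages_My = c(1, 2, 3))
    )
    run <- implant(600000L, gc = 0.45, plans = plans, seed = 424242L)
    cands <- find_repeat_pairs(run$genome, detect_config())
    list(run = run, cands = cands)
  })
}

bench_models <- function() {
  fixture("bench_models", function() load_domain_models())
}

# Reciprocal overlap of a candidate interval with each truth interval.
reciprocal_overlap <- function(cand_start, cand_end, truth) {
  ov <- pmin(cand_end, truth$end) - pmax(cand_start, truth$start)
  ov <- pmax(ov, 0)
  pmin(ov / (cand_end - cand_start), ov / (truth$end - truth$start))
}

# Match detected candidates to truth full-length elements; returns
# list(recall, precision, matches).
detection_metrics <- function(cands, truth, min_ro = 0.9) {
  full <- truth[truth$class == "full", , drop = FALSE]
  hit <- vapply(seq_len(nrow(full)), function(i) {
    any(reciprocal_overlap(cands$start, cands$end, full[i, ]) >= min_ro)
  }, logical(1L))
  implanted <- truth
  fp <- vapply(seq_len(nrow(cands)), function(i) {
    ov <- pmin(cands$end[i], implanted$end) - pmax(cands$start[i], implanted$start)
    all(ov <= 0)
  }, logical(1L))
  list(recall = mean(hit), precision = 1 - mean(fp),
       n_full = nrow(full), n_cands = nrow(cands))
}
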