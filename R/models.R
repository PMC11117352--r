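## Position-specific score models for retroelement proteins and domains
## (GAG, POL core, RT, RH, INT, ENV), plus local profile alignment and
## DDE-triad localisation.  Models are log-odds column score vectors in bits
## over the 20 amino acids, scored against proteins by affine-gap local
## dynamic programming (a deliberately simple, dependency-free analogue of
## profile-HMM search; thresholds are in bits and configurable).

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1L]]

#' Build a position-specific score matrix from a consensus sequence
#'
#' Column scores are log2 odds against a uniform background (1/20): the
#' consensus residue carries probability `match_prob`, the remaining mass is
#' spread over the other 19 residues.  Unknown residues (X) score -1 bit,
#' stops -8 bits.
#'
#' @param consensus Amino-acid consensus string.
#' @param match_prob Per-column consensus emission probability.
#' @return Numeric matrix, rows = residues (20 aa + X + `*` + `#` mask),
#'   columns = model positions.
#' @export
build_pssm <- function(consensus, match_prob = 0.7) {
  stopifnot(match_prob > 0.05, match_prob < 1)
  cons <- strsplit(toupper(consensus), "", fixed = TRUE)[[1L]]
  stopifnot(all(cons %in% AA20))
  bg <- 1 / 20
  s_match <- log2(match_prob / bg)
  s_miss <- log2(((1 - match_prob) / 19) / bg)
  m <- matrix(s_miss, nrow = 23L, ncol = length(cons),
              dimnames = list(c(AA20, "X", "*", "#"), NULL))
  m[cbind(match(cons, AA20), seq_along(cons))] <- s_match
  m["X", ] <- -1
  m["*", ] <- -8
  m["#", ] <- -1000
  m
}

#' Load the bundled domain models
#'
#' Reads the synthetic model definition TSV shipped with the package (or a
#' user file of the same layout) and builds one scoring model per row.
#'
#' @param path Model definition TSV; defaults to the bundled file.
#' @return Named list of models; each has `name`, `pssm`, `length`,
#'   `bit_threshold`, `gap_open`, `gap_extend`, `consensus` and (for INT)
#'   `catalytic` (0-based columns of D1, D2, E).
#' @export
load_domain_models <- function(path = system.file("extdata",
                                                  "domain_models_synthetic.tsv",
                                                  package = "tetraltr")) {
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(nrow(df) > 0L)
  models <- lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    mod <- list(name = row$name,
                consensus = row$consensus,
                pssm = build_pssm(row$consensus, row$match_prob),
                length = nchar(row$consensus),
                bit_threshold = row$bit_threshold,
                gap_open = row$gap_open,
                gap_extend = row$gap_extend)
    if (!is.na(row$cat_d1)) {
      mod$catalytic <- c(d1 = row$cat_d1, d2 = row$cat_d2, e = row$cat_e)
    }
    mod
  })
  stats::setNames(models, df$name)
}

## Affine-gap Smith-Waterman of a PSSM against a protein.  Row-vectorised:
## the E (gap-in-protein) recurrence collapses to a prefix cummax because
## gap_open >= gap_extend.  Returns the best local hit with start/end in both
## protein and model coordinates (0-based half-open).
pssm_best_hit <- function(pssm, prot_chars, gap_open, gap_extend) {
  n <- length(prot_chars)
  m <- ncol(pssm)
  ridx <- match(prot_chars, rownames(pssm))
  ridx[is.na(ridx)] <- match("X", rownames(pssm))
  H <- matrix(0, m, n)
  Fm <- matrix(-Inf, m, n)
  Em <- matrix(-Inf, m, n)
  idx <- seq_len(n)
  h_prev <- numeric(n)
  f_prev <- rep(-Inf, n)
  for (i in seq_len(m)) {
    srow <- pssm[, i][ridx]
    diag_h <- c(0, h_prev[-n]) + srow
    f_row <- pmax(h_prev - gap_open, f_prev - gap_extend)
    h0 <- pmax(0, diag_h, f_row)
    scan <- cummax(h0 - gap_open + gap_extend * idx)
    e_row <- c(-Inf, scan[-n]) - gap_extend * idx
    h_row <- pmax(h0, e_row)
    H[i, ] <- h_row
    Fm[i, ] <- f_row
    Em[i, ] <- e_row
    h_prev <- h_row
    f_prev <- f_row
  }
  best <- which.max(H)
  score <- H[best]
  i <- (best - 1L) %% m + 1L
  j <- (best - 1L) %/% m + 1L
  end_i <- i; end_j <- j
  eps <- 1e-9
  state <- "H"
  while (i >= 1L && j >= 1L) {
    if (state == "H") {
      h <- H[i, j]
      if (h <= eps) break
      srow_val <- pssm[ridx[j], i]
      diag_val <- if (i > 1L && j > 1L) H[i - 1L, j - 1L] else 0
      if (abs(h - (diag_val + srow_val)) < eps) {
        i <- i - 1L; j <- j - 1L
        if (i == 0L || j == 0L) break
      } else if (is.finite(Em[i, j]) && abs(h - Em[i, j]) < eps) {
        state <- "E"
      } else if (is.finite(Fm[i, j]) && abs(h - Fm[i, j]) < eps) {
        state <- "F"
      } else break
    } else if (state == "E") {
      prev_h <- if (j > 1L) H[i, j - 1L] else -Inf
      if (abs(Em[i, j] - (prev_h - gap_open)) < eps) {
        j <- j - 1L; state <- "H"
      } else {
        ev <- Em[i, j]; j <- j - 1L
        if (j < 1L || !is.finite(Em[i, j]) || abs(Em[i, j] - (ev + gap_extend)) > eps) state <- "H"
      }
    } else {
      prev_h <- if (i > 1L) H[i - 1L, j] else -Inf
      if (abs(Fm[i, j] - (prev_h - gap_open)) < eps) {
        i <- i - 1L; state <- "H"
      } else {
        fv <- Fm[i, j]; i <- i - 1L
        if (i < 1L || !is.finite(Fm[i, j]) || abs(Fm[i, j] - (fv + gap_extend)) > eps) state <- "H"
      }
    }
  }
  ## (i, j) is the last cell NOT consumed by the alignment, so the hit
  ## starts at 1-based (i + 1, j + 1), i.e. 0-based (i, j).
  list(score = score,
       prot_start = j, prot_end = end_j,
       model_start = i, model_end = end_i)
}

#' Scan a protein with a set of domain models
#'
#' Best local affine-gap alignment of each model against the protein; hits
#' scoring at or above the model's bit threshold are reported.  After a hit
#' the covered protein stretch is masked and the scan repeats, so multiple
#' non-overlapping hits per model are possible.
#'
#' @param protein Amino-acid sequence (character scalar).
#' @param models Named list from [load_domain_models()].
#' @param max_hits_per_model Cap on non-overlapping hits per model.
#' @return data.frame with columns model, prot_start, prot_end (0-based
#'   half-open aa coordinates), model_start, model_end, bits.
#' @export
scan_domains <- function(protein, models = load_domain_models(),
                         max_hits_per_model = 3L) {
  stopifnot(length(protein) == 1L)
  hits <- list()
  if (nchar(protein) == 0L || length(models) == 0L) {
    return(data.frame(model = character(), prot_start = integer(),
                      prot_end = integer(), model_start = integer(),
                      model_end = integer(), bits = numeric(),
                      stringsAsFactors = FALSE))
  }
  chars0 <- strsplit(toupper(protein), "", fixed = TRUE)[[1L]]
  for (mod in models) {
    chars <- chars0
    for (k in seq_len(max_hits_per_model)) {
      hit <- pssm_best_hit(mod$pssm, chars, mod$gap_open, mod$gap_extend)
      if (hit$score < mod$bit_threshold) break
      hits[[length(hits) + 1L]] <- data.frame(
        model = mod$name, prot_start = hit$prot_start, prot_end = hit$prot_end,
        model_start = hit$model_start, model_end = hit$model_end,
        bits = hit$score, stringsAsFactors = FALSE)
      chars[(hit$prot_start + 1L):hit$prot_end] <- "#"
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(model = character(), prot_start = integer(),
                      prot_end = integer(), model_start = integer(),
                      model_end = integer(), bits = numeric(),
                      stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, hits)
  out[order(-out$bits), , drop = FALSE]
}

#' Locate the integrase DDE catalytic triad within an INT hit
#'
#' The model's catalytic columns are projected through the hit alignment
#' (prot_pos = prot_start + (column - model_start)); the actual D, D and E
#' residues nearest each projection (within `window` aa, ordering D1 < D2 < E
#' enforced) are selected, minimising total deviation with a leftmost-D1
#' tie-break.  The triad is canonical when the observed D2->E spacing equals
#' `expected_spacing`.
#'
#' @param protein Amino-acid sequence carrying the hit.
#' @param int_hit One row of [scan_domains()] output for the INT model.
#' @param int_model The INT model (with `catalytic` columns).
#' @param expected_spacing Canonical D2->E spacing in aa (default 35).
#' @param window Search window around each projected position (aa).
#' @return List with 0-based positions `d1`, `d2`, `e`, `spacing_d2_e`,
#'   `canonical`; or `NULL` when no ordered D..D..E triple exists.
#' @export
locate_dde <- function(protein, int_hit, int_model, expected_spacing = 35L,
                       window = 8L) {
  stopifnot(!is.null(int_model$catalytic))
  chars <- strsplit(toupper(protein), "", fixed = TRUE)[[1L]]
  cat_cols <- int_model$catalytic
  proj <- int_hit$prot_start + (cat_cols - int_hit$model_start)
  ## local alignment may clip a few terminal residues of the domain, so the
  ## search window is allowed to run slightly past the hit boundaries
  lo <- max(0L, int_hit$prot_start - window)
  hi <- min(length(chars) - 1L, int_hit$prot_end - 1L + window)
  cand <- function(res, center) {
    pos <- which(chars == res) - 1L
    pos <- pos[pos >= max(lo, center - window) & pos <= min(hi, center + window)]
    pos[order(abs(pos - center), pos)]
  }
  d1s <- cand("D", proj[["d1"]])
  d2s <- cand("D", proj[["d2"]])
  es <- cand("E", proj[["e"]])
  if (length(d1s) == 0L || length(d2s) == 0L || length(es) == 0L) return(NULL)
  best <- NULL
  for (d1 in d1s) for (d2 in d2s) for (e in es) {
    if (!(d1 < d2 && d2 < e)) next
    dev <- abs(d1 - proj[["d1"]]) + abs(d2 - proj[["d2"]]) + abs(e - proj[["e"]])
    if (is.null(best) || dev < best$dev ||
        (dev == best$dev && d1 < best$d1)) {
      best <- list(d1 = d1, d2 = d2, e = e, dev = dev)
    }
  }
  if (is.null(best)) return(NULL)
  spacing <- best$e - best$d2
  list(d1 = best$d1, d2 = best$d2, e = best$e,
       spacing_d2_e = spacing,
       canonical = spacing == expected_spacing)
}
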