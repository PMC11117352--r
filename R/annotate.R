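## ORF discovery over six frames, domain annotation of the encoded proteins,
## DDE-triad localisation, structural layout typing and the full-length
## verdict: an element is full-length when it has LTRs at both ends, encodes
## a protein longer than 500 aa, and carries a detectable RT domain.

#' Scan a region for open reading frames in six frames
#'
#' Maximal stop-to-stop ORFs (runs between stop codons, including runs
#' truncated by the region edge) with amino-acid length strictly greater
#' than `min_aa`, over the three forward and three reverse-complement
#' frames.  Genomic intervals are 0-based half-open relative to the region
#' and exclude the stop codon, so `3 * aa_len == end - start`.
#'
#' @param region DNA sequence (character scalar).
#' @param min_aa Minimum ORF length (strict inequality).
#' @return data.frame sorted by decreasing length: frame, start, end,
#'   strand, aa_len, protein.
#' @export
scan_orfs <- function(region, min_aa = 500L) {
  stopifnot(length(region) == 1L, nchar(region) > 0L)
  n <- nchar(region)
  rows <- list()
  for (frame in 0:5) {
    prot <- translate_frame(region, frame)
    if (nchar(prot) == 0L) next
    chars <- strsplit(prot, "", fixed = TRUE)[[1L]]
    stops <- which(chars == "*")
    bounds <- c(0L, stops, length(chars) + 1L)
    for (b in seq_len(length(bounds) - 1L)) {
      a0 <- bounds[b]        # aa index before ORF (0-based start = a0)
      a1 <- bounds[b + 1L] - 1L  # last aa index of ORF (1-based)
      len <- a1 - a0
      if (len <= min_aa) next
      off <- frame %% 3L
      nt0 <- off + 3L * a0
      nt1 <- off + 3L * a1
      if (frame < 3L) {
        s <- nt0; e <- nt1
      } else {
        s <- n - nt1; e <- n - nt0
      }
      rows[[length(rows) + 1L]] <- data.frame(
        frame = frame, start = s, end = e,
        strand = if (frame < 3L) "+" else "-",
        aa_len = len,
        protein = substr(prot, a0 + 1L, a1),
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(frame = integer(), start = integer(), end = integer(),
                      strand = character(), aa_len = integer(),
                      protein = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(-out$aa_len, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Type the structural layout of an element
#'
#' Fused gag-pol when one ORF carries both a GAG hit and a Pol-region hit
#' (POL/RT/RH/INT); env-bearing when any ORF has an ENV hit; pol-only when
#' no GAG hit exists anywhere; otherwise separate gag + pol.
#'
#' @param hits data.frame of domain hits with columns `model` and `orf`
#'   (ORF identifier).
#' @return One of `"gag_pol_fused"`, `"gag_pol_env"`, `"pol_only"`,
#'   `"gag_pol"`, or `"none"` when there are no hits.
#' @export
type_layout <- function(hits) {
  if (nrow(hits) == 0L) return("none")
  pol_models <- c("POL", "RT", "RH", "INT")
  has_gag <- any(hits$model == "GAG")
  has_env <- any(hits$model == "ENV")
  fused <- any(vapply(split(hits$model, hits$orf), function(m) {
    "GAG" %in% m && any(m %in% pol_models)
  }, logical(1L)))
  if (fused) return("gag_pol_fused")
  if (has_env) return("gag_pol_env")
  if (!has_gag) return("pol_only")
  "gag_pol"
}

#' Full-length verdict for an annotated element
#'
#' Conjunction of the three criteria defining a full-length element: LTRs at
#' both ends, an encoded protein longer than 500 aa, and at least one RT
#' domain hit.
#'
#' @param has_both_ltrs,max_orf_aa,has_rt The three observations.
#' @param min_aa Protein length threshold (strict; default 500).
#' @return List with `full_length` (logical) and `reasons` (character vector
#'   of failed criteria, empty when full-length).
#' @export
full_length_verdict <- function(has_both_ltrs, max_orf_aa, has_rt,
                                min_aa = 500L) {
  reasons <- character(0)
  if (!has_both_ltrs) reasons <- c(reasons, "LTR missing")
  if (!(max_orf_aa > min_aa)) {
    reasons <- c(reasons, sprintf("no ORF longer than %d aa", min_aa))
  }
  if (!has_rt) reasons <- c(reasons, "no RT domain")
  list(full_length = length(reasons) == 0L, reasons = reasons)
}

#' Annotate candidate elements
#'
#' For each candidate: extract the element region (optionally extended by
#' `flank` bp), scan ORFs in six frames, scan each ORF's protein with the
#' domain models, locate the DDE triad within the best INT hit, type the
#' structural layout and apply the full-length verdict.
#'
#' @param genome Named character vector of contigs.
#' @param cands Candidate data.frame ([find_repeat_pairs()] output, or
#'   [truth_candidates()] for generator truth).  LTR columns may be NA for
#'   records known to lack an LTR.
#' @param models Domain models.
#' @param min_aa Full-length protein threshold (strict).
#' @param orf_min_aa Minimum ORF length to annotate (domains also live on
#'   proteins below the full-length threshold, e.g. short gag/env ORFs).
#' @param flank Extra flanking sequence used for the ORF scan (bp).
#' @param expected_spacing Canonical DDE spacing (aa).
#' @return List of element records; each has `candidate`, `orfs`, `hits`,
#'   `dde`, `layout`, `full_length`, `reasons`.  See [elements_table()].
#' @export
annotate_elements <- function(genome, cands, models = load_domain_models(),
                              min_aa = 500L, orf_min_aa = 100L,
                              flank = 0L, expected_spacing = 35L) {
  seqlens <- stats::setNames(nchar(genome), names(genome))
  records <- vector("list", nrow(cands))
  for (i in seq_len(nrow(cands))) {
    cand <- cands[i, , drop = FALSE]
    s <- max(0L, cand$start - flank)
    e <- min(unname(seqlens[[cand$contig]]), cand$end + flank)
    region <- substr(genome[[cand$contig]], s + 1L, e)
    orfs <- scan_orfs(region, min_aa = orf_min_aa)
    if (nrow(orfs) > 0L) {
      orfs$start <- orfs$start + s
      orfs$end <- orfs$end + s
      orfs$orf <- sprintf("orf%02d", seq_len(nrow(orfs)))
    } else {
      orfs$orf <- character(0)
    }
    hit_rows <- list()
    for (oi in seq_len(nrow(orfs))) {
      h <- scan_domains(orfs$protein[oi], models)
      if (nrow(h) > 0L) {
        h$orf <- orfs$orf[oi]
        hit_rows[[length(hit_rows) + 1L]] <- h
      }
    }
    hits <- if (length(hit_rows) > 0L) do.call(rbind, hit_rows) else
      data.frame(model = character(), prot_start = integer(),
                 prot_end = integer(), model_start = integer(),
                 model_end = integer(), bits = numeric(), orf = character(),
                 stringsAsFactors = FALSE)
    dde <- NULL
    int_hits <- hits[hits$model == "INT", , drop = FALSE]
    if (nrow(int_hits) > 0L && "INT" %in% names(models)) {
      best <- int_hits[which.max(int_hits$bits), , drop = FALSE]
      prot <- orfs$protein[match(best$orf, orfs$orf)]
      dde <- locate_dde(prot, best, models[["INT"]],
                        expected_spacing = expected_spacing)
    }
    has_both <- !is.na(cand$ltr5_start) && !is.na(cand$ltr3_start)
    max_aa <- if (nrow(orfs) > 0L) max(orfs$aa_len) else 0L
    verdict <- full_length_verdict(has_both, max_aa, any(hits$model == "RT"),
                                   min_aa = min_aa)
    records[[i]] <- list(candidate = cand,
                         orfs = orfs[, setdiff(names(orfs), "protein"), drop = FALSE],
                         proteins = stats::setNames(orfs$protein, orfs$orf),
                         hits = hits, dde = dde,
                         layout = type_layout(hits),
                         full_length = verdict$full_length,
                         reasons = verdict$reasons)
  }
  records
}

#' Build candidate rows from generator truth records
#'
#' Lets the annotation stage run on every implanted copy (full, truncated,
#' solo LTR) with its true interval and LTR sub-intervals, for
#' verdict-vs-truth comparisons.
#'
#' @param truth Truth data.frame from [implant()].
#' @export
truth_candidates <- function(truth) {
  data.frame(contig = truth$contig, start = truth$start, end = truth$end,
             strand = truth$strand,
             ltr5_start = truth$ltr5_start, ltr5_end = truth$ltr5_end,
             ltr3_start = truth$ltr3_start, ltr3_end = truth$ltr3_end,
             ltr_identity = NA_real_, motif_ok = NA, tsd = NA_character_,
             score = NA_real_, ID = truth$ID, stringsAsFactors = FALSE)
}

#' Flatten element records to a summary table
#'
#' @param records List from [annotate_elements()].
#' @return data.frame: one row per element with interval, layout, verdict,
#'   longest-ORF length, per-domain hit flags and DDE spacing.
#' @export
elements_table <- function(records) {
  rows <- lapply(records, function(r) {
    cand <- r$candidate
    data.frame(contig = cand$contig, start = cand$start, end = cand$end,
               ID = if ("ID" %in% names(cand)) cand$ID else NA_character_,
               layout = r$layout, full_length = r$full_length,
               reasons = paste(r$reasons, collapse = "; "),
               max_orf_aa = if (nrow(r$orfs) > 0L) max(r$orfs$aa_len) else 0L,
               n_orfs = nrow(r$orfs),
               has_gag = any(r$hits$model == "GAG"),
               has_rt = any(r$hits$model == "RT"),
               has_rh = any(r$hits$model == "RH"),
               has_int = any(r$hits$model == "INT"),
               has_env = any(r$hits$model == "ENV"),
               dde_spacing = if (!is.null(r$dde)) r$dde$spacing_d2_e else NA_integer_,
               dde_canonical = if (!is.null(r$dde)) r$dde$canonical else NA,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
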