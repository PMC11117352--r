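## De novo detection of candidate LTR retrotransspons as paired similar
## direct repeats bounding a 4-10 kb span: exact k-mer seeds shared by two
## loci at a compatible separation are chained per diagonal and extended
## without gaps under an X-drop rule; overlapping candidates are resolved by
## score.  Because the two LTRs of an element are direct repeats, the search
## is reverse-complement symmetric: scanning the forward strand finds every
## pair that scanning the reverse strand would (the coordinates map onto each
## other), so a single forward pass covers both strands.

#' Detection configuration
#'
#' @param k Seed k-mer length.
#' @param min_ltr_identity Minimum LTR pair identity (percent).
#' @param ltr_len_bounds Allowed LTR length range (bp).
#' @param element_len_bounds Allowed element span (LTR start to LTR end), bp;
#'   the 4-10 kb default is the full-length selection window.
#' @param max_gap_in_extension Maximum gap (bp) between seeds merged on one
#'   diagonal.
#' @param flank Flank extension used by [extend_flanks()] (bp).
#' @param xdrop X-drop termination threshold for ungapped extension.
#' @param match,mismatch Extension scores.
#' @param max_kmer_occ Skip k-mers occurring more often than this
#'   (low-complexity guard).
#' @return List of class `detect_config`.
#' @export
detect_config <- function(k = 13L, min_ltr_identity = 80,
                          ltr_len_bounds = c(100L, 1500L),
                          element_len_bounds = c(4000L, 10000L),
                          max_gap_in_extension = 100L,
                          flank = 4000L, xdrop = 30, match = 1, mismatch = -2,
                          max_kmer_occ = 60L) {
  stopifnot(k >= 8L, element_len_bounds[1L] < element_len_bounds[2L],
            ltr_len_bounds[1L] < ltr_len_bounds[2L])
  structure(list(k = k, min_ltr_identity = min_ltr_identity,
                 ltr_len_bounds = ltr_len_bounds,
                 element_len_bounds = element_len_bounds,
                 max_gap_in_extension = max_gap_in_extension,
                 flank = flank, xdrop = xdrop, match = match,
                 mismatch = mismatch, max_kmer_occ = max_kmer_occ),
            class = "detect_config")
}

## Ungapped X-drop extension along one diagonal.  rv: raw genome vector;
## from: first 1-based position beyond the seed (towards `dir`); d: diagonal
## offset; returns number of accepted positions.
xdrop_extend <- function(rv, from, d, dir, cfg, limit) {
  n <- length(rv)
  steps <- seq(0L, limit - 1L)
  pos1 <- from + dir * steps
  pos2 <- pos1 + d
  ok <- pos1 >= 1L & pos2 <= n
  if (!any(ok)) return(0L)
  pos1 <- pos1[ok]; pos2 <- pos2[ok]
  cmp <- rv[pos1] == rv[pos2]
  sc <- cumsum(ifelse(cmp, cfg$match, cfg$mismatch))
  run_best <- cummax(sc)
  stop_at <- which(run_best - sc > cfg$xdrop)
  upto <- if (length(stop_at) > 0L) stop_at[1L] - 1L else length(sc)
  if (upto == 0L) return(0L)
  which.max(sc[seq_len(upto)])
}

#' Find paired-repeat (LTR) candidates in a genome
#'
#' @param genome Named character vector of contigs (from [read_fasta()]).
#' @param cfg A [detect_config()].
#' @return data.frame of candidates (0-based half-open): contig, start, end,
#'   strand, ltr5_start/end, ltr3_start/end, ltr_identity, motif_ok, tsd,
#'   score.  Empty when nothing is found.
#' @export
find_repeat_pairs <- function(genome, cfg = detect_config()) {
  stopifnot(is.character(genome), !is.null(names(genome)))
  out <- lapply(names(genome), function(ctg) {
    find_pairs_one(genome[[ctg]], ctg, cfg)
  })
  res <- do.call(rbind, out)
  if (is.null(res)) res <- empty_candidates()
  rownames(res) <- NULL
  res
}

empty_candidates <- function() {
  data.frame(contig = character(), start = integer(), end = integer(),
             strand = character(), ltr5_start = integer(), ltr5_end = integer(),
             ltr3_start = integer(), ltr3_end = integer(),
             ltr_identity = numeric(), motif_ok = logical(),
             tsd = character(), score = numeric(), stringsAsFactors = FALSE)
}

find_pairs_one <- function(seq, ctg, cfg) {
  n <- nchar(seq)
  if (n <= cfg$element_len_bounds[1L]) return(empty_candidates())
  k <- cfg$k
  d_min <- cfg$element_len_bounds[1L] - cfg$ltr_len_bounds[2L]
  d_max <- cfg$element_len_bounds[2L] - cfg$ltr_len_bounds[1L]
  starts <- seq_len(n - k + 1L)
  km <- substring(seq, starts, starts + k - 1L)
  keep <- !grepl("N", km, fixed = TRUE)
  dt <- data.table::data.table(kmer = km[keep], pos = starts[keep])
  dt <- dt[, if (.N >= 2L && .N <= cfg$max_kmer_occ) list(pos = list(pos)),
           by = "kmer"]
  if (nrow(dt) == 0L) return(empty_candidates())
  pair_list <- lapply(dt$pos, function(p) {
    p <- sort(p)
    cmb <- utils::combn(p, 2L)
    d <- cmb[2L, ] - cmb[1L, ]
    sel <- d >= d_min & d <= d_max
    if (!any(sel)) return(NULL)
    cbind(i = cmb[1L, sel], d = d[sel])
  })
  pairs <- do.call(rbind, pair_list)
  if (is.null(pairs) || nrow(pairs) == 0L) return(empty_candidates())
  pt <- data.table::data.table(i = pairs[, "i"], d = pairs[, "d"])
  data.table::setorder(pt, d, i)
  gap_brk <- c(TRUE, diff(pt$i) > cfg$max_gap_in_extension | diff(pt$d) != 0L)
  data.table::set(pt, j = "cluster", value = cumsum(gap_brk))
  clusters <- pt[, list(i1 = min(i), i2 = max(i), d = d[1L]), by = "cluster"]
  rv <- charToRaw(seq)
  limit <- cfg$ltr_len_bounds[2L] + 200L
  cands <- vector("list", nrow(clusters))
  for (ci in seq_len(nrow(clusters))) {
    i1 <- clusters$i1[ci]; i2 <- clusters$i2[ci]; d <- clusters$d[ci]
    ext_l <- xdrop_extend(rv, i1 - 1L, d, -1L, cfg, limit)
    ext_r <- xdrop_extend(rv, i2 + k, d, +1L, cfg, limit)
    s5 <- i1 - ext_l
    e5 <- i2 + k - 1L + ext_r
    if (e5 - s5 + 1L > d) e5 <- s5 + d - 1L  # LTR loci must not overlap
    len <- e5 - s5 + 1L
    if (len < cfg$ltr_len_bounds[1L] || len > cfg$ltr_len_bounds[2L]) next
    span <- d + len
    if (span < cfg$element_len_bounds[1L] || span > cfg$element_len_bounds[2L]) next
    ident <- 100 * sum(rv[s5:e5] == rv[(s5 + d):(e5 + d)]) / len
    if (ident < cfg$min_ltr_identity) next
    cands[[ci]] <- data.frame(contig = ctg, start = s5 - 1L, end = e5 + d,
                              strand = "+",
                              ltr5_start = s5 - 1L, ltr5_end = e5,
                              ltr3_start = s5 + d - 1L, ltr3_end = e5 + d,
                              ltr_identity = ident, motif_ok = FALSE,
                              tsd = NA_character_,
                              score = ident / 100 * len,
                              stringsAsFactors = FALSE)
  }
  cands <- do.call(rbind, cands)
  if (is.null(cands) || nrow(cands) == 0L) return(empty_candidates())
  ## overlap resolution: keep best score, deterministic leftmost tie-break
  cands <- cands[order(-cands$score, cands$start), , drop = FALSE]
  kept <- logical(nrow(cands))
  ends <- numeric(0); starts_kept <- numeric(0)
  for (i in seq_len(nrow(cands))) {
    if (!any(cands$start[i] < ends & cands$end[i] > starts_kept)) {
      kept[i] <- TRUE
      starts_kept <- c(starts_kept, cands$start[i])
      ends <- c(ends, cands$end[i])
    }
  }
  cands <- cands[kept, , drop = FALSE]
  cands <- cands[order(cands$start), , drop = FALSE]
  ## annotations (never filters): TG...CA terminal motif and 4-6 bp TSD.
  ## Ungapped extension can over/under-run termini by a few bp, so the motif
  ## is accepted within +/- 3 bp of the called boundary (coordinates are not
  ## adjusted; boundary polishing is out of scope).
  near_motif <- function(pos0, motif, at_start) {
    vapply(pos0, function(p) {
      offs <- p + (-3L):3L
      offs <- offs[offs >= 0L & offs + 2L <= n]
      any(substring(seq, offs + 1L, offs + 2L) == motif)
    }, logical(1L))
  }
  cands$motif_ok <- near_motif(cands$ltr5_start, "TG", TRUE) &
    near_motif(cands$ltr3_end - 2L, "CA", FALSE)
  cands$tsd <- vapply(seq_len(nrow(cands)), function(i) {
    for (w in 6:4) {
      a0 <- cands$ltr5_start[i] - w
      if (a0 < 0L || cands$ltr3_end[i] + w > n) next
      left <- substr(seq, a0 + 1L, a0 + w)
      right <- substr(seq, cands$ltr3_end[i] + 1L, cands$ltr3_end[i] + w)
      if (left == right && !grepl("N", left, fixed = TRUE)) return(left)
    }
    NA_character_
  }, "")
  rownames(cands) <- NULL
  cands
}

#' Filter candidates by element length
#'
#' Keeps candidates whose element span lies within the configured bounds
#' (inclusive at both ends).  Order is preserved; the before/after counts
#' are attached as the `funnel` attribute for identification-funnel tables.
#'
#' @param cands Candidate data.frame from [find_repeat_pairs()].
#' @param cfg A [detect_config()]; its `element_len_bounds` are applied.
#' @export
filter_by_element_length <- function(cands, cfg = detect_config()) {
  len <- cands$end - cands$start
  keep <- len >= cfg$element_len_bounds[1L] & len <= cfg$element_len_bounds[2L]
  out <- cands[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "funnel") <- c(identified = nrow(cands), length_filtered = nrow(out))
  out
}

#' Extend candidate intervals by flanking sequence
#'
#' Grows each element interval by `flank` bp on each side, clipped to the
#' contig.
#'
#' @param cands Candidate data.frame.
#' @param seqlens Named contig lengths.
#' @param flank Flank size in bp.
#' @return data.frame with columns contig, start, end (0-based half-open).
#' @export
extend_flanks <- function(cands, seqlens, flank = 4000L) {
  stopifnot(all(cands$contig %in% names(seqlens)))
  data.frame(contig = cands$contig,
             start = pmax(0L, cands$start - flank),
             end = pmin(unname(seqlens[cands$contig]), cands$end + flank),
             stringsAsFactors = FALSE)
}
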