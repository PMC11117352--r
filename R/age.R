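## Divergence estimation and molecular-clock insertion dating.
##
## Divergence K between a copy and its family consensus (or between the two
## LTRs of one copy) is corrected with the Kimura two-parameter model and
## converted to an insertion time t = K / (2 r), reported in millions of
## years (My) with the default rate r = 1e-8 substitutions/site/year.

#' Count transition/transversion divergence between two aligned sequences
#'
#' Columns containing a gap (`-`) or `N` in either sequence are excluded from
#' the comparable-site count.  Transitions are A<->G and C<->T; every other
#' difference is a transversion.
#'
#' @param a,b Aligned sequences of equal length (character scalars, may
#'   contain `-` gaps).
#' @return List with `sites`, `transitions`, `transversions`, `P`
#'   (transition proportion) and `Q` (transversion proportion).
#' @export
count_divergence <- function(a, b) {
  stopifnot(length(a) == 1L, length(b) == 1L)
  if (nchar(a) != nchar(b)) stop("sequences must be aligned (equal length)")
  av <- strsplit(toupper(a), "", fixed = TRUE)[[1L]]
  bv <- strsplit(toupper(b), "", fixed = TRUE)[[1L]]
  ok <- av %in% c("A", "C", "G", "T") & bv %in% c("A", "C", "G", "T")
  av <- av[ok]; bv <- bv[ok]
  sites <- length(av)
  if (sites == 0L) stop("no comparable sites (all columns gapped or ambiguous)")
  diff <- av != bv
  pur <- c("A", "G")
  ts <- diff & ((av %in% pur) == (bv %in% pur))
  n_ts <- sum(ts)
  n_tv <- sum(diff) - n_ts
  list(sites = sites, transitions = n_ts, transversions = n_tv,
       P = n_ts / sites, Q = n_tv / sites)
}

#' Kimura two-parameter distance
#'
#' K = -1/2 * log((1 - 2P - Q) * sqrt(1 - 2Q)).  Saturated inputs
#' (1 - 2P - Q <= 0 or 1 - 2Q <= 0) yield `NA` with a warning rather than an
#' error, so landscape code can drop them with a logged count.
#'
#' @param P Transition proportion (or a list from [count_divergence()],
#'   in which case `Q` is taken from it).
#' @param Q Transversion proportion.
#' @return Corrected divergence K (substitutions/site), `NA` on saturation.
#' @export
kimura2p <- function(P, Q = NULL) {
  if (is.list(P)) { Q <- P$Q; P <- P$P }
  stopifnot(length(P) == length(Q))
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  K <- ifelse(w1 > 0 & w2 > 0, -0.5 * log(w1 * sqrt(pmax(w2, 0))), NA_real_)
  if (anyNA(K)) warning("kimura2p: ", sum(is.na(K)), " saturated alignment(s) -> NA")
  K
}

#' Convert divergence to insertion time
#'
#' t = K / (2 r), reported in millions of years.
#'
#' @param K Divergence (substitutions/site); may be a vector, NAs propagate.
#' @param r Substitution rate per site per year (default 1e-8).
#' @return Insertion time in My.
#' @export
insertion_time <- function(K, r = 1e-8) {
  if (!is.numeric(r) || length(r) != 1L || r <= 0) stop("rate r must be > 0")
  if (any(K < 0, na.rm = TRUE)) stop("divergence K must be >= 0")
  K / (2 * r) / 1e6
}

#' Globally align two nucleotide sequences
#'
#' Needleman-Wunsch with affine gaps (match 1, mismatch -1, gap open 10,
#' gap extend 2 by default -- stiff gaps keep substitution-only divergence
#' estimates free of gap-assisted misalignment); terminal gaps are part of
#' the alignment.
#'
#' @param a,b DNA sequences (character scalars).
#' @param gap_open,gap_extend Gap penalties (positive numbers).
#' @return List with gapped strings `a` and `b` of equal length.
#' @export
align_pair <- function(a, b, gap_open = 10, gap_extend = 2) {
  stopifnot(nchar(a) > 0L, nchar(b) > 0L)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  list(a = as.character(Biostrings::alignedPattern(aln)),
       b = as.character(Biostrings::alignedSubject(aln)))
}

#' Estimate the insertion age of one element copy
#'
#' Two divergence channels are supported.  `inter_ltr` aligns the element's
#' two LTRs against each other: both start identical at insertion and each
#' accumulates r*t, so their mutual divergence is K = 2rt and t = K/2r.
#' `vs_consensus` aligns the internal (inter-LTR) region against the family
#' consensus internal region, whose divergence runs at 2rt on the same clock
#' convention; the LTRs are excluded there because their mutual divergence is
#' the other channel.
#'
#' @param mode `"inter_ltr"` or `"vs_consensus"`.
#' @param ltr5,ltr3 LTR sequences of the copy (required for inter_ltr).
#' @param internal,consensus_internal Internal-region sequences of the copy
#'   and of the family consensus (required for vs_consensus).
#' @param r Clock rate (substitutions/site/year).
#' @return List with `P`, `Q`, `sites`, `K` and `t_My` (NA on saturation).
#' @export
estimate_age <- function(mode = c("inter_ltr", "vs_consensus"),
                         ltr5 = NULL, ltr3 = NULL,
                         internal = NULL, consensus_internal = NULL,
                         r = 1e-8) {
  mode <- match.arg(mode)
  pair <- if (mode == "inter_ltr") {
    stopifnot(!is.null(ltr5), !is.null(ltr3))
    align_pair(ltr5, ltr3)
  } else {
    stopifnot(!is.null(internal), !is.null(consensus_internal))
    align_pair(internal, consensus_internal)
  }
  st <- count_divergence(pair$a, pair$b)
  K <- suppressWarnings(kimura2p(st))
  t <- if (is.na(K)) NA_real_ else insertion_time(K, r)
  c(st, list(K = K, t_My = t, mode = mode))
}

#' Build a per-family insertion-age landscape
#'
#' Bins element copies by insertion age and reports, per family and age bin,
#' the percentage of the genome covered by copies in that bin.  A family is
#' flagged as recently active when its modal bin starts below
#' `recent_cutoff_My`.
#'
#' @param ages data.frame with columns `family`, `t_My`, `length_bp`.
#' @param genome_length Total genome length in bp.
#' @param bin_width Bin width in My (default 1).
#' @param recent_cutoff_My Recent-activity threshold in My (default 5).
#' @return List with `landscape` (family, bin_start, bin_end, coverage_pct)
#'   and `recent` (named logical per family); copies with `NA` age are
#'   excluded with a message.
#' @export
build_landscape <- function(ages, genome_length, bin_width = 1,
                            recent_cutoff_My = 5) {
  stopifnot(all(c("family", "t_My", "length_bp") %in% names(ages)),
            genome_length > 0, bin_width > 0)
  n_na <- sum(is.na(ages$t_My))
  if (n_na > 0L) {
    message("build_landscape: excluding ", n_na, " copies with undefined (saturated) age")
    ages <- ages[!is.na(ages$t_My), , drop = FALSE]
  }
  fams <- sort(unique(as.character(ages$family)))
  if (nrow(ages) == 0L) {
    return(list(landscape = data.frame(family = character(), bin_start = numeric(),
                                       bin_end = numeric(), coverage_pct = numeric()),
                recent = stats::setNames(logical(0), character(0))))
  }
  bin <- floor(ages$t_My / bin_width)
  n_bins <- max(bin) + 1L
  rows <- list()
  recent <- stats::setNames(logical(length(fams)), fams)
  for (f in fams) {
    sel <- as.character(ages$family) == f
    cov <- vapply(0:(n_bins - 1L), function(b) {
      sum(ages$length_bp[sel & bin == b]) / genome_length * 100
    }, numeric(1L))
    rows[[f]] <- data.frame(family = f,
                            bin_start = (0:(n_bins - 1L)) * bin_width,
                            bin_end = (1:n_bins) * bin_width,
                            coverage_pct = cov)
    modal <- which.max(cov) - 1L
    recent[[f]] <- sum(cov) > 0 && (modal * bin_width) < recent_cutoff_My
  }
  list(landscape = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       recent = recent)
}
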