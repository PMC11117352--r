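## Aggregation of pipeline outputs into the survey's three table shapes
## (identification funnel, element characterisation, family-by-species
## distribution) and family-by-family protein similarity matrices.
## Transcribed reference tables from a published ten-genome tetraodontiform
## LTR survey are bundled so the aggregation logic can be checked against
## printed totals without any network access.

#' Family to superfamily mapping
#'
#' Gypsy comprises Gmr, Mag, V-clade, CsRN1 and Barthez; ERV comprises
#' Orthoretrovirinae and the Epsilon retroviruses; BEL-PAO and Copia are
#' their own superfamilies.
#'
#' @return Named character vector (family -> superfamily).
#' @export
family_superfamily_map <- function() {
  c("Gmr" = "Gypsy", "Mag" = "Gypsy", "V-clade" = "Gypsy",
    "CsRN1" = "Gypsy", "Barthez" = "Gypsy",
    "BEL-PAO" = "BEL-PAO", "Copia" = "Copia",
    "Orthoretrovirinae" = "ERV", "Epsilon retrovirus" = "ERV",
    "unclassified" = "unclassified")
}

#' Load the bundled survey reference tables
#'
#' @return List with `funnel`, `elements`, `distribution` data.frames.
#' @export
load_survey_tables <- function() {
  p <- function(f) system.file("extdata", f, package = "tetraltr")
  list(
    funnel = utils::read.delim(p("survey_funnel.tsv"), comment.char = "#",
                               check.names = FALSE, stringsAsFactors = FALSE),
    elements = utils::read.delim(p("survey_elements.tsv"), comment.char = "#",
                                 check.names = FALSE, stringsAsFactors = FALSE),
    distribution = utils::read.delim(p("survey_distribution.tsv"),
                                     comment.char = "#", check.names = FALSE,
                                     stringsAsFactors = FALSE))
}

#' Summarise the identification funnel
#'
#' Per-genome counts of identified, length-filtered and full-length
#' elements, with a totals row.  Monotonicity (identified >= length-filtered
#' >= full-length) is enforced.
#'
#' @param per_genome data.frame with columns `species`, `identified`,
#'   `length_filtered`, `full_length`.
#' @return data.frame with an appended `Total` row.
#' @export
summarize_funnel <- function(per_genome) {
  need <- c("species", "identified", "length_filtered", "full_length")
  stopifnot(all(need %in% names(per_genome)))
  df <- per_genome[, need, drop = FALSE]
  bad <- which(!(df$identified >= df$length_filtered &
                 df$length_filtered >= df$full_length))
  if (length(bad) > 0L) {
    stop("funnel counts must be monotone non-increasing; violated for ",
         df$species[bad[[1L]]])
  }
  totals <- data.frame(species = "Total",
                       identified = sum(df$identified),
                       length_filtered = sum(df$length_filtered),
                       full_length = sum(df$full_length),
                       stringsAsFactors = FALSE)
  rbind(df, totals)
}

#' Summarise the element characterisation table
#'
#' Rolls element rows up to families and superfamilies (copy and structure
#' counts) and reports headline statistics: number of elements, consensus
#' length range, the largest element copy count.
#'
#' @param elements data.frame with columns `family`, `element`, `copies`,
#'   `full_ltr`, `gag_n`, `pol_n`, `env_n`, `consensus_bp` (others pass
#'   through).
#' @param map Family to superfamily mapping.
#' @return List: `elements` (input), `families`, `superfamilies` (rollup
#'   data.frames) and `stats` (n_elements, n_families, n_superfamilies,
#'   total_copies, consensus_min, consensus_max, max_copies,
#'   max_copies_element).
#' @export
summarize_elements <- function(elements, map = family_superfamily_map()) {
  need <- c("family", "element", "copies", "full_ltr", "gag_n", "pol_n",
            "env_n", "consensus_bp")
  stopifnot(all(need %in% names(elements)))
  roll <- function(keys) {
    agg <- stats::aggregate(
      elements[, c("copies", "full_ltr", "gag_n", "pol_n", "env_n")],
      by = list(group = keys), FUN = sum)
    agg$n_elements <- as.integer(table(keys)[agg$group])
    agg
  }
  fam <- roll(elements$family)
  names(fam)[1L] <- "family"
  unknown <- setdiff(fam$family, names(map))
  if (length(unknown) > 0L) stop("no superfamily mapping for: ", unknown[[1L]])
  sup <- roll(unname(map[elements$family]))
  names(sup)[1L] <- "superfamily"
  imax <- which.max(elements$copies)
  list(elements = elements, families = fam, superfamilies = sup,
       stats = list(n_elements = nrow(elements),
                    n_families = nrow(fam),
                    n_superfamilies = nrow(sup),
                    total_copies = sum(elements$copies),
                    consensus_min = min(elements$consensus_bp),
                    consensus_max = max(elements$consensus_bp),
                    max_copies = elements$copies[imax],
                    max_copies_element = elements$element[imax]))
}

#' Summarise the family-by-species distribution
#'
#' Computes superfamily rollup rows, per-species column totals and the
#' number of species in which each superfamily is present.
#'
#' @param distribution data.frame: `family` column plus one numeric column
#'   per species.
#' @param map Family to superfamily mapping.
#' @return List: `families` (input), `superfamilies` (rollup),
#'   `species_totals` (named vector), `presence` (species count per
#'   superfamily).
#' @export
summarize_distribution <- function(distribution, map = family_superfamily_map()) {
  stopifnot("family" %in% names(distribution))
  species <- setdiff(names(distribution), "family")
  m <- as.matrix(distribution[, species, drop = FALSE])
  if (any(m < 0)) stop("distribution counts must be non-negative")
  sup_keys <- unname(map[distribution$family])
  if (anyNA(sup_keys)) {
    stop("no superfamily mapping for: ",
         distribution$family[which(is.na(sup_keys))[1L]])
  }
  sup <- rowsum(m, group = sup_keys)
  storage.mode(sup) <- "integer"
  presence <- apply(sup > 0, 1L, sum)
  list(families = distribution,
       superfamilies = data.frame(superfamily = rownames(sup), sup,
                                  check.names = FALSE, row.names = NULL),
       species_totals = stats::setNames(as.integer(colSums(sup)),
                                        colnames(sup)),
       presence = presence)
}

#' Mean pairwise identity matrix between protein families
#'
#' For a chosen protein/domain level, the (i, j) cell is the mean of all
#' pairwise identities between members of family i and family j (within a
#' family: all unordered member pairs).  Singleton families have an
#' undefined (NA) diagonal and are flagged.
#'
#' @param proteins Named character vector of protein sequences.
#' @param families Character vector of family labels parallel to
#'   `proteins`.
#' @return List: `matrix` (symmetric, percent), `n` (members per family),
#'   `singletons` (family names with a single member).
#' @export
similarity_heatmap <- function(proteins, families) {
  stopifnot(length(proteins) == length(families), length(proteins) >= 1L)
  fams <- sort(unique(families))
  nf <- length(fams)
  idx <- split(seq_along(proteins), families)
  out <- matrix(NA_real_, nf, nf, dimnames = list(fams, fams))
  for (a in seq_len(nf)) {
    for (b in a:nf) {
      ia <- idx[[fams[a]]]; ib <- idx[[fams[b]]]
      pairs <- if (a == b) {
        if (length(ia) < 2L) NULL else utils::combn(ia, 2L)
      } else {
        as.matrix(expand.grid(ia, ib))
      }
      if (is.null(pairs)) next
      if (a == b) pairs <- t(pairs) else pairs <- unname(pairs)
      vals <- apply(pairs, 1L, function(p) {
        pairwise_identity(proteins[[p[1L]]], proteins[[p[2L]]],
                          type = "protein")
      })
      out[a, b] <- out[b, a] <- mean(vals)
    }
  }
  n <- vapply(idx, length, integer(1L))[fams]
  list(matrix = out, n = n, singletons = fams[n == 1L])
}
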