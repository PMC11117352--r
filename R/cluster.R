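## Pairwise identity, greedy 50%-identity clustering, center-star consensus,
## LTR boundary refinement, reference-panel family/superfamily assignment
## and a neighbor-joining classification tree.

#' Global pairwise identity
#'
#' Needleman-Wunsch with affine gaps; identity = matches / alignment columns
#' (terminal gaps included), in percent.
#'
#' @param a,b Sequences (character scalars).
#' @param type `"dna"` (match 1 / mismatch -1) or `"protein"` (BLOSUM62).
#' @param gap_open,gap_extend Gap penalties (positive).  The DNA defaults
#'   (10/2) are deliberately stiff so that unrelated sequences are not
#'   pushed towards inflated gap-assisted identities; with cheap gaps,
#'   random DNA aligns at ~50% identity and a 50% clustering threshold
#'   stops separating families.
#' @return Identity percentage in `[0, 100]`.
#' @export
pairwise_identity <- function(a, b, type = c("dna", "protein"),
                              gap_open = 10,
                              gap_extend = if (type[1L] == "dna") 2 else 1) {
  type <- match.arg(type)
  if (is.na(a) || is.na(b) || nchar(a) == 0L || nchar(b) == 0L) {
    stop("pairwise_identity: empty sequence")
  }
  mat <- if (type == "dna") {
    Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                             baseOnly = FALSE)
  } else {
    get_blosum62()
  }
  if (type == "protein") {
    a <- gsub("[*]", "X", a); b <- gsub("[*]", "X", b)
  }
  aln <- Biostrings::pairwiseAlignment(a, b, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = gap_open,
                                       gapExtension = gap_extend)
  len <- nchar(as.character(Biostrings::alignedPattern(aln)))
  100 * Biostrings::nmatch(aln) / len
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Greedy length-sorted identity clustering
#'
#' Sequences are processed longest first (ties by id, lexicographic); each
#' joins the first existing centroid it matches at >= `threshold` percent
#' identity, otherwise it founds a new cluster.  Deterministic given the
#' input set.
#'
#' @param seqs Named character vector.
#' @param threshold Identity threshold in percent (default 50; the `>=`
#'   boundary semantics means exactly-threshold joins).
#' @param type Passed to [pairwise_identity()].
#' @param identity_fun Optional `function(id_a, id_b)` returning percent
#'   identity, overriding alignment (used for testing and precomputed
#'   matrices).
#' @return List of clusters, each `list(centroid, members)`; also an
#'   `assignment` attribute (named centroid per input id).
#' @export
greedy_cluster <- function(seqs, threshold = 50, type = "dna",
                           identity_fun = NULL) {
  stopifnot(!is.null(names(seqs)), !anyDuplicated(names(seqs)))
  ord <- order(-nchar(seqs), names(seqs))
  ids <- names(seqs)[ord]
  idf <- identity_fun %||%
    function(i, j) pairwise_identity(seqs[[i]], seqs[[j]], type = type)
  clusters <- list()
  assign <- character(0)
  for (id in ids) {
    placed <- FALSE
    for (ci in seq_along(clusters)) {
      if (idf(clusters[[ci]]$centroid, id) >= threshold) {
        clusters[[ci]]$members <- c(clusters[[ci]]$members, id)
        assign[id] <- clusters[[ci]]$centroid
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      clusters[[length(clusters) + 1L]] <- list(centroid = id, members = id)
      assign[id] <- id
    }
  }
  attr(clusters, "assignment") <- assign
  clusters
}

#' Center-star consensus of cluster members
#'
#' The longest member (ties by id) is the center; every other member is
#' globally aligned to it and projected onto the center's columns
#' (insertions relative to the center are dropped).  Per column the majority
#' symbol wins; ties among bases go to the lexicographically smallest base;
#' majority-gap columns are dropped.
#'
#' @param members Named character vector of member sequences.
#' @return Consensus sequence (character scalar).
#' @export
build_consensus <- function(members) {
  stopifnot(length(members) >= 1L)
  if (length(members) == 1L) return(unname(members[[1L]]))
  ord <- order(-nchar(members), names(members))
  center <- members[[ord[1L]]]
  L <- nchar(center)
  counts <- matrix(0L, nrow = 6L, ncol = L,
                   dimnames = list(c("A", "C", "G", "T", "N", "-"), NULL))
  cch <- strsplit(center, "", fixed = TRUE)[[1L]]
  counts[cbind(match(cch, rownames(counts)), seq_len(L))] <- 1L
  for (k in ord[-1L]) {
    pr <- align_pair(members[[k]], center)
    ach <- strsplit(pr$a, "", fixed = TRUE)[[1L]]
    bch <- strsplit(pr$b, "", fixed = TRUE)[[1L]]
    keep <- bch != "-"
    proj <- ach[keep]  # member symbols on center columns ('-' for deletions)
    ri <- match(proj, rownames(counts))
    ri[is.na(ri)] <- match("N", rownames(counts))
    counts[cbind(ri, seq_len(L))] <- counts[cbind(ri, seq_len(L))] + 1L
  }
  cons <- vapply(seq_len(L), function(j) {
    col <- counts[, j]
    top <- max(col)
    winners <- rownames(counts)[col == top]
    if (identical(winners, "-")) return("")
    winners <- setdiff(winners, "-")
    sort(winners)[1L]
  }, "")
  paste(cons, collapse = "")
}

#' Refine LTR boundaries per cluster
#'
#' For clusters with three or more members the LTR termini are re-called on
#' the cluster consensus by a repeat-pair search restricted to spans
#' covering most of the consensus.  Smaller clusters adopt the terminus of
#' the best-matching already-refined LTR (local alignment of defined
#' end-LTRs against the centroid sequence); clusters with no assignable
#' terminus are flagged, not dropped.
#'
#' @param clusters Output of [greedy_cluster()].
#' @param seqs Named element sequences backing the cluster members.
#' @param cfg A [detect_config()] for the consensus repeat search.
#' @param adopt_min_identity Minimum local identity to adopt a terminus.
#' @return data.frame per cluster: centroid, size, consensus (sequence),
#'   ltr_length, method (`consensus_repeat`, `adopted`, `flagged`),
#'   flagged.
#' @export
refine_ltr_boundaries <- function(clusters, seqs, cfg = NULL,
                                  adopt_min_identity = 70) {
  res <- lapply(clusters, function(cl) {
    cons <- build_consensus(seqs[cl$members])
    data.frame(centroid = cl$centroid, size = length(cl$members),
               consensus = cons, ltr_length = NA_integer_,
               method = "pending", flagged = FALSE,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  ltr_seqs <- list()
  big <- which(out$size >= 3L)
  for (i in big) {
    L <- nchar(out$consensus[i])
    cfg_i <- cfg %||% detect_config(
      element_len_bounds = c(max(200L, round(0.7 * L)), L),
      ltr_len_bounds = c(50L, max(100L, min(1500L, L %/% 2L))),
      min_ltr_identity = 80)
    cand <- find_repeat_pairs(stats::setNames(out$consensus[i], "cons"), cfg_i)
    if (nrow(cand) > 0L) {
      cand <- cand[order(-(cand$end - cand$start)), , drop = FALSE]
      best <- cand[1L, ]
      out$ltr_length[i] <- best$ltr5_end - best$ltr5_start
      out$method[i] <- "consensus_repeat"
      ltr_seqs[[out$centroid[i]]] <-
        substr(out$consensus[i], best$ltr5_start + 1L, best$ltr5_end)
    } else {
      out$method[i] <- "flagged"
      out$flagged[i] <- TRUE
    }
  }
  small <- which(out$size < 3L)
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = FALSE)
  for (i in small) {
    best_ident <- -Inf; best_len <- NA_integer_
    target <- out$consensus[i]
    for (ltr in ltr_seqs) {
      aln <- Biostrings::pairwiseAlignment(ltr, target, type = "local",
                                           substitutionMatrix = mat,
                                           gapOpening = 4, gapExtension = 1)
      alen <- nchar(as.character(Biostrings::alignedPattern(aln)))
      if (alen < 0.5 * nchar(ltr)) next
      ident <- 100 * Biostrings::nmatch(aln) / alen
      if (ident > best_ident) {
        best_ident <- ident
        best_len <- alen
      }
    }
    if (is.finite(best_ident) && best_ident >= adopt_min_identity) {
      out$ltr_length[i] <- best_len
      out$method[i] <- "adopted"
    } else {
      out$method[i] <- "flagged"
      out$flagged[i] <- TRUE
    }
  }
  rownames(out) <- NULL
  out
}

#' Read a reference panel FASTA
#'
#' Headers carry `family=` and `superfamily=` tags:
#' `>id family=Gmr superfamily=Gypsy`.
#'
#' @param path Panel FASTA path.
#' @return data.frame: id, family, superfamily, protein.
#' @export
read_panel <- function(path) {
  bs <- Biostrings::readBStringSet(path)
  hdr <- names(bs)
  grab <- function(key) {
    m <- regmatches(hdr, regexpr(paste0(key, "=[^ ]+"), hdr))
    vapply(strsplit(m, "=", fixed = TRUE), `[[`, "", 2L)
  }
  fam <- gsub("_", " ", grab("family"))
  sup <- gsub("_", " ", grab("superfamily"))
  data.frame(id = sub("\\s.*$", "", hdr), family = fam, superfamily = sup,
             protein = as.character(bs), stringsAsFactors = FALSE)
}

#' The bundled synthetic reference panel
#'
#' One RT-bearing Pol (or Gag-Pol) protein per family, constructed
#' deterministically from the family templates; identical to the shipped
#' `panel_synthetic.faa`.
#'
#' @return data.frame as [read_panel()].
#' @export
default_panel <- function() {
  tl <- family_templates()
  rows <- lapply(tl, function(t) {
    prots <- family_proteins(t)
    pol <- if (!is.null(prots$pol)) prots$pol else prots$gagpol
    data.frame(id = paste0("synthref_", gsub(" ", "_", t$name)),
               family = t$family, superfamily = t$superfamily,
               protein = pol, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assign a cluster to a family and superfamily
#'
#' Best-hit identity of the cluster's RT-bearing protein against the panel,
#' with structural overrides: an env layout forces the ERV superfamily and a
#' fused gag-pol layout restricts candidates to Gmr/Mag; conflicts are
#' resolved in favour of structure with the support level recorded.  Best
#' hits below `floor` percent give family "unclassified" (superfamily from
#' structure when determinable).
#'
#' @param protein RT-bearing protein of the cluster consensus.
#' @param panel Panel data.frame ([default_panel()] / [read_panel()]).
#' @param layout Structural layout label from [type_layout()].
#' @param floor Identity floor in percent (default 20).
#' @return data.frame row: family, superfamily, best_identity, best_hit,
#'   support.
#' @export
assign_family <- function(protein, panel, layout = "gag_pol", floor = 20) {
  if (is.null(protein) || is.na(protein) || nchar(protein) == 0L) {
    stop("assign_family: cluster has no RT-bearing protein")
  }
  ident <- vapply(panel$protein, function(p) {
    pairwise_identity(protein, p, type = "protein")
  }, numeric(1L), USE.NAMES = FALSE)
  best <- which.max(ident)
  family <- panel$family[best]
  superfamily <- panel$superfamily[best]
  support <- "similarity"
  restrict <- NULL
  if (layout == "gag_pol_env" && superfamily != "ERV") {
    restrict <- which(panel$superfamily == "ERV")
  } else if (layout == "gag_pol_fused" && !family %in% c("Gmr", "Mag")) {
    restrict <- which(panel$family %in% c("Gmr", "Mag"))
  }
  if (!is.null(restrict) && length(restrict) > 0L) {
    message("assign_family: structural layout '", layout,
            "' overrides similarity best hit ", family)
    best <- restrict[which.max(ident[restrict])]
    family <- panel$family[best]
    superfamily <- panel$superfamily[best]
    support <- "structural"
  } else if ((layout == "gag_pol_env" && superfamily == "ERV") ||
             (layout == "gag_pol_fused" && family %in% c("Gmr", "Mag"))) {
    support <- "both"
  }
  if (ident[best] < floor) {
    family <- "unclassified"
    superfamily <- switch(layout,
                          gag_pol_env = "ERV",
                          gag_pol_fused = "Gypsy",
                          "unclassified")
    support <- if (superfamily == "unclassified") "similarity" else "structural"
  }
  data.frame(family = family, superfamily = superfamily,
             best_identity = ident[best], best_hit = panel$id[best],
             support = support, stringsAsFactors = FALSE)
}

#' Extract the RT-bearing protein from a consensus sequence
#'
#' Scans ORFs and returns the protein of the ORF carrying the best RT hit.
#'
#' @param consensus Consensus DNA sequence.
#' @param models Domain models.
#' @param orf_min_aa Minimum ORF length scanned.
#' @return Character scalar or `NULL` when no RT-bearing ORF exists.
#' @export
consensus_pol <- function(consensus, models = load_domain_models(),
                          orf_min_aa = 300L) {
  orfs <- scan_orfs(consensus, min_aa = orf_min_aa)
  best <- NULL; best_bits <- -Inf
  for (i in seq_len(nrow(orfs))) {
    h <- scan_domains(orfs$protein[i], models["RT"])
    if (nrow(h) > 0L && max(h$bits) > best_bits) {
      best_bits <- max(h$bits)
      best <- orfs$protein[i]
    }
  }
  best
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor-joining on a symmetric zero-diagonal distance matrix
#' (for classification the pipeline uses (100 - identity)/100); negative
#' branch lengths are clamped to zero.
#'
#' @param dist Square symmetric numeric matrix with zero diagonal and
#'   row/column names (the leaf labels).
#' @return An `ape::phylo` tree (unrooted).
#' @export
nj_tree <- function(dist) {
  stopifnot(is.matrix(dist), nrow(dist) == ncol(dist), nrow(dist) >= 3L)
  if (!isTRUE(all.equal(dist, t(dist), tolerance = 1e-8))) {
    stop("nj_tree: distance matrix must be symmetric")
  }
  if (any(abs(diag(dist)) > 1e-12)) stop("nj_tree: diagonal must be zero")
  tree <- ape::nj(stats::as.dist(dist))
  tree$edge.length[tree$edge.length < 0] <- 0
  tree
}
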