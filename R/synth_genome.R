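## Synthetic genomes with implanted LTR retrotransposons of known family
## geometry, copy class and insertion age.  Implants follow the element
## geometries observed in compact tetraodontiform genomes (consensus
## ~4.3-9.9 kb, LTRs ~0.17-1.1 kb, gag/pol/env layouts including the
## gag-pol fusion of Gmr/Mag and the env-bearing Epsilon retroviruses), so
## detection, annotation, classification and dating can all be verified
## against ground truth at desk scale.

## Run expr under a local RNG seeded with `seed`, restoring global RNG state.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Derive a child seed from a root seed
#'
#' Keeps every source of randomness traceable to one root; results stay
#' below 2^31 so they are valid R integer seeds.
#'
#' @param root Root integer seed.
#' @param i Child index (integer or character; characters are hashed).
#' @export
derive_seed <- function(root, i) {
  if (is.character(i)) i <- sum(utf8ToInt(i) * seq_len(nchar(i)))
  as.integer((as.numeric(root) * 48271 + as.numeric(i) * 1000003 + 12345) %% 2147483647)
}

## Stable per-family seed (independent of the user's run seed) so that a
## family's protein cores are the same in every session -- the bundled
## reference panel depends on this.
family_seed <- function(family) derive_seed(7777L, family)

## Substitute a fraction of core positions with other residues, protecting
## listed 0-based positions (catalytic residues).
vary_core <- function(consensus, frac, protect = integer(0)) {
  chars <- strsplit(consensus, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  free <- setdiff(seq_len(n), protect + 1L)
  k <- round(frac * length(free))
  pos <- sample(free, k)
  for (p in pos) chars[p] <- sample(setdiff(AA20, chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Default family templates
#'
#' One template per family, with the geometry (consensus length, LTR length,
#' protein lengths, layout) of a representative element of that family in
#' compact tetraodontiform genomes.  Layouts: `gag_pol` (separate ORFs),
#' `gag_pol_fused` (single ORF, the Gmr/Mag pattern), `pol_only`
#' (CsRN1/BEL-PAO/Orthoretrovirinae pattern), `gag_pol_env` (Epsilon
#' retroviruses).  The BEL-PAO integrase core carries a non-canonical
#' D2->E spacing of 42 aa; all others the canonical 35.
#'
#' @param include_short Also include an undersized decoy template (3.5 kb
#'   consensus) that the 4-10 kb element-length filter must remove; useful
#'   for exercising the identification funnel.
#' @return Named list of templates.
#' @export
family_templates <- function(include_short = FALSE) {
  t <- list(
    list(name = "Gmr1", family = "Gmr", superfamily = "Gypsy",
         layout = "gag_pol_fused", consensus_length = 6465L, ltr_length = 518L,
         gagpol_aa = 1634L),
    list(name = "Mag1", family = "Mag", superfamily = "Gypsy",
         layout = "gag_pol_fused", consensus_length = 4696L, ltr_length = 208L,
         gagpol_aa = 1365L),
    list(name = "V-clade1", family = "V-clade", superfamily = "Gypsy",
         layout = "gag_pol", consensus_length = 5558L, ltr_length = 538L,
         gag_aa = 371L, pol_aa = 1119L),
    list(name = "CsRN1-1", family = "CsRN1", superfamily = "Gypsy",
         layout = "pol_only", consensus_length = 4337L, ltr_length = 174L,
         pol_aa = 1061L),
    list(name = "Barthez1", family = "Barthez", superfamily = "Gypsy",
         layout = "gag_pol", consensus_length = 7871L, ltr_length = 1116L,
         gag_aa = 355L, pol_aa = 1394L),
    list(name = "BEL1", family = "BEL-PAO", superfamily = "BEL-PAO",
         layout = "pol_only", consensus_length = 7624L, ltr_length = 728L,
         pol_aa = 1434L, dde_spacing = 42L),
    list(name = "Copia1", family = "Copia", superfamily = "Copia",
         layout = "gag_pol", consensus_length = 4794L, ltr_length = 233L,
         gag_aa = 454L, pol_aa = 653L),
    list(name = "Orthoretrovirinae1", family = "Orthoretrovirinae",
         superfamily = "ERV", layout = "pol_only", consensus_length = 8626L,
         ltr_length = 433L, pol_aa = 1108L),
    list(name = "Epsilon2", family = "Epsilon retrovirus", superfamily = "ERV",
         layout = "gag_pol_env", consensus_length = 8158L, ltr_length = 382L,
         gag_aa = 219L, pol_aa = 951L, env_aa = 554L)
  )
  if (include_short) {
    t <- c(t, list(list(name = "Short1", family = "unclassified",
                        superfamily = "unclassified", layout = "pol_only",
                        consensus_length = 3500L, ltr_length = 250L,
                        pol_aa = 600L)))
  }
  stats::setNames(t, vapply(t, `[[`, "", "name"))
}

template_protein_lengths <- function(t) {
  switch(t$layout,
         gag_pol = c(gag = t$gag_aa, pol = t$pol_aa),
         gag_pol_fused = c(gagpol = t$gagpol_aa),
         pol_only = c(pol = t$pol_aa),
         gag_pol_env = c(gag = t$gag_aa, pol = t$pol_aa, env = t$env_aa),
         stop("unknown layout: ", t$layout))
}

validate_template <- function(t) {
  if (is.null(t$ltr_length) || t$ltr_length <= 0) {
    stop("template '", t$name, "': ltr_length must be positive")
  }
  aa <- template_protein_lengths(t)
  need <- 2L * t$ltr_length + sum(3L * aa + 3L)
  if (need > t$consensus_length) {
    stop("template '", t$name, "': LTRs + ORFs (", need,
         " bp) exceed consensus_length (", t$consensus_length, ")")
  }
  invisible(t)
}

#' Family-specific protein sequences of a template
#'
#' Each family's proteins embed family-varied copies of the shared domain
#' cores (30% of non-catalytic positions substituted) separated by
#' family-specific filler, so that domain detection fires on every family
#' while inter-family protein identity stays low.  Deterministic per family
#' (independent of any run seed) -- the bundled reference panel relies on
#' this.
#'
#' @param t A template from [family_templates()].
#' @param models Domain models whose cores are embedded.
#' @return Named list of protein strings (subset of gag, pol, gagpol, env).
#' @export
family_proteins <- function(t, models = load_domain_models()) {
  aa_lens <- template_protein_lengths(t)
  spacing <- if (is.null(t$dde_spacing)) 35L else t$dde_spacing
  with_seed(family_seed(t$family), {
    core <- lapply(models, function(m) {
      protect <- if (!is.null(m$catalytic)) unname(m$catalytic) else integer(0)
      v <- vary_core(m$consensus, 0.3, protect)
      if (m$name == "INT" && spacing != 35L) {
        chars <- strsplit(v, "", fixed = TRUE)[[1L]]
        cat <- m$catalytic
        chars[cat[["e"]] + 1L] <- "Q"
        pos_e <- cat[["d2"]] + spacing + 1L
        stopifnot(pos_e <= length(chars))
        chars[pos_e] <- "E"
        v <- paste(chars, collapse = "")
      }
      v
    })
    filler <- function(n) paste(sample(AA20, n, replace = TRUE), collapse = "")
    pol_block <- function(total) {
      cores <- paste0(core$POL, core$RT, core$RH, core$INT)
      n_core <- nchar(cores)
      rest <- total - n_core - 1L  # leading M
      stopifnot(rest >= 4L)
      seg <- diff(round(seq(0, rest, length.out = 6L)))
      paste0("M", filler(seg[1L]), core$POL, filler(seg[2L]), core$RT,
             filler(seg[3L]), core$RH, filler(seg[4L]), core$INT,
             filler(seg[5L]))
    }
    domain_block <- function(total, core_seq) {
      rest <- total - nchar(core_seq) - 1L
      stopifnot(rest >= 2L)
      a <- rest %/% 2L
      paste0("M", filler(a), core_seq, filler(rest - a))
    }
    prots <- list()
    for (nm in names(aa_lens)) {
      prots[[nm]] <- switch(nm,
        gag = domain_block(aa_lens[[nm]], core$GAG),
        env = domain_block(aa_lens[[nm]], core$ENV),
        pol = pol_block(aa_lens[[nm]]),
        gagpol = {
          gag_part <- ceiling(aa_lens[[nm]] / 4L)
          paste0(domain_block(gag_part, core$GAG),
                 substring(pol_block(aa_lens[[nm]] - gag_part + 1L), 2L))
        })
      stopifnot(nchar(prots[[nm]]) == aa_lens[[nm]])
    }
    prots
  })
}

## Reverse-translate a protein with uniformly sampled synonymous codons.
CODON_TABLE <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

reverse_translate <- function(protein) {
  chars <- strsplit(protein, "", fixed = TRUE)[[1L]]
  codons <- vapply(chars, function(a) {
    opts <- CODON_TABLE[[a]]
    opts[sample.int(length(opts), 1L)]
  }, "")
  paste(codons, collapse = "")
}

random_dna <- function(n, gc = 0.45) {
  if (n <= 0L) return("")
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

#' Build the consensus sequence of a family template
#'
#' Layout: 5'LTR + spacers interleaving the layout's ORFs (ATG start,
#' family-specific protein, stop codon) + 3'LTR.  The two LTRs are identical
#' (the state at insertion time), start with TG and end with CA.  The same
#' seed always yields the same sequence.
#'
#' @param t A template from [family_templates()].
#' @param seed Integer seed.
#' @param models Domain models (the template proteins embed their cores).
#' @return List with `seq`, `orfs` (data.frame: name, start, end 0-based
#'   half-open within the element, aa_len, protein), `ltr5`/`ltr3` interval
#'   vectors `c(start, end)`, and `template`.
#' @export
build_template_consensus <- function(t, seed, models = load_domain_models()) {
  validate_template(t)
  prots <- family_proteins(t, models)
  ## mix the template name into the stream so that two templates built with
  ## the same seed do not share random draws (which would correlate their
  ## LTRs and spacers across families)
  with_seed(derive_seed(seed, t$name), {
    L <- t$ltr_length
    ltr <- random_dna(L)
    substr(ltr, 1L, 2L) <- "TG"
    substr(ltr, L - 1L, L) <- "CA"
    orf_dna <- lapply(prots, function(p) {
      paste0(reverse_translate(p), sample(c("TAA", "TAG", "TGA"), 1L))
    })
    spare <- t$consensus_length - 2L * L - sum(nchar(unlist(orf_dna)))
    n_gap <- length(orf_dna) + 1L
    gaps <- diff(round(seq(0, spare, length.out = n_gap + 1L)))
    pieces <- character(0)
    orf_rows <- list()
    pos <- L
    for (i in seq_along(orf_dna)) {
      sp <- random_dna(gaps[i])
      pos <- pos + nchar(sp)
      orf_rows[[i]] <- data.frame(name = names(orf_dna)[i], start = pos,
                                  end = pos + nchar(orf_dna[[i]]),
                                  aa_len = nchar(prots[[i]]),
                                  protein = prots[[i]],
                                  stringsAsFactors = FALSE)
      pos <- pos + nchar(orf_dna[[i]])
      pieces <- c(pieces, sp, orf_dna[[i]])
    }
    pieces <- c(pieces, random_dna(gaps[n_gap]))
    seq <- paste0(ltr, paste(pieces, collapse = ""), ltr)
    stopifnot(nchar(seq) == t$consensus_length)
    list(seq = seq,
         orfs = do.call(rbind, orf_rows),
         ltr5 = c(0L, L),
         ltr3 = c(t$consensus_length - L, t$consensus_length),
         template = t)
  })
}

## K2P closed-form category probabilities at distance d with ts/tv rate
## ratio kappa: P(transition), P(transversion), P(no net change).
k2p_probs <- function(d, kappa) {
  bt <- d / (kappa + 2)
  at <- kappa * bt
  p_ts <- 0.25 + 0.25 * exp(-4 * bt) - 0.5 * exp(-2 * (at + bt))
  p_tv <- 0.5 - 0.5 * exp(-4 * bt)
  c(ts = p_ts, tv = p_tv)
}

TS_MAP <- c(A = "G", G = "A", C = "T", T = "C")
TV_MAP <- list(A = c("C", "T"), G = c("C", "T"), C = c("A", "G"), T = c("A", "G"))

## Mutate chars[lo:hi] (1-based inclusive) in place under K2P at distance d.
mutate_region <- function(chars, lo, hi, d, kappa) {
  if (hi < lo || d <= 0) return(chars)
  pr <- k2p_probs(d, kappa)
  idx <- lo:hi
  u <- stats::runif(length(idx))
  base <- chars[idx]
  valid <- base %in% c("A", "C", "G", "T")
  ts_sel <- valid & u < pr[["ts"]]
  tv_sel <- valid & u >= pr[["ts"]] & u < pr[["ts"]] + pr[["tv"]]
  chars[idx[ts_sel]] <- TS_MAP[base[ts_sel]]
  if (any(tv_sel)) {
    pick <- stats::runif(sum(tv_sel)) < 0.5
    chars[idx[tv_sel]] <- vapply(seq_len(sum(tv_sel)), function(k) {
      TV_MAP[[base[tv_sel][k]]][if (pick[k]) 1L else 2L]
    }, "")
  }
  chars
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

## Purifying selection on ORFs: redraw substitutions that create an in-frame
## premature stop, and revert changes that destroy a terminal stop codon.
repair_orfs <- function(chars, orig, orfs) {
  for (i in seq_len(nrow(orfs))) {
    s <- orfs$start[i]; e <- orfs$end[i]
    starts <- seq(s + 1L, e - 2L, by = 3L)
    cod <- paste0(chars[starts], chars[starts + 1L], chars[starts + 2L])
    term <- length(cod)
    if (!cod[term] %in% STOP_CODONS) {
      p <- starts[term]
      chars[p:(p + 2L)] <- orig[p:(p + 2L)]
    }
    bad <- which(cod[-term] %in% STOP_CODONS)
    for (b in bad) {
      p <- starts[b]
      pos <- p + 0:2
      mut <- pos[chars[pos] != orig[pos]]
      fixed <- FALSE
      for (m in mut) {
        for (alt in setdiff(c("A", "C", "G", "T"), c(chars[m], orig[m]))) {
          trial <- chars[pos]
          trial[m - p + 1L] <- alt
          if (!paste(trial, collapse = "") %in% STOP_CODONS) {
            chars[m] <- alt
            fixed <- TRUE
            break
          }
        }
        if (fixed) break
      }
      if (!fixed) chars[pos] <- orig[pos]
    }
  }
  chars
}

#' Mutate an element copy under the Kimura two-parameter clock
#'
#' Substitutions are drawn from the closed-form K2P category probabilities at
#' the target distance, so [kimura2p()] inverts the process exactly in
#' expectation (multiple hits included).  The internal region diverges at
#' 2*r*age (the copy-vs-consensus clock convention behind t = K/2r) while
#' each LTR, when its interval is supplied, diverges at r*age per lineage so
#' that the divergence between the two LTRs of a copy is 2*r*age as well --
#' both dating channels are then exactly self-consistent.  With
#' `preserve_orfs`, substitutions that would create a premature stop in a
#' supplied ORF are redrawn (purifying selection on active elements).
#'
#' @param seq Element sequence (character scalar).
#' @param age_My Insertion age in millions of years.
#' @param rate_r Clock rate, substitutions/site/year (default 1e-8).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param seed Integer seed.
#' @param ltr5,ltr3 Optional `c(start, end)` 0-based half-open LTR intervals.
#' @param orfs Optional ORF data.frame (from [build_template_consensus()]).
#' @param preserve_orfs Reject nonsense substitutions within ORFs.
#' @return List with `seq`, realized `transitions`, `transversions`,
#'   `n_changed`.
#' @export
mutate_copy <- function(seq, age_My, rate_r = 1e-8, kappa = 2, seed = 1L,
                        ltr5 = NULL, ltr3 = NULL, orfs = NULL,
                        preserve_orfs = TRUE) {
  stopifnot(age_My >= 0, rate_r > 0, kappa > 0)
  orig <- strsplit(seq, "", fixed = TRUE)[[1L]]
  n <- length(orig)
  d_int <- 2 * rate_r * age_My * 1e6
  d_ltr <- rate_r * age_My * 1e6
  chars <- orig
  chars <- with_seed(seed, {
    if (is.null(ltr5) && is.null(ltr3)) {
      chars <- mutate_region(chars, 1L, n, d_int, kappa)
    } else {
      covered <- rep(FALSE, n)
      for (iv in list(ltr5, ltr3)) {
        if (!is.null(iv)) {
          chars <- mutate_region(chars, iv[1L] + 1L, iv[2L], d_ltr, kappa)
          covered[(iv[1L] + 1L):iv[2L]] <- TRUE
        }
      }
      runs <- rle(covered)
      ends <- cumsum(runs$lengths)
      starts <- ends - runs$lengths + 1L
      for (k in which(!runs$values)) {
        chars <- mutate_region(chars, starts[k], ends[k], d_int, kappa)
      }
      chars
    }
    if (preserve_orfs && !is.null(orfs) && nrow(orfs) > 0L) {
      chars <- repair_orfs(chars, orig, orfs)
    }
    chars
  })
  diff <- which(chars != orig)
  pur <- c("A", "G")
  is_ts <- (orig[diff] %in% pur) == (chars[diff] %in% pur)
  list(seq = paste(chars, collapse = ""),
       transitions = sum(is_ts),
       transversions = sum(!is_ts),
       n_changed = length(diff))
}

#' Generate a genome with implanted LTR retrotransposons and truth records
#'
#' The background is i.i.d. with the requested GC; implants are spliced in at
#' uniformly drawn, non-overlapping positions separated by at least
#' `min_gap` bp (neighbouring same-family copies closer than the element
#' length bound would create chimeric LTR pairings that are structurally
#' indistinguishable from real elements; real full-length elements are far
#' sparser than any desk-scale benchmark).  Each implant is a mutated copy of
#' its template consensus; full copies keep both LTRs, truncated copies lose
#' one LTR plus 30-60% of the internal region, solo LTRs are a single LTR.
#' A target-site duplication of `tsd_len` bp flanks each implant.
#'
#' @param genome_size Background size in bp (final genome is larger by the
#'   implanted length).
#' @param gc Background GC fraction.
#' @param plans List of implant plans; each a list with `template` (name or
#'   template object), `n_full`, `n_truncated`, `n_solo`, `ages_My`
#'   (recycled over copies), and optional `rate_r`, `kappa`.
#' @param seed Root seed; all sampling derives from it.
#' @param min_gap Minimum distance between implant insertion points (bp).
#' @param tsd_len Target-site duplication length (0 disables).
#' @param contig Contig name of the emitted genome.
#' @return List: `genome` (named character vector), `truth` (data.frame with
#'   interval, class, template, family, ages, LTR sub-intervals, realized
#'   substitution counts), `consensus` (per-template consensus objects),
#'   `config` (echo of the arguments).
#' @export
implant <- function(genome_size, gc = 0.45, plans = list(), seed = 1L,
                    min_gap = 10000L, tsd_len = 5L, contig = "synth1") {
  stopifnot(genome_size > 0)
  templates <- family_templates(include_short = TRUE)
  copies <- list()
  consensus <- list()
  for (pi in seq_along(plans)) {
    plan <- plans[[pi]]
    t <- if (is.character(plan$template)) {
      if (!plan$template %in% names(templates)) stop("unknown template: ", plan$template)
      templates[[plan$template]]
    } else plan$template
    rate_r <- if (is.null(plan$rate_r)) 1e-8 else plan$rate_r
    kappa <- if (is.null(plan$kappa)) 2 else plan$kappa
    if (is.null(consensus[[t$name]])) {
      consensus[[t$name]] <- build_template_consensus(t, derive_seed(seed, t$name))
    }
    cons <- consensus[[t$name]]
    classes <- rep(c("full", "truncated", "solo_ltr"),
                   c(plan$n_full %||% 0L, plan$n_truncated %||% 0L,
                     plan$n_solo %||% 0L))
    if (length(classes) == 0L) next
    ages <- rep_len(plan$ages_My %||% 0, length(classes))
    for (ci in seq_along(classes)) {
      cseed <- derive_seed(seed, paste0(t$name, "#", ci))
      cls <- classes[ci]
      if (cls == "solo_ltr") {
        ltr <- substr(cons$seq, 1L, t$ltr_length)
        mut <- mutate_copy(ltr, ages[ci], rate_r, kappa, cseed)
        copies[[length(copies) + 1L]] <- list(
          seq = mut$seq, class = cls, template = t, age = ages[ci],
          n_sub = mut$n_changed,
          ltr5 = c(0L, t$ltr_length), ltr3 = NULL)
      } else {
        mut <- mutate_copy(cons$seq, ages[ci], rate_r, kappa, cseed,
                           ltr5 = cons$ltr5, ltr3 = cons$ltr3,
                           orfs = cons$orfs,
                           preserve_orfs = (cls == "full"))
        if (cls == "full") {
          copies[[length(copies) + 1L]] <- list(
            seq = mut$seq, class = cls, template = t, age = ages[ci],
            n_sub = mut$n_changed, ltr5 = cons$ltr5, ltr3 = cons$ltr3)
        } else {
          keep_side <- with_seed(derive_seed(cseed, 1L),
                                 sample(c("5p", "3p"), 1L))
          frac <- with_seed(derive_seed(cseed, 2L), stats::runif(1L, 0.3, 0.6))
          L <- t$ltr_length
          int_len <- nchar(mut$seq) - 2L * L
          cut <- round(frac * int_len)
          if (keep_side == "5p") {
            s <- substr(mut$seq, 1L, L + (int_len - cut))
            ltr5 <- c(0L, L); ltr3 <- NULL
          } else {
            s <- substr(mut$seq, L + cut + 1L, nchar(mut$seq))
            ltr5 <- NULL; ltr3 <- c(nchar(s) - L, nchar(s))
          }
          copies[[length(copies) + 1L]] <- list(
            seq = s, class = cls, template = t, age = ages[ci],
            n_sub = NA_integer_, ltr5 = ltr5, ltr3 = ltr3)
        }
      }
    }
  }
  total_implant <- sum(vapply(copies, function(cp) nchar(cp$seq), 0))
  if (total_implant >= genome_size) {
    stop("total implanted length (", total_implant,
         ") must be below genome size (", genome_size, ")")
  }
  background <- with_seed(derive_seed(seed, "background"),
                          random_dna(genome_size, gc))
  n_cp <- length(copies)
  points <- integer(0)
  if (n_cp > 0L) {
    points <- with_seed(derive_seed(seed, "placement"), {
      pts <- integer(0)
      tries <- 0L
      lo <- max(tsd_len, 1L)
      while (length(pts) < n_cp) {
        cand <- sample.int(genome_size - 2L * min_gap, 1L) + min_gap
        if (cand > lo && all(abs(cand - pts) >= min_gap)) {
          pts <- c(pts, cand)
        }
        tries <- tries + 1L
        if (tries > 1000L * n_cp) {
          stop("implant placement failed: cannot satisfy min_gap = ", min_gap)
        }
      }
      sort(pts)
    })
    ord <- with_seed(derive_seed(seed, "order"), sample.int(n_cp))
    copies <- copies[ord]
  }
  pieces <- character(0)
  truth_rows <- list()
  prev <- 0L
  offset <- 0L
  for (k in seq_len(n_cp)) {
    p <- points[k]
    cp <- copies[[k]]
    pieces <- c(pieces, substr(background, prev + 1L, p))
    tsd <- if (tsd_len > 0L) substr(background, p - tsd_len + 1L, p) else ""
    start <- p + offset
    len <- nchar(cp$seq)
    pieces <- c(pieces, cp$seq, tsd)
    iv <- function(x, base) if (is.null(x)) c(NA_integer_, NA_integer_) else x + base
    l5 <- iv(cp$ltr5, start)
    l3 <- iv(cp$ltr3, start)
    truth_rows[[k]] <- data.frame(
      ID = sprintf("implant%03d", k), contig = contig,
      start = start, end = start + len, strand = "+",
      class = cp$class, template = cp$template$name,
      family = cp$template$family, superfamily = cp$template$superfamily,
      age_My = cp$age, n_sub = cp$n_sub, length_bp = len,
      ltr5_start = l5[1L], ltr5_end = l5[2L],
      ltr3_start = l3[1L], ltr3_end = l3[2L],
      stringsAsFactors = FALSE)
    offset <- offset + len + nchar(tsd)
    prev <- p
  }
  pieces <- c(pieces, substr(background, prev + 1L, genome_size))
  genome <- stats::setNames(paste(pieces, collapse = ""), contig)
  truth <- if (n_cp > 0L) do.call(rbind, truth_rows) else
    data.frame(ID = character(), contig = character(), start = integer(),
               end = integer(), strand = character(), class = character(),
               template = character(), family = character(),
               superfamily = character(), age_My = numeric(), n_sub = integer(),
               length_bp = integer(), ltr5_start = integer(),
               ltr5_end = integer(), ltr3_start = integer(),
               ltr3_end = integer(), stringsAsFactors = FALSE)
  list(genome = genome, truth = truth, consensus = consensus,
       config = list(genome_size = genome_size, gc = gc, seed = seed,
                     min_gap = min_gap, tsd_len = tsd_len,
                     n_implants = n_cp))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a synthetic run to disk (FASTA genome, truth GFF3, manifest TSV,
#' JSON config echo)
#'
#' @param run Result of [implant()].
#' @param dir Output directory (created if needed).
#' @export
write_synth_run <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_fasta(run$genome, file.path(dir, "genome.fa"))
  seqlens <- stats::setNames(nchar(run$genome), names(run$genome))
  truth <- run$truth
  gff <- truth[, c("contig", "start", "end", "strand", "ID", "class",
                   "template", "family", "age_My")]
  gff$type <- "LTR_retrotransposon"
  write_gff3(gff, file.path(dir, "truth.gff3"), seqlens = seqlens)
  utils::write.table(truth, file.path(dir, "manifest.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$config, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
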