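#' @importFrom Biostrings readBStringSet writeXStringSet DNAStringSet DNAString
#'   reverseComplement translate AAString pairwiseAlignment nmatch
#'   alignedPattern alignedSubject nucleotideSubstitutionMatrix
#' @importFrom stats setNames runif rbinom
#' @importFrom utils head tail
NULL

VALID_BASES <- c("A", "C", "G", "T", "N")

#' Read a FASTA file of genome sequences
#'
#' Sequences are uppercased and any residue outside A/C/G/T/N is collapsed to
#' N (ambiguity codes carry no information for the 4-letter k-mer machinery
#' downstream).  The number of collapsed residues is reported via a message
#' and attached as the `n_ambiguous` attribute.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per record (names are the
#'   first whitespace-delimited token of each header), with attribute
#'   `n_ambiguous`.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  bs <- Biostrings::readBStringSet(path)
  if (length(bs) == 0L) stop("FASTA format error: file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(bs))
  if (any(ids == "")) stop("FASTA format error: record with empty id in ", path)
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0L) {
    stop("FASTA format error: duplicate id '", dup[[1L]], "' in ", path)
  }
  s <- toupper(as.character(bs))
  cleaned <- gsub("[^ACGTN]", "N", s)
  n_bad <- sum(nchar(gsub("[ACGTN]", "", s)))
  if (n_bad > 0L) {
    message("read_fasta: collapsed ", n_bad, " non-ACGTN residue(s) to N")
  }
  out <- stats::setNames(cleaned, ids)
  attr(out, "n_ambiguous") <- n_bad
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector of sequences.
#' @param path Output path.
#' @param width Line wrap width (default 60).
#' @export
write_fasta <- function(seqs, path, width = 60L) {
  stopifnot(length(seqs) > 0L, !is.null(names(seqs)))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Reverse complement
#'
#' A<->T, C<->G, N<->N.  Involution: `reverse_complement(reverse_complement(x))`
#' is `x`.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
reverse_complement <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

#' Translate one of six reading frames
#'
#' Frames 0-2 are offsets on the forward strand, frames 3-5 the same offsets
#' on the reverse complement.  The standard genetic code is used; stop codons
#' are rendered as `*`; an incomplete trailing codon is dropped; codons
#' containing N translate to X.
#'
#' @param x A single DNA sequence (character scalar).
#' @param frame Integer 0-5.
#' @return Character scalar amino-acid sequence (possibly empty).
#' @export
translate_frame <- function(x, frame) {
  stopifnot(length(x) == 1L, frame %in% 0:5)
  s <- if (frame >= 3L) reverse_complement(x) else x
  off <- frame %% 3L
  n <- nchar(s)
  if (n - off < 3L) return("")
  len <- ((n - off) %/% 3L) * 3L
  sub <- substr(s, off + 1L, off + len)
  aa <- Biostrings::translate(Biostrings::DNAString(sub), if.fuzzy.codon = "solve",
                              no.init.codon = TRUE)
  as.character(aa)
}

#' Validate genomic intervals (0-based half-open)
#'
#' @param iv data.frame with columns contig, start, end (and optionally
#'   strand); coordinates 0-based half-open.
#' @param seqlens Optional named vector of contig lengths for bounds checks.
#' @return The validated data.frame, invisibly usable.
#' @export
validate_intervals <- function(iv, seqlens = NULL) {
  stopifnot(all(c("contig", "start", "end") %in% names(iv)))
  if (nrow(iv) == 0L) return(iv)
  bad <- which(!(iv$start >= 0 & iv$start < iv$end))
  if (length(bad) > 0L) {
    stop("invalid interval (need 0 <= start < end) at row ", bad[[1L]])
  }
  if (!is.null(seqlens)) {
    unknown <- setdiff(unique(iv$contig), names(seqlens))
    if (length(unknown) > 0L) stop("interval on unknown contig: ", unknown[[1L]])
    over <- which(iv$end > seqlens[iv$contig])
    if (length(over) > 0L) {
      stop("interval exceeds contig length at row ", over[[1L]], " (",
           iv$contig[over[[1L]]], ":", iv$start[over[[1L]]], "-", iv$end[over[[1L]]], ")")
    }
  }
  iv
}

## GFF3 I/O.  Internal coordinates are 0-based half-open; GFF3 is 1-based
## inclusive, so start maps to start+1 and the half-open end is numerically
## the inclusive end.  Columns beyond the interval/type/ID become
## key=value attribute pairs and round-trip through read_gff3.

#' Write intervals as GFF3
#'
#' @param iv data.frame with columns contig, start, end and optionally
#'   strand, type, ID; any further columns become GFF3 attributes.
#' @param path Output path.
#' @param seqlens Optional named contig lengths; written as
#'   `##sequence-region` directives and used for bounds validation.
#' @param source Value of the GFF3 source column.
#' @export
write_gff3 <- function(iv, path, seqlens = NULL, source = "tetraltr") {
  validate_intervals(iv, seqlens)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (!is.null(seqlens)) {
    writeLines(paste("##sequence-region", names(seqlens), 1L, unname(seqlens)), con)
  }
  if (nrow(iv) == 0L) return(invisible(path))
  type <- if ("type" %in% names(iv)) iv$type else rep("LTR_retrotransposon", nrow(iv))
  strand <- if ("strand" %in% names(iv)) iv$strand else rep("+", nrow(iv))
  id <- if ("ID" %in% names(iv)) iv$ID else paste0("feat", seq_len(nrow(iv)))
  extra <- setdiff(names(iv), c("contig", "start", "end", "strand", "type", "ID"))
  attrs <- paste0("ID=", id)
  for (col in extra) {
    val <- iv[[col]]
    keep <- !is.na(val)
    add <- ifelse(keep, paste0(";", col, "=", val), "")
    attrs <- paste0(attrs, add)
  }
  lines <- paste(iv$contig, source, type, iv$start + 1L, iv$end, ".", strand, ".",
                 attrs, sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a GFF3 file written by [write_gff3()]
#'
#' @param path GFF3 path.
#' @return data.frame with 0-based half-open coordinates and one column per
#'   attribute key.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  if (length(body) == 0L) {
    return(data.frame(contig = character(), start = integer(), end = integer(),
                      strand = character(), type = character(), ID = character(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(body, "\t", fixed = TRUE)
  if (any(lengths(f) != 9L)) stop("GFF3 format error: expected 9 columns in ", path)
  m <- do.call(rbind, f)
  out <- data.frame(contig = m[, 1L],
                    start = as.integer(m[, 4L]) - 1L,
                    end = as.integer(m[, 5L]),
                    strand = m[, 7L],
                    type = m[, 3L],
                    stringsAsFactors = FALSE)
  attr_list <- lapply(strsplit(m[, 9L], ";", fixed = TRUE), function(kv) {
    parts <- strsplit(kv, "=", fixed = TRUE)
    stats::setNames(vapply(parts, function(p) paste(p[-1L], collapse = "="), ""),
                    vapply(parts, `[[`, "", 1L))
  })
  keys <- unique(unlist(lapply(attr_list, names)))
  for (k in keys) {
    v <- vapply(attr_list, function(a) if (k %in% names(a)) a[[k]] else NA_character_, "")
    suppressWarnings(num <- as.numeric(v))
    out[[k]] <- if (!anyNA(num[!is.na(v)])) num else v
  }
  if ("ID" %in% names(out)) out$ID <- as.character(out$ID)
  out
}
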