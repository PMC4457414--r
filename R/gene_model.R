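# Gene models: one species' gene as ordered exons on a genomic sequence.
# Coordinates are 0-based half-open genomic intervals; all intron-level work
# happens in transcript orientation, so '-' strand genes are handled once
# here and nowhere else.

#' Construct a gene model
#'
#' A gene model is a set of non-overlapping exons on a genomic sequence
#' (typically the slice from predicted start to stop codon). Introns are the
#' gaps between consecutive exons. Models whose spliced CDS length is not a
#' multiple of 3 are flagged `partial` rather than rejected, mirroring how
#' truncated gene predictions are treated downstream (they contribute MISSING
#' cells to landscapes).
#'
#' @param gene_id gene identifier.
#' @param species species identifier.
#' @param strand "+" or "-".
#' @param exons two-column matrix or data.frame (`start`, `end`) of 0-based
#'   half-open genomic intervals, in any order; they are sorted by start.
#' @param genomic_seq nucleotide string covering all exons.
#' @return object of class `gene_model`.
#' @export
gene_model <- function(gene_id, species, strand, exons, genomic_seq) {
  stopifnot(is.character(gene_id), is.character(species),
            strand %in% c("+", "-"), nchar(genomic_seq) > 0)
  exons <- as.matrix(exons)
  if (ncol(exons) != 2) stop("exons must have two columns (start, end)")
  colnames(exons) <- c("start", "end")
  storage.mode(exons) <- "integer"
  exons <- exons[order(exons[, "start"]), , drop = FALSE]
  if (nrow(exons) == 0) stop("gene ", gene_id, ": no exons")
  if (any(exons[, "end"] <= exons[, "start"]))
    stop("gene ", gene_id, ": empty or inverted exon interval")
  if (max(exons[, "end"]) > nchar(genomic_seq))
    stop("gene ", gene_id, ": exon beyond genomic sequence")
  if (nrow(exons) > 1) {
    gaps <- exons[-1, "start"] - exons[-nrow(exons), "end"]
    if (any(gaps < 0))
      stop("gene ", gene_id, ": overlapping exons")
    if (any(gaps > 0 & gaps < 4))
      stop("gene ", gene_id, ": intron shorter than 4 nt")
    if (any(gaps == 0))
      stop("gene ", gene_id, ": abutting exons (zero-length intron)")
  }
  cds_len <- sum(exons[, "end"] - exons[, "start"])
  structure(list(
    gene_id = gene_id, species = species, strand = strand,
    exons = exons, genomic_seq = toupper(genomic_seq),
    cds_length = cds_len, partial = (cds_len %% 3L != 0L)
  ), class = "gene_model")
}

#' @export
print.gene_model <- function(x, ...) {
  cat(sprintf("<gene_model> %s (%s) strand %s: %d exon(s), CDS %d nt%s\n",
              x$gene_id, x$species, x$strand, nrow(x$exons), x$cds_length,
              if (x$partial) " [partial]" else ""))
  invisible(x)
}

# Exon sequences in transcript (5'->3') order, strand-corrected.
.transcript_exons <- function(gene) {
  seqs <- apply(gene$exons, 1, function(e)
    substr(gene$genomic_seq, e[1] + 1L, e[2]))
  if (gene$strand == "-") seqs <- rev(vapply(seqs, revcomp, character(1)))
  unname(seqs)
}

#' Spliced coding sequence of a gene model
#'
#' Concatenates the exon sequences in transcript orientation (reverse
#' complemented for '-' strand genes).
#'
#' @param gene a [gene_model()].
#' @return nucleotide string.
#' @export
splice_cds <- function(gene) paste(.transcript_exons(gene), collapse = "")

#' Test a spliced CDS for internal stop codons
#'
#' Pseudogenized orthologues are recognised by an in-frame stop codon in the
#' spliced CDS. The terminal codon is not counted.
#'
#' @param cds nucleotide string, length divisible by 3.
#' @return `TRUE` if an internal stop codon is present.
#' @export
has_internal_stop <- function(cds) {
  stopifnot(nchar(cds) %% 3 == 0)
  n <- nchar(cds)
  if (n < 6) return(FALSE)
  starts <- seq(1L, n - 5L, by = 3L)
  any(substring(cds, starts, starts + 2L) %in% c("TAA", "TAG", "TGA"))
}

#' Extract intron instances from a gene model
#'
#' One intron per inter-exon gap, in transcript order. `cds_offset` counts
#' coding nucleotides 5' of the intron, so `cds_offset %% 3` is the intron
#' phase. Sequences are strand-corrected (always written 5'->3' on the
#' transcript).
#'
#' @param gene a [gene_model()].
#' @return data.frame with columns `gene_id`, `species`, `ordinal`,
#'   `cds_offset`, `length`, `sequence`, `donor`, `acceptor`, `intron_class`.
#' @export
extract_introns <- function(gene) {
  stopifnot(inherits(gene, "gene_model"))
  n <- nrow(gene$exons)
  empty <- data.frame(
    gene_id = character(0), species = character(0), ordinal = integer(0),
    cds_offset = integer(0), length = integer(0), sequence = character(0),
    donor = character(0), acceptor = character(0),
    intron_class = character(0), stringsAsFactors = FALSE)
  if (n == 1) return(empty)
  # genomic gaps in ascending order
  gaps <- cbind(start = gene$exons[-n, "end"], end = gene$exons[-1, "start"])
  gap_seq <- apply(gaps, 1, function(g)
    substr(gene$genomic_seq, g[1] + 1L, g[2]))
  exon_len <- gene$exons[, "end"] - gene$exons[, "start"]
  if (gene$strand == "+") {
    ord_seq <- gap_seq
    offsets <- cumsum(exon_len)[-n]
  } else {
    ord_seq <- rev(vapply(gap_seq, revcomp, character(1)))
    offsets <- cumsum(rev(exon_len))[-n]
  }
  out <- data.frame(
    gene_id = gene$gene_id, species = gene$species,
    ordinal = seq_len(n - 1L),
    cds_offset = as.integer(offsets),
    length = nchar(ord_seq),
    sequence = unname(ord_seq),
    donor = substr(ord_seq, 1, 2),
    acceptor = substr(ord_seq, nchar(ord_seq) - 1, nchar(ord_seq)),
    intron_class = "UNCLASSIFIED",
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Assemble a gene model from a CDS and an intron table
#'
#' Inverse of [extract_introns()] + [splice_cds()]: interleaves intron
#' sequences into a coding sequence at the given coding offsets and derives
#' the exon intervals. Used by the simulator and fixture builders.
#'
#' @param gene_id,species identifiers.
#' @param cds coding sequence (transcript orientation).
#' @param introns data.frame with `cds_offset` and `sequence` (may have 0
#'   rows).
#' @param strand "+" (default) or "-"; for "-" the emitted genomic sequence is
#'   the reverse complement of the transcript-orientation assembly.
#' @return a [gene_model()].
#' @export
assemble_gene <- function(gene_id, species, cds, introns, strand = "+") {
  if (nrow(introns) > 0) {
    stopifnot(all(introns$cds_offset > 0),
              all(introns$cds_offset < nchar(cds)),
              !anyDuplicated(introns$cds_offset))
    introns <- introns[order(introns$cds_offset), , drop = FALSE]
  }
  offs <- c(0L, introns$cds_offset, nchar(cds))
  pieces <- character(0)
  exon_lens <- integer(0)
  for (i in seq_len(length(offs) - 1L)) {
    ex <- substr(cds, offs[i] + 1L, offs[i + 1L])
    exon_lens <- c(exon_lens, nchar(ex))
    pieces <- c(pieces, ex)
    if (i <= nrow(introns)) pieces <- c(pieces, introns$sequence[i])
  }
  genomic <- paste(pieces, collapse = "")
  # transcript-orientation exon coordinates
  intron_lens <- nchar(introns$sequence)
  starts <- integer(length(exon_lens)); ends <- integer(length(exon_lens))
  pos <- 0L
  for (i in seq_along(exon_lens)) {
    starts[i] <- pos; ends[i] <- pos + exon_lens[i]
    pos <- ends[i] + if (i <= length(intron_lens)) intron_lens[i] else 0L
  }
  if (strand == "-") {
    L <- nchar(genomic)
    genomic <- revcomp(genomic)
    new_starts <- L - ends; new_ends <- L - starts
    starts <- rev(new_starts); ends <- rev(new_ends)
  }
  gene_model(gene_id, species, strand,
             cbind(start = starts, end = ends), genomic)
}
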