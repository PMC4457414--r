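# Standard-format I/O: FASTA via Biostrings, GFF3 via rtracklayer, newick via
# ape. Gene models live on one contig each; the GFF3 carries exon features
# grouped by their Parent gene ID.

#' Read a DNA FASTA file
#' @param path FASTA file.
#' @return named character vector of sequences.
#' @export
read_dna_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to FASTA
#' @param seqs named character vector.
#' @param path output file.
#' @export
write_dna_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}

#' Read an aligned protein FASTA
#'
#' All rows must have equal length; row names are species identifiers.
#'
#' @param path aligned FASTA file.
#' @return named character vector (one aligned row per species).
#' @export
read_protein_alignment <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  rows <- stats::setNames(as.character(x), names(x))
  if (length(unique(nchar(rows))) != 1)
    stop("alignment rows differ in length: ", path)
  rows
}

#' Read a rooted species tree in newick format
#' @param path newick file.
#' @return an `ape` `phylo` object.
#' @export
read_species_tree <- function(path) {
  tr <- ape::read.tree(path)
  if (anyDuplicated(tr$tip.label)) stop("duplicate leaf names in tree: ", path)
  tr
}

#' Write gene models as genomic FASTA + GFF3
#'
#' Each gene model is emitted on its own contig named
#' `<species>|<gene_id>`; exon features carry `Parent=<gene_id>`.
#'
#' @param genes list of [gene_model()] objects.
#' @param fasta_path,gff3_path output files.
#' @export
write_gene_models <- function(genes, fasta_path, gff3_path) {
  contigs <- stats::setNames(
    vapply(genes, `[[`, character(1), "genomic_seq"),
    vapply(genes, function(g) paste(g$species, g$gene_id, sep = "|"),
           character(1)))
  write_dna_fasta(contigs, fasta_path)
  rows <- do.call(rbind, lapply(genes, function(g) data.frame(
    contig = paste(g$species, g$gene_id, sep = "|"),
    start = g$exons[, "start"] + 1L,
    end = g$exons[, "end"],
    strand = g$strand,
    ID = paste(g$species, g$gene_id, "exon", seq_len(nrow(g$exons)),
               sep = "."),
    Parent = g$gene_id,
    species = g$species,
    stringsAsFactors = FALSE)))
  gr <- GenomicRanges::GRanges(
    seqnames = rows$contig,
    ranges = IRanges::IRanges(start = rows$start, end = rows$end),
    strand = rows$strand,
    type = "exon", ID = rows$ID, Parent = rows$Parent,
    species = rows$species)
  rtracklayer::export(gr, gff3_path, format = "gff3")
  invisible(gff3_path)
}

#' Read gene models from GFF3 + genomic FASTA
#'
#' Exon features are grouped by their `Parent` attribute (falling back to
#' `gene_id`), one gene model per group. The contig naming convention of
#' [write_gene_models()] (`species|gene`) is used to recover the species when
#' no `species` attribute is present.
#'
#' @param gff3_path GFF3 with exon features.
#' @param fasta_path genomic FASTA (contig names matching the GFF3 seqnames).
#' @return named list of [gene_model()] objects (names = gene IDs).
#' @export
read_gene_models <- function(gff3_path, fasta_path) {
  contigs <- read_dna_fasta(fasta_path)
  gr <- rtracklayer::import(gff3_path, format = "gff3")
  gr <- gr[gr$type == "exon"]
  meta <- S4Vectors::mcols(gr)
  parent <- if ("Parent" %in% colnames(meta)) {
    vapply(meta$Parent, function(p) as.character(p)[1], character(1))
  } else as.character(meta$gene_id)
  contig_of <- as.character(GenomicRanges::seqnames(gr))
  # a gene lives on one contig; orthologue sets reuse a gene ID across
  # species, so exon groups are keyed by (contig, Parent)
  key <- paste(contig_of, parent, sep = "\r")
  out <- list()
  for (k in unique(key)) {
    sub <- gr[key == k]
    gid <- parent[key == k][1]
    contig <- as.character(GenomicRanges::seqnames(sub))[1]
    if (!contig %in% names(contigs))
      stop("contig ", contig, " absent from FASTA")
    sp <- if ("species" %in% colnames(S4Vectors::mcols(sub)) &&
              !is.na(S4Vectors::mcols(sub)$species[1])) {
      as.character(S4Vectors::mcols(sub)$species[1])
    } else sub("\\|.*$", "", contig)
    nm <- if (is.null(out[[gid]])) gid else contig
    out[[nm]] <- gene_model(
      gene_id = gid, species = sp,
      strand = as.character(GenomicRanges::strand(sub))[1],
      exons = cbind(start = GenomicRanges::start(sub) - 1L,
                    end = GenomicRanges::end(sub)),
      genomic_seq = contigs[[contig]])
  }
  out
}
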