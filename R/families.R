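# ILE families: single-linkage clustering of intron sequences by pairwise
# identity, IUPAC consensus construction, assignment of new sequences to
# families and length-based intron classification (ILE / RSI / degenerate-ILE
# candidate).

#' Default thresholds for family building, classification and landscapes
#'
#' * `cluster_threshold` (0.80): single-linkage clustering joins sequences
#'   with pairwise identity strictly above this fraction.
#' * `min_identity` (0.70): minimum identity to a family consensus for a
#'   query to be assigned to that family.
#' * `rsi_range` (40--60 bp): length range treated as a regular spliceosomal
#'   intron when no family matches (fungal RSIs are typically 50--55 bp).
#' * `long_intron` (70 bp): unassigned introns at least this long are flagged
#'   degenerate-ILE candidates (ILE-scale lengths, e.g. 81/87 bp, without
#'   recognisable family identity).
#' * `activity` (0.98): a family whose best pair reaches this identity is
#'   considered still actively multiplying.
#' * `sliding_window` (15 nt): positions strictly closer than this are
#'   sliding/parallel-gain candidates.
#' * `shift_window` (1 codon): boundary refinement may snap a projected
#'   position onto a nearby shared position at most this many codons away.
#' * `flank` (12 nt): exonic context length per side used when scoring a snap.
#' * `min_family_loci` (2): a built family only counts as an ILE family when
#'   its members span at least this many distinct loci (gene x position) —
#'   near-identical copies in unrelated places are the defining ILE property.
#' * `identity_denominator`: "alignment" (default; internal gaps count) or
#'   "columns" (gapped columns excluded).
#'
#' @param ... named overrides of the defaults above.
#' @return named list of parameters.
#' @export
ile_params <- function(...) {
  p <- list(
    cluster_threshold = 0.80,
    min_identity = 0.70,
    rsi_range = c(40L, 60L),
    long_intron = 70L,
    activity = 0.98,
    sliding_window = 15L,
    shift_window = 1L,
    flank = 12L,
    min_family_loci = 2L,
    identity_denominator = "alignment")
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad)) stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  p[names(over)] <- over
  stopifnot(p$cluster_threshold >= 0, p$cluster_threshold <= 1,
            p$min_identity >= 0, p$min_identity <= 1,
            p$sliding_window > 0, p$shift_window >= 0)
  p
}

#' Pairwise identity of two nucleotide sequences
#'
#' Global end-gap-free alignment (match 1, mismatch 0, gap -1), identity =
#' matches / aligned length. IUPAC codes match when their base sets intersect,
#' so consensus sequences can be compared with plain sequences. With
#' `denominator = "columns"` gapped columns are excluded from the denominator.
#'
#' @param a,b non-empty nucleotide strings (IUPAC codes allowed).
#' @param denominator "alignment" (gaps included) or "columns".
#' @return identity fraction in `[0, 1]`.
#' @export
pairwise_identity <- function(a, b, denominator = c("alignment", "columns")) {
  denominator <- match.arg(denominator)
  if (!nzchar(a) || !nzchar(b)) stop("pairwise_identity(): empty sequence")
  # canonical orientation: co-optimal alignments can differ in gap placement
  # between (a,b) and (b,a); fixing the order makes identity symmetric
  if (toupper(b) < toupper(a)) { tmp <- a; a <- b; b <- tmp }
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(toupper(a)), Biostrings::DNAString(toupper(b)),
    type = "overlap", substitutionMatrix = .iupac_submat(),
    gapOpening = 0, gapExtension = 1)
  p <- as.character(Biostrings::alignedPattern(pa))
  s <- as.character(Biostrings::alignedSubject(pa))
  if (nchar(p) == 0) return(0)
  ok <- iupac_compatible(p, s)
  denom <- if (denominator == "alignment") nchar(p) else {
    pc <- strsplit(p, "")[[1]]; sc <- strsplit(s, "")[[1]]
    sum(pc != "-" & sc != "-")
  }
  if (denom == 0) return(0)
  sum(ok) / denom
}

# All-pairs identity matrix (symmetric, unit diagonal). Plain-ACGT inputs go
# through a batched path: pairs are grouped by their canonical subject (the
# lexicographically larger sequence) and aligned with one vectorised
# pairwiseAlignment call per group, which is orders of magnitude faster than
# the scalar loop and produces the same alignments.
identity_matrix <- function(seqs, denominator = "alignment") {
  n <- length(seqs)
  m <- diag(1, n)
  dimnames(m) <- list(names(seqs), names(seqs))
  if (n < 2) return(m)
  up <- toupper(unlist(seqs))
  plain <- !any(grepl("[^ACGT]", up))
  if (!plain || denominator != "alignment") {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      m[i, j] <- m[j, i] <- pairwise_identity(seqs[[i]], seqs[[j]],
                                              denominator = denominator)
    }
    return(m)
  }
  for (j in seq_len(n)) {
    dup <- which(up == up[j])
    m[dup, j] <- m[j, dup] <- 1
    grp <- which(up < up[j])
    if (length(grp) == 0) next
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::DNAStringSet(up[grp]), Biostrings::DNAString(up[j]),
      type = "overlap", substitutionMatrix = .iupac_submat(),
      gapOpening = 0, gapExtension = 1)
    len <- Biostrings::nchar(pa)
    id <- ifelse(len > 0, Biostrings::nmatch(pa) / len, 0)
    m[grp, j] <- m[j, grp] <- id
  }
  m
}

#' Align a set of sequences
#'
#' Equal-length inputs are treated as already aligned (the common case for
#' near-identical ILE copies); otherwise mafft is run on a temporary FASTA.
#' Input order is preserved.
#'
#' @param seqs named character vector.
#' @return named character vector of equal-length aligned rows (upper case).
#' @export
align_sequences <- function(seqs) {
  stopifnot(length(seqs) >= 1, !is.null(names(seqs)))
  if (length(unique(nchar(seqs))) == 1) return(toupper(seqs))
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_dna_fasta(seqs, fin)
  status <- system2("mafft", c("--auto", "--quiet", shQuote(fin)),
                    stdout = fout)
  if (!identical(status, 0L)) stop("mafft failed with status ", status)
  aln <- toupper(read_dna_fasta(fout))
  aln[names(seqs)]
}

#' Build ILE families by single-linkage identity clustering
#'
#' Sequences are joined into one family whenever their pairwise identity
#' exceeds `threshold` (strictly), and families are the connected components
#' of that relation. Families are ordered by size (descending), ties broken by
#' the lexicographically smallest member id, and named
#' `<prefix>01, <prefix>02, ...`. Members of multi-sequence families are
#' aligned and an IUPAC consensus is built.
#'
#' @param seqs named character vector of intron sequences (>= 1).
#' @param threshold identity threshold for linkage (default 0.80).
#' @param name_prefix family name prefix (default "fam").
#' @param params [ile_params()] list (identity denominator).
#' @return list of `ile_family` objects: each has `name`, `members`
#'   (data.frame `id`, `sequence`), `alignment`, `consensus`,
#'   `max_pairwise_identity`, `mean_pairwise_identity`.
#' @export
build_families <- function(seqs, threshold = 0.80, name_prefix = "fam",
                           params = ile_params()) {
  if (length(seqs) == 0) stop("build_families(): no sequences")
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))) ||
      anyDuplicated(names(seqs)))
    stop("build_families(): sequences must have unique non-empty names")
  idm <- identity_matrix(seqs, denominator = params$identity_denominator)
  adj <- (idm > threshold); diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  comp <- igraph::components(g)$membership
  groups <- split(names(seqs), comp)
  ord <- order(-vapply(groups, length, integer(1)),
               vapply(groups, function(g) sort(g)[1], character(1)))
  groups <- groups[ord]
  fams <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    ids <- sort(groups[[i]])
    sub <- seqs[ids]
    if (length(ids) >= 2) {
      aln <- align_sequences(sub)
      cons <- consensus_iupac(aln)
      subm <- idm[ids, ids, drop = FALSE]
      off <- subm[upper.tri(subm)]
      maxi <- max(off); meani <- mean(off)
    } else {
      aln <- toupper(sub)
      cons <- toupper(sub[[1]])
      maxi <- NA_real_; meani <- NA_real_
    }
    fams[[i]] <- structure(list(
      name = sprintf("%s%02d", name_prefix, i),
      members = data.frame(id = ids, sequence = unname(sub),
                           stringsAsFactors = FALSE),
      alignment = aln,
      consensus = cons,
      max_pairwise_identity = maxi,
      mean_pairwise_identity = meani), class = "ile_family")
  }
  fams
}

#' @export
print.ile_family <- function(x, ...) {
  cat(sprintf("<ile_family> %s: %d member(s), consensus %d nt, max id %s\n",
              x$name, nrow(x$members), nchar(x$consensus),
              ifelse(is.na(x$max_pairwise_identity), "NA",
                     sprintf("%.3f", x$max_pairwise_identity))))
  invisible(x)
}

#' IUPAC consensus of an alignment
#'
#' Per column: the majority base when one base holds >= 50% of the non-gap
#' residues without a tie; otherwise the smallest IUPAC code covering all
#' bases at frequency >= `min_freq`. All-gap columns are dropped.
#'
#' @param aligned named character vector of equal-length aligned rows.
#' @param min_freq inclusion frequency for ambiguity codes (default 0.25).
#' @return IUPAC consensus string.
#' @export
consensus_iupac <- function(aligned, min_freq = 0.25) {
  lens <- unique(nchar(aligned))
  if (length(lens) != 1) stop("consensus_iupac(): rows not aligned")
  mat <- do.call(rbind, strsplit(toupper(aligned), ""))
  cols <- apply(mat, 2, function(col) {
    col <- col[col != "-"]
    if (length(col) == 0) return(NA_character_)
    tab <- table(col) / length(col)
    top <- max(tab)
    if (top >= 0.5 && sum(tab == top) == 1) return(names(which.max(tab)))
    keep <- names(tab)[tab >= min_freq]
    if (length(keep) == 0) keep <- names(tab)[tab == top]
    iupac_code(keep)
  })
  paste(cols[!is.na(cols)], collapse = "")
}

#' Assign a query sequence to the best-matching ILE family
#'
#' The query is compared to every family consensus with IUPAC-aware identity
#' (a base matches any code containing it); the best family wins, ties broken
#' by family order. Below `min_identity` the assignment is `NA` (no family).
#'
#' @param query nucleotide string.
#' @param families list of `ile_family` objects (non-empty).
#' @param min_identity assignment threshold (default 0.70).
#' @param params [ile_params()] list.
#' @return list with `family` (name or `NA`), `identity`.
#' @export
assign_to_family <- function(query, families, min_identity = 0.70,
                             params = ile_params()) {
  if (length(families) == 0) stop("assign_to_family(): no families")
  ids <- vapply(families, function(f)
    pairwise_identity(query, f$consensus,
                      denominator = params$identity_denominator), numeric(1))
  best <- which.max(ids)  # first maximum = family-order tie-break
  if (ids[best] < min_identity)
    return(list(family = NA_character_, identity = max(ids)))
  list(family = families[[best]]$name, identity = ids[best])
}

#' Classify an intron as ILE, RSI or degenerate-ILE candidate
#'
#' An intron assigned to an ILE family at `min_identity` or better is an ILE.
#' Otherwise long introns (>= `long_intron`, default 70 bp) are degenerate-ILE
#' candidates — ILE-scale length without recognisable family identity — and
#' introns within `rsi_range` (default 40--60 bp) are regular spliceosomal
#' introns; everything else is UNCLASSIFIED.
#'
#' @param sequence intron sequence.
#' @param families list of `ile_family` objects (may be empty/NULL).
#' @param params [ile_params()] list.
#' @return one of "ILE", "DEGENERATE_ILE_CANDIDATE", "RSI", "UNCLASSIFIED".
#' @export
classify_intron <- function(sequence, families = NULL, params = ile_params()) {
  len <- nchar(sequence)
  if (length(families) > 0) {
    hit <- assign_to_family(sequence, families,
                            min_identity = params$min_identity,
                            params = params)
    if (!is.na(hit$family)) return("ILE")
  }
  if (len >= params$long_intron) return("DEGENERATE_ILE_CANDIDATE")
  if (len >= params$rsi_range[1] && len <= params$rsi_range[2]) return("RSI")
  "UNCLASSIFIED"
}

#' Activity status of an ILE family
#'
#' A family is considered still actively multiplying when its best member
#' pair reaches `threshold` identity (default 0.98, the identity scale seen
#' for recently multiplied elements); otherwise it is degenerate. Singleton
#' families carry no pairwise signal and are undetermined.
#'
#' @param family an `ile_family`.
#' @param threshold activity identity threshold.
#' @return "ACTIVE", "DEGENERATE" or "UNDETERMINED".
#' @export
family_activity <- function(family, threshold = 0.98) {
  if (nrow(family$members) < 2) return("UNDETERMINED")
  if (family$max_pairwise_identity >= threshold) "ACTIVE" else "DEGENERATE"
}

#' Filter built families down to ILE-family candidates
#'
#' ILEs are defined by near-identical copies in unrelated places; a built
#' family qualifies when it has >= 2 members spanning >= `min_loci` distinct
#' loci. Locus labels are supplied per member id (e.g. `gene|afo`).
#'
#' @param families list of `ile_family` objects.
#' @param loci named character vector mapping member id -> locus label.
#' @param min_loci minimum number of distinct loci (default 2).
#' @return filtered list of families.
#' @export
filter_ile_families <- function(families, loci, min_loci = 2L) {
  keep <- vapply(families, function(f) {
    if (nrow(f$members) < 2) return(FALSE)
    length(unique(loci[f$members$id])) >= min_loci
  }, logical(1))
  families[keep]
}

#' Summarise a family list as a table
#' @param families list of `ile_family` objects.
#' @return data.frame with one row per family.
#' @export
families_table <- function(families) {
  do.call(rbind, lapply(families, function(f) data.frame(
    family = f$name, n_members = nrow(f$members),
    consensus_length = nchar(f$consensus),
    max_pairwise_identity = f$max_pairwise_identity,
    mean_pairwise_identity = f$mean_pairwise_identity,
    activity = family_activity(f),
    stringsAsFactors = FALSE)))
}
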