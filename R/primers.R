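# Primer design from ILE family alignments and in-silico PCR. Conserved
# stretches of the member alignment become (possibly degenerate) primers;
# amplicons are predicted by IUPAC-aware scanning of template sequences with
# a 3'-anchored match requirement, emulating the amplicon-size profiles a gel
# would show.

#' Find conserved gap-free windows in a family alignment
#'
#' Every window of `window_len` columns containing no gap and at most
#' `max_variable` variable columns (columns where members disagree) is
#' reported, ranked by number of variable columns (ascending) then by the
#' length of the invariant run at the window's 3' end (descending), then by
#' start.
#'
#' @param aligned named character vector of equal-length aligned member rows.
#' @param window_len window width in columns (>= 15).
#' @param max_variable maximum number of variable columns per window
#'   (default 4).
#' @return data.frame `start`, `end` (1-based inclusive columns),
#'   `n_variable`, `tail_conserved`, `sequence` (IUPAC window code).
#' @export
find_conserved_stretches <- function(aligned, window_len = 18L,
                                     max_variable = 4L) {
  lens <- unique(nchar(aligned))
  if (length(lens) != 1) stop("rows not aligned")
  if (window_len < 15) stop("window_len must be >= 15")
  if (window_len > lens) stop("window_len exceeds alignment length")
  mat <- do.call(rbind, strsplit(toupper(aligned), ""))
  has_gap <- apply(mat, 2, function(col) any(col == "-"))
  variable <- apply(mat, 2, function(col) length(unique(col)) > 1)
  starts <- seq_len(lens - window_len + 1L)
  rows <- lapply(starts, function(s) {
    idx <- s:(s + window_len - 1L)
    if (any(has_gap[idx])) return(NULL)
    nv <- sum(variable[idx])
    if (nv > max_variable) return(NULL)
    tail_run <- 0L
    for (i in rev(idx)) {
      if (variable[i]) break
      tail_run <- tail_run + 1L
    }
    data.frame(start = s, end = s + window_len - 1L, n_variable = nv,
               tail_conserved = tail_run,
               sequence = make_degenerate_primer(mat[, idx, drop = FALSE])$sequence,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(data.frame(
    start = integer(0), end = integer(0), n_variable = integer(0),
    tail_conserved = integer(0), sequence = character(0)))
  out[order(out$n_variable, -out$tail_conserved, out$start), , drop = FALSE]
}

#' Encode an alignment window as a degenerate primer
#'
#' Each column becomes the IUPAC code of the bases observed in it; the
#' primer's degeneracy is the product of the code sizes.
#'
#' @param window character matrix (members x columns), gap-free.
#' @return list `sequence` (IUPAC string), `degeneracy`,
#'   `n_variable_positions`.
#' @export
make_degenerate_primer <- function(window) {
  if (any(window == "-")) stop("window contains a gap column")
  codes <- apply(window, 2, function(col) iupac_code(unique(col)))
  seq <- paste(codes, collapse = "")
  list(sequence = seq,
       degeneracy = iupac_degeneracy(seq),
       n_variable_positions = sum(!codes %in% c("A", "C", "G", "T")))
}

#' Design a primer pair for an ILE family
#'
#' The forward primer is the best conserved window starting in the 5' half of
#' the member alignment; the reverse primer is the reverse complement of the
#' best non-overlapping window further 3'. Both are degenerate IUPAC codes of
#' their windows; the reverse primer is stored 5'->3' as it would be
#' synthesized (i.e. on the antisense strand).
#'
#' For large, partly degenerated families a window budget of a few variable
#' positions may be unsatisfiable over all members; `representatives`
#' restricts the design to the members closest to the family consensus (the
#' usual practice of designing on the most conserved copies), at the cost
#' that strongly diverged members may no longer be amplified.
#'
#' @param family an `ile_family` (or a named character vector of aligned
#'   rows).
#' @param window_len primer length (default 18).
#' @param max_variable maximum variable positions per primer (default 4).
#' @param representatives design on this many most-consensus-like members
#'   (default `NULL`: use all members).
#' @return object of class `primer_pair`: `forward`, `reverse`,
#'   `target_families`, `degeneracy`, `n_variable_positions`,
#'   `fwd_window`/`rev_window` (alignment columns).
#' @export
design_primer_pair <- function(family, window_len = 18L, max_variable = 4L,
                               representatives = NULL) {
  aligned <- if (inherits(family, "ile_family")) family$alignment else family
  fam_name <- if (inherits(family, "ile_family")) family$name else NA_character_
  if (!is.null(representatives) && representatives < length(aligned)) {
    cons <- if (inherits(family, "ile_family")) family$consensus else
      consensus_iupac(aligned)
    ids <- vapply(aligned, function(m)
      pairwise_identity(gsub("-", "", m), cons), numeric(1))
    keep <- names(sort(ids, decreasing = TRUE))[seq_len(representatives)]
    aligned <- aligned[keep]
  }
  st <- find_conserved_stretches(aligned, window_len, max_variable)
  if (nrow(st) == 0) stop("no conserved stretch of length ", window_len,
                          " with <= ", max_variable, " variable positions")
  alen <- nchar(aligned[[1]])
  # walk forward candidates in rank order (5'-half first) until one leaves
  # room for a non-overlapping reverse window
  fwd_cand <- rbind(st[st$start <= alen / 2, , drop = FALSE],
                    st[st$start > alen / 2, , drop = FALSE])
  fwd <- rev <- NULL
  for (i in seq_len(nrow(fwd_cand))) {
    rev_cand <- st[st$start > fwd_cand$end[i], , drop = FALSE]
    if (nrow(rev_cand) == 0) next
    fwd <- fwd_cand[i, ]
    # prefer the most 3' among the best-ranked candidates
    best <- rev_cand[rev_cand$n_variable == min(rev_cand$n_variable), ,
                     drop = FALSE]
    rev <- best[which.max(best$end), ]
    break
  }
  if (is.null(fwd))
    stop("no non-overlapping forward/reverse window pair available")
  fwd_primer <- fwd$sequence
  rev_primer <- revcomp(rev$sequence)
  structure(list(
    forward = fwd_primer,
    reverse = rev_primer,
    target_families = fam_name,
    degeneracy = iupac_degeneracy(fwd_primer) * iupac_degeneracy(rev_primer),
    n_variable_positions =
      sum(!strsplit(fwd_primer, "")[[1]] %in% c("A", "C", "G", "T")) +
      sum(!strsplit(rev_primer, "")[[1]] %in% c("A", "C", "G", "T")),
    fwd_window = c(fwd$start, fwd$end),
    rev_window = c(rev$start, rev$end)), class = "primer_pair")
}

#' @export
print.primer_pair <- function(x, ...) {
  cat(sprintf("<primer_pair> %s\n  fwd 5'-%s-3'\n  rev 5'-%s-3'  degeneracy %d\n",
              ifelse(is.na(x$target_families), "", x$target_families),
              x$forward, x$reverse, x$degeneracy))
  invisible(x)
}

# All sites where `primer` (IUPAC, 5'->3' sense) anneals to `template` with at
# most max_mismatch mismatches and its 3'-terminal `anchor` bases matching
# without mismatch. Returns data.frame(start, end (1-based inclusive),
# mismatches). anchor_side = "right" for a sense-strand primer (3' end is the
# right end of the site) or "left" for the reverse-complemented reverse
# primer (its 3' end maps to the left end of the site on the sense strand).
.primer_sites <- function(template, primer, max_mismatch, anchor = 3L,
                          anchor_side = c("right", "left")) {
  anchor_side <- match.arg(anchor_side)
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(primer), Biostrings::DNAString(template),
    max.mismatch = max_mismatch, fixed = "subject")
  if (length(hits) == 0)
    return(data.frame(start = integer(0), end = integer(0),
                      mismatches = integer(0)))
  starts <- BiocGenerics::start(hits)
  ends <- BiocGenerics::end(hits)
  plen <- nchar(primer)
  rows <- lapply(seq_along(starts), function(i) {
    site <- substr(template, starts[i], ends[i])
    if (nchar(site) != plen) return(NULL)  # clipped at template edge
    ok <- iupac_compatible(primer, site)
    anchor_idx <- if (anchor_side == "right")
      seq(plen - anchor + 1L, plen) else seq_len(anchor)
    if (!all(ok[anchor_idx])) return(NULL)
    mm <- sum(!ok)
    if (mm > max_mismatch) return(NULL)
    data.frame(start = starts[i], end = ends[i], mismatches = mm)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) data.frame(start = integer(0), end = integer(0),
                               mismatches = integer(0)) else out
}

#' Predict PCR amplicons on a template (in-silico PCR)
#'
#' Finds every locus where the forward primer matches the sense strand and
#' the reverse primer matches the antisense strand downstream within
#' `max_amplicon`, each with at most `max_mismatch` IUPAC-aware mismatches
#' and an exact match over the 3'-terminal 3 nt. Primer sites may not
#' overlap. Results are sorted by start, then end.
#'
#' @param template nucleotide string.
#' @param pair a `primer_pair` (or list with `forward`, `reverse`).
#' @param max_mismatch allowed mismatches per primer (default 0).
#' @param max_amplicon maximum product length in bp (default 1000).
#' @param template_id identifier copied into the output.
#' @return data.frame `template_id`, `start`, `end` (0-based half-open),
#'   `length`, `fwd_mismatches`, `rev_mismatches`; zero rows when no product.
#' @export
insilico_pcr <- function(template, pair, max_mismatch = 0L,
                         max_amplicon = 1000L, template_id = "template") {
  stopifnot(nchar(pair$forward) >= 15, nchar(pair$reverse) >= 15)
  template <- toupper(template)
  fwd_sites <- .primer_sites(template, toupper(pair$forward), max_mismatch,
                             anchor_side = "right")
  rev_sites <- .primer_sites(template, revcomp(toupper(pair$reverse)),
                             max_mismatch, anchor_side = "left")
  out <- list()
  for (i in seq_len(nrow(fwd_sites))) for (j in seq_len(nrow(rev_sites))) {
    f <- fwd_sites[i, ]; r <- rev_sites[j, ]
    if (r$start <= f$end) next           # sites must not overlap
    len <- r$end - f$start + 1L
    if (len > max_amplicon) next
    out[[length(out) + 1L]] <- data.frame(
      template_id = template_id,
      start = f$start - 1L, end = r$end, length = len,
      fwd_mismatches = f$mismatches, rev_mismatches = r$mismatches,
      stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(template_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      fwd_mismatches = integer(0), rev_mismatches = integer(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res[order(res$start, res$end), , drop = FALSE]
}
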