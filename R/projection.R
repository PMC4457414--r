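# Projection of intron positions onto a shared protein-alignment coordinate
# frame. A projected position is (alignment column of the codon containing or
# following the intron, phase); the scalar alignment-frame offset
# afo = 3*column + phase uniquely identifies a position and makes
# nucleotide-scale distances between positions of different species
# well-defined.

#' Project an intron position onto an aligned protein row
#'
#' The intron with `cds_offset` coding nucleotides 5' of it lands in codon
#' `floor(cds_offset/3)` (0-based) of its protein; the projected column is the
#' alignment column of that codon's residue in `row`. Phase-0 introns (between
#' codons) are assigned to the column of the codon that follows them, so the
#' alignment-frame offset `3*column + phase` increases strictly along a gene.
#'
#' @param cds_offset number of coding nucleotides 5' of the intron.
#' @param row aligned amino-acid string for the intron's species (gap `-`).
#' @param alignment_id optional identifier of the alignment; distances are
#'   only defined between positions of one alignment.
#' @return object of class `intron_position`: list with `column` (0-based),
#'   `phase` (0/1/2), `afo` (= 3*column + phase) and `alignment_id`.
#' @export
project_position <- function(cds_offset, row, alignment_id = NULL) {
  stopifnot(cds_offset >= 0)
  chars <- strsplit(row, "")[[1]]
  res_cols <- which(chars != "-")  # 1-based columns of non-gap residues
  k <- cds_offset %/% 3L           # 0-based codon index
  if (k + 1L > length(res_cols))
    stop("projection error: cds_offset ", cds_offset,
         " beyond coding capacity of row (", length(res_cols), " residues)")
  structure(list(
    column = as.integer(res_cols[k + 1L] - 1L),
    phase = as.integer(cds_offset %% 3L),
    afo = as.integer(3L * (res_cols[k + 1L] - 1L) + cds_offset %% 3L),
    alignment_id = alignment_id
  ), class = "intron_position")
}

#' Recover a CDS offset from a projected position
#'
#' Inverse of [project_position()] for the same row: counts the non-gap
#' residues strictly 5' of the projected column and restores
#' `3*k + phase`.
#'
#' @param pos an `intron_position`.
#' @param row the aligned protein row the position was projected from.
#' @return integer CDS offset.
#' @export
unproject_position <- function(pos, row) {
  chars <- strsplit(row, "")[[1]]
  if (pos$column + 1L > length(chars) || chars[pos$column + 1L] == "-")
    stop("column ", pos$column, " is not a residue of this row")
  k <- sum(chars[seq_len(pos$column)] != "-")
  as.integer(3L * k + pos$phase)
}

#' Nucleotide distance between two projected intron positions
#'
#' Absolute difference of alignment-frame offsets. Only defined for positions
#' projected onto the same protein alignment; gaps count through alignment
#' columns, not through either species' ungapped sequence.
#'
#' @param a,b `intron_position` objects.
#' @return non-negative integer distance in nucleotides.
#' @export
position_distance <- function(a, b) {
  stopifnot(inherits(a, "intron_position"), inherits(b, "intron_position"))
  if (!is.null(a$alignment_id) && !is.null(b$alignment_id) &&
      !identical(a$alignment_id, b$alignment_id))
    stop("positions come from different alignments")
  abs(a$afo - b$afo)
}

#' @export
print.intron_position <- function(x, ...) {
  cat(sprintf("<intron_position> column %d phase %d (afo %d)\n",
              x$column, x$phase, x$afo))
  invisible(x)
}

# Vectorised projection for an intron table; appends column/phase/afo.
project_intron_table <- function(introns, row, alignment_id = NULL) {
  if (nrow(introns) == 0) {
    introns$column <- integer(0); introns$phase <- integer(0)
    introns$afo <- integer(0)
    return(introns)
  }
  proj <- lapply(introns$cds_offset, project_position, row = row,
                 alignment_id = alignment_id)
  introns$column <- vapply(proj, `[[`, integer(1), "column")
  introns$phase <- vapply(proj, `[[`, integer(1), "phase")
  introns$afo <- vapply(proj, `[[`, integer(1), "afo")
  introns
}
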