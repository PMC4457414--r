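# IUPAC nucleotide ambiguity arithmetic used by consensus building, primer
# design and family assignment. Codes are kept as character vectors; all
# containment logic goes through the base-set map so that e.g. "R" matches "A"
# and "N" matches everything.

.iupac_sets <- local({
  m <- Biostrings::IUPAC_CODE_MAP
  lapply(m, function(x) strsplit(x, "")[[1]])
})

#' IUPAC code covering a set of bases
#'
#' Returns the single IUPAC nucleotide code whose base set equals the set of
#' observed bases, e.g. `c("A","G")` -> `"R"`.
#'
#' @param bases character vector of A/C/G/T (or IUPAC codes; their base sets
#'   are unioned first).
#' @return single character IUPAC code.
#' @export
iupac_code <- function(bases) {
  set <- sort(unique(unlist(.iupac_sets[toupper(bases)])))
  if (length(set) == 0 || anyNA(set)) {
    stop("iupac_code(): input contains non-IUPAC characters: ",
         paste(bases, collapse = ","))
  }
  key <- paste(set, collapse = "")
  hit <- names(which(vapply(.iupac_sets, function(s)
    identical(sort(s), set), logical(1))))
  if (length(hit) != 1) stop("no IUPAC code for base set ", key)
  hit
}

#' Number of sequences encoded by a degenerate oligonucleotide
#'
#' Degeneracy is the product over positions of the number of bases each IUPAC
#' code stands for; a plain ACGT oligo has degeneracy 1.
#'
#' @param seq IUPAC nucleotide string.
#' @return integer degeneracy.
#' @export
iupac_degeneracy <- function(seq) {
  ch <- strsplit(toupper(seq), "")[[1]]
  sizes <- vapply(.iupac_sets[ch], length, integer(1))
  prod(sizes)
}

# Per-position compatibility of two equal-length IUPAC strings: TRUE where the
# base sets intersect. Gaps never match anything.
iupac_compatible <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  stopifnot(length(ca) == length(cb))
  mapply(function(x, y) {
    if (x == "-" || y == "-") return(FALSE)
    length(intersect(.iupac_sets[[x]], .iupac_sets[[y]])) > 0
  }, ca, cb, USE.NAMES = FALSE)
}

# Substitution matrix over the IUPAC alphabet: 1 where base sets intersect,
# 0 otherwise. Used for identity-style alignments (gap penalties carry the
# only negative scores).
.iupac_submat <- local({
  mat <- NULL
  function() {
    if (is.null(mat)) {
      letters <- names(.iupac_sets)
      m <- matrix(0, length(letters), length(letters),
                  dimnames = list(letters, letters))
      for (i in letters) for (j in letters) {
        if (length(intersect(.iupac_sets[[i]], .iupac_sets[[j]])) > 0)
          m[i, j] <- 1
      }
      mat <<- m
    }
    mat
  }
})

# Reverse complement preserving ambiguity codes.
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# Random DNA helpers (uniform base composition).
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
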