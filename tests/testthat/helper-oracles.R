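# Independent brute-force oracles and small generators shared by the tests.
# The oracles deliberately avoid the package's own code paths: clade
# enumeration instead of MRCA lookup, full O(n^2)/per-offset scans instead of
# sorted or Biostrings-backed matching.

# All clades of a rooted tree as leaf-name sets (one per internal node),
# found by direct recursion over the edge matrix.
oracle_clades <- function(tree) {
  ntip <- ape::Ntip(tree)
  tips_below <- function(node) {
    if (node <= ntip) return(tree$tip.label[node])
    kids <- tree$edge[tree$edge[, 1] == node, 2]
    unlist(lapply(kids, tips_below))
  }
  lapply(seq(ntip + 1, ntip + tree$Nnode), tips_below)
}

# Category of a presence row by exhaustive clade enumeration.
oracle_classify_position <- function(states, tree) {
  scored <- names(states)[states != "MISSING"]
  present <- names(states)[states == "PRESENT"]
  if (length(present) == length(scored)) return("CONSERVED")
  if (length(present) == 1) return("SINGLE_PRESENCE")
  clades <- oracle_clades(tree)
  mono <- any(vapply(clades, function(cl)
    length(cl) >= 2 && setequal(intersect(cl, scored), present), logical(1)))
  if (mono) return("SINGLE_PRESENCE_IN_CLADE")
  if (length(scored) - length(present) == 1) return("SINGLE_ABSENCE")
  "PRESENCE_ABSENCE_POLYMORPHISM"
}

# All close pairs by the obvious O(n^2) double loop.
oracle_sliding_pairs <- function(afos, window = 15L) {
  afos <- sort(unique(afos))
  out <- list()
  for (i in seq_along(afos)) for (j in seq_along(afos)) {
    if (i < j && afos[j] - afos[i] > 0 && afos[j] - afos[i] < window)
      out[[length(out) + 1]] <- data.frame(afo_a = afos[i], afo_b = afos[j],
                                           distance = afos[j] - afos[i])
  }
  if (length(out)) do.call(rbind, out) else
    data.frame(afo_a = integer(0), afo_b = integer(0), distance = integer(0))
}

# Per-offset sliding-window primer matching (every placement enumerated).
# allowed[b, k]: may template base b sit under primer position k?
.oracle_allowed <- function(primer) {
  sets <- ilescape:::.iupac_sets
  ch <- strsplit(toupper(primer), "")[[1]]
  m <- matrix(FALSE, 4, length(ch), dimnames = list(c("A", "C", "G", "T")))
  for (k in seq_along(ch)) m[sets[[ch[k]]], k] <- TRUE
  m
}

oracle_primer_sites <- function(template, primer, max_mm, anchor_side) {
  tch <- strsplit(toupper(template), "")[[1]]
  tidx <- match(tch, c("A", "C", "G", "T"))
  allowed <- .oracle_allowed(primer)
  pl <- ncol(allowed)
  n <- length(tch) - pl + 1
  if (n < 1) return(data.frame(start = integer(0), end = integer(0),
                               mismatches = integer(0)))
  anchor <- if (anchor_side == "right") seq(pl - 2, pl) else 1:3
  rows <- list()
  for (s in seq_len(n)) {
    ok <- allowed[cbind(tidx[s:(s + pl - 1)], seq_len(pl))]
    if (!all(ok[anchor])) next
    mm <- sum(!ok)
    if (mm > max_mm) next
    rows[[length(rows) + 1]] <- data.frame(start = s, end = s + pl - 1,
                                           mismatches = mm)
  }
  if (length(rows)) do.call(rbind, rows) else
    data.frame(start = integer(0), end = integer(0), mismatches = integer(0))
}

oracle_pcr <- function(template, pair, max_mm = 0L, max_amp = 1000L) {
  fwd <- oracle_primer_sites(template, pair$forward, max_mm, "right")
  rev <- oracle_primer_sites(template, ilescape:::revcomp(pair$reverse),
                             max_mm, "left")
  out <- list()
  for (i in seq_len(nrow(fwd))) for (j in seq_len(nrow(rev))) {
    if (rev$start[j] <= fwd$end[i]) next
    len <- rev$end[j] - fwd$start[i] + 1L
    if (len > max_amp) next
    out[[length(out) + 1]] <- data.frame(
      start = fwd$start[i] - 1L, end = rev$end[j], length = len,
      fwd_mismatches = fwd$mismatches[i], rev_mismatches = rev$mismatches[j])
  }
  if (length(out) == 0) return(data.frame(
    start = integer(0), end = integer(0), length = integer(0),
    fwd_mismatches = integer(0), rev_mismatches = integer(0)))
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Replace every ambiguity code by one concrete base it encodes.
instantiate_primer <- function(seq) {
  sets <- ilescape:::.iupac_sets
  ch <- strsplit(toupper(seq), "")[[1]]
  paste(vapply(ch, function(x) sets[[x]][1], character(1)), collapse = "")
}

rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                              collapse = "")

rand_intron <- function(len) paste0("GT", rand_dna(len - 4), "AG")

# Insert n gap columns at random places in an aligned row.
insert_gaps <- function(row, n) {
  ch <- strsplit(row, "")[[1]]
  for (i in seq_len(n)) {
    pos <- sample(length(ch) + 1, 1)
    ch <- append(ch, "-", after = pos - 1)
  }
  paste(ch, collapse = "")
}

# Random PRESENT/ABSENT/MISSING row over a tree's species with >= 1 PRESENT.
rand_state_row <- function(species, p_present = 0.4, p_missing = 0.15) {
  repeat {
    r <- runif(length(species))
    states <- ifelse(r < p_missing, "MISSING",
                     ifelse(r < p_missing + (1 - p_missing) * p_present,
                            "PRESENT", "ABSENT"))
    names(states) <- species
    if (any(states == "PRESENT")) return(states)
  }
}
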