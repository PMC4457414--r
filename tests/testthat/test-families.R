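# Identity computation, single-linkage family building, consensus rules,
# family assignment and intron classification.

test_that("pairwise identity matches hand-counted alignments", {
  expect_equal(pairwise_identity("GTAAGTACGA", "GTAAGTACGA"), 1.0)
  # gapless optimum: 9 of 10 positions match
  expect_equal(pairwise_identity("GTAAGTACGA", "GTAAGTACGT"), 0.9)
  expect_equal(pairwise_identity("AAAA", "TTTT"), 0.0)
  expect_error(pairwise_identity("", "ACGT"), "empty")
})

test_that("identity is symmetric and reflexive on random sequences", {
  set.seed(3)
  for (rep in 1:20) {
    a <- rand_dna(sample(20:80, 1)); b <- rand_dna(sample(20:80, 1))
    expect_equal(pairwise_identity(a, b), pairwise_identity(b, a))
    expect_equal(pairwise_identity(a, a), 1.0)
  }
})

test_that("families are single-linkage components of the >threshold relation", {
  set.seed(11)
  s <- rand_intron(60)
  seqs <- c(a1 = s, a2 = s, a3 = s)
  fams <- build_families(seqs)
  expect_length(fams, 1)
  expect_equal(fams[[1]]$max_pairwise_identity, 1.0)
  expect_setequal(fams[[1]]$members$id, names(seqs))

  # two internally identical groups, ~50% between-group identity
  t <- rand_intron(60)
  two <- build_families(c(a1 = s, a2 = s, b1 = t, b2 = t))
  expect_length(two, 2)
  expect_setequal(unlist(lapply(two, function(f) f$members$id)),
                  c("a1", "a2", "b1", "b2"))
  groups <- lapply(two, function(f) sort(f$members$id))
  expect_true(any(vapply(groups, identical, logical(1), c("a1", "a2"))))
  expect_true(any(vapply(groups, identical, logical(1), c("b1", "b2"))))

  # strict inequality: distinct sequences at threshold 1.0 stay singletons
  singles <- build_families(c(x = s, y = t,
                              z = ilescape:::.mutate_intron(s, 0.05)),
                            threshold = 1.0)
  expect_length(singles, 3)
})

test_that("family building partitions the input and is threshold-monotone", {
  set.seed(23)
  for (rep in 1:8) {
    base <- replicate(3, rand_intron(sample(50:70, 1)))
    seqs <- unlist(lapply(seq_along(base), function(i)
      stats::setNames(
        vapply(1:3, function(.) ilescape:::.mutate_intron(base[i],
                                                          runif(1, 0, 0.25)),
               character(1)),
        paste0("s", i, "_", 1:3))))
    lo <- build_families(seqs, threshold = 0.75)
    hi <- build_families(seqs, threshold = 0.9)
    for (built in list(lo, hi)) {
      members <- unlist(lapply(built, function(f) f$members$id))
      expect_setequal(members, names(seqs))   # covers the input
      expect_false(anyDuplicated(members) > 0)  # no sequence in two families
    }
    # refinement: every high-threshold family sits inside one low-threshold one
    for (f in hi) {
      host <- vapply(lo, function(g) all(f$members$id %in% g$members$id),
                     logical(1))
      expect_equal(sum(host), 1)
    }
  }
})

test_that("consensus applies the majority and 25% IUPAC inclusion rules", {
  expect_equal(consensus_iupac(c(a = "ACGT")), "ACGT")
  expect_equal(consensus_iupac(c(a = "A", b = "A", c = "A", d = "C")), "A")
  expect_equal(consensus_iupac(c(a = "A", b = "A", c = "C", d = "C")), "M")
  expect_equal(consensus_iupac(c(a = "A-G", b = "A-G")), "AG")  # all-gap dropped
  set.seed(2)
  for (k in 1:4) {
    s <- rand_dna(30)
    rows <- stats::setNames(rep(s, k), paste0("r", 1:k))
    expect_equal(consensus_iupac(rows), s)
  }
  expect_error(consensus_iupac(c(a = "ACG", b = "AC")), "not aligned")
})

test_that("assignment is IUPAC-aware and thresholded", {
  set.seed(6)
  s <- rand_intron(60)
  fams <- build_families(c(m1 = s, m2 = s))
  hit <- assign_to_family(s, fams)
  expect_equal(hit$family, "fam01")
  expect_equal(hit$identity, 1.0)
  expect_equal(assign_to_family("ACGT", list(structure(list(
    name = "f", consensus = "ACGN"), class = "ile_family")))$identity, 1.0)
  miss <- assign_to_family(rand_dna(60), fams, min_identity = 0.95)
  expect_true(is.na(miss$family))
})

test_that("intron classification uses family identity then length", {
  set.seed(9)
  cons <- rand_intron(72)
  fams <- build_families(c(m1 = cons, m2 = cons))
  expect_equal(classify_intron(cons, fams), "ILE")
  expect_equal(classify_intron(rand_intron(52), fams), "RSI")
  expect_equal(classify_intron(rand_intron(85), fams),
               "DEGENERATE_ILE_CANDIDATE")
  expect_equal(classify_intron(rand_intron(65), fams), "UNCLASSIFIED")
  expect_equal(classify_intron(rand_intron(30), NULL), "UNCLASSIFIED")
})

test_that("family activity reflects the best member pair", {
  s <- rand_intron(60)
  active <- build_families(c(m1 = s, m2 = s))[[1]]
  expect_equal(family_activity(active), "ACTIVE")
  # exactly 9 interior mismatches in 60 nt -> best pair 51/60 = 0.85
  ch <- strsplit(s, "")[[1]]
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  idx <- seq(5, 45, by = 5)
  ch[idx] <- vapply(ch[idx], flip, character(1))
  s2 <- paste(ch, collapse = "")
  degen <- structure(list(name = "d",
                          members = data.frame(id = c("x", "y"),
                                               sequence = c(s, s2)),
                          max_pairwise_identity = pairwise_identity(s, s2)),
                     class = "ile_family")
  expect_equal(degen$max_pairwise_identity, 0.85)
  expect_equal(family_activity(degen), "DEGENERATE")
  singleton <- build_families(c(only = s))[[1]]
  expect_equal(family_activity(singleton), "UNDETERMINED")
})

test_that("locus-aware filtering keeps only multi-locus families", {
  s <- rand_intron(60); t <- rand_intron(55)
  fams <- build_families(c(a = s, b = s, c = t, d = t))
  loci <- c(a = "g1|100", b = "g1|100", c = "g1|200", d = "g2|300")
  kept <- filter_ile_families(fams, loci)
  expect_length(kept, 1)
  expect_setequal(kept[[1]]$members$id, c("c", "d"))
})
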