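# Landscape construction, phylogeny-aware position classification, boundary
# refinement, sliding pairs, parallel-gain calling and the gain frequency.

fixture_tree <- function() {
  ape::read.tree(text = paste0(
    "(((A1:1,A2:1):1,(A3:1,(A4:1,A5:1):1):1):1,",
    "((B1:1,B2:1):1,(B3:1,(B4:1,B5:1):1):1):1);"))
}

test_that("position categories follow the stated precedence", {
  tree <- fixture_tree()
  sp <- tree$tip.label
  mk <- function(present, missing = character(0)) {
    s <- stats::setNames(rep("ABSENT", 10), sp)
    s[present] <- "PRESENT"; s[missing] <- "MISSING"
    s
  }
  expect_equal(classify_position(mk(sp), tree), "CONSERVED")
  expect_equal(classify_position(mk(sp[-4]), tree), "SINGLE_ABSENCE")
  expect_equal(classify_position(mk("A3"), tree), "SINGLE_PRESENCE")
  expect_equal(classify_position(mk(c("B4", "B5")), tree),
               "SINGLE_PRESENCE_IN_CLADE")
  expect_equal(classify_position(mk(c("A1", "B4")), tree),
               "PRESENCE_ABSENCE_POLYMORPHISM")
  # MISSING species leave the denominator entirely
  expect_equal(classify_position(mk(sp[-(1:2)], missing = sp[1:2]), tree),
               "CONSERVED")
  # a clade completed by a MISSING member still reads as clade-restricted
  expect_equal(classify_position(mk(c("B4"), missing = "B5"), tree),
               "SINGLE_PRESENCE")
  expect_error(classify_position(mk(character(0)), tree), "no PRESENT")
})

test_that("classification matches the clade-enumeration oracle", {
  set.seed(47)
  for (rep in 1:60) {
    tree <- ape::rtree(sample(4:12, 1))
    states <- rand_state_row(tree$tip.label)
    expect_equal(classify_position(states, tree),
                 oracle_classify_position(states, tree),
                 info = paste(names(states), states, collapse = " "))
  }
})

test_that("sliding pairs are exactly the close pairs, strictly under 15 nt", {
  pos <- data.frame(afo = c(100, 101, 109, 130, 145, 300, 303))
  pairs <- detect_sliding_pairs(pos)
  # (100,101)=1, (100,109)=9, (101,109)=8, (300,303)=3; (130,145)=15 is not
  # strictly below the window and must not be flagged
  expect_equal(pairs$distance, c(1, 9, 8, 3))
  expect_equal(nrow(pairs), 4)
  expect_false(any(pairs$distance >= 15))
  expect_false(any(pairs$distance == 0))
  # duplicated afos collapse to one position, never a zero-distance pair
  expect_equal(nrow(detect_sliding_pairs(data.frame(afo = c(7, 7)))), 0)
})

test_that("sliding detection equals the O(n^2) oracle on random sets", {
  set.seed(53)
  for (rep in 1:40) {
    afos <- sample(0:400, sample(2:40, 1))
    mine <- detect_sliding_pairs(data.frame(afo = afos))
    ref <- oracle_sliding_pairs(afos)
    rownames(mine) <- rownames(ref) <- NULL
    expect_equal(mine, ref)
  }
})

test_that("boundary refinement snaps only when flank identity improves", {
  # base CDS; carriers of the shared position at offset 303 have CDSs whose
  # junction context equals the query's context at 300 (a 3-nt upstream
  # shift), so the snap strictly improves junction-anchored identity
  set.seed(59)
  base <- ilescape:::.random_cds(900)
  shift3 <- function(s) paste0("CAT", substr(s, 1, 897))
  cds <- c(spX = base, spY = shift3(base), spZ = shift3(base))
  tab <- function(offset) data.frame(
    gene_id = "g", species = NA, ordinal = 1L, cds_offset = offset,
    length = 50L, sequence = "", donor = "GT", acceptor = "AG",
    intron_class = "UNCLASSIFIED", column = offset %/% 3L,
    phase = offset %% 3L, afo = offset, stringsAsFactors = FALSE)
  tables <- list(spX = tab(300L), spY = tab(303L), spZ = tab(303L))
  r <- refine_boundaries(tables, cds)
  expect_equal(r$tables$spX$afo, 303L)
  expect_equal(r$log$action, "snapped")
  expect_equal(c(r$log$afo_from, r$log$afo_to), c(300L, 303L))

  # no shared position nearby: nothing changes
  lone <- refine_boundaries(list(spX = tab(300L), spY = tab(500L),
                                 spZ = tab(500L)), cds)
  expect_equal(lone$tables$spX$afo, 300L)
  expect_equal(nrow(lone$log), 0)
})

test_that("equally scoring snap candidates leave the position unchanged", {
  # periodic region => zero lag-3 self-identity, so both candidates score
  # identically and the tie must be flagged, not resolved arbitrarily
  set.seed(61)
  base <- ilescape:::.random_cds(900)
  base <- paste0(substr(base, 1, 269), strrep("ACGT", 13),
                 substr(base, 322, 900))
  fwd3 <- function(s) paste0("CAT", substr(s, 1, 897))   # context at 303
  back3 <- function(s) paste0(substr(s, 4, 900), "CAT")  # context at 297
  cds <- c(spX = base, spY = fwd3(base), spZ = fwd3(base),
           spU = back3(base), spV = back3(base))
  tab <- function(offset) data.frame(
    gene_id = "g", species = NA, ordinal = 1L, cds_offset = offset,
    length = 50L, sequence = "", donor = "GT", acceptor = "AG",
    intron_class = "UNCLASSIFIED", column = offset %/% 3L,
    phase = offset %% 3L, afo = offset, stringsAsFactors = FALSE)
  tables <- list(spX = tab(300L), spY = tab(303L), spZ = tab(303L),
                 spU = tab(297L), spV = tab(297L))
  r <- refine_boundaries(tables, cds)
  expect_equal(r$tables$spX$afo, 300L)
  expect_true("ambiguous_tie" %in% r$log$action[r$log$species == "spX"])
})

test_that("landscapes aggregate states, classes and pseudogene flags", {
  tree <- ape::read.tree(text = "(spA:1,(spB:1,spC:1):1);")
  cds <- ilescape:::.random_cds(300)
  int <- function(off) data.frame(cds_offset = off,
                                  sequence = rand_intron(50),
                                  stringsAsFactors = FALSE)
  set.seed(67)
  gA <- assemble_gene("g", "spA", cds, rbind(int(90), int(150)))
  gB <- assemble_gene("g", "spB", cds, int(90))
  gC <- assemble_gene("g", "spC", cds, int(90))
  aln <- stats::setNames(rep(as.character(
    Biostrings::translate(Biostrings::DNAString(cds))), 3),
    c("spA", "spB", "spC"))
  ls <- build_landscape(list(spA = gA, spB = gB, spC = gC), aln, tree)
  expect_equal(ls$positions$afo, c(90L, 150L))
  expect_equal(unname(ls$states["90", ]), rep("PRESENT", 3))
  expect_equal(unname(ls$states["150", ]), c("PRESENT", "ABSENT", "ABSENT"))
  calls <- classify_landscape(ls)
  expect_equal(calls$category, c("CONSERVED", "SINGLE_PRESENCE"))
  expect_false(any(ls$pseudogene))

  # an in-frame stop in one orthologue raises its pseudogene flag
  cds_stop <- paste0(substr(cds, 1, 150), "TAA", substr(cds, 154, 300))
  gB2 <- assemble_gene("g", "spB", cds_stop, int(90))
  ls2 <- build_landscape(list(spA = gA, spB = gB2, spC = gC), aln, tree)
  expect_true(ls2$pseudogene[["spB"]])
  expect_false(ls2$pseudogene[["spA"]])

  expect_error(build_landscape(list(spA = gA), aln[1:2],
                               ape::read.tree(text = "(x:1,y:1);")),
               "absent from tree")
})

test_that("landscapes ignore species order and all-MISSING species", {
  fx <- make_parallel_gain_fixture(seed = 3)
  ls1 <- build_landscape(fx$genes, fx$alignment, fx$tree)
  shuffle <- rev(names(fx$alignment))
  ls2 <- build_landscape(fx$genes[shuffle], fx$alignment[shuffle], fx$tree)
  expect_equal(ls1$positions, ls2$positions)
  expect_equal(ls1$states, ls2$states[, colnames(ls1$states)])
  # a species with no orthologue is all-MISSING and changes no category
  ls3 <- build_landscape(fx$genes[-3], fx$alignment, fx$tree)
  expect_equal(unname(ls3$states[, names(fx$genes)[3]]),
               rep("MISSING", nrow(ls3$states)))
  keep <- intersect(rownames(ls1$states), rownames(ls3$states))
  c1 <- classify_landscape(ls1); c3 <- classify_landscape(ls3)
  dropped_sp <- names(fx$genes)[3]
  for (afo in as.integer(keep)) {
    i1 <- match(afo, c1$afo); i3 <- match(afo, c3$afo)
    # categories may only differ where the dropped species was load-bearing
    if (ls1$states[as.character(afo), dropped_sp] == "ABSENT" &&
        c1$category[i1] == "CONSERVED") next
    expect_equal(c3$category[i3], c1$category[i1], info = afo)
  }
})

test_that("parallel gains need an ILE side and an outside non-ILE partner", {
  tree <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  mk_landscape <- function(states, classes) {
    structure(list(
      positions = data.frame(column = as.integer(rownames(states)) %/% 3L,
                             phase = as.integer(rownames(states)) %% 3L,
                             afo = as.integer(rownames(states))),
      states = states, classes = classes, tree = tree),
      class = "intron_landscape")
  }
  sp <- c("a", "b", "c", "d")
  st <- matrix("ABSENT", 2, 4, dimnames = list(c("100", "105"), sp))
  cl <- matrix(NA_character_, 2, 4, dimnames = dimnames(st))
  # two RSI-only positions 5 nt apart: sliding candidates, no parallel call
  st["100", "a"] <- "PRESENT"; cl["100", "a"] <- "RSI"
  st["105", c("c", "d")] <- "PRESENT"; cl["105", c("c", "d")] <- "RSI"
  ls <- mk_landscape(st, cl)
  calls <- call_parallel_gains(ls, classify_landscape(ls))
  expect_false(any(calls$parallel_gain))
  expect_true(all(nzchar(calls$sliding_partners)))

  # ILE in one species, RSI in the distant clade: a parallel gain
  cl["100", "a"] <- "ILE"
  ls <- mk_landscape(st, cl)
  calls <- call_parallel_gains(ls, classify_landscape(ls))
  expect_true(all(calls$parallel_gain))
  expect_equal(calls$ile_side, c(TRUE, FALSE))
  expect_equal(unique(calls$parallel_confidence), "PARALLEL")

  # degenerate-ILE partner only downgrades confidence
  cl["105", c("c", "d")] <- "DEGENERATE_ILE_CANDIDATE"
  ls <- mk_landscape(st, cl)
  calls <- call_parallel_gains(ls, classify_landscape(ls))
  expect_equal(unique(calls$parallel_confidence), "POSSIBLE_PARALLEL")

  # an ILE sharing one and the same position with an RSI is only reported
  st2 <- matrix("ABSENT", 1, 4, dimnames = list("100", sp))
  cl2 <- matrix(NA_character_, 1, 4, dimnames = dimnames(st2))
  st2["100", c("a", "c")] <- "PRESENT"
  cl2["100", "a"] <- "ILE"; cl2["100", "c"] <- "RSI"
  ls2 <- mk_landscape(st2, cl2)
  calls2 <- call_parallel_gains(ls2, classify_landscape(ls2))
  expect_true(calls2$ambiguous_coincident)
  expect_false(calls2$parallel_gain)
})

test_that("the gain frequency reports percent with its counts", {
  f <- gain_frequency(3, 13)
  expect_equal(f$percent, 23L)
  expect_equal(c(f$numerator, f$denominator), c(3, 13))
  expect_equal(gain_frequency(0, 13)$percent, 0L)
  expect_true(is.na(gain_frequency(0, 0)$percent))
})
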