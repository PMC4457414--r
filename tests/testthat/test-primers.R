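# Conserved-stretch detection, degenerate primer encoding and in-silico PCR.

test_that("conserved stretches respect the variable-column budget", {
  set.seed(17)
  s <- rand_dna(60)
  same <- c(a = s, b = s, c = s)
  st <- find_conserved_stretches(same, window_len = 20)
  expect_equal(nrow(st), 60 - 20 + 1)   # every window qualifies
  expect_true(all(st$n_variable == 0))

  # five variable columns inside every window of 30 -> excluded at budget 4
  ch <- strsplit(s, "")[[1]]
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  varied <- ch
  idx <- c(25, 27, 29, 31, 33)
  varied[idx] <- vapply(ch[idx], flip, character(1))
  aln5 <- c(a = s, b = paste(varied, collapse = ""))
  # windows starting in 4..25 span all five variable columns (25,27,...,33)
  st5 <- find_conserved_stretches(aln5, window_len = 30, max_variable = 4)
  expect_true(all(st5$start < 4 | st5$start > 25))
  expect_true(any(st5$n_variable > 0))

  # max_variable 0: the family-specific primer case, fully conserved only
  st0 <- find_conserved_stretches(aln5, window_len = 15, max_variable = 0)
  expect_true(all(st0$n_variable == 0))
  expect_true(all(st0$end < 25 | st0$start > 33))

  expect_error(find_conserved_stretches(same, window_len = 100), "exceeds")
})

test_that("degenerate encoding multiplies code sizes", {
  w <- rbind(strsplit("ACGT", "")[[1]], strsplit("ACGT", "")[[1]])
  p <- make_degenerate_primer(w)
  expect_equal(p$sequence, "ACGT")
  expect_equal(p$degeneracy, 1)
  w2 <- rbind(c("A", "C"), c("C", "T"))   # columns {A,C} and {C,T}
  p2 <- make_degenerate_primer(w2)
  expect_equal(p2$sequence, "MY")
  expect_equal(p2$degeneracy, 4)
  expect_equal(p2$n_variable_positions, 2)
  w3 <- rbind(c("A", "G"), c("G", "C"))   # {A,G}=R, {G,C}=S
  expect_equal(make_degenerate_primer(w3)$sequence, "RS")
  # degeneracy is multiplicative over concatenated windows
  expect_equal(iupac_degeneracy(paste0(p2$sequence, "RS")),
               p2$degeneracy * 4)
  expect_error(make_degenerate_primer(rbind(c("A", "-"), c("A", "A"))), "gap")
})

test_that("in-silico PCR recovers constructed amplicons", {
  set.seed(19)
  fwd <- rand_dna(18); rev <- rand_dna(18)
  pair <- list(forward = fwd, reverse = rev)
  tpl <- paste0(fwd, rand_dna(100), ilescape:::revcomp(rev))
  amp <- insilico_pcr(tpl, pair)
  expect_equal(nrow(amp), 1)
  expect_equal(amp$length, 18 + 100 + 18)
  expect_equal(c(amp$start, amp$end), c(0L, nchar(tpl)))
  expect_equal(amp$fwd_mismatches + amp$rev_mismatches, 0L)

  # no site at all
  expect_equal(nrow(insilico_pcr(rand_dna(500), pair)), 0)

  # two forward sites sharing one reverse site within range
  tpl2 <- paste0(fwd, rand_dna(50), fwd, rand_dna(60),
                 ilescape:::revcomp(rev))
  amp2 <- insilico_pcr(tpl2, pair)
  expect_equal(nrow(amp2), 2)
  expect_equal(amp2$end[1], amp2$end[2])

  # the amplicon cap suppresses long products
  expect_equal(nrow(insilico_pcr(tpl2, pair, max_amplicon = 100)), 1)
})

test_that("mismatch tolerance spares the 3' anchor", {
  set.seed(29)
  fwd <- rand_dna(18); rev <- rand_dna(18)
  pair <- list(forward = fwd, reverse = rev)
  flip <- function(b) c(A = "C", C = "G", G = "T", T = "A")[[b]]
  mutate_at <- function(s, i) {
    ch <- strsplit(s, "")[[1]]; ch[i] <- flip(ch[i]); paste(ch, collapse = "")
  }
  mid_mut <- mutate_at(fwd, 9)     # internal mismatch
  end_mut <- mutate_at(fwd, 17)    # inside the 3'-terminal 3 nt
  tpl_mid <- paste0(mid_mut, rand_dna(80), ilescape:::revcomp(rev))
  tpl_end <- paste0(end_mut, rand_dna(80), ilescape:::revcomp(rev))
  expect_equal(nrow(insilico_pcr(tpl_mid, pair, max_mismatch = 0)), 0)
  expect_equal(nrow(insilico_pcr(tpl_mid, pair, max_mismatch = 1)), 1)
  expect_equal(nrow(insilico_pcr(tpl_end, pair, max_mismatch = 1)), 0)
})

test_that("every family member is amplified by its own best primer pair", {
  set.seed(31)
  cons <- rand_intron(80)
  members <- stats::setNames(
    vapply(1:6, function(.) ilescape:::.mutate_intron(cons, 0.04),
           character(1)), paste0("m", 1:6))
  fam <- build_families(members)[[1]]
  pair <- design_primer_pair(fam)
  expect_lte(pair$n_variable_positions, 8)
  for (m in fam$members$sequence) {
    tpl <- paste0(rand_dna(150), m, rand_dna(150))
    amp <- insilico_pcr(tpl, pair)
    expect_gte(nrow(amp), 1)
    expect_true(any(amp$fwd_mismatches + amp$rev_mismatches == 0))
  }
})

test_that("matching agrees with the per-offset oracle on random templates", {
  set.seed(37)
  pair <- list(forward = "ACGTMGGTACRTTGCAST", reverse = "TTGCASTACGYACGTAGT")
  for (rep in 1:10) {
    tpl <- rand_dna(2000)
    if (rep %% 2 == 0) {
      # implant a product so non-empty results are exercised too
      ins <- paste0(instantiate_primer(pair$forward), rand_dna(120),
                    ilescape:::revcomp(instantiate_primer(pair$reverse)))
      cut <- sample(500:1500, 1)
      tpl <- paste0(substr(tpl, 1, cut), ins, substr(tpl, cut + 1, 2000))
    }
    mine <- insilico_pcr(tpl, pair, max_mismatch = 1)
    ref <- oracle_pcr(tpl, pair, max_mm = 1)
    expect_equal(nrow(mine), nrow(ref))
    if (nrow(mine) > 0) {
      expect_equal(mine$start, ref$start)
      expect_equal(mine$end, ref$end)
      expect_equal(mine$fwd_mismatches, ref$fwd_mismatches)
      expect_equal(mine$rev_mismatches, ref$rev_mismatches)
    }
  }
})
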