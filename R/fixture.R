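# Hand-constructed benchmark orthologue set encoding the canonical
# parallel-gain configuration: ILEs inserted 1, 8 and 3 nt (alignment frame)
# away from regular-intron positions conserved in a distant clade, plus
# distractor positions covering every classification category.

#' Build the parallel-gain benchmark fixture
#'
#' A 10-species orthologue set (two clades of five, species A1--A5 and
#' B1--B5) for one 900-nt gene. Three near-identical ILE copies sit 1, 8 and
#' 3 nt from RSI positions conserved in (sub)clades of the B side, so a
#' correct pipeline must call exactly three parallel gains at those
#' distances. Distractors: a conserved ancestral intron, a single-absence
#' position, a presence-absence polymorphic position and a lone ILE with no
#' nearby partner. One species (B5) is emitted on the '-' strand to exercise
#' strand handling end-to-end. Ground truth per position is returned
#' alongside the data.
#'
#' @param seed RNG seed for the concrete sequences (structure is fixed).
#' @param with_iles include the ILE insertions (set `FALSE` for the negative
#'   control: no parallel gains must be called).
#' @return list `genes` (species -> [gene_model()]), `alignment` (named
#'   aligned protein rows), `tree` (`phylo`), `truth` (data.frame `afo`,
#'   `category`, `parallel_gain`, `ile_side`), `ile_consensus`.
#' @export
make_parallel_gain_fixture <- function(seed = 1L, with_iles = TRUE) {
  withr::with_seed(seed, .fixture_impl(with_iles))
}

.fixture_impl <- function(with_iles) {
  tree <- ape::read.tree(text = paste0(
    "(((A1:0.08,A2:0.08):0.05,(A3:0.08,(A4:0.06,A5:0.06):0.04):0.05):0.12,",
    "((B1:0.08,B2:0.08):0.05,(B3:0.08,(B4:0.06,B5:0.06):0.04):0.05):0.12);"))
  species <- tree$tip.label
  L <- 900L
  root_cds <- .random_cds(L)
  cds <- stats::setNames(
    vapply(species, function(.) .mutate_cds(root_cds, 0.015), character(1)),
    species)

  ile_consensus <- random_intron(72L)
  ile_copy <- function() .mutate_intron(ile_consensus, 0.02)
  # Conserved RSI positions carry homologous but anciently diverged copies:
  # heavy interior divergence keeps them below the 80% family linkage.
  rsi_set <- function(carriers, len = 52L) {
    base <- random_intron(len)
    stats::setNames(vapply(carriers, function(.)
      .mutate_intron(base, 0.30), character(1)), carriers)
  }

  introns <- stats::setNames(
    replicate(length(species), .empty_intron_state(), simplify = FALSE),
    species)
  add <- function(sp, offset, seq, fam = NA_character_) {
    introns[[sp]] <<- rbind(introns[[sp]], data.frame(
      cds_offset = as.integer(offset), sequence = seq, family = fam,
      stringsAsFactors = FALSE))
  }

  # afo 60: ancestral intron, singly absent in B4
  s60 <- rsi_set(setdiff(species, "B4"))
  for (sp in names(s60)) add(sp, 60L, s60[[sp]])
  # afo 150: conserved in all ten species
  s150 <- rsi_set(species)
  for (sp in names(s150)) add(sp, 150L, s150[[sp]])
  # parallel-gain partners: RSIs conserved in B-side (sub)clades
  s300 <- rsi_set(c("B1", "B2", "B3", "B4", "B5"))
  for (sp in names(s300)) add(sp, 300L, s300[[sp]])
  s450 <- rsi_set(c("B1", "B2", "B3", "B4", "B5"))
  for (sp in names(s450)) add(sp, 450L, s450[[sp]])
  s600 <- rsi_set(c("B3", "B4", "B5"))
  for (sp in names(s600)) add(sp, 600L, s600[[sp]])
  # afo 720: presence-absence polymorphism (no clade explains it)
  s720 <- rsi_set(c("A1", "A3", "B2"))
  for (sp in names(s720)) add(sp, 720L, s720[[sp]])
  if (with_iles) {
    add("A1", 301L, ile_copy(), "ile")   # 1 nt from the RSI at 300
    add("A2", 458L, ile_copy(), "ile")   # 8 nt from the RSI at 450
    add("A1", 603L, ile_copy(), "ile")   # 3 nt from the RSI at 600
    add("A4", 810L, ile_copy(), "ile")   # lone ILE, no partner within 15 nt
  }

  genes <- stats::setNames(lapply(species, function(sp)
    assemble_gene("fixgene", sp, cds[[sp]], introns[[sp]],
                  strand = if (sp == "B5") "-" else "+")), species)
  alignment <- stats::setNames(vapply(species, function(sp)
    as.character(Biostrings::translate(Biostrings::DNAString(cds[[sp]]))),
    character(1)), species)

  truth <- data.frame(
    afo = c(60L, 150L, 300L, 450L, 600L, 720L),
    category = c("SINGLE_ABSENCE", "CONSERVED", "SINGLE_PRESENCE_IN_CLADE",
                 "SINGLE_PRESENCE_IN_CLADE", "SINGLE_PRESENCE_IN_CLADE",
                 "PRESENCE_ABSENCE_POLYMORPHISM"),
    parallel_gain = c(FALSE, FALSE, with_iles, with_iles, with_iles, FALSE),
    ile_side = FALSE, stringsAsFactors = FALSE)
  if (with_iles) {
    truth <- rbind(truth, data.frame(
      afo = c(301L, 458L, 603L, 810L),
      category = "SINGLE_PRESENCE",
      parallel_gain = c(TRUE, TRUE, TRUE, FALSE),
      ile_side = c(TRUE, TRUE, TRUE, FALSE), stringsAsFactors = FALSE))
  }
  truth <- truth[order(truth$afo), , drop = FALSE]
  rownames(truth) <- NULL
  list(genes = genes, alignment = alignment, tree = tree, truth = truth,
       ile_consensus = ile_consensus)
}
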