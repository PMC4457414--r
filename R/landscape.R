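# The intron landscape: the matrix of projected intron positions x species
# for one orthologue set, its phylogeny-aware classification, sliding-pair
# detection and parallel-gain calling.

POSITION_CATEGORIES <- c("CONSERVED", "SINGLE_PRESENCE",
                         "SINGLE_PRESENCE_IN_CLADE",
                         "PRESENCE_ABSENCE_POLYMORPHISM", "SINGLE_ABSENCE")

# Leaves of the smallest clade containing the species in `tips`.
.mrca_clade <- function(tree, tips) {
  if (length(tips) == 1) return(tips)
  node <- ape::getMRCA(tree, tips)
  ape::extract.clade(tree, node)$tip.label
}

#' Classify one intron position against the phylogeny
#'
#' MISSING species are excluded from the denominator. Categories are applied
#' in strict precedence: present in all scored species -> CONSERVED; present
#' in exactly one -> SINGLE_PRESENCE; present in exactly the scored members
#' of one monophyletic clade (>= 2 leaves) -> SINGLE_PRESENCE_IN_CLADE;
#' absent in exactly one -> SINGLE_ABSENCE; anything else ->
#' PRESENCE_ABSENCE_POLYMORPHISM.
#'
#' @param states named character vector per species: "PRESENT", "ABSENT" or
#'   "MISSING"; at least one PRESENT.
#' @param tree rooted `phylo` whose tips cover the species.
#' @return category string.
#' @export
classify_position <- function(states, tree) {
  scored <- names(states)[states != "MISSING"]
  present <- names(states)[states == "PRESENT"]
  if (length(present) == 0) stop("classify_position(): no PRESENT species")
  if (!all(scored %in% tree$tip.label))
    stop("species not in tree: ",
         paste(setdiff(scored, tree$tip.label), collapse = ", "))
  if (length(present) == length(scored)) return("CONSERVED")
  if (length(present) == 1) return("SINGLE_PRESENCE")
  clade <- .mrca_clade(tree, present)
  if (setequal(intersect(clade, scored), present))
    return("SINGLE_PRESENCE_IN_CLADE")
  if (length(scored) - length(present) == 1) return("SINGLE_ABSENCE")
  "PRESENCE_ABSENCE_POLYMORPHISM"
}

#' Refine projected intron positions against shared positions
#'
#' Deterministic replacement for manual curation of misaligned
#' exon-intron-exon boundaries: an intron's projected position may snap onto
#' an existing position carried by >= 2 other species at most
#' `shift_window` codons away, but only when doing so increases the
#' cross-species identity of the exonic junction context. For each candidate
#' the junction-anchored context identity (both introns' flanks compared at
#' their own junctions) is compared against the alignment-implied identity
#' (the query's flanks compared at the offset the current projection claims);
#' a strict improvement snaps, ties leave the position unchanged and flag it
#' ambiguous. All decisions are logged.
#'
#' @param tables named list (per species) of projected intron tables
#'   (from [project_intron_table()]).
#' @param cds named character vector of spliced CDS per species.
#' @param params [ile_params()] (uses `shift_window`, `flank`).
#' @return list `tables` (with snapped `afo`/`column`/`phase`) and `log`
#'   (data.frame of every snap/ambiguity decision).
#' @export
refine_boundaries <- function(tables, cds, params = ile_params()) {
  log <- list()
  if (params$shift_window == 0) {
    return(list(tables = tables,
                log = data.frame(species = character(0), afo_from = integer(0),
                                 afo_to = integer(0), action = character(0))))
  }
  max_shift <- 3L * params$shift_window
  flank <- params$flank
  all_pos <- do.call(rbind, lapply(names(tables), function(sp) {
    t <- tables[[sp]]
    if (nrow(t) == 0) return(NULL)
    data.frame(species = sp, afo = t$afo, cds_offset = t$cds_offset,
               stringsAsFactors = FALSE)
  }))
  if (is.null(all_pos)) {
    return(list(tables = tables,
                log = data.frame(species = character(0), afo_from = integer(0),
                                 afo_to = integer(0), action = character(0))))
  }
  ctx_ident <- function(sp_i, o_i, sp_j, o_j) {
    a <- cds[[sp_i]]; b <- cds[[sp_j]]
    left <- min(flank, o_i, o_j)
    right <- min(flank, nchar(a) - o_i, nchar(b) - o_j)
    if (left + right <= 0) return(0)
    sa <- substr(a, o_i - left + 1, o_i + right)
    sb <- substr(b, o_j - left + 1, o_j + right)
    mean(strsplit(sa, "")[[1]] == strsplit(sb, "")[[1]])
  }
  for (sp in names(tables)) {
    t <- tables[[sp]]
    for (i in seq_len(nrow(t))) {
      p <- t$afo[i]
      carriers_at <- function(afo) all_pos[all_pos$afo == afo &
                                             all_pos$species != sp, ,
                                           drop = FALSE]
      cand_afos <- unique(all_pos$afo[all_pos$species != sp])
      cand_afos <- cand_afos[abs(cand_afos - p) > 0 &
                               abs(cand_afos - p) <= max_shift]
      cand_afos <- Filter(function(q) nrow(carriers_at(q)) >= 2, cand_afos)
      if (length(cand_afos) == 0) next
      scores <- vapply(cand_afos, function(q) {
        cr <- carriers_at(q)
        snap <- mean(vapply(seq_len(nrow(cr)), function(k)
          ctx_ident(sp, t$cds_offset[i], cr$species[k], cr$cds_offset[k]),
          numeric(1)))
        stay <- mean(vapply(seq_len(nrow(cr)), function(k)
          ctx_ident(sp, t$cds_offset[i], cr$species[k],
                    cr$cds_offset[k] + (p - q)), numeric(1)))
        snap - stay
      }, numeric(1))
      best <- max(scores)
      if (best <= 0) next
      if (sum(scores == best) > 1) {
        log[[length(log) + 1]] <- data.frame(
          species = sp, afo_from = p, afo_to = NA_integer_,
          action = "ambiguous_tie", stringsAsFactors = FALSE)
        next
      }
      q <- cand_afos[which.max(scores)]
      t$afo[i] <- q
      t$column[i] <- q %/% 3L
      t$phase[i] <- q %% 3L
      log[[length(log) + 1]] <- data.frame(
        species = sp, afo_from = p, afo_to = as.integer(q),
        action = "snapped", stringsAsFactors = FALSE)
    }
    tables[[sp]] <- t
  }
  log <- if (length(log)) do.call(rbind, log) else
    data.frame(species = character(0), afo_from = integer(0),
               afo_to = integer(0), action = character(0))
  list(tables = tables, log = log)
}

#' Build the intron landscape of an orthologue set
#'
#' Extracts and classifies the introns of every species' gene model, projects
#' them onto the shared protein alignment, optionally refines boundaries, and
#' assembles the positions x species state matrix. A species contributes
#' MISSING where it has no orthologue, where its model is partial, or where
#' its alignment row is gapped at the position's column; pseudogene flags are
#' set for species whose spliced CDS contains an internal stop codon.
#'
#' @param genes named list (species -> [gene_model()]); species lacking an
#'   orthologue are simply absent.
#' @param alignment named character vector of aligned protein rows (defines
#'   the landscape's species set).
#' @param tree rooted `phylo`; every landscape species must be a tip.
#' @param families ILE families used to classify introns (may be NULL).
#' @param params [ile_params()].
#' @param refine snap misprojected boundaries (default TRUE).
#' @param alignment_id identifier stored with the positions.
#' @return object of class `intron_landscape`: `positions` (data.frame
#'   `column`, `phase`, `afo`), `states` and `classes` matrices (positions x
#'   species), `introns` (all projected intron tables), `pseudogene` flags,
#'   `tree`, `refinements` log.
#' @export
build_landscape <- function(genes, alignment, tree, families = NULL,
                            params = ile_params(), refine = TRUE,
                            alignment_id = "aln") {
  species <- names(alignment)
  if (length(species) < 2) stop("need >= 2 species")
  if (!all(species %in% tree$tip.label))
    stop("species absent from tree: ",
         paste(setdiff(species, tree$tip.label), collapse = ", "))
  if (!all(names(genes) %in% species))
    stop("gene models for species outside the alignment: ",
         paste(setdiff(names(genes), species), collapse = ", "))
  cds <- list(); tables <- list(); pseudo <- stats::setNames(
    rep(NA, length(species)), species)
  for (sp in species) {
    g <- genes[[sp]]
    if (is.null(g)) next
    cds[[sp]] <- splice_cds(g)
    if (!g$partial) pseudo[sp] <- has_internal_stop(cds[[sp]])
    tab <- extract_introns(g)
    tab$intron_class <- vapply(tab$sequence, classify_intron,
                               character(1), families = families,
                               params = params)
    tables[[sp]] <- project_intron_table(tab, alignment[[sp]],
                                         alignment_id = alignment_id)
  }
  refinements <- data.frame(species = character(0), afo_from = integer(0),
                            afo_to = integer(0), action = character(0))
  if (refine && length(tables) > 0) {
    r <- refine_boundaries(tables, unlist(cds), params)
    tables <- r$tables
    refinements <- r$log
  }
  afos <- sort(unique(unlist(lapply(tables, function(t) t$afo))))
  positions <- data.frame(column = afos %/% 3L, phase = afos %% 3L,
                          afo = afos)
  states <- matrix("ABSENT", nrow = length(afos), ncol = length(species),
                   dimnames = list(as.character(afos), species))
  classes <- matrix(NA_character_, nrow = length(afos),
                    ncol = length(species),
                    dimnames = list(as.character(afos), species))
  aln_chars <- lapply(alignment, function(r) strsplit(r, "")[[1]])
  for (sp in species) {
    g <- genes[[sp]]
    if (is.null(g)) { states[, sp] <- "MISSING"; next }
    if (g$partial) { states[, sp] <- "MISSING"; next }
    gap_at <- vapply(positions$column + 1L, function(cl)
      cl > length(aln_chars[[sp]]) || aln_chars[[sp]][cl] == "-", logical(1))
    states[gap_at, sp] <- "MISSING"
    t <- tables[[sp]]
    for (i in seq_len(nrow(t))) {
      key <- as.character(t$afo[i])
      states[key, sp] <- "PRESENT"
      classes[key, sp] <- t$intron_class[i]
    }
  }
  keep <- rowSums(states == "PRESENT") > 0
  if (!all(keep)) warning("dropping position(s) with no PRESENT species")
  structure(list(
    positions = positions[keep, , drop = FALSE],
    states = states[keep, , drop = FALSE],
    classes = classes[keep, , drop = FALSE],
    introns = tables,
    pseudogene = pseudo,
    tree = tree,
    alignment_id = alignment_id,
    refinements = refinements), class = "intron_landscape")
}

#' @export
print.intron_landscape <- function(x, ...) {
  cat(sprintf("<intron_landscape> %d position(s) x %d species\n",
              nrow(x$positions), ncol(x$states)))
  if (nrow(x$positions) > 0) {
    sym <- matrix(".", nrow = nrow(x$states), ncol = ncol(x$states),
                  dimnames = dimnames(x$states))
    sym[x$states == "PRESENT"] <- "#"
    sym[x$states == "MISSING"] <- "?"
    hdr <- formatC(x$positions$afo, width = 5)
    cat("  afo:", hdr, "\n")
    for (sp in colnames(x$states)) {
      cat(sprintf("  %-8s", sp),
          formatC(sym[, sp], width = 5), "\n")
    }
    cat("  (# present, . absent, ? missing)\n")
  }
  invisible(x)
}

#' Classify every landscape position
#'
#' @param landscape an `intron_landscape`.
#' @return data.frame `afo`, `column`, `phase`, `category`, `n_present`,
#'   `n_absent`, `n_missing`, plus empty call columns filled in by
#'   [call_parallel_gains()].
#' @export
classify_landscape <- function(landscape) {
  pos <- landscape$positions
  out <- pos
  out$category <- vapply(seq_len(nrow(pos)), function(i)
    classify_position(landscape$states[i, ], landscape$tree), character(1))
  out$n_present <- rowSums(landscape$states == "PRESENT")
  out$n_absent <- rowSums(landscape$states == "ABSENT")
  out$n_missing <- rowSums(landscape$states == "MISSING")
  out$sliding_partners <- ""
  out$ile_side <- FALSE
  out$parallel_gain <- FALSE
  out$parallel_confidence <- NA_character_
  out$ambiguous_coincident <- FALSE
  out$evidence <- ""
  out
}

#' Detect intron sliding candidate pairs
#'
#' All unordered pairs of landscape positions strictly closer than `window`
#' nucleotides (and not identical) in the alignment frame.
#'
#' @param positions data.frame with an `afo` column (or an
#'   `intron_landscape`).
#' @param window sliding window in nt (default 15; strict `<`).
#' @return data.frame `afo_a`, `afo_b` (`afo_a < afo_b`), `distance`.
#' @export
detect_sliding_pairs <- function(positions, window = 15L) {
  if (inherits(positions, "intron_landscape")) positions <- positions$positions
  afo <- sort(unique(positions$afo))
  out <- list()
  i <- 1L
  while (i < length(afo)) {
    j <- i + 1L
    while (j <= length(afo) && afo[j] - afo[i] < window) {
      out[[length(out) + 1L]] <- data.frame(
        afo_a = afo[i], afo_b = afo[j], distance = afo[j] - afo[i])
      j <- j + 1L
    }
    i <- i + 1L
  }
  if (length(out) == 0)
    return(data.frame(afo_a = integer(0), afo_b = integer(0),
                      distance = integer(0)))
  do.call(rbind, out)
}

#' Call parallel intron gains from sliding pairs
#'
#' For each sliding pair in which one position carries only ILE-class introns
#' and its partner carries RSI-class introns in species outside the clade
#' spanned by the ILE carriers, both positions are marked as a parallel gain
#' (an ILE inserted independently next to an older regular intron). If the
#' partner's outside introns are degenerate-ILE candidates rather than RSIs,
#' the call is downgraded to POSSIBLE_PARALLEL. Positions whose own cells mix
#' ILE and RSI classes (the same column occupied by both) are flagged
#' `ambiguous_coincident` and never auto-called.
#'
#' @param landscape an `intron_landscape` with classified intron cells.
#' @param calls data.frame from [classify_landscape()].
#' @param pairs data.frame from [detect_sliding_pairs()].
#' @return `calls` with `sliding_partners`, `ile_side`, `parallel_gain`,
#'   `parallel_confidence`, `ambiguous_coincident`, `evidence` filled in.
#' @export
call_parallel_gains <- function(landscape, calls,
                                pairs = detect_sliding_pairs(landscape)) {
  st <- landscape$states; cl <- landscape$classes
  cell_classes <- function(afo) {
    key <- as.character(afo)
    row <- cl[key, ]           # named row vector
    row[st[key, ] == "PRESENT"]
  }
  carriers <- function(afo) {
    key <- as.character(afo)
    colnames(st)[st[key, ] == "PRESENT"]
  }
  # coincident ILE/RSI at one and the same position: report, do not call
  for (i in seq_len(nrow(calls))) {
    cc <- cell_classes(calls$afo[i])
    if (any(cc == "ILE") && any(cc %in% c("RSI", "DEGENERATE_ILE_CANDIDATE"))) {
      calls$ambiguous_coincident[i] <- TRUE
      calls$evidence[i] <- paste0(calls$evidence[i],
                                  "ILE coincident with non-ILE intron at the same position; ")
    }
  }
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$afo_a[k]; b <- pairs$afo_b[k]; d <- pairs$distance[k]
    ia <- match(a, calls$afo); ib <- match(b, calls$afo)
    calls$sliding_partners[ia] <- paste0(calls$sliding_partners[ia],
                                         sprintf("%d(d=%d);", b, d))
    calls$sliding_partners[ib] <- paste0(calls$sliding_partners[ib],
                                         sprintf("%d(d=%d);", a, d))
    for (ord in list(c(a, b), c(b, a))) {
      ile_afo <- ord[1]; partner_afo <- ord[2]
      cc_ile <- cell_classes(ile_afo)
      if (!(length(cc_ile) > 0 && all(cc_ile == "ILE"))) next
      if (calls$ambiguous_coincident[match(ile_afo, calls$afo)]) next
      ile_carriers <- carriers(ile_afo)
      clade <- .mrca_clade(landscape$tree, ile_carriers)
      cc_part <- cell_classes(partner_afo)
      outside <- setdiff(names(cc_part), clade)
      if (length(outside) == 0) next
      out_classes <- cc_part[outside]
      conf <- if (any(out_classes == "RSI")) "PARALLEL"
        else if (any(out_classes == "DEGENERATE_ILE_CANDIDATE"))
          "POSSIBLE_PARALLEL" else NA_character_
      if (is.na(conf)) next
      ii <- match(ile_afo, calls$afo); ip <- match(partner_afo, calls$afo)
      calls$ile_side[ii] <- TRUE
      upgrade <- function(old, new) {
        if (is.na(old) || old == "POSSIBLE_PARALLEL") new else old
      }
      calls$parallel_gain[c(ii, ip)] <- TRUE
      calls$parallel_confidence[ii] <- upgrade(calls$parallel_confidence[ii],
                                               conf)
      calls$parallel_confidence[ip] <- upgrade(calls$parallel_confidence[ip],
                                               conf)
      ev <- sprintf(
        "ILE at afo %d (%s) %d nt from %s intron(s) at afo %d outside its clade; ",
        ile_afo, paste(ile_carriers, collapse = ","), d,
        paste(unique(out_classes), collapse = "/"), partner_afo)
      calls$evidence[ii] <- paste0(calls$evidence[ii], ev)
      calls$evidence[ip] <- paste0(calls$evidence[ip], ev)
    }
  }
  calls
}

#' Parallel intron gain frequency
#'
#' Percentage of presence-absence polymorphic positions explained by parallel
#' gains: `100 * numerator / denominator`, rounded to the nearest integer,
#' where the numerator counts parallel-gain positions on the ILE side and the
#' denominator counts PRESENCE_ABSENCE_POLYMORPHISM positions. With a zero
#' denominator the frequency is undefined (`NA`).
#'
#' @param calls data.frame from [call_parallel_gains()], or a numerator count
#'   when `denominator` is given directly.
#' @param denominator optional explicit denominator count.
#' @return list `percent` (integer or NA), `numerator`, `denominator`.
#' @export
gain_frequency <- function(calls, denominator = NULL) {
  if (is.data.frame(calls)) {
    num <- sum(calls$parallel_gain & calls$ile_side)
    den <- sum(calls$category == "PRESENCE_ABSENCE_POLYMORPHISM")
  } else {
    stopifnot(is.numeric(calls), !is.null(denominator))
    num <- calls; den <- denominator
  }
  pct <- if (den == 0) NA_integer_ else as.integer(round(100 * num / den))
  list(percent = pct, numerator = num, denominator = den)
}
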