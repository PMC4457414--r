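# Recovery benchmarking: Dollo-style position-level gain/loss calls from a
# landscape, compared against the simulator's true event log.

#' Dollo-style gain/loss calls for every landscape position
#'
#' For each position, the smallest clade containing all carriers is taken as
#' the gain point: a gain is called when that clade does not span all scored
#' species (i.e. the position is not parsimoniously ancestral), and a loss is
#' called when a scored species inside the clade lacks the intron.
#'
#' @param landscape an `intron_landscape`.
#' @param gene_id identifier copied into the output.
#' @return data.frame `gene_id`, `afo`, `gain_called`, `loss_called`.
#' @export
recover_position_events <- function(landscape, gene_id = "gene") {
  st <- landscape$states
  n <- nrow(landscape$positions)
  gain <- logical(n); loss <- logical(n)
  for (i in seq_len(n)) {
    row <- st[i, ]
    scored <- names(row)[row != "MISSING"]
    present <- names(row)[row == "PRESENT"]
    clade <- intersect(.mrca_clade(landscape$tree, present), scored)
    gain[i] <- !setequal(clade, scored)
    loss[i] <- length(setdiff(clade, present)) > 0
  }
  data.frame(gene_id = gene_id, afo = landscape$positions$afo,
             gain_called = gain, loss_called = loss,
             stringsAsFactors = FALSE)
}

#' Score pipeline gain/loss calls against the true event log
#'
#' Builds the landscape of every simulated gene, derives position-level
#' gain/loss calls with [recover_position_events()], and compares them with
#' the leaf-observable events of the true log: a gain is observable when the
#' gained intron survives in at least one leaf, a loss when its position is
#' still occupied in at least one other leaf (events invisible at the leaves
#' are unrecoverable in principle). In the simulator's gap-free alignments
#' the alignment-frame offset of a position equals its CDS offset, so calls
#' and events are matched on (gene, offset, type).
#'
#' @param sim an `ile_simulation`.
#' @param refine passed to [build_landscape()].
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `n_true`,
#'   `n_called`, and the `calls` / `truth` key sets.
#' @export
evaluate_recovery <- function(sim, refine = TRUE) {
  leaf_offsets <- lapply(sim$genes, function(per_sp)
    sort(unique(unlist(lapply(per_sp, function(g)
      extract_introns(g)$cds_offset)))))
  truth <- character(0)
  ev <- sim$events
  for (i in seq_len(nrow(ev))) {
    type <- if (ev$type[i] == "LOSS") "LOSS" else "GAIN"
    observable <- ev$cds_offset[i] %in% leaf_offsets[[ev$gene_id[i]]]
    if (observable)
      truth <- c(truth, paste(ev$gene_id[i], ev$cds_offset[i], type,
                              sep = ":"))
  }
  truth <- unique(truth)
  called <- character(0)
  for (g in names(sim$genes)) {
    ls <- build_landscape(sim$genes[[g]], sim$alignments[[g]], sim$tree,
                          families = NULL, refine = refine)
    rec <- recover_position_events(ls, gene_id = g)
    if (any(rec$gain_called))
      called <- c(called, paste(g, rec$afo[rec$gain_called], "GAIN",
                                sep = ":"))
    if (any(rec$loss_called))
      called <- c(called, paste(g, rec$afo[rec$loss_called], "LOSS",
                                sep = ":"))
  }
  called <- unique(called)
  tp <- length(intersect(called, truth))
  list(tp = tp, fp = length(setdiff(called, truth)),
       fn = length(setdiff(truth, called)),
       precision = if (length(called)) tp / length(called) else NA_real_,
       recall = if (length(truth)) tp / length(truth) else NA_real_,
       n_true = length(truth), n_called = length(called),
       calls = called, truth = truth)
}

#' Pooled recovery benchmark over multiple simulation seeds
#'
#' Runs [simulate_ile_evolution()] + [evaluate_recovery()] for `n_seeds`
#' consecutive seeds and pools true/false positives across seeds.
#'
#' @param n_seeds number of replicate simulations (default 20).
#' @param base_seed first seed; replicate `i` uses `base_seed + i - 1`.
#' @param ... overrides passed to [sim_params()].
#' @return list `precision`, `recall`, `n_true`, `n_called`, `per_seed`
#'   (data.frame of per-replicate counts).
#' @export
recovery_benchmark <- function(n_seeds = 20L, base_seed = 1L, ...) {
  tp <- fp <- fn <- 0L
  rows <- list()
  for (i in seq_len(n_seeds)) {
    params <- sim_params(seed = base_seed + i - 1L, ...)
    res <- evaluate_recovery(simulate_ile_evolution(params))
    tp <- tp + res$tp; fp <- fp + res$fp; fn <- fn + res$fn
    rows[[i]] <- data.frame(seed = params$seed, tp = res$tp, fp = res$fp,
                            fn = res$fn, precision = res$precision,
                            recall = res$recall)
  }
  list(precision = tp / (tp + fp), recall = tp / (tp + fn),
       n_true = tp + fn, n_called = tp + fp,
       per_seed = do.call(rbind, rows))
}
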