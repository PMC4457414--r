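# Umbrella pipeline: families -> classification -> landscape -> position
# calls -> parallel gains -> frequency, with deterministic on-disk reports.

#' Run the full intron-landscape pipeline on one orthologue set
#'
#' Pools the introns of all species, builds candidate families by
#' single-linkage identity clustering and keeps those whose members span
#' several loci as ILE families, then builds and classifies the landscape,
#' detects sliding pairs, calls parallel gains and computes the parallel-gain
#' frequency.
#'
#' @param genes named list (species -> [gene_model()]).
#' @param alignment named character vector of aligned protein rows.
#' @param tree rooted `phylo` covering the species.
#' @param params [ile_params()].
#' @param refine snap misprojected boundaries (default TRUE).
#' @param families optional pre-built ILE families; when NULL they are built
#'   from the orthologue set's own introns.
#' @return object of class `ile_pipeline`: `families`, `landscape`, `calls`,
#'   `sliding`, `frequency`, `summary`.
#' @export
run_pipeline <- function(genes, alignment, tree, params = ile_params(),
                         refine = TRUE, families = NULL) {
  if (length(genes) == 0) stop("run_pipeline(): empty orthologue set")
  if (is.null(families)) {
    pool <- list(); loci <- character(0)
    for (sp in names(genes)) {
      tab <- extract_introns(genes[[sp]])
      if (nrow(tab) == 0) next
      tab <- project_intron_table(tab, alignment[[sp]])
      ids <- sprintf("%s|%s|%d", sp, tab$gene_id, tab$afo)
      pool[ids] <- tab$sequence
      loci[ids] <- sprintf("%s|%d", tab$gene_id, tab$afo)
    }
    families <- if (length(pool) > 0) {
      built <- build_families(unlist(pool),
                              threshold = params$cluster_threshold,
                              params = params)
      filter_ile_families(built, loci, min_loci = params$min_family_loci)
    } else list()
  }
  landscape <- build_landscape(genes, alignment, tree, families = families,
                               params = params, refine = refine)
  calls <- classify_landscape(landscape)
  sliding <- detect_sliding_pairs(landscape, window = params$sliding_window)
  calls <- call_parallel_gains(landscape, calls, sliding)
  freq <- gain_frequency(calls)
  parallel_pairs <- sliding[
    sliding$afo_a %in% calls$afo[calls$parallel_gain] &
      sliding$afo_b %in% calls$afo[calls$parallel_gain] &
      (sliding$afo_a %in% calls$afo[calls$ile_side] |
         sliding$afo_b %in% calls$afo[calls$ile_side]), , drop = FALSE]
  summary <- list(
    n_positions = nrow(calls),
    category_counts = as.list(table(factor(calls$category,
                                           levels = POSITION_CATEGORIES))),
    n_sliding_pairs = nrow(sliding),
    n_parallel_gains = nrow(parallel_pairs),
    parallel_distances = parallel_pairs$distance,
    n_pseudogenes = sum(landscape$pseudogene, na.rm = TRUE),
    frequency = freq)
  structure(list(families = families, landscape = landscape, calls = calls,
                 sliding = sliding, parallel_pairs = parallel_pairs,
                 frequency = freq, summary = summary),
            class = "ile_pipeline")
}

#' @export
print.ile_pipeline <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("<ile_pipeline> %d position(s): %d sliding pair(s), ",
                     "%d parallel gain(s)\n"),
              s$n_positions, s$n_sliding_pairs, s$n_parallel_gains))
  for (cat_name in names(s$category_counts))
    cat(sprintf("  %-30s %d\n", cat_name, s$category_counts[[cat_name]]))
  f <- s$frequency
  cat(sprintf("  parallel-gain frequency: %s%% (%d/%d)\n",
              ifelse(is.na(f$percent), "NA", f$percent),
              f$numerator, f$denominator))
  invisible(x)
}

#' Run the pipeline from files and write its reports
#'
#' Reads gene models (GFF3 + FASTA), the protein alignment and the species
#' tree, runs [run_pipeline()], and writes `landscape.tsv`, `landscape.json`,
#' `calls.tsv` and `summary.json` into `out_dir`. Every report carries a
#' header (package version, parameter echo, parameter hash) and the outputs
#' are bit-identical across re-runs with the same inputs.
#'
#' @param gff3,genome_fasta gene models of the orthologue set.
#' @param alignment_fasta aligned protein FASTA (rows named by species).
#' @param tree_file rooted newick species tree.
#' @param out_dir output directory.
#' @param params [ile_params()].
#' @param refine snap misprojected boundaries (default TRUE).
#' @return the `ile_pipeline` object, invisibly.
#' @export
run_pipeline_files <- function(gff3, genome_fasta, alignment_fasta, tree_file,
                               out_dir, params = ile_params(),
                               refine = TRUE) {
  models <- read_gene_models(gff3, genome_fasta)
  genes <- stats::setNames(models,
                           vapply(models, `[[`, character(1), "species"))
  alignment <- read_protein_alignment(alignment_fasta)
  tree <- read_species_tree(tree_file)
  res <- run_pipeline(genes, alignment, tree, params = params,
                      refine = refine)
  write_pipeline_reports(res, out_dir, params = params)
  invisible(res)
}

# Hash of the parameter list for the reproducibility header.
.params_hash <- function(params) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeLines(jsonlite::toJSON(params, auto_unbox = TRUE, digits = NA), tmp)
  unname(tools::md5sum(tmp))
}

#' Write the pipeline's TSV/JSON reports
#'
#' @param res an `ile_pipeline`.
#' @param out_dir output directory (created if needed).
#' @param params the [ile_params()] used (echoed into every header).
#' @return `out_dir`, invisibly.
#' @export
write_pipeline_reports <- function(res, out_dir, params = ile_params()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hdr <- sprintf("# ilescape %s | params %s",
                 as.character(utils::packageVersion("ilescape")),
                 .params_hash(params))
  ls <- res$landscape
  state_cols <- as.data.frame(ls$states, stringsAsFactors = FALSE)
  for (sp in colnames(ls$states)) {
    cls <- ls$classes[, sp]
    state_cols[[sp]] <- ifelse(
      ls$states[, sp] == "PRESENT",
      paste0("P:", cls),
      ifelse(ls$states[, sp] == "ABSENT", "A", "M"))
  }
  land_tab <- cbind(res$calls[, c("afo", "column", "phase", "category",
                                  "sliding_partners", "parallel_gain",
                                  "parallel_confidence")],
                    state_cols)
  write_tsv <- function(df, path) {
    con <- file(path, "w")
    writeLines(hdr, con)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
    close(con)
  }
  write_tsv(land_tab, file.path(out_dir, "landscape.tsv"))
  write_tsv(res$calls, file.path(out_dir, "calls.tsv"))
  jsonlite::write_json(
    list(header = list(version =
                         as.character(utils::packageVersion("ilescape")),
                       params = params, params_md5 = .params_hash(params)),
         positions = res$calls, states = state_cols,
         pseudogene = as.list(ls$pseudogene)),
    file.path(out_dir, "landscape.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  jsonlite::write_json(
    c(list(header = list(version =
                           as.character(utils::packageVersion("ilescape")),
                         params = params, params_md5 = .params_hash(params))),
      res$summary),
    file.path(out_dir, "summary.json"), auto_unbox = TRUE, digits = NA,
    na = "null")
  invisible(out_dir)
}
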