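#' Pipeline configuration
#'
#' Bundles the thresholds the analyses conventionally use (differential
#' cutoff P < 0.01, variant retention P < 0.05, +/- 1 kb association and
#' +/- 10 kb TSS windows, 5 kb anchor flank, 10,000 overlap shuffles, 1,000
#' GSEA permutations) with either a simulation block or an input directory.
#'
#' @param seed master seed; every stochastic stage derives a named substream.
#' @param sim a [sim_config()] used when `input_dir` is NULL (its seed is
#'   overridden by `seed`).
#' @param input_dir optional directory holding a bundle previously written
#'   by [write_sim_bundle()] (or files in the same formats).
#' @param alpha_diff differential significance cutoff.
#' @param alpha_variant variant retention cutoff (strict `<`).
#' @param window_assoc peak-peak association window (bp).
#' @param window_tss TSS association window (bp).
#' @param flank_anchor loop-anchor flank (bp).
#' @param n_perm_overlap shuffles per permutation test.
#' @param n_perm_gsea GSEA permutations.
#' @param k_clusters K for expression clustering.
#' @param expr_genes,expr_sigma size and noise of the expression simulation.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(seed = 1, sim = sim_config(seed = seed),
                            input_dir = NULL,
                            alpha_diff = 0.01, alpha_variant = 0.05,
                            window_assoc = 1000, window_tss = 10000,
                            flank_anchor = 5000, n_perm_overlap = 10000,
                            n_perm_gsea = 1000, k_clusters = 4,
                            expr_genes = 2000, expr_sigma = 0.25) {
  stopifnot(alpha_diff > 0, alpha_variant > 0, window_assoc >= 0,
            window_tss >= 0, flank_anchor >= 0, n_perm_overlap >= 1,
            n_perm_gsea >= 1, k_clusters >= 2)
  sim$seed <- seed
  structure(as.list(environment()), class = "pipeline_config")
}

#' Load a previously written data bundle
#'
#' Reads the plain-text files emitted by [write_sim_bundle()] back into a
#' bundle (without planted truth), so external data in the same formats can
#' drive the pipeline.
#'
#' @param dir directory containing chrom.sizes, peaks.bed, counts.tsv,
#'   conditions.tsv, tss.bed, bound_sites.bed, loops.bedpe, variants.tsv and
#'   second_signal.tsv.
#' @return a `sim_bundle`-shaped list (with `truth = NULL`).
#' @export
read_sim_bundle <- function(dir) {
  p <- function(f) {
    fp <- file.path(dir, f)
    if (!file.exists(fp)) stop2("missing input file: ", fp)
    fp
  }
  g <- read_chrom_sizes(p("chrom.sizes"))
  peaks <- read_bed(p("peaks.bed"), g, role = "peaks")
  sm <- read_signal_matrix(p("counts.tsv"), p("conditions.tsv"), peaks = peaks)
  second <- utils::read.table(p("second_signal.tsv"), sep = "\t", header = TRUE,
                              stringsAsFactors = FALSE)
  structure(list(genome = g, peaks = peaks, counts = sm, peak_class = NULL,
                 tss = read_bed(p("tss.bed"), g, role = "TSS"),
                 second_signal = setNames(second$signal, second$peak_id),
                 bound_sites = read_bed(p("bound_sites.bed"), g, role = "bound_sites"),
                 loops = read_bedpe(p("loops.bedpe"), g),
                 variants = read_variants(p("variants.tsv"), g),
                 truth = NULL, config = NULL),
            class = "sim_bundle")
}

write_report <- function(df, path, meta) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# %s", meta), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Executes every stage end to end: data (simulate or load), depth
#' normalization, differential testing, feeding classification, the
#' permutation-enrichment grid (TSSs and bound sites against each peak
#' class), signal correlation, per-class signal summaries, expression
#' clustering with nutrient-response set selection and pre-ranked GSEA,
#' variant-to-gene linking through loops, and GSEA of the linked gene set.
#' Nine report tables are written to `out_dir`, each stamped with the seed
#' and a config fingerprint; a rerun with the same config and inputs is
#' bit-identical. A stage failure aborts with the stage name; reports
#' already written are kept and a `FAILED_<stage>` marker is left.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory for report tables.
#' @param quiet suppress progress messages.
#' @return (invisibly) an `epifeed_run` list with every stage's in-memory
#'   result plus `files`, `seed`, `config_hash`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(unclass(config))
  meta <- sprintf("epifeed seed=%d config=%s", config$seed, hash)
  say <- function(...) if (!quiet) message(sprintf("[%s] ", format(Sys.time(), "%H:%M:%S")), ...)
  stage <- function(name, expr) {
    say("stage: ", name)
    tryCatch(expr, error = function(e) {
      file.create(file.path(out_dir, paste0("FAILED_", name)))
      stop2("stage '", name, "' failed: ", conditionMessage(e))
    })
  }
  res <- list(seed = config$seed, config_hash = hash, files = character())
  emit <- function(df, file) {
    path <- file.path(out_dir, file)
    write_report(df, path, meta)
    res$files <<- c(res$files, path)
  }

  bundle <- stage("data", {
    if (!is.null(config$input_dir)) read_sim_bundle(config$input_dir)
    else simulate_dataset(config$sim)
  })
  res$bundle <- bundle

  norm <- stage("normalize", normalize_total(bundle$counts))

  res$differential <- stage("differential",
                            simple_differential(norm, "fasted", "fed"))
  emit(as.data.frame(res$differential), "01_differential.tsv")

  res$classes <- stage("classify",
                       classify_feeding(res$differential, alpha = config$alpha_diff))
  emit(data.frame(peak_id = names(res$classes), class = as.character(res$classes)),
       "02_peak_classes.tsv")

  res$permutation <- stage("permutation_grid", {
    cls <- levels(res$classes)
    pairs <- list()
    for (cl in cls) {
      sel <- bundle$peaks[res$classes == cl]
      attr(sel, "role") <- cl
      if (nrow(sel) == 0) next
      pairs[[paste0("TSS|", cl)]] <- list(reference = bundle$tss, test = sel)
      pairs[[paste0("bound_sites|", cl)]] <- list(reference = bundle$bound_sites, test = sel)
    }
    # TSS pairs use the +/- 10 kb window, site pairs +/- 1 kb
    tssp <- grepl("^TSS\\|", names(pairs))
    out <- rbind(
      if (any(tssp)) batch_permutation(pairs[tssp], window_bp = config$window_tss,
                                       n_iter = config$n_perm_overlap,
                                       seed = config$seed),
      if (any(!tssp)) batch_permutation(pairs[!tssp], window_bp = config$window_assoc,
                                        n_iter = config$n_perm_overlap,
                                        seed = config$seed))
    out$window_bp <- ifelse(grepl("^TSS\\|", out$id), config$window_tss,
                            config$window_assoc)
    out
  })
  emit(res$permutation, "03_permutation.tsv")

  res$correlation <- stage("correlation", {
    x <- rowMeans(norm$counts)
    y <- bundle$second_signal[rownames(norm$counts)]
    c(signal_correlation(x, y), list(tracks = "mean_peak_signal_vs_second"))
  })
  emit(data.frame(comparison = res$correlation$tracks, rho = res$correlation$rho,
                  p = res$correlation$p, n = res$correlation$n),
       "04_correlation.tsv")

  res$class_summary <- stage("class_summary",
                             class_signal_summary(rowMeans(norm$counts), res$classes))
  emit(res$class_summary$stats, "05_class_summary.tsv")

  expr <- stage("expression", {
    simulate_expression(n_genes = config$expr_genes, sigma = config$expr_sigma,
                        seed = substream_seed(config$seed, "expression"))
  })
  res$expression <- expr

  res$clusters <- stage("cluster", {
    km <- kmeans_logfc(expr$log2fc, k = config$k_clusters,
                       seed = substream_seed(config$seed, "kmeans"))
    nutrient <- select_nutrient_response_cluster(km)
    list(kmeans = km, nutrient = nutrient)
  })
  emit(data.frame(gene_id = names(res$clusters$kmeans$cluster),
                  cluster = res$clusters$kmeans$cluster,
                  nutrient_response = names(res$clusters$kmeans$cluster) %in%
                    res$clusters$nutrient$genes),
       "06_clusters.tsv")

  res$gsea <- stage("gsea", {
    ranked <- ranked_list(rownames(expr$log2fc), expr$log2fc[, 1])
    r <- gsea_preranked(ranked, res$clusters$nutrient$genes,
                        n_perm = config$n_perm_gsea,
                        seed = substream_seed(config$seed, "gsea"),
                        set_name = "nutrient_response")
    gsea_batch_fdr(list(r))
  })
  emit(res$gsea, "07_gsea.tsv")

  res$links <- stage("link", {
    variant_linked_geneset(bundle$bound_sites, bundle$variants, bundle$loops,
                           bundle$tss, alpha = config$alpha_variant,
                           flank_bp = config$flank_anchor)
  })
  emit(if (nrow(res$links$links) > 0) res$links$links
       else data.frame(site_id = character(), variant_id = character(),
                       gene_id = character(), loop_id = character()),
       "08_links.tsv")

  res$gsea_linked <- stage("gsea_linked", {
    ranked <- ranked_list(rownames(expr$log2fc), expr$log2fc[, 1])
    genes <- intersect(res$links$genes, ranked$id)
    if (length(genes) == 0) {
      data.frame(set = "variant_linked", es = NA_real_, nes = NA_real_,
                 p = NA_real_, fdr = NA_real_, n_set = 0L,
                 leading_edge_size = 0L)
    } else {
      r <- gsea_preranked(ranked, genes, n_perm = config$n_perm_gsea,
                          seed = substream_seed(config$seed, "gsea_linked"),
                          set_name = "variant_linked")
      gsea_batch_fdr(list(r))
    }
  })
  emit(res$gsea_linked, "09_linked_geneset_gsea.tsv")

  say("done: ", length(res$files), " report tables in ", out_dir)
  class(res) <- "epifeed_run"
  invisible(res)
}

#' @export
print.epifeed_run <- function(x, ...) {
  cat(sprintf("epifeed run (seed %d, config %s): %d report tables\n",
              x$seed, x$config_hash, length(x$files)))
  cat(paste0("  ", basename(x$files), collapse = "\n"), "\n")
  invisible(x)
}
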