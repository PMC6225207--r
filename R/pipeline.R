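#' End-to-end pipeline configuration
#'
#' Bundles the inputs and stage parameters of the full composition + motif
#' analysis. All paths must exist at [run_full_pipeline()] time.
#'
#' @param query_fasta Path to the query FASTA (e.g. known quadruplex binding
#'   proteins).
#' @param background_fasta Named character vector of background FASTA paths
#'   (at least one; the first is used for the enrichment comparison shown in
#'   the report, all are run).
#' @param reference_freq Optional path to a residue/fraction TSV
#'   ([read_reference_frequencies()]); if `NULL` the pooled background
#'   frequencies are used.
#' @param motifs Named character vector of scan peptides (default the FMR1
#'   RGG-box and NIQI consensus).
#' @param scan_p,predict_p p-value thresholds for scanning (0.01) and
#'   candidate prediction (0.1).
#' @param q_thresholds Two q cut-offs for the per-protein partition.
#' @param top_n Candidates kept by [predict_candidates()].
#' @param enrichment A [test_config()].
#' @param clustering A [bootstrap_config()].
#' @param discovery A [sampler_config()], or `NULL` to skip discovery.
#' @param seed Global seed applied to stage configs that were left at their
#'   default seed.
#' @param out_dir Output directory (created if missing).
#' @return A list of class `PipelineConfig`.
#' @export
pipeline_config <- function(query_fasta, background_fasta,
                            reference_freq = NULL,
                            motifs = c(FMR1 = FMR1_MOTIF, NIQI = NIQI_MOTIF),
                            scan_p = 0.01, predict_p = 0.1,
                            q_thresholds = c(0.05, 0.1), top_n = 100L,
                            enrichment = test_config(),
                            clustering = bootstrap_config(),
                            discovery = sampler_config(),
                            seed = 1L, out_dir = "quadbind_out") {
  stopifnot(scan_p > 0, scan_p < 1, predict_p > 0, predict_p < 1)
  if (is.null(names(background_fasta)))
    names(background_fasta) <- sprintf("background%d",
                                       seq_along(background_fasta))
  if (is.null(names(motifs)))
    names(motifs) <- sprintf("motif%d", seq_along(motifs))
  enrichment$seed <- as.integer(seed)
  clustering$seed <- as.integer(seed)
  if (!is.null(discovery)) discovery$seed <- as.integer(seed)
  structure(list(query_fasta = query_fasta,
                 background_fasta = background_fasta,
                 reference_freq = reference_freq, motifs = motifs,
                 scan_p = scan_p, predict_p = predict_p,
                 q_thresholds = q_thresholds, top_n = as.integer(top_n),
                 enrichment = enrichment, clustering = clustering,
                 discovery = discovery, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "PipelineConfig")
}

.write_tsv <- function(df, path, cfg, stage, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# quadbind %s | stage: %s | seed: %d",
                       as.character(utils::packageVersion("quadbind")),
                       stage, cfg$seed),
               if (length(extra)) paste0("# ", extra)), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}

.stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full composition + motif analysis
#'
#' Executes, in order: composition matrix and boxplot statistics of the query
#' set; relative enrichment against the reference frequencies; bootstrap
#' enrichment tests against every background set; residue-content correlation
#' analysis; average-linkage clustering with multiscale-bootstrap support;
#' PWM scans of each configured motif (with q partition and multi-hit table);
#' de novo motif discovery; and candidate prediction against the first
#' background set. All tables are written as TSV with a header line recording
#' the package version, seed and stage; the tree as newick; discovered motifs
#' in MEME minimal format. Reruns with the same config are byte-identical.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list of in-memory stage results plus `manifest`
#'   (data frame of output files and stage parameters).
#' @export
run_full_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "PipelineConfig"))
  for (f in c(cfg$query_fasta, cfg$background_fasta, cfg$reference_freq))
    if (!file.exists(f))
      stop("pipeline stage 'config' failed: input file not found: ", f)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(...) file.path(cfg$out_dir, ...)
  manifest <- list()
  note <- function(file, stage, params = "")
    manifest[[length(manifest) + 1L]] <<- data.frame(
      file = file, stage = stage, params = params, stringsAsFactors = FALSE)

  query <- .stage("read_query", read_fasta(cfg$query_fasta, name = "query"))
  backgrounds <- lapply(names(cfg$background_fasta), function(nm)
    .stage(paste0("read_background:", nm),
           read_fasta(cfg$background_fasta[[nm]], name = nm)))
  names(backgrounds) <- names(cfg$background_fasta)

  cm <- .stage("composition", composition_matrix(query))
  .write_tsv(data.frame(protein = rownames(cm),
                        round(unclass(cm), 6), check.names = FALSE),
             out("composition.tsv"), cfg, "composition")
  note("composition.tsv", "composition")

  bx <- .stage("boxplot", boxplot_stats(cm))
  .write_tsv(bx$summary, out("boxplot_summary.tsv"), cfg, "boxplot")
  if (!is.null(bx$outliers))
    .write_tsv(bx$outliers, out("boxplot_outliers.tsv"), cfg, "boxplot")
  note("boxplot_summary.tsv", "boxplot")

  ref <- if (!is.null(cfg$reference_freq))
    .stage("reference", read_reference_frequencies(cfg$reference_freq))
  else reference_frequencies_from_set(backgrounds[[1L]])
  rc <- .stage("relative_change", relative_change(colMeans(cm), ref))
  .write_tsv(cbind(residue = rownames(rc), rc),
             out("relative_change.tsv"), cfg, "relative_change")
  note("relative_change.tsv", "relative_change")

  enr <- lapply(names(backgrounds), function(nm) {
    e <- .stage(paste0("enrichment:", nm),
                bootstrap_enrichment(query, backgrounds[[nm]],
                                     cfg$enrichment))
    .write_tsv(e, out(sprintf("enrichment_%s.tsv", nm)), cfg,
               paste0("enrichment:", nm),
               sprintf("n_boot: %d | unit: %s", cfg$enrichment$n_boot,
                       cfg$enrichment$sampling_unit))
    note(sprintf("enrichment_%s.tsv", nm), "enrichment")
    e
  })
  names(enr) <- names(backgrounds)

  corr <- .stage("correlation", correlation_analysis(cm))
  .write_tsv(data.frame(residue = rownames(corr$r), round(corr$r, 6),
                        check.names = FALSE),
             out("correlation_r.tsv"), cfg, "correlation")
  .write_tsv(data.frame(residue = rownames(corr$p),
                        signif(corr$p, 6), check.names = FALSE),
             out("correlation_p.tsv"), cfg, "correlation")
  note("correlation_r.tsv", "correlation")

  tree <- .stage("clustering", multiscale_bootstrap_support(cm,
                                                            cfg$clustering))
  writeLines(to_newick(tree), out("tree.nwk"))
  picks <- cut_by_support(tree, min_au = 95)
  memb <- if (length(picks$clusters)) data.frame(
    protein = unlist(picks$clusters),
    cluster = rep(seq_along(picks$clusters), lengths(picks$clusters)),
    au = rep(round(picks$au, 1), lengths(picks$clusters)),
    bp = rep(round(picks$bp, 1), lengths(picks$clusters)),
    stringsAsFactors = FALSE)
  else data.frame(protein = character(), cluster = integer(),
                  au = numeric(), bp = numeric())
  if (length(picks$unassigned))
    memb <- rbind(memb, data.frame(protein = picks$unassigned, cluster = NA,
                                   au = NA, bp = NA))
  .write_tsv(memb, out("clusters.tsv"), cfg, "clustering",
             sprintf("n_boot: %d | distance: %s | min_au: 95",
                     cfg$clustering$n_boot, cfg$clustering$distance))
  note("tree.nwk", "clustering"); note("clusters.tsv", "clustering")

  scans <- lapply(names(cfg$motifs), function(nm) {
    motif <- peptide_to_pwm(cfg$motifs[[nm]], name = nm)
    res <- .stage(paste0("scan:", nm),
                  scan_set(query, motif, p_threshold = cfg$scan_p))
    .write_tsv(res$hits, out(sprintf("scan_%s_hits.tsv", nm)), cfg,
               paste0("scan:", nm), sprintf("p_threshold: %g", cfg$scan_p))
    qp <- classify_by_q(res, cfg$q_thresholds)
    .write_tsv(qp$assignment, out(sprintf("scan_%s_qbins.tsv", nm)), cfg,
               paste0("scan:", nm))
    mh <- multi_hit_proteins(res, 2L)
    mh$positions <- vapply(mh$positions, paste, "", collapse = ",")
    .write_tsv(mh, out(sprintf("scan_%s_multihit.tsv", nm)), cfg,
               paste0("scan:", nm))
    note(sprintf("scan_%s_hits.tsv", nm), "scan")
    list(result = res, q_partition = qp)
  })
  names(scans) <- names(cfg$motifs)

  discovery <- NULL
  if (!is.null(cfg$discovery)) {
    discovery <- .stage("discovery", gibbs_discover(query, cfg$discovery))
    write_meme(discovery$motif, out("discovered_motif.meme"))
    writeLines(paste(format(names(overlay_occurrences(discovery, query)),
                            width = max(nchar(query$ids))),
                     overlay_occurrences(discovery, query)),
               out("discovery_overlay.txt"))
    note("discovered_motif.meme", "discovery")
  }

  pred_motif <- peptide_to_pwm(cfg$motifs[[length(cfg$motifs)]],
                               name = names(cfg$motifs)[length(cfg$motifs)])
  pred <- .stage("prediction",
                 predict_candidates(backgrounds[[1L]], pred_motif,
                                    p_threshold = cfg$predict_p,
                                    top_n = cfg$top_n, exclude = query))
  .write_tsv(pred, out("predicted_candidates.tsv"), cfg, "prediction",
             sprintf("p_threshold: %g | top_n: %d", cfg$predict_p,
                     cfg$top_n))
  note("predicted_candidates.tsv", "prediction")

  manifest <- do.call(rbind, manifest)
  .write_tsv(manifest, out("manifest.tsv"), cfg, "manifest",
             sprintf("global seed: %d", cfg$seed))
  invisible(list(composition = cm, boxplot = bx, relative_change = rc,
                 enrichment = enr, correlation = corr, tree = tree,
                 clusters = picks, scans = scans, discovery = discovery,
                 predictions = pred, manifest = manifest))
}
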