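#' Pipeline configuration
#'
#' Bundles all inputs and tuning parameters of the trans-regulator
#' prediction pipeline. Defaults mirror the standard analysis settings:
#' scan p-value threshold 3.73e-6 (chosen inside the stable odds-ratio
#' plateau), 20 replicate coldspot draws, 50 kb hotspot exclusion distance,
#' candidate filter `O_hc > 1.20` and `p < 0.05`, coverage-graph edge
#' threshold 0.16, and recombination reference terms GO:0006310 (DNA
#' recombination) and GO:0007127 (meiosis I).
#'
#' @param genome Genome: FASTA path, `DNAStringSet`, or named character
#'   vector.
#' @param hotspots Hotspots: BED path or [region_set()].
#' @param motifs Motifs: file path (JASPAR/TRANSFAC/MEME) or named list of
#'   [motif_matrix()] objects.
#' @param dag Optional ontology: OBO path or [go_dag()].
#' @param annotations Optional gene annotations: path (GAF/TSV) or
#'   [annotation_map()].
#' @param go_genes Background gene set `G` for the GO gap analysis; default
#'   the scanned motif names plus every annotated gene (emulating the full
#'   panel of proteins considered).
#' @param reference_terms Recombination-related reference term ids.
#' @param p_threshold,q_max Scan p-value threshold and q-value filter bound.
#' @param count_filter Count a region as "with hit" on the raw p-value
#'   filter (`"p"`, default) or on `q <= q_max` (`"q"`).
#' @param n_replicates Number of coldspot draws to average.
#' @param min_distance Coldspot exclusion distance (bp).
#' @param or_min,p_max Candidate (HG) selection thresholds.
#' @param w_t Coverage-graph edge weight threshold.
#' @param background `"uniform"` (default) or `"sequence"` (0-order model
#'   estimated from the hotspot sequences).
#' @param pseudocount,granularity Scoring-matrix smoothing and p-value DP
#'   bins.
#' @param seed Integer seed covering every random stage.
#' @param out_dir Optional directory: when set, every stage output is
#'   persisted as TSV stamped with the configuration hash.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(genome, hotspots, motifs, dag = NULL,
                            annotations = NULL, go_genes = NULL,
                            reference_terms = c("GO:0006310", "GO:0007127"),
                            p_threshold = 3.73e-6, q_max = 0.05,
                            count_filter = c("p", "q"),
                            n_replicates = 20, min_distance = 50000,
                            or_min = 1.20, p_max = 0.05, w_t = 0.16,
                            background = c("uniform", "sequence"),
                            pseudocount = 0.1, granularity = 1000,
                            seed = 1, out_dir = NULL) {
  if (p_threshold <= 0 || p_threshold > 1) stop_config("invalid p_threshold")
  if (n_replicates < 1) stop_config("n_replicates must be >= 1")
  if (w_t < 0 || w_t > 1) stop_config("invalid w_t")
  structure(list(genome = genome, hotspots = hotspots, motifs = motifs,
                 dag = dag, annotations = annotations, go_genes = go_genes,
                 reference_terms = reference_terms,
                 p_threshold = p_threshold, q_max = q_max,
                 count_filter = match.arg(count_filter),
                 n_replicates = n_replicates, min_distance = min_distance,
                 or_min = or_min, p_max = p_max, w_t = w_t,
                 background = match.arg(background),
                 pseudocount = pseudocount, granularity = granularity,
                 seed = seed, out_dir = out_dir),
            class = "pipeline_config")
}

load_pipeline_inputs <- function(cfg) {
  genome <- genome_as_character(cfg$genome)
  gt <- stats::setNames(nchar(genome), names(genome))
  hotspots <- if (inherits(cfg$hotspots, "region_set")) cfg$hotspots
              else read_bed(cfg$hotspots, genome = gt)
  motifs <- if (is.character(cfg$motifs)) read_motifs(cfg$motifs) else cfg$motifs
  if (!length(motifs)) stop_config("no motifs supplied")
  dag <- if (is.null(cfg$dag) || inherits(cfg$dag, "go_dag")) cfg$dag
         else parse_obo(cfg$dag)
  ann <- if (is.null(cfg$annotations) ||
             inherits(cfg$annotations, "annotation_map")) cfg$annotations
         else read_annotations(cfg$annotations, dag)
  list(genome = genome, genome_table = gt, hotspots = hotspots,
       motifs = motifs, dag = dag, annotations = ann)
}

#' Run the trans-regulator prediction pipeline
#'
#' Executes the full analysis: hotspot sequence extraction, per-motif
#' scanning of hotspots, `n_replicates` independent coldspot draws scanned
#' per motif, replicate-averaged odds-ratio enrichment with Yates
#' chi-square, candidate (HG) selection, GO gap-score ranking (when an
#' ontology is supplied) and meet/min coverage-graph clustering of the
#' candidates. Every random stage runs under the configuration seed, so
#' identical configurations reproduce identical outputs.
#'
#' @param cfg A [pipeline_config()].
#' @return An object of class `transreg_run`: list with `enrichment`,
#'   `hg`, `go_gap`, `reference_similarity`, `coverage_graph`,
#'   `clusters_threshold`, `clusters_hierarchical`, `coverage`,
#'   `hits_hot`, `n_hotspots`, `config`, `log`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  inp <- load_pipeline_inputs(cfg)
  logline <- character(0)
  say <- function(...) {
    msg <- paste0(...)
    logline <<- c(logline, msg)
    message("[hotspotTF] ", msg)
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  with_seed(cfg$seed, {
    hot_seqs <- stage("extract_hotspots",
                      extract_sequences(inp$hotspots, inp$genome))
    N_H <- nrow(inp$hotspots)
    say("hotspots: ", N_H, " regions, mean length ",
        round(mean(region_lengths(inp$hotspots)), 2), " bp")
    bg <- if (cfg$background == "uniform") rep(0.25, 4)
          else background_from_sequences(hot_seqs)
    sms <- lapply(inp$motifs, make_scoring_matrix, background = bg,
                  pseudocount = cfg$pseudocount)
    hits_hot <- list()
    hot_counts <- numeric(0)
    for (nm in names(sms)) {
      h <- stage("scan_hotspots",
                 scan_regions(sms[[nm]], hot_seqs, cfg$p_threshold,
                              granularity = cfg$granularity))
      h <- attach_qvalues(h, n_scanned_positions(hot_seqs, sms[[nm]]$width))
      if (cfg$count_filter == "q") h <- h[h$q_value <= cfg$q_max, , drop = FALSE]
      hits_hot[[nm]] <- h
      hot_counts[nm] <- count_region_hits(h, inp$hotspots)$regions_with_hit
      say("scan ", nm, ": ", nrow(h), " hotspot hits in ", hot_counts[nm],
          " regions")
    }
    cold_counts <- stats::setNames(
      rep(list(numeric(0)), length(sms)), names(sms))
    N_C <- N_H
    for (r in seq_len(cfg$n_replicates)) {
      cs <- stage("sample_coldspots",
                  sample_coldspots(inp$hotspots, inp$genome_table,
                                   min_distance = cfg$min_distance,
                                   genome_seq = inp$genome))
      cold_seqs <- extract_sequences(cs, inp$genome)
      for (nm in names(sms)) {
        minp <- region_min_pvalues(sms[[nm]], cold_seqs,
                                   granularity = cfg$granularity)
        cold_counts[[nm]] <- c(cold_counts[[nm]],
                               sum(minp <= cfg$p_threshold))
      }
      say("coldspot replicate ", r, " scanned")
    }
    enr <- stage("enrichment",
                 enrich_motifs(hot_counts, cold_counts, N_H, N_C))
    hg <- select_candidates(enr, or_min = cfg$or_min, p_max = cfg$p_max)
    say("HG candidates: ", paste(hg, collapse = ", "))

    go_gap <- NULL; refsim <- NULL
    if (!is.null(inp$dag) && !is.null(inp$annotations) && length(hg)) {
      g_all <- cfg$go_genes %||% union(names(sms), names(inp$annotations))
      go_gap <- stage("go_gap",
                      rank_terms_by_gap(inp$dag, hg, g_all, inp$annotations))
      refs <- intersect(cfg$reference_terms, inp$dag$terms$id)
      hg_ann <- intersect(hg, names(inp$annotations))
      if (length(refs) && length(hg_ann)) {
        refsim <- data.frame(
          gene = hg_ann,
          similarity = vapply(hg_ann, function(g)
            gene_to_reference_terms(inp$dag, g, refs, inp$annotations),
            numeric(1)), stringsAsFactors = FALSE)
        refsim <- refsim[order(-refsim$similarity), ]
        rownames(refsim) <- NULL
      }
      say("GO gap ranking over ", nrow(go_gap), " terms")
    }

    cg <- NULL; cl_thr <- NULL; cl_hier <- NULL; cov_sum <- NULL
    cov_genes <- hg[vapply(hg, function(g)
      nrow(hits_hot[[g]]) > 0, logical(1))]
    if (length(cov_genes)) {
      cov <- coverage_map(do.call(rbind, hits_hot[cov_genes]))
      cg <- stage("coverage_graph", build_coverage_graph(cov))
      cl_thr <- threshold_clusters(cg, cfg$w_t)
      cl_hier <- hierarchical_clusters(cg, k = length(cl_thr))
      cov_sum <- coverage_summary(cl_thr, cov, n_hotspots = N_H)
      say("coverage graph: ", length(cov_genes), " genes, ",
          length(cl_thr), " threshold clusters")
    }

    out <- structure(list(enrichment = enr, hg = hg, go_gap = go_gap,
                          reference_similarity = refsim,
                          coverage_graph = cg,
                          clusters_threshold = cl_thr,
                          clusters_hierarchical = cl_hier,
                          coverage = cov_sum,
                          hits_hot = hits_hot, n_hotspots = N_H,
                          config = cfg, log = logline),
                     class = "transreg_run")
    if (!is.null(cfg$out_dir)) persist_run(out, cfg$out_dir)
    out
  })
}

# Persist all stage outputs as TSV, stamped with the config hash.
persist_run <- function(run, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  stamp <- paste0("config_hash=", config_hash(run$config[
    setdiff(names(run$config), "out_dir")]))
  write_tsv(as.data.frame(run$enrichment),
            file.path(out_dir, "enrichment.tsv"), stamp)
  writeLines(run$hg, file.path(out_dir, "hg_genes.txt"))
  if (!is.null(run$go_gap))
    write_tsv(run$go_gap, file.path(out_dir, "go_gaps.tsv"), stamp)
  if (!is.null(run$clusters_threshold)) {
    cl <- run$clusters_threshold
    write_tsv(data.frame(gene = unlist(cl),
                         cluster = rep(seq_along(cl), lengths(cl))),
              file.path(out_dir, "clusters.tsv"), stamp)
    cs <- run$coverage
    write_tsv(data.frame(cluster = seq_along(cs$cluster_union),
                         n_genes = cs$cluster_sizes,
                         hotspots_covered = cs$cluster_union),
              file.path(out_dir, "coverage_summary.tsv"),
              c(stamp, paste0("overall_union=", cs$overall_union),
                paste0("uncovered=", cs$uncovered)))
  }
  hits <- do.call(rbind, run$hits_hot)
  write_tsv(as.data.frame(hits), file.path(out_dir, "hits_hotspots.tsv"), stamp)
  writeLines(run$log, file.path(out_dir, "run.log"))
  invisible(out_dir)
}

#' @export
print.transreg_run <- function(x, ...) {
  cat("<transreg_run>\n")
  cat("  hotspots:", x$n_hotspots, "\n")
  cat("  motifs scanned:", nrow(x$enrichment), "\n")
  cat("  HG candidates:", if (length(x$hg)) paste(x$hg, collapse = ", ")
      else "(none)", "\n")
  if (!is.null(x$clusters_threshold))
    cat("  coverage clusters:", length(x$clusters_threshold),
        "(threshold), hotspots covered:", x$coverage$overall_union, "\n")
  invisible(x)
}

#' @export
summary.transreg_run <- function(object, ...) {
  cat("Enrichment (odds ratio, Yates chi-square):\n")
  print(object$enrichment)
  if (!is.null(object$go_gap)) {
    cat("\nTop GO terms by gap score:\n")
    print(utils::head(object$go_gap, 10))
  }
  if (!is.null(object$clusters_threshold)) {
    cat("\nCoverage clusters (threshold ", object$config$w_t, "):\n", sep = "")
    for (i in seq_along(object$clusters_threshold))
      cat("  ", i, ": ", paste(object$clusters_threshold[[i]],
                               collapse = ", "), "\n", sep = "")
    cat("Hotspots covered by any cluster:", object$coverage$overall_union,
        "of", object$n_hotspots, "\n")
  }
  invisible(object)
}

#' Odds-ratio stability across scan p-value thresholds
#'
#' Re-computes the per-motif enrichment across a grid of scan thresholds,
#' reusing one pass of window scoring per sequence set (only the per-region
#' minimum p-values are needed), with the same replicate coldspot draws as
#' [run_pipeline()] under the same seed.
#'
#' @param cfg A [pipeline_config()].
#' @param thresholds Increasing vector of p-value thresholds in `(0, 1]`.
#' @return data.frame of class `transreg_sweep` with columns `threshold`,
#'   `gene`, `HM`, `CM`, `O_hc`.
#' @export
sweep_thresholds <- function(cfg, thresholds) {
  stopifnot(inherits(cfg, "pipeline_config"))
  if (!length(thresholds)) stop_config("empty threshold list")
  if (any(thresholds <= 0 | thresholds > 1))
    stop_config("thresholds must lie in (0, 1]")
  thresholds <- sort(thresholds)
  inp <- load_pipeline_inputs(cfg)
  with_seed(cfg$seed, {
    hot_seqs <- extract_sequences(inp$hotspots, inp$genome)
    N_H <- nrow(inp$hotspots); N_C <- N_H
    bg <- if (cfg$background == "uniform") rep(0.25, 4)
          else background_from_sequences(hot_seqs)
    sms <- lapply(inp$motifs, make_scoring_matrix, background = bg,
                  pseudocount = cfg$pseudocount)
    minp_hot <- lapply(sms, region_min_pvalues, sequences = hot_seqs,
                       granularity = cfg$granularity)
    minp_cold <- lapply(seq_len(cfg$n_replicates), function(r) {
      cs <- sample_coldspots(inp$hotspots, inp$genome_table,
                             min_distance = cfg$min_distance,
                             genome_seq = inp$genome)
      cold_seqs <- extract_sequences(cs, inp$genome)
      lapply(sms, region_min_pvalues, sequences = cold_seqs,
             granularity = cfg$granularity)
    })
    rows <- list()
    for (th in thresholds) {
      for (nm in names(sms)) {
        HM <- sum(minp_hot[[nm]] <= th)
        CM <- mean(vapply(minp_cold, function(rep)
          sum(rep[[nm]] <= th), numeric(1)))
        tab <- contingency_table(HM, N_H - HM, CM, N_C - CM)
        rows[[length(rows) + 1L]] <- data.frame(
          threshold = th, gene = nm, HM = HM, CM = CM,
          O_hc = as.numeric(odds_ratio(tab)), stringsAsFactors = FALSE)
      }
    }
    out <- do.call(rbind, rows)
    class(out) <- c("transreg_sweep", "data.frame")
    out
  })
}

#' Plot odds-ratio stability across thresholds
#' @param x A [sweep_thresholds()] table.
#' @param ... Passed to [graphics::matplot()].
#' @return `x`, invisibly.
#' @export
plot.transreg_sweep <- function(x, ...) {
  genes <- unique(x$gene)
  th <- sort(unique(x$threshold))
  m <- sapply(genes, function(g)
    x$O_hc[x$gene == g][order(x$threshold[x$gene == g])])
  graphics::matplot(th, m, type = "b", log = "x", pch = seq_along(genes),
                    xlab = "scan p-value threshold",
                    ylab = expression(O[hc]), ...)
  graphics::legend("topright", legend = genes, pch = seq_along(genes),
                   col = seq_along(genes), bty = "n")
  invisible(x)
}

#' Assemble the paper-like synthetic benchmark world
#'
#' Generates the complete synthetic study under one seed: genome and
#' hotspots per the configuration, every configured motif planted
#' (hotspots at `p_hot`, coldspot-eligible background at `p_cold`), and the
#' toy GO world with the enriched motifs (those with `p_hot > p_cold`) as
#' the marked gene set. The returned pieces plug directly into
#' [pipeline_config()].
#'
#' @param cfg A [synth_config()].
#' @return List with `genome`, `genome_table`, `hotspots`, `motifs` (named
#'   list of [motif_matrix()], degeneracy 0.1), `dag`, `annotations`,
#'   `go_genes`, `truth` (per-motif planted copies, marked terms, enriched
#'   motif names).
#' @export
synthetic_world <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  gen <- generate_genome_and_hotspots(cfg)
  genome <- gen$genome
  truth <- list(seed = cfg$seed, planted = list())
  with_seed(cfg$seed + 1L, {
    for (m in cfg$motifs) {
      pl <- plant_motifs(genome, gen$hotspots, m,
                         min_distance = cfg$min_distance)
      genome <- pl$genome
      truth$planted[[m$name]] <- pl$truth
    }
  })
  enriched <- vapply(cfg$motifs, function(m) m$p_hot > m$p_cold, logical(1))
  all_names <- vapply(cfg$motifs, `[[`, character(1), "name")
  hg_true <- all_names[enriched]
  world <- generate_go_world(cfg$go, hg_true,
                             extra_background_genes = all_names[!enriched])
  motifs <- stats::setNames(
    lapply(cfg$motifs, function(m)
      consensus_motif(m$name, m$consensus, degeneracy = 0.1)),
    vapply(cfg$motifs, `[[`, character(1), "name"))
  truth$enriched_motifs <- hg_true
  truth$marked_terms <- world$marked_terms
  list(genome = genome, genome_table = gen$genome_table,
       hotspots = gen$hotspots, motifs = motifs, dag = world$dag,
       annotations = world$annotations, go_genes = world$all_genes,
       truth = truth)
}
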