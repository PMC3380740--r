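#' Configuration for the synthetic benchmark world
#'
#' Describes a fully self-contained synthetic dataset: uniform-composition
#' chromosomes, hotspot intervals, motifs planted at different per-region
#' rates in hotspots versus background, and a toy GO world in which a marked
#' term family is enriched among the planted (high odds ratio) genes.
#'
#' Hotspots are laid out so that any two are at least `2 * min_distance`
#' apart, guaranteeing that valid coldspots exist.
#'
#' @param n_chromosomes,chrom_length Number and length (bp) of chromosomes.
#' @param n_hotspots Total hotspots, distributed round-robin over
#'   chromosomes.
#' @param hotspot_length Fixed length, or `c(min, max)` for uniform lengths.
#'   Default 3414 bp, the scale of experimentally mapped mouse hotspots.
#' @param min_distance Hotspot/coldspot exclusion distance (bp).
#' @param motifs List of motif specs: each a list with `name`, `consensus`,
#'   `p_hot` (per-hotspot planting probability) and `p_cold` (per-background-
#'   window planting probability), `p_cold <= p_hot` for enriched motifs.
#' @param go List: `depth`, `branching` of the balanced is_a tree,
#'   `n_background_genes`, `terms_per_gene`.
#' @param seed Integer seed; all generators are pure functions of
#'   (config, seed).
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_chromosomes = 4, chrom_length = 6e6,
                         n_hotspots = 200, hotspot_length = 3414,
                         min_distance = 50000,
                         motifs = default_motif_specs(),
                         go = list(depth = 3, branching = 3,
                                   n_background_genes = 40,
                                   terms_per_gene = 3),
                         seed = 1) {
  max_len <- max(hotspot_length)
  n_per_chr <- ceiling(n_hotspots / n_chromosomes)
  slot <- floor(chrom_length / n_per_chr)
  if (slot < max_len + 2 * min_distance)
    stop_config("infeasible placement: need chrom_length/n_per_chr >= ",
                "hotspot_length + 2*min_distance")
  for (m in motifs) {
    if (m$p_cold > m$p_hot + 1e-12)
      stop_config("motif ", m$name, ": p_cold must be <= p_hot")
    if (m$p_hot > 1 || m$p_cold < 0)
      stop_config("motif ", m$name, ": rates must lie in [0, 1]")
  }
  structure(list(n_chromosomes = n_chromosomes, chrom_length = chrom_length,
                 n_hotspots = n_hotspots, hotspot_length = hotspot_length,
                 min_distance = min_distance, motifs = motifs, go = go,
                 seed = seed),
            class = "synth_config")
}

#' Default planted-motif specifications
#'
#' Three enriched motifs and one null motif. The planting rates are chosen
#' for the scaled-down problem sizes used throughout: with a few hundred
#' regions the per-region rate contrast must be larger than the subtle
#' genome-scale enrichment seen on ~10^4 real hotspots for the chi-square
#' filter to retain power.
#'
#' @return List of motif specs (see [synth_config()]).
#' @export
default_motif_specs <- function() {
  list(
    list(name = "TFA1", consensus = "ACGGTAAGCGTTC", p_hot = 0.45, p_cold = 0.18),
    list(name = "TFB2", consensus = "TTGACCGGATCAT", p_hot = 0.35, p_cold = 0.15),
    list(name = "TFC3", consensus = "GCATTCGAAGGTC", p_hot = 0.30, p_cold = 0.10),
    list(name = "NULLX", consensus = "CATGGCTAATCGA", p_hot = 0.15, p_cold = 0.15))
}

#' Generate a synthetic genome with hotspot intervals
#'
#' Chromosome sequences are i.i.d. uniform ACGT. Each chromosome is divided
#' into equal slots, one hotspot per slot at a uniform offset, which
#' guarantees pairwise hotspot gaps of at least `2 * min_distance`.
#'
#' @param cfg A [synth_config()].
#' @return List with `genome` (named character vector), `hotspots`
#'   (a [region_set()]), `genome_table` (named lengths) and `truth`
#'   (placement record).
#' @export
generate_genome_and_hotspots <- function(cfg) {
  with_seed(cfg$seed, {
    chroms <- sprintf("chr%d", seq_len(cfg$n_chromosomes))
    base_codes <- utf8ToInt("ACGT")
    genome <- vapply(chroms, function(ch)
      intToUtf8(base_codes[sample.int(4L, cfg$chrom_length, replace = TRUE)]),
      character(1))
    counts <- diff(floor(seq(0, cfg$n_hotspots, length.out = cfg$n_chromosomes + 1)))
    ch_v <- character(0); st_v <- numeric(0); en_v <- numeric(0)
    for (ci in seq_along(chroms)) {
      n <- counts[ci]
      if (!n) next
      slot <- floor(cfg$chrom_length / n)
      lens <- if (length(cfg$hotspot_length) == 2)
        sample(cfg$hotspot_length[1]:cfg$hotspot_length[2], n, replace = TRUE)
      else rep(cfg$hotspot_length, n)
      play <- slot - lens - 2 * cfg$min_distance
      if (any(play < 0)) stop_config("infeasible placement on ", chroms[ci])
      off <- floor(stats::runif(n) * (play + 1))
      st <- (seq_len(n) - 1) * slot + off
      ch_v <- c(ch_v, rep(chroms[ci], n))
      st_v <- c(st_v, st); en_v <- c(en_v, st + lens)
    }
    gt <- stats::setNames(rep(cfg$chrom_length, length(chroms)), chroms)
    hs <- region_set(ch_v, st_v, en_v,
                     id = sprintf("hs%04d", seq_along(ch_v)),
                     role = "hotspot", genome = gt)
    list(genome = genome, hotspots = hs, genome_table = gt,
         truth = list(seed = cfg$seed, n_hotspots = nrow(hs)))
  })
}

#' Plant exact consensus copies into region sequences
#'
#' Each sequence independently receives one exact consensus copy with the
#' given probability, at a uniform offset and strand (the reverse strand
#' plants the reverse complement).
#'
#' @param sequences Named character vector of region sequences.
#' @param consensus Consensus string over ACGT.
#' @param prob Per-region planting probability.
#' @param seed Integer seed.
#' @return List with `sequences` (modified) and `truth` (data.frame
#'   `region_id`, `offset`, `strand`; one row per planted copy).
#' @export
plant_in_sequences <- function(sequences, consensus, prob, seed = NULL) {
  consensus <- toupper(consensus)
  w <- nchar(consensus)
  rc <- revcomp_string(consensus)
  with_seed(seed, {
    lens <- nchar(sequences)
    if (any(lens < w)) stop_config("motif longer than a region")
    take <- stats::runif(length(sequences)) < prob
    offs <- floor(stats::runif(length(sequences)) * (lens - w + 1))
    strands <- ifelse(stats::runif(length(sequences)) < 0.5, "+", "-")
    for (i in which(take)) {
      substr(sequences[i], offs[i] + 1, offs[i] + w) <-
        if (strands[i] == "+") consensus else rc
    }
    list(sequences = sequences,
         truth = data.frame(region_id = names(sequences)[take],
                            offset = offs[take], strand = strands[take],
                            stringsAsFactors = FALSE))
  })
}

revcomp_string <- function(x)
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))

# Coldspot-eligible zones: complement of hotspots padded by min_distance.
eligible_zones <- function(genome_table, hotspots, min_distance) {
  out <- list()
  for (ch in names(genome_table)) {
    hs <- hotspots[hotspots$chrom == ch, , drop = FALSE]
    L <- genome_table[[ch]]
    if (!nrow(hs)) { out[[ch]] <- cbind(0, L); next }
    o <- order(hs$start)
    lo <- pmax(hs$start[o] - min_distance, 0)
    hi <- pmin(hs$end[o] + min_distance, L)
    starts <- c(0, hi)
    ends <- c(lo, L)
    keep <- ends > starts
    out[[ch]] <- cbind(starts[keep], ends[keep])
  }
  out
}

#' Plant motifs into a synthetic genome
#'
#' Hotspots: each hotspot independently receives one exact consensus copy
#' with probability `p_hot`, at a uniform offset and strand. Background:
#' copies are dropped as a Poisson process over the coldspot-eligible zones
#' (at least `min_distance` from every hotspot) with per-bp density
#' `-log(1 - p_cold) / (L - w + 1)`, so that a uniformly placed coldspot of
#' length `L` contains at least one full copy with probability `p_cold`.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param hotspots Hotspot [region_set()].
#' @param motif_spec One motif spec (see [synth_config()]).
#' @param min_distance Exclusion distance used for the background zones.
#' @param window_length Reference coldspot length `L` for the background
#'   rate (default: mean hotspot length).
#' @param seed Integer seed.
#' @return List with `genome` (modified) and `truth` (data.frame
#'   `where` ("hotspot"/"background"), `chrom`, `start`, `strand`).
#' @export
plant_motifs <- function(genome, hotspots, motif_spec, min_distance = 50000,
                         window_length = NULL, seed = NULL) {
  consensus <- toupper(motif_spec$consensus)
  w <- nchar(consensus)
  rc <- revcomp_string(consensus)
  gt <- stats::setNames(nchar(genome), names(genome))
  if (is.null(window_length)) window_length <- mean(region_lengths(hotspots))
  raw_fwd <- charToRaw(consensus)
  raw_rev <- charToRaw(rc)
  with_seed(seed, {
    raws <- lapply(genome, charToRaw)   # avoid copying chromosomes per plant
    rows <- list()
    # hotspot planting
    take <- stats::runif(nrow(hotspots)) < motif_spec$p_hot
    for (i in which(take)) {
      len <- hotspots$end[i] - hotspots$start[i]
      off <- hotspots$start[i] + floor(stats::runif(1) * (len - w + 1))
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      raws[[hotspots$chrom[i]]][(off + 1):(off + w)] <-
        if (strand == "+") raw_fwd else raw_rev
      rows[[length(rows) + 1L]] <- data.frame(
        where = "hotspot", chrom = hotspots$chrom[i], start = off,
        strand = strand, stringsAsFactors = FALSE)
    }
    # background planting (Poisson over eligible zones, copies fully inside)
    if (motif_spec$p_cold > 0) {
      dens <- -log(1 - motif_spec$p_cold) / (window_length - w + 1)
      zones <- eligible_zones(gt, hotspots, min_distance)
      for (ch in names(zones)) {
        z <- zones[[ch]]
        widths <- pmax(z[, 2] - z[, 1] - w, 0)
        total <- sum(widths)
        if (total <= 0) next
        n <- stats::rpois(1, dens * total)
        if (!n) next
        pos <- sort(floor(stats::runif(n) * total))
        cum <- cumsum(widths)
        zi <- findInterval(pos, c(0, cum), rightmost.closed = TRUE)
        starts <- z[zi, 1] + pos - c(0, cum)[zi]
        for (s in starts) {
          strand <- if (stats::runif(1) < 0.5) "+" else "-"
          raws[[ch]][(s + 1):(s + w)] <- if (strand == "+") raw_fwd else raw_rev
          rows[[length(rows) + 1L]] <- data.frame(
            where = "background", chrom = ch, start = s, strand = strand,
            stringsAsFactors = FALSE)
        }
      }
    }
    truth <- if (length(rows)) do.call(rbind, rows) else
      data.frame(where = character(), chrom = character(),
                 start = numeric(), strand = character())
    genome <- vapply(raws, rawToChar, character(1))
    list(genome = genome, truth = truth)
  })
}

#' Generate a toy GO world with a marked enriched subtree
#'
#' Builds a balanced `is_a` tree (one biological_process root, `branching`
#' children per internal node, `depth` levels below the root) and an
#' annotation set in which the designated high-odds-ratio genes are
#' annotated exclusively inside a marked depth-1 subtree while background
#' genes are annotated uniformly (round-robin, hence deterministic) across
#' all leaves. By construction the marked terms are then enriched among the
#' HG genes.
#'
#' @param go GO spec list (`depth`, `branching`, `n_background_genes`,
#'   `terms_per_gene`), see [synth_config()].
#' @param hg_genes Character vector of genes to enrich (e.g. planted motif
#'   names).
#' @param extra_background_genes Additional named genes (e.g. non-enriched
#'   motifs) annotated like the anonymous background genes.
#' @param enrich If `FALSE`, HG genes are annotated like background genes
#'   (null world: all gaps ~ 0).
#' @return List with `dag` (a [go_dag()]), `annotations` (an
#'   [annotation_map()]), `marked_terms`, `background_genes`, `all_genes`.
#' @export
generate_go_world <- function(go, hg_genes,
                              extra_background_genes = character(),
                              enrich = TRUE) {
  d <- go$depth; b <- go$branching
  if (d < 2 || b < 2) stop_config("GO spec needs depth >= 2 and branching >= 2")
  n_terms <- sum(b^(0:d))
  ids <- sprintf("GO:%07d", 9000000 + seq_len(n_terms))
  level <- integer(n_terms)
  parent <- rep(NA_integer_, n_terms)
  nxt <- 2L
  queue <- 1L
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    if (level[v] < d) {
      kids <- nxt:(nxt + b - 1L)
      parent[kids] <- v
      level[kids] <- level[v] + 1L
      nxt <- nxt + b
      queue <- c(queue, kids)
    }
  }
  terms <- data.frame(id = ids,
                      name = c("root", sprintf("term_%d", seq_len(n_terms - 1))),
                      namespace = "biological_process",
                      stringsAsFactors = FALSE)
  edges <- data.frame(child = ids[!is.na(parent)],
                      parent = ids[parent[!is.na(parent)]],
                      type = "is_a", stringsAsFactors = FALSE)
  dag <- go_dag(terms, edges)
  # marked subtree: first depth-1 child and all its descendants
  marked_root <- which(level == 1L)[1]
  in_marked <- rep(FALSE, n_terms)
  in_marked[marked_root] <- TRUE
  for (v in seq_len(n_terms)[-1]) if (in_marked[parent[v]]) in_marked[v] <- TRUE
  leaves <- which(level == d)
  marked_leaves <- ids[intersect(leaves, which(in_marked))]
  all_leaves <- ids[leaves]
  k <- go$terms_per_gene
  round_robin <- function(pool, n_genes) {
    idx <- (outer(seq_len(k), (seq_len(n_genes) - 1) * k, "+") - 1) %%
      length(pool) + 1
    lapply(seq_len(n_genes), function(j) unique(pool[idx[, j]]))
  }
  # null mode spreads each HG gene's terms evenly across the whole leaf set
  # (stride L/k), so no subtree is over-represented among the HG genes
  strided <- function(pool, n_genes) {
    L <- length(pool)
    stride <- max(1L, floor(L / k))
    lapply(seq_len(n_genes), function(j)
      unique(pool[((seq_len(k) - 1L) * stride + (j - 1L)) %% L + 1L]))
  }
  bg_genes <- c(extra_background_genes,
                sprintf("gene%03d", seq_len(go$n_background_genes)))
  hg_ann <- if (enrich) round_robin(marked_leaves, length(hg_genes))
            else strided(all_leaves, length(hg_genes))
  ann <- c(stats::setNames(hg_ann, hg_genes),
           stats::setNames(round_robin(all_leaves, length(bg_genes)), bg_genes))
  list(dag = dag, annotations = annotation_map(ann, dag),
       marked_terms = ids[in_marked], background_genes = bg_genes,
       all_genes = c(hg_genes, bg_genes))
}

#' Write a GO DAG as an OBO 1.2 file
#' @param dag A [go_dag()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_obo <- function(dag, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("format-version: 1.2", ""), con)
  for (i in seq_len(nrow(dag$terms))) {
    id <- dag$terms$id[i]
    e <- dag$edges[dag$edges$child == id, , drop = FALSE]
    writeLines(c("[Term]",
                 paste0("id: ", id),
                 paste0("name: ", dag$terms$name[i]),
                 paste0("namespace: ", dag$terms$namespace[i]),
                 if (nrow(e)) ifelse(e$type == "is_a",
                                     paste0("is_a: ", e$parent),
                                     paste0("relationship: part_of ", e$parent)),
                 ""), con)
  }
  invisible(path)
}

#' Write an annotation map as two-column TSV
#' @param ann An [annotation_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  df <- data.frame(gene = rep(names(ann), lengths(ann)),
                   term = unlist(ann, use.names = FALSE))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
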