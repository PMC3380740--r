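# Shared fixtures, built in code at test time.

# 3-term toy ontology: root R with is_a children A and B.
toy_dag <- function() {
  go_dag(data.frame(id = c("R", "A", "B"), name = c("root", "a", "b"),
                    namespace = "biological_process",
                    stringsAsFactors = FALSE),
         data.frame(child = c("A", "B"), parent = c("R", "R"),
                    type = "is_a", stringsAsFactors = FALSE))
}

# Adds a part_of child C under A.
toy_dag_partof <- function() {
  go_dag(data.frame(id = c("R", "A", "B", "C"),
                    name = c("root", "a", "b", "c"),
                    namespace = "biological_process",
                    stringsAsFactors = FALSE),
         data.frame(child = c("A", "B", "C"), parent = c("R", "R", "A"),
                    type = c("is_a", "is_a", "part_of"),
                    stringsAsFactors = FALSE))
}

# Printed enrichment counts shipped with the package.
published_counts <- function() {
  utils::read.table(system.file("extdata", "published_enrichment_counts.tsv",
                                package = "hotspotTF"),
                    header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

# Random uppercase DNA sequences, generated in bulk.
random_dna <- function(n, len, seed = NULL) {
  gen <- function() {
    big <- intToUtf8(utf8ToInt("ACGT")[sample.int(4L, n * len, replace = TRUE)])
    stats::setNames(substring(big, (seq_len(n) - 1) * len + 1,
                              seq_len(n) * len),
                    sprintf("r%05d", seq_len(n)))
  }
  if (is.null(seed)) gen() else withr_seed(seed, gen())
}

# Minimal seed sandbox (keeps the ambient RNG stream untouched).
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Exhaustive-enumeration oracle for score p-values: all 4^w words.
enum_pvalue_oracle <- function(llr, background) {
  w <- nrow(llr)
  words <- as.matrix(expand.grid(rep(list(1:4), w)))
  scores <- apply(words, 1, function(wd) sum(llr[cbind(seq_len(w), wd)]))
  probs <- apply(words, 1, function(wd) prod(background[wd]))
  function(s) sum(probs[scores >= s])
}

# Brute-force connected components by breadth-first reachability.
bfs_components <- function(adj) {
  n <- nrow(adj)
  seen <- rep(FALSE, n)
  comps <- list()
  for (v in seq_len(n)) {
    if (seen[v]) next
    frontier <- v; comp <- integer(0)
    while (length(frontier)) {
      comp <- c(comp, frontier)
      seen[frontier] <- TRUE
      frontier <- setdiff(which(rowSums(adj[, frontier, drop = FALSE] > 0) > 0),
                          which(seen))
    }
    comps[[length(comps) + 1L]] <- sort(rownames(adj)[comp])
  }
  comps
}

# A 13-gene coverage map whose meet/min graph has one 10-gene cluster (all
# pairs sharing a 30-hotspot core, weights 0.3) and three near-isolated
# genes (weights 0.1 to the core, 0.1 among themselves).
constructed_cluster_world <- function() {
  core <- sprintf("hs%03d", 1:30)
  shared_low <- sprintf("hs%03d", 27:30)   # 4 core hotspots the outliers touch
  cov <- list()
  for (i in 1:10)
    cov[[paste0("g", sprintf("%02d", i))]] <-
      c(core, sprintf("p%02d_%03d", i, 1:70))
  for (i in 1:3)
    cov[[paste0("s", i)]] <- c(shared_low, sprintf("q%d_%03d", i, 1:36))
  coverage_map(cov)
}

# Small synthetic world + pipeline run, shared across pipeline tests.
tiny_world <- local({
  cache <- new.env(parent = emptyenv())
  function() {
    if (is.null(cache$world)) {
      cfg <- synth_config(n_chromosomes = 2, chrom_length = 2e6,
                          n_hotspots = 100, hotspot_length = 1000,
                          min_distance = 15000, seed = 404)
      cache$cfg <- cfg
      cache$world <- synthetic_world(cfg)
    }
    list(cfg = cache$cfg, world = cache$world)
  }
})
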