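#' Parse a Gene Ontology OBO file
#'
#' Reads OBO 1.2 `[Term]` stanzas into a directed acyclic graph. `is_a:`
#' lines and `relationship: part_of` lines become typed child-to-parent
#' edges; obsolete terms are skipped. Edges pointing at terms absent from
#' the file are dropped.
#'
#' @param path OBO file path.
#' @return An object of class `go_dag`: list with `terms` (data.frame `id`,
#'   `name`, `namespace`), `edges` (data.frame `child`, `parent`, `type`),
#'   `roots` (character vector of terms with no parents) and `parents`
#'   (adjacency list used internally).
#' @export
parse_obo <- function(path) {
  lines <- readLines(path)
  starts <- grep("^\\[", lines)
  term_starts <- which(lines == "[Term]")
  ids <- character(0); nms <- character(0); nss <- character(0)
  ech <- character(0); epa <- character(0); ety <- character(0)
  bounds <- c(starts, length(lines) + 1L)
  for (s in term_starts) {
    e <- bounds[which(bounds == s) + 1L] - 1L
    block <- lines[(s + 1L):e]
    if (any(grepl("^is_obsolete: *true", block))) next
    id <- sub("^id: *", "", grep("^id:", block, value = TRUE)[1])
    nm <- sub("^name: *", "", grep("^name:", block, value = TRUE)[1])
    ns <- sub("^namespace: *", "", grep("^namespace:", block, value = TRUE)[1])
    if (is.na(id)) next
    ids <- c(ids, id); nms <- c(nms, nm %||% NA_character_)
    nss <- c(nss, if (length(ns) && !is.na(ns)) ns else "biological_process")
    isa <- sub(" *!.*$", "", sub("^is_a: *", "", grep("^is_a:", block, value = TRUE)))
    po <- sub(" *!.*$", "",
              sub("^relationship: *part_of *", "",
                  grep("^relationship: *part_of ", block, value = TRUE)))
    isa <- trimws(isa); po <- trimws(po)
    ech <- c(ech, rep(id, length(isa) + length(po)))
    epa <- c(epa, isa, po)
    ety <- c(ety, rep(c("is_a", "part_of"), c(length(isa), length(po))))
  }
  go_dag(data.frame(id = ids, name = nms, namespace = nss,
                    stringsAsFactors = FALSE),
         data.frame(child = ech, parent = epa, type = ety,
                    stringsAsFactors = FALSE))
}

#' Construct a GO DAG from term and edge tables
#'
#' @param terms data.frame with columns `id`, `name`, `namespace`.
#' @param edges data.frame with columns `child`, `parent`, `type`
#'   (`"is_a"` or `"part_of"`). Edges referencing unknown terms are dropped.
#' @return A `go_dag` (see [parse_obo()]). Errors if the graph is cyclic.
#' @export
go_dag <- function(terms, edges) {
  if (anyDuplicated(terms$id)) stop_config("duplicate term ids")
  keep <- edges$child %in% terms$id & edges$parent %in% terms$id
  edges <- edges[keep, , drop = FALSE]
  parents <- split(seq_len(nrow(edges)), edges$child)
  dag <- structure(list(terms = terms, edges = edges,
                        roots = setdiff(terms$id, edges$child),
                        parents = parents),
                   class = "go_dag")
  assert_acyclic(dag)
  dag
}

# DFS with colouring along child -> parent edges: error on cycles.
assert_acyclic <- function(dag) {
  state <- new.env(parent = emptyenv())
  adj <- split(dag$edges$parent, dag$edges$child)
  visit <- function(v) {
    st <- state[[v]] %||% 0L
    if (st == 1L) stop_config("cyclic ontology at term ", v)
    if (st == 2L) return(invisible())
    state[[v]] <- 1L
    for (p in adj[[v]] %||% character(0)) visit(p)
    state[[v]] <- 2L
    invisible()
  }
  for (v in dag$terms$id) visit(v)
  invisible(dag)
}

#' @export
print.go_dag <- function(x, ...) {
  cat(sprintf("<go_dag> %d terms, %d edges, namespaces: %s\n",
              nrow(x$terms), nrow(x$edges),
              paste(unique(x$terms$namespace), collapse = ", ")))
  invisible(x)
}

term_namespace <- function(dag, t) {
  i <- match(t, dag$terms$id)
  if (anyNA(i)) stop_config("unknown term id: ", t[which(is.na(i))[1]])
  dag$terms$namespace[i]
}

#' Wang S-values of a term's ancestor closure
#'
#' The semantic contribution of each ancestor `a` to term `t`:
#' `S_t(t) = 1` and `S_t(a) = max over children c of a on paths to t of
#' w_edge * S_t(c)`, with edge weights by relationship type.
#'
#' @param dag A [go_dag()].
#' @param t Term id.
#' @param w_isa,w_partof Edge weights for `is_a` / `part_of` (defaults 0.8 /
#'   0.6).
#' @return Named numeric vector of S-values over the closure (including `t`).
#' @export
term_svalues <- function(dag, t, w_isa = 0.8, w_partof = 0.6) {
  if (!t %in% dag$terms$id) stop_config("unknown term id: ", t)
  wts <- c(is_a = w_isa, part_of = w_partof)
  sv <- stats::setNames(1, t)
  frontier <- t
  # relax child->parent edges breadth-first until values stabilise; weights
  # < 1 so the max can only be improved a bounded number of times
  while (length(frontier)) {
    nxt <- character(0)
    for (v in frontier) {
      eidx <- dag$parents[[v]]
      if (is.null(eidx)) next
      for (j in eidx) {
        p <- dag$edges$parent[j]
        cand <- wts[[dag$edges$type[j]]] * sv[[v]]
        if (is.na(sv[p]) || cand > sv[[p]] + 1e-15) {
          sv[p] <- cand
          nxt <- c(nxt, p)
        }
      }
    }
    frontier <- unique(nxt)
  }
  sv
}

#' Semantic similarity between two GO terms (Wang measure)
#'
#' Graph-based similarity: each term's ancestor closure receives S-values
#' (see [term_svalues()]); the similarity is the summed S-values over the
#' common ancestors divided by the two terms' total semantic values.
#' Terms in different namespaces have similarity 0 by convention.
#'
#' @param dag A [go_dag()].
#' @param t1,t2 Term ids.
#' @param w_isa,w_partof Edge weights.
#' @return Similarity in `[0, 1]`; 1 when `t1 == t2`.
#' @examples
#' dag <- go_dag(data.frame(id = c("R", "A", "B"), name = NA,
#'                          namespace = "biological_process"),
#'               data.frame(child = c("A", "B"), parent = "R", type = "is_a"))
#' term_similarity(dag, "A", "B")  # 1.6 / 3.6
#' @export
term_similarity <- function(dag, t1, t2, w_isa = 0.8, w_partof = 0.6) {
  if (term_namespace(dag, t1) != term_namespace(dag, t2)) return(0)
  if (t1 == t2) return(1)
  s1 <- term_svalues(dag, t1, w_isa, w_partof)
  s2 <- term_svalues(dag, t2, w_isa, w_partof)
  common <- intersect(names(s1), names(s2))
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

# Internal: similarity from precomputed S-value vectors.
sim_from_svalues <- function(s1, s2) {
  common <- intersect(names(s1), names(s2))
  if (!length(common)) return(0)
  sum(s1[common] + s2[common]) / (sum(s1) + sum(s2))
}

#' Build a gene-to-term annotation map
#'
#' @param x Either a data.frame whose first two columns are (gene, term) —
#'   e.g. a two-column TSV read with `read.table` — or a named list of term
#'   id vectors.
#' @param dag A [go_dag()]; annotations to unknown terms are dropped with a
#'   warning.
#' @return Named list (gene -> character vector of term ids) of class
#'   `annotation_map`. Genes left without any known term are removed.
#' @export
annotation_map <- function(x, dag) {
  if (is.data.frame(x))
    x <- split(as.character(x[[2]]), as.character(x[[1]]))
  x <- lapply(x, unique)
  all_terms <- unique(unlist(x))
  unknown <- setdiff(all_terms, dag$terms$id)
  if (length(unknown)) {
    warning("dropping annotations to ", length(unknown), " unknown term(s)")
    x <- lapply(x, function(ts) setdiff(ts, unknown))
  }
  x <- x[vapply(x, length, integer(1)) > 0]
  structure(x, class = "annotation_map")
}

#' Read gene annotations from GAF 2.x or two-column TSV
#'
#' GAF files (detected by a `!gaf-version` header or >= 15 columns) use
#' column 3 (gene symbol) and column 5 (GO id); otherwise the file is read
#' as `gene<TAB>term` pairs.
#'
#' @param path File path.
#' @param dag A [go_dag()] used to validate term ids.
#' @return An [annotation_map()].
#' @export
read_annotations <- function(path, dag) {
  first <- readLines(path, n = 1)
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           comment.char = "!", quote = "",
                           stringsAsFactors = FALSE)
  if (grepl("^!gaf", first) || ncol(tab) >= 15) {
    df <- data.frame(gene = tab[[3]], term = tab[[5]])
  } else df <- data.frame(gene = tab[[1]], term = tab[[2]])
  annotation_map(df, dag)
}

ann_terms <- function(ann, g) {
  ts <- ann[[g]]
  if (is.null(ts) || !length(ts)) NULL else ts
}

#' Similarity between a term and a gene
#'
#' Mean Wang similarity between `t` and each term annotating `g`:
#' `S(t, g) = mean over t' in T(g) of sim(t, t')`.
#'
#' @param dag A [go_dag()].
#' @param t Term id.
#' @param g Gene id.
#' @param ann An [annotation_map()].
#' @param w_isa,w_partof Edge weights.
#' @return `S(t, g)` in `[0, 1]`. Errors for unannotated genes (Eq. divides
#'   by `|T(g)|`): such genes must be excluded, not scored 0.
#' @export
term_gene_similarity <- function(dag, t, g, ann, w_isa = 0.8, w_partof = 0.6) {
  ts <- ann_terms(ann, g)
  if (is.null(ts)) stop_config("gene has no annotations: ", g)
  mean(vapply(ts, function(tp) term_similarity(dag, t, tp, w_isa, w_partof),
              numeric(1)))
}

#' Similarity between a term and a gene set
#'
#' `S(t, G) = mean over annotated genes g in G of S(t, g)`. Genes without
#' annotations are dropped before averaging.
#'
#' @inheritParams term_gene_similarity
#' @param genes Character vector of gene ids.
#' @return `S(t, G)` in `[0, 1]`. Errors when no gene in the set is
#'   annotated.
#' @export
term_geneset_similarity <- function(dag, t, genes, ann,
                                    w_isa = 0.8, w_partof = 0.6) {
  genes <- genes[genes %in% names(ann)]
  if (!length(genes)) stop_config("no annotated gene in the set")
  mean(vapply(genes, function(g)
    term_gene_similarity(dag, t, g, ann, w_isa, w_partof), numeric(1)))
}

#' Gap enrichment score of a GO term
#'
#' Relative excess of the term's similarity to the candidate set over its
#' similarity to the background gene set:
#' `gap(t) = (S(t, HG) - S(t, G)) / S(t, G)`. A large gap marks a term
#' enriched among high-odds-ratio genes. When `S(t, G) = 0` the gap is
#' defined as 0 with a warning (rather than +-Inf).
#'
#' @inheritParams term_gene_similarity
#' @param hg Candidate gene set (high odds ratio).
#' @param g_all Background gene set (all genes considered).
#' @return `gap(t) >= -1`.
#' @export
gap_score <- function(dag, t, hg, g_all, ann, w_isa = 0.8, w_partof = 0.6) {
  s_hg <- term_geneset_similarity(dag, t, hg, ann, w_isa, w_partof)
  s_g <- term_geneset_similarity(dag, t, g_all, ann, w_isa, w_partof)
  if (s_g == 0) {
    warning("S(t, G) = 0 for term ", t, "; gap set to 0")
    return(0)
  }
  (s_hg - s_g) / s_g
}

# Candidate-term universe: terms annotating >= 1 background gene, plus all
# their ancestors, restricted to one namespace.
candidate_terms <- function(dag, genes, ann, namespace = "biological_process",
                            w_isa = 0.8, w_partof = 0.6) {
  direct <- unique(unlist(ann[intersect(genes, names(ann))]))
  anc <- unique(unlist(lapply(direct, function(t) names(term_svalues(dag, t)))))
  terms <- union(direct, anc)
  if (!is.null(namespace))
    terms <- terms[term_namespace(dag, terms) == namespace]
  sort(terms)
}

#' Rank GO terms by gap score
#'
#' Computes the gap for every candidate term (by default: all terms
#' annotating at least one background gene, plus their ancestors, within one
#' namespace) and ranks them in descending gap order, ties broken by term id.
#'
#' @inheritParams gap_score
#' @param terms Candidate term ids; `NULL` for the default universe.
#' @param namespace Namespace restriction for the default universe
#'   (`"biological_process"`), or `NULL` for all.
#' @param top_k Keep the top `top_k` terms (default all).
#' @return data.frame with `rank`, `term`, `name`, `gap`.
#' @export
rank_terms_by_gap <- function(dag, hg, g_all, ann, terms = NULL,
                              namespace = "biological_process", top_k = Inf,
                              w_isa = 0.8, w_partof = 0.6) {
  if (is.null(terms))
    terms <- candidate_terms(dag, g_all, ann, namespace, w_isa, w_partof)
  if (!length(terms)) stop_config("no candidate terms")
  # precompute S-values once per distinct term involved
  genes_hg <- intersect(hg, names(ann))
  genes_g <- intersect(g_all, names(ann))
  if (!length(genes_hg) || !length(genes_g))
    stop_config("no annotated genes in HG or G")
  ann_term_ids <- unique(unlist(ann[genes_g]))
  sv <- lapply(stats::setNames(nm = union(terms, ann_term_ids)),
               function(t) term_svalues(dag, t, w_isa, w_partof))
  ns <- stats::setNames(term_namespace(dag, names(sv)), names(sv))
  sim1 <- function(t, tp) {
    if (ns[[t]] != ns[[tp]]) return(0)
    if (t == tp) return(1)
    sim_from_svalues(sv[[t]], sv[[tp]])
  }
  gene_score <- function(t, g) mean(vapply(ann[[g]], function(tp) sim1(t, tp),
                                           numeric(1)))
  gaps <- vapply(terms, function(t) {
    s_hg <- mean(vapply(genes_hg, function(g) gene_score(t, g), numeric(1)))
    s_g <- mean(vapply(genes_g, function(g) gene_score(t, g), numeric(1)))
    if (s_g == 0) 0 else (s_hg - s_g) / s_g
  }, numeric(1))
  o <- order(-gaps, terms)
  out <- data.frame(rank = seq_along(terms),
                    term = terms[o],
                    name = dag$terms$name[match(terms[o], dag$terms$id)],
                    gap = unname(gaps[o]), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  utils::head(out, top_k)
}

#' Similarity of a gene to a set of reference terms
#'
#' Mean over reference terms `t` of `S(t, g)`; used to score candidate
#' regulators against recombination-related terms such as DNA recombination
#' (GO:0006310) and meiosis I (GO:0007127).
#'
#' @inheritParams term_gene_similarity
#' @param reference_terms Character vector of term ids.
#' @return Mean similarity in `[0, 1]`.
#' @export
gene_to_reference_terms <- function(dag, g, reference_terms, ann,
                                    w_isa = 0.8, w_partof = 0.6) {
  if (!length(reference_terms)) stop_config("reference_terms must be non-empty")
  mean(vapply(reference_terms, function(t)
    term_gene_similarity(dag, t, g, ann, w_isa, w_partof), numeric(1)))
}
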