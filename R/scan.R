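#' Convert a motif into a log-likelihood-ratio scoring matrix
#'
#' Smooths the position frequency matrix with an additive pseudocount spread
#' according to the background, then takes per-position, per-base
#' log2-likelihood ratios against the background:
#' `llr[i,b] = log2( (n[i,b] + pc*bg[b]) / (N[i] + pc) / bg[b] )`,
#' where `n[i,b]` is the (effective) base count and `N[i]` the per-position
#' effective site count. With `pseudocount = 0`, zero probabilities are
#' floored at 1e-6 so every score stays finite.
#'
#' @param motif A [motif_matrix()].
#' @param background Base probability vector (A,C,G,T), strictly positive,
#'   summing to 1. Default uniform.
#' @param pseudocount Additive smoothing constant (default 0.1).
#' @return An object of class `scoring_matrix`: list with `name`, `llr`
#'   (width x 4 matrix, bits), `background`, `pseudocount`, `width`.
#' @examples
#' sm <- make_scoring_matrix(consensus_motif("toy", "ACGT"), pseudocount = 0)
#' sm$llr[1, "A"]  # 2 bits: log2(1 / 0.25)
#' @export
make_scoring_matrix <- function(motif, background = rep(0.25, 4),
                                pseudocount = 0.1) {
  if (!inherits(motif, "motif_matrix")) stop_config("motif must be a motif_matrix")
  if (motif$width < 1) stop_config("zero-width motif")
  background <- check_background(background)
  if (pseudocount < 0) stop_config("pseudocount must be >= 0")
  n <- motif$probs * motif$nsites
  p <- sweep(n, 2, background * pseudocount, "+") / (motif$nsites + pseudocount)
  p <- pmax(p, 1e-6)   # keeps log-ratios finite when pseudocount = 0
  llr <- log2(sweep(p, 2, background, "/"))
  dimnames(llr) <- list(NULL, DNA_BASES)
  structure(list(name = motif$name, llr = llr, background = background,
                 pseudocount = pseudocount, width = motif$width),
            class = "scoring_matrix")
}

check_background <- function(background) {
  background <- as.numeric(background)
  if (length(background) != 4 || any(background <= 0) ||
      abs(sum(background) - 1) > 1e-6)
    stop_config("background must be 4 strictly positive probabilities summing to 1")
  background
}

#' Estimate a 0-order background from sequences
#' @param sequences Character vector of DNA sequences.
#' @return Base probability vector (A,C,G,T); N bases are ignored.
#' @export
background_from_sequences <- function(sequences) {
  counts <- vapply(DNA_BASES, function(b)
    sum(nchar(gsub(paste0("[^", b, "]"), "", toupper(sequences)))), numeric(1))
  counts / sum(counts)
}

# Reverse-complement of a scoring (or integer) matrix: reverse positions and
# swap complementary columns (column order A,C,G,T -> reversed is T,G,C,A).
revcomp_matrix <- function(m) {
  out <- m[rev(seq_len(nrow(m))), c(4L, 3L, 2L, 1L), drop = FALSE]
  colnames(out) <- DNA_BASES
  out
}

# Exact distribution of the integer-discretised score of a random width-w
# word under a 0-order background. Returns tail probabilities:
# tail[j] = Pr[K >= kmin + j - 1].
score_dp_tail <- function(K, background) {
  kminrow <- apply(K, 1, min)
  kmaxrow <- apply(K, 1, max)
  cur <- 1
  curmin <- 0L
  for (i in seq_len(nrow(K))) {
    new <- numeric(length(cur) + (kmaxrow[i] - kminrow[i]))
    for (b in 1:4) {
      sh <- K[i, b] - kminrow[i]
      idx <- seq_along(cur) + sh
      new[idx] <- new[idx] + cur * background[b]
    }
    cur <- new
    curmin <- curmin + kminrow[i]
  }
  list(tail = rev(cumsum(rev(cur))), kmin = curmin,
       kmax = curmin + length(cur) - 1L)
}

#' Exact score p-values by dynamic programming
#'
#' Computes the null distribution of the motif score of a random width-w word
#' drawn from the 0-order background, by dynamic programming over scores
#' discretised to `granularity` bins spanning the achievable score range.
#' Returns a monotone non-increasing step function `p(s) = Pr[score >= s]`,
#' with `p(s) = 1` for any `s` at or below the minimum achievable score.
#' The function is conservative to within the discretisation: its value at
#' `s` is bracketed by the exact tail probabilities at `s +- w * bin_width`.
#'
#' @param sm A [make_scoring_matrix()] result.
#' @param background Base probabilities for the null model (defaults to the
#'   scoring matrix's own background).
#' @param granularity Number of score bins (>= 100; default 1000).
#' @return A vectorised function mapping score (bits) to p-value, of class
#'   `score_pvalue_map`, carrying the discretisation as attributes.
#' @examples
#' sm <- make_scoring_matrix(consensus_motif("toy", "ACGT"), pseudocount = 0)
#' pmap <- score_pvalue_function(sm)
#' pmap(sum(apply(sm$llr, 1, max)))  # best word: 4^-4
#' @export
score_pvalue_function <- function(sm, background = sm$background,
                                  granularity = 1000) {
  background <- check_background(background)
  if (granularity < 100) stop_config("granularity must be >= 100")
  llr <- sm$llr
  w <- nrow(llr)
  minS <- sum(apply(llr, 1, min))
  maxS <- sum(apply(llr, 1, max))
  if (maxS - minS < 1e-12) {
    f <- function(s) as.numeric(s <= maxS + 1e-12)
    attr(f, "degenerate") <- TRUE
    attr(f, "min_score") <- minS; attr(f, "max_score") <- maxS
    class(f) <- c("score_pvalue_map", "function")
    return(f)
  }
  unit <- (maxS - minS) / granularity
  K <- matrix(as.integer(round(llr / unit)), nrow = w)
  dp <- score_dp_tail(K, background)
  tail <- dp$tail; kmin <- dp$kmin; kmax <- dp$kmax
  f <- function(s) {
    idx <- ceiling(s / unit - w / 2 - 1e-9) - kmin + 1
    out <- numeric(length(s))
    out[idx <= 1] <- 1
    inside <- idx > 1 & idx <= length(tail)
    out[inside] <- tail[idx[inside]]
    out
  }
  attr(f, "degenerate") <- FALSE
  attr(f, "K") <- K; attr(f, "tail") <- tail
  attr(f, "kmin") <- kmin; attr(f, "kmax") <- kmax
  attr(f, "unit") <- unit; attr(f, "width") <- w
  attr(f, "min_score") <- minS; attr(f, "max_score") <- maxS
  attr(f, "bin_width") <- unit
  class(f) <- c("score_pvalue_map", "function")
  f
}

# Encode an uppercase DNA string as integers 1..4 (N and friends -> NA).
encode_dna <- function(seq) {
  lut <- rep(NA_integer_, 256)
  lut[utf8ToInt("A")] <- 1L; lut[utf8ToInt("C")] <- 2L
  lut[utf8ToInt("G")] <- 3L; lut[utf8ToInt("T")] <- 4L
  lut[utf8ToInt(seq)]
}

# Integer window scores of matrix K over an encoded sequence; NA where the
# window touches an ambiguous base.
window_int_scores <- function(K, code) {
  w <- nrow(K)
  n <- length(code) - w + 1L
  if (n < 1L) return(integer(0))
  s <- K[1L, code[seq_len(n)]]
  if (w > 1L) for (j in 2:w) s <- s + K[j, code[seq_len(n) + (j - 1L)]]
  s
}

#' Scan region sequences for motif occurrences
#'
#' Scores every window of every sequence on both strands (the reverse strand
#' scores the reverse complement of the window) and emits a hit wherever the
#' exact score p-value is at or below `p_threshold`. Windows containing an
#' ambiguous base never match. Window p-values are exact tail probabilities
#' of the discretised score distribution, so identical scores always receive
#' identical p-values on either strand.
#'
#' @param sm A [make_scoring_matrix()] result.
#' @param sequences Named character vector of uppercase DNA sequences
#'   (region id -> sequence), e.g. from [extract_sequences()].
#' @param p_threshold Emit hits with p-value <= this, in (0, 1].
#' @param granularity Score bins for the p-value DP.
#' @return A data.frame of class `motif_hits`, sorted by ascending p-value,
#'   with columns `motif`, `region_id`, `offset` (0-based forward-strand
#'   start of the window), `strand`, `score` (bits), `p_value`, `q_value`
#'   (`NA` until [attach_qvalues()]).
#' @export
scan_regions <- function(sm, sequences, p_threshold = 3.73e-6,
                         granularity = 1000) {
  if (!is.numeric(p_threshold) || p_threshold <= 0 || p_threshold > 1)
    stop_config("p_threshold must be in (0, 1]")
  if (is.null(names(sequences)) && length(sequences))
    stop_config("sequences must be named by region id")
  pmap <- score_pvalue_function(sm, granularity = granularity)
  scans <- scan_int_scores(sm, pmap, sequences)
  res <- list()
  for (strand in c("+", "-")) {
    llr <- if (strand == "+") sm$llr else revcomp_matrix(sm$llr)
    tail <- scans$tails[[strand]]
    for (rid in names(sequences)) {
      ks <- scans$scores[[strand]][[rid]]
      if (!length(ks)) next
      pv <- tail_lookup(tail, ks, scans$kmin[[strand]])
      sel <- which(!is.na(pv) & pv <= p_threshold)
      if (!length(sel)) next
      code <- scans$codes[[rid]]
      w <- sm$width
      bits <- vapply(sel, function(i)
        sum(llr[cbind(seq_len(w), code[i:(i + w - 1L)])]), numeric(1))
      res[[length(res) + 1L]] <- data.frame(
        motif = sm$name, region_id = rid, offset = sel - 1L, strand = strand,
        score = bits, p_value = pv[sel], q_value = NA_real_,
        stringsAsFactors = FALSE)
    }
  }
  hits <- if (length(res)) do.call(rbind, res) else
    data.frame(motif = character(), region_id = character(),
               offset = integer(), strand = character(), score = numeric(),
               p_value = numeric(), q_value = numeric(),
               stringsAsFactors = FALSE)
  hits <- hits[order(hits$p_value, hits$region_id, hits$offset, hits$strand), ]
  rownames(hits) <- NULL
  class(hits) <- c("motif_hits", "data.frame")
  hits
}

# Shared machinery for scan_regions / region_min_pvalues: integer window
# scores per region and strand, plus per-strand tail distributions.
scan_int_scores <- function(sm, pmap, sequences) {
  if (isTRUE(attr(pmap, "degenerate")))
    stop_config("degenerate scoring matrix (all words score equally): ",
                "scanning is uninformative")
  K <- attr(pmap, "K")
  Krc <- revcomp_matrix(K)
  bg <- sm$background
  dp_rc <- score_dp_tail(Krc, bg)
  codes <- lapply(sequences, encode_dna)
  scores <- list(
    "+" = lapply(codes, function(cd) window_int_scores(K, cd)),
    "-" = lapply(codes, function(cd) window_int_scores(Krc, cd)))
  list(scores = scores, codes = codes,
       tails = list("+" = attr(pmap, "tail"), "-" = dp_rc$tail),
       kmin = list("+" = attr(pmap, "kmin"), "-" = dp_rc$kmin))
}

tail_lookup <- function(tail, k, kmin) {
  idx <- k - kmin + 1L
  out <- rep(NA_real_, length(k))
  ok <- !is.na(idx)
  out[ok & idx <= 1L] <- 1
  inside <- ok & idx > 1L & idx <= length(tail)
  out[inside] <- tail[idx[inside]]
  out[ok & idx > length(tail)] <- 0
  out
}

# Per-region minimum window p-value across both strands (1 when the region
# has no scoreable window). Used to sweep enrichment over thresholds without
# re-scanning.
region_min_pvalues <- function(sm, sequences, granularity = 1000) {
  pmap <- score_pvalue_function(sm, granularity = granularity)
  scans <- scan_int_scores(sm, pmap, sequences)
  out <- rep(1, length(sequences))
  names(out) <- names(sequences)
  for (strand in c("+", "-")) {
    tail <- scans$tails[[strand]]
    kmin <- scans$kmin[[strand]]
    for (rid in names(sequences)) {
      ks <- scans$scores[[strand]][[rid]]
      ks <- ks[!is.na(ks)]
      if (!length(ks)) next
      out[rid] <- min(out[rid], tail_lookup(tail, max(ks), kmin))
    }
  }
  out
}

#' Number of scanned positions for multiple-testing correction
#'
#' Both strands of every window: `2 * sum(length - width + 1)` over regions.
#'
#' @param sequences Named character vector of region sequences.
#' @param width Motif width.
#' @return Integer count of scanned (position, strand) pairs.
#' @export
n_scanned_positions <- function(sequences, width) {
  2 * sum(pmax(nchar(sequences) - width + 1, 0))
}

#' Attach Benjamini-Hochberg q-values to a hit table
#'
#' @param hits A [scan_regions()] hit table.
#' @param n_tests Total number of scanned positions (see
#'   [n_scanned_positions()]); must be at least the number of hits.
#' @return The hit table with `q_value` filled in:
#'   `q_i = min_{j >= i} p_(j) * n_tests / j`, capped at 1.
#' @export
attach_qvalues <- function(hits, n_tests) {
  if (n_tests < nrow(hits))
    stop_config("n_tests must be >= number of hits")
  hits$q_value <- stats::p.adjust(hits$p_value, method = "BH", n = n_tests)
  hits
}

#' Count hits and hit-bearing regions
#'
#' @param hits A hit table from [scan_regions()].
#' @param regions The scanned [region_set()] (or a character vector of region
#'   ids).
#' @return List with `total_hits` (all hit positions, overlapping hits
#'   included), `regions_with_hit` (regions with >= 1 hit on either strand)
#'   and `regions_without_hit`.
#' @export
count_region_hits <- function(hits, regions) {
  ids <- if (is.character(regions)) regions else regions$id
  unknown <- setdiff(unique(hits$region_id), ids)
  if (length(unknown))
    stop_config("hit(s) reference unknown region id: ", unknown[1])
  with_hit <- length(unique(hits$region_id))
  list(total_hits = nrow(hits), regions_with_hit = with_hit,
       regions_without_hit = length(ids) - with_hit)
}

#' Write a hit table as FIMO-like TSV
#' @param hits A hit table.
#' @param path Output path.
#' @param comments Optional `#`-prefixed header comments.
#' @return `path`, invisibly.
#' @export
write_hits <- function(hits, path, comments = character()) {
  write_tsv(as.data.frame(hits), path, comments)
}

#' Read a hit table written by [write_hits()]
#' @param path File path.
#' @return A `motif_hits` data.frame.
#' @export
read_hits <- function(path) {
  hits <- utils::read.table(path, header = TRUE, sep = "\t",
                            comment.char = "#", stringsAsFactors = FALSE)
  class(hits) <- c("motif_hits", "data.frame")
  hits
}
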