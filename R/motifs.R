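DNA_BASES <- c("A", "C", "G", "T")

#' Construct a motif matrix
#'
#' A `motif_matrix` stores a position frequency matrix (PFM) for one
#' DNA-binding protein: one row per motif position, columns A, C, G, T.
#' Counts are kept as given; row sums serve as the effective number of
#' observed sites per position when the matrix is smoothed into a scoring
#' matrix. Probability matrices (rows summing to 1) are accepted and are
#' assigned `nsites` effective sites per row.
#'
#' @param name Motif/protein label.
#' @param counts Numeric matrix (width x 4) of non-negative base counts or
#'   probabilities; columns in A, C, G, T order.
#' @param nsites Effective site count assumed when `counts` rows are
#'   probabilities (default 20, a common scanner convention).
#' @return An object of class `motif_matrix` with elements `name`, `counts`,
#'   `probs` (row-normalised), `nsites` (per-row effective counts), `width`.
#' @examples
#' m <- motif_matrix("toy", matrix(c(8, 2, 0, 0), 1, 4))
#' m$probs
#' @export
motif_matrix <- function(name, counts, nsites = 20) {
  counts <- as.matrix(counts)
  if (ncol(counts) != 4)
    stop_config("motif counts must have 4 columns (A,C,G,T)")
  if (nrow(counts) < 1) stop_config("motif width must be >= 1")
  if (any(counts < 0) || any(!is.finite(counts)))
    stop_config("motif counts must be finite and non-negative")
  rs <- rowSums(counts)
  if (any(rs == 0)) stop_config("motif has an all-zero position")
  probs <- counts / rs
  # rows that were already probabilities carry no real count information
  neff <- ifelse(abs(rs - 1) < 1e-6, nsites, rs)
  dimnames(probs) <- list(NULL, DNA_BASES)
  structure(list(name = name, counts = counts, probs = probs,
                 nsites = neff, width = nrow(counts)),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat(sprintf("<motif_matrix> %s  width=%d\n", x$name, x$width))
  print(round(x$probs, 3))
  invisible(x)
}

#' Build a motif from a consensus sequence
#'
#' Each position gives probability `1 - degeneracy` to the consensus base and
#' spreads `degeneracy` evenly over the other three.
#'
#' @param name Motif label.
#' @param consensus DNA string over ACGT.
#' @param degeneracy Total off-consensus probability per position.
#' @param nsites Effective site count (see [motif_matrix()]).
#' @return A [motif_matrix()].
#' @export
consensus_motif <- function(name, consensus, degeneracy = 0, nsites = 20) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  if (!all(bases %in% DNA_BASES)) stop_config("consensus must be over ACGT")
  m <- matrix(degeneracy / 3, nrow = length(bases), ncol = 4,
              dimnames = list(NULL, DNA_BASES))
  m[cbind(seq_along(bases), match(bases, DNA_BASES))] <- 1 - degeneracy
  motif_matrix(name, m, nsites = nsites)
}

#' Read motifs in JASPAR PFM format
#'
#' Accepts both the bracketed 4-row layout (`A [ 4 19 0 ]` ...) and the plain
#' 4-row numeric layout, one or more motifs per file, each introduced by a
#' `>identifier name` header.
#'
#' @param path File path.
#' @return Named list of [motif_matrix()] objects.
#' @export
read_jaspar <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop_config("no '>' motif headers in ", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (k in seq_along(heads)) {
    block <- lines[(bounds[k] + 1L):(bounds[k + 1L] - 1L)]
    hdr <- strsplit(sub("^>", "", lines[heads[k]]), "\\s+")[[1]]
    name <- if (length(hdr) >= 2) hdr[2] else hdr[1]
    if (length(block) < 4)
      stop_config("JASPAR motif ", name, ": expected 4 base rows")
    rows <- lapply(block[1:4], function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", l)
      l <- gsub("[][]", " ", l)
      as.numeric(strsplit(trimws(l), "\\s+")[[1]])
    })
    lab <- toupper(substr(block[1:4], 1, 1))
    counts <- do.call(cbind, rows)   # width x 4, rows given per base
    colnames(counts) <- if (all(sort(lab) == DNA_BASES)) lab else DNA_BASES
    counts <- counts[, DNA_BASES, drop = FALSE]
    out[[name]] <- motif_matrix(name, counts)
  }
  out
}

#' Read motifs from a TRANSFAC matrix file
#'
#' Parses `matrix.dat`-style blocks: count rows between the `P0`/`PO` header
#' and the block terminator, names taken from the `NA` field (falling back to
#' `ID` then `AC`).
#'
#' @param path File path.
#' @return Named list of [motif_matrix()] objects.
#' @export
read_transfac <- function(path) {
  lines <- readLines(path)
  out <- list()
  name <- NULL; rows <- list(); in_matrix <- FALSE
  flush <- function() {
    if (length(rows)) {
      counts <- do.call(rbind, rows)
      colnames(counts) <- DNA_BASES
      nm <- name %||% paste0("motif", length(out) + 1L)
      out[[nm]] <<- motif_matrix(nm, counts)
    }
    name <<- NULL; rows <<- list(); in_matrix <<- FALSE
  }
  for (l in lines) {
    tag <- substr(l, 1, 2)
    if (tag == "//") { flush(); next }
    if (tag %in% c("AC", "ID") && is.null(name))
      name <- trimws(substring(l, 3))
    if (tag == "NA") name <- trimws(substring(l, 3))
    if (tag %in% c("P0", "PO")) { in_matrix <- TRUE; next }
    if (in_matrix) {
      f <- strsplit(trimws(l), "\\s+")[[1]]
      if (length(f) >= 5 && grepl("^[0-9]+$", f[1])) {
        rows[[length(rows) + 1L]] <- as.numeric(f[2:5])
      } else in_matrix <- FALSE
    }
  }
  flush()
  out
}

#' Read motifs in MEME minimal format
#'
#' Parses `MOTIF` blocks with their `letter-probability matrix:` sections;
#' probabilities are taken as given (alphabet must be ACGT).
#'
#' @param path File path.
#' @param nsites Effective site count assumed when the header does not carry
#'   `nsites=`.
#' @return Named list of [motif_matrix()] objects.
#' @export
read_meme <- function(path, nsites = 20) {
  lines <- readLines(path)
  out <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (grepl("^MOTIF\\s", lines[i])) {
      hdr <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      name <- hdr[2]
      j <- i + 1L
      while (j <= length(lines) && !grepl("letter-probability matrix", lines[j]))
        j <- j + 1L
      if (j > length(lines))
        stop_config("MEME motif ", name, ": no letter-probability matrix")
      w <- as.integer(sub(".*\\bw=\\s*(\\d+).*", "\\1", lines[j]))
      ns <- if (grepl("nsites=", lines[j]))
        as.numeric(sub(".*nsites=\\s*([0-9.]+).*", "\\1", lines[j])) else nsites
      rows <- lapply(lines[(j + 1L):(j + w)], function(l)
        as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:4]))
      counts <- do.call(rbind, rows)
      colnames(counts) <- DNA_BASES
      out[[name]] <- motif_matrix(name, counts, nsites = ns)
      i <- j + w + 1L
    } else i <- i + 1L
  }
  if (!length(out)) stop_config("no MOTIF blocks in ", path)
  out
}

#' Write motifs in MEME minimal format
#'
#' @param motifs Named list of [motif_matrix()] objects.
#' @param path Output path.
#' @param background Background probabilities recorded in the header.
#' @return `path`, invisibly.
#' @export
write_meme <- function(motifs, path, background = rep(0.25, 4)) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("MEME version 4", "", "ALPHABET= ACGT", "",
               "Background letter frequencies",
               paste(sprintf("%s %.6f", DNA_BASES, background),
                     collapse = " "), ""), con)
  for (m in motifs) {
    writeLines(c(paste("MOTIF", m$name),
                 sprintf("letter-probability matrix: alength= 4 w= %d nsites= %d",
                         m$width, round(mean(m$nsites))),
                 apply(m$probs, 1, function(r)
                   paste(sprintf("%.6f", r), collapse = " ")),
                 ""), con)
  }
  invisible(path)
}

#' Read motifs, dispatching on file format
#'
#' Detects MEME (`MEME version` or `MOTIF` lines), JASPAR (`>` headers) or
#' TRANSFAC (`P0`/`PO` blocks) content.
#'
#' @param path File path.
#' @return Named list of [motif_matrix()] objects.
#' @export
read_motifs <- function(path) {
  head <- readLines(path, n = 50)
  if (any(grepl("^(MEME version|MOTIF\\s)", head))) return(read_meme(path))
  if (any(grepl("^>", head))) return(read_jaspar(path))
  if (any(grepl("^(P0|PO)\\b", head))) return(read_transfac(path))
  stop_config("unrecognised motif file format: ", path)
}
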