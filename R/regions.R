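#' Construct a set of genomic regions
#'
#' A `region_set` holds named genomic intervals (0-based, half-open) on a
#' genome described by a chromosome-length table. Regions play one of two
#' roles: `"hotspot"` (recombination hotspots) or `"coldspot"` (matched
#' control regions, which must be pairwise non-overlapping).
#'
#' @param chrom Character vector of chromosome names.
#' @param start,end Integer vectors of 0-based half-open interval bounds.
#' @param id Optional character vector of unique region ids. Defaults to
#'   `"chrom:start-end"`.
#' @param role `"hotspot"` or `"coldspot"`.
#' @param genome Named numeric vector of chromosome lengths (bp). When
#'   supplied, intervals are checked against it.
#' @param genome_id Optional label for the genome assembly.
#' @return An object of class `region_set`: a data.frame with columns
#'   `chrom`, `start`, `end`, `id` and attributes `role`, `genome`,
#'   `genome_id`.
#' @examples
#' rs <- region_set("chr1", 100, 200, genome = c(chr1 = 1000))
#' region_lengths(rs)
#' @export
region_set <- function(chrom, start, end, id = NULL,
                       role = c("hotspot", "coldspot"),
                       genome = NULL, genome_id = "synthetic") {
  role <- match.arg(role)
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (length(chrom) != length(start) || length(start) != length(end))
    stop_config("chrom, start and end must have equal length")
  if (any(start < 0) || any(end <= start))
    stop_config("intervals must satisfy 0 <= start < end")
  if (is.null(id)) id <- sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end))
  if (anyDuplicated(id))
    stop_config("region ids must be unique within a set")
  if (!is.null(genome)) {
    bad <- !(chrom %in% names(genome))
    if (any(bad))
      stop_config("chromosome(s) not in genome table: ",
                  paste(unique(chrom[bad]), collapse = ", "))
    over <- end > genome[chrom]
    if (any(over))
      stop_config("interval beyond chromosome length: ", id[which(over)[1]])
  }
  df <- data.frame(chrom = as.character(chrom), start = start, end = end,
                   id = as.character(id), stringsAsFactors = FALSE)
  if (role == "coldspot" && has_overlap(df))
    stop_config("coldspot regions must be pairwise non-overlapping")
  structure(df, role = role, genome = genome, genome_id = genome_id,
            class = c("region_set", "data.frame"))
}

# TRUE if any two intervals on the same chromosome overlap.
has_overlap <- function(df) {
  for (ch in unique(df$chrom)) {
    sub <- df[df$chrom == ch, , drop = FALSE]
    if (nrow(sub) < 2) next
    o <- order(sub$start)
    if (any(sub$start[o][-1] < sub$end[o][-nrow(sub)])) return(TRUE)
  }
  FALSE
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("<region_set> role=%s  n=%d  genome=%s\n",
              attr(x, "role"), nrow(x), attr(x, "genome_id") %||% "?"))
  if (nrow(x)) {
    cat(sprintf("  mean length: %.2f bp\n", mean(region_lengths(x))))
    print(utils::head(as.data.frame(x), 5))
    if (nrow(x) > 5) cat("  ...", nrow(x) - 5, "more\n")
  }
  invisible(x)
}

#' Region lengths in base pairs
#' @param regions A [region_set()].
#' @return Numeric vector of interval lengths (`end - start`).
#' @export
region_lengths <- function(regions) regions$end - regions$start

#' Read a chromosome-length table
#'
#' Reads a whitespace-separated table whose first two columns are chromosome
#' name and length (the `samtools faidx` `.fai` dialect; extra columns are
#' ignored).
#'
#' @param path File path.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_genome_table <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop_config("genome table needs >= 2 columns (name, length)")
  stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]]))
}

#' Read genomic intervals from a BED file
#'
#' Parses a 3+ column tab-separated BED file into a [region_set()].
#' Coordinates are taken as BED-native 0-based half-open. When a fourth
#' column is present it provides the region id, otherwise ids are assigned
#' as `"chrom:start-end"`.
#'
#' @param path BED file path.
#' @param genome Named numeric vector of chromosome lengths, e.g. from
#'   [read_genome_table()]. Intervals must fall within their chromosome.
#' @param role Region role, `"hotspot"` (default) or `"coldspot"`.
#' @return A [region_set()] in file order.
#' @export
read_bed <- function(path, genome = NULL, role = "hotspot") {
  lines <- readLines(path)
  keep <- !grepl("^(#|track\\b|browser\\b)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (!length(idx))
    return(region_set(character(), numeric(), numeric(), role = role,
                      genome = genome))
  fields <- strsplit(lines[idx], "\t", fixed = TRUE)
  n <- vapply(fields, length, integer(1))
  if (any(n < 3))
    stop_config("malformed BED line ", idx[which(n < 3)[1]],
                ": fewer than 3 tab-separated fields")
  chrom <- vapply(fields, `[[`, character(1), 1)
  start <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 2)))
  end <- suppressWarnings(as.numeric(vapply(fields, `[[`, character(1), 3)))
  bad <- is.na(start) | is.na(end) | start != floor(start) | end != floor(end)
  if (any(bad))
    stop_config("malformed BED line ", idx[which(bad)[1]],
                ": start/end not integers")
  id <- ifelse(n >= 4, vapply(fields, function(f) f[min(4, length(f))],
                              character(1)), NA_character_)
  if (anyNA(id)) id <- NULL
  region_set(chrom, start, end, id = id, role = role, genome = genome)
}

#' Write a region set as BED
#' @param regions A [region_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(regions, path) {
  df <- data.frame(regions$chrom, as.integer(regions$start),
                   as.integer(regions$end), regions$id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Coerce a genome sequence argument (DNAStringSet, named character vector, or
# FASTA path) to a named character vector of uppercase sequences.
genome_as_character <- function(genome) {
  if (is.character(genome) && length(genome) == 1 && file.exists(genome))
    genome <- Biostrings::readDNAStringSet(genome)
  if (methods::is(genome, "DNAStringSet")) {
    nm <- sub("\\s.*$", "", names(genome))
    genome <- stats::setNames(as.character(genome), nm)
  }
  if (!is.character(genome) || is.null(names(genome)))
    stop_config("genome must be a FASTA path, DNAStringSet or named character vector")
  genome
}

#' Extract region sequences from a genome
#'
#' Returns the DNA sequence of every region, uppercased, with any non-ACGT
#' character (including soft-masked lowercase that does not code a base)
#' replaced by `N`.
#'
#' @param regions A [region_set()].
#' @param genome FASTA file path, `Biostrings::DNAStringSet`, or named
#'   character vector of chromosome sequences.
#' @return Named character vector (region id -> sequence); lengths equal the
#'   interval lengths.
#' @export
extract_sequences <- function(regions, genome) {
  genome <- genome_as_character(genome)
  miss <- setdiff(unique(regions$chrom), names(genome))
  if (length(miss))
    stop_config("chromosome(s) missing from genome: ", paste(miss, collapse = ", "))
  lens <- nchar(genome)[regions$chrom]
  if (any(regions$end > lens))
    stop_config("interval beyond chromosome sequence: ",
                regions$id[which(regions$end > lens)[1]])
  seqs <- substring(genome[regions$chrom], regions$start + 1, regions$end)
  seqs <- toupper(seqs)
  seqs <- gsub("[^ACGT]", "N", seqs)
  stats::setNames(seqs, regions$id)
}

# Gap (bp) between [s1,e1) and [s2,e2): 0 when they touch or overlap.
interval_gap <- function(s1, e1, s2, e2) pmax(pmax(s2 - e1, s1 - e2), 0)

#' Sample coldspot control regions
#'
#' Draws, for every hotspot, one control region on the same chromosome with
#' identical length, such that every control lies at least `min_distance`
#' (closest-end gap) from every hotspot on that chromosome and controls are
#' pairwise non-overlapping. These are the three matching constraints the
#' enrichment analysis relies on: the controls reproduce the hotspot length
#' distribution and per-chromosome counts while sampling the distant genomic
#' background.
#'
#' Placement is uniform rejection sampling per hotspot, processing hotspots
#' in descending length order (long intervals are hardest to place).
#'
#' @param hotspots A hotspot [region_set()].
#' @param genome Named numeric vector of chromosome lengths.
#' @param min_distance Minimum end-to-end gap (bp) between any coldspot and
#'   any hotspot. Default 50000.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param max_attempts Rejection-sampling budget per interval.
#' @param genome_seq Optional genome sequence (any form accepted by
#'   [extract_sequences()]); when given, candidate regions whose N fraction
#'   exceeds `max_n_fraction` are rejected, since hit counts inside
#'   assembly-gap runs are meaningless.
#' @param max_n_fraction Maximum tolerated fraction of N bases.
#' @return A coldspot [region_set()] with ids `cold_<hotspot id>`.
#' @export
sample_coldspots <- function(hotspots, genome, min_distance = 50000,
                             seed = NULL, max_attempts = 10000,
                             genome_seq = NULL, max_n_fraction = 0.5) {
  if (!is.null(genome_seq)) genome_seq <- genome_as_character(genome_seq)
  with_seed(seed, {
    ord <- order(-region_lengths(hotspots))
    out_chrom <- character(0); out_start <- numeric(0)
    out_end <- numeric(0); out_id <- character(0)
    for (i in ord) {
      ch <- hotspots$chrom[i]
      len <- hotspots$end[i] - hotspots$start[i]
      L <- genome[[ch]]
      if (is.null(L) || is.na(L))
        stop_config("chromosome not in genome table: ", ch)
      hs <- hotspots[hotspots$chrom == ch, , drop = FALSE]
      cs_sel <- out_chrom == ch
      placed <- FALSE
      for (att in seq_len(max_attempts)) {
        s <- sample.int(L - len + 1L, 1L) - 1
        e <- s + len
        if (any(interval_gap(hs$start, hs$end, s, e) < min_distance)) next
        if (any(cs_sel) &&
            any(out_start[cs_sel] < e & s < out_end[cs_sel])) next
        if (!is.null(genome_seq)) {
          frag <- toupper(substring(genome_seq[[ch]], s + 1, e))
          nfrac <- 1 - nchar(gsub("[^ACGT]", "", frag)) / len
          if (nfrac > max_n_fraction) next
        }
        out_chrom <- c(out_chrom, ch); out_start <- c(out_start, s)
        out_end <- c(out_end, e)
        out_id <- c(out_id, paste0("cold_", hotspots$id[i]))
        cs_sel <- out_chrom == ch
        placed <- TRUE
        break
      }
      if (!placed)
        stop("coldspot placement failed on chromosome ", ch,
             " after ", max_attempts, " attempts", call. = FALSE)
    }
    region_set(out_chrom, out_start, out_end, id = out_id, role = "coldspot",
               genome = genome, genome_id = attr(hotspots, "genome_id"))
  })
}

#' Validate a coldspot set against its hotspots
#'
#' Checks the three coldspot constraints: per-chromosome length multisets
#' match the hotspots, every coldspot is at least `min_distance` from every
#' hotspot on its chromosome, and coldspots are pairwise non-overlapping.
#' Violations are reported, not raised.
#'
#' @param coldspots,hotspots [region_set()] objects on the same genome.
#' @param min_distance Minimum end-to-end gap in bp.
#' @return A list of class `coldspot_validation` with elements `pass`
#'   (logical), `violations` (character vector) and `first_violation`.
#' @export
validate_coldspots <- function(coldspots, hotspots, min_distance = 50000) {
  viol <- character(0)
  for (ch in union(unique(hotspots$chrom), unique(coldspots$chrom))) {
    hl <- sort(region_lengths(hotspots[hotspots$chrom == ch, , drop = FALSE]))
    cl <- sort(region_lengths(coldspots[coldspots$chrom == ch, , drop = FALSE]))
    if (length(hl) != length(cl) || (length(hl) && any(hl != cl)))
      viol <- c(viol, paste0("length multiset mismatch on ", ch))
  }
  for (i in seq_len(nrow(coldspots))) {
    hs <- hotspots[hotspots$chrom == coldspots$chrom[i], , drop = FALSE]
    if (!nrow(hs)) next
    g <- interval_gap(hs$start, hs$end, coldspots$start[i], coldspots$end[i])
    if (any(g < min_distance))
      viol <- c(viol, paste0("coldspot ", coldspots$id[i], " within ",
                             min_distance, " bp of hotspot ",
                             hs$id[which(g < min_distance)[1]]))
  }
  if (has_overlap(as.data.frame(coldspots)))
    viol <- c(viol, "overlapping coldspots")
  structure(list(pass = length(viol) == 0, violations = viol,
                 first_violation = if (length(viol)) viol[1] else NA_character_),
            class = "coldspot_validation")
}

#' @export
print.coldspot_validation <- function(x, ...) {
  cat("<coldspot_validation>", if (x$pass) "PASS" else "FAIL", "\n")
  if (!x$pass) cat(paste0("  - ", x$violations, "\n"), sep = "")
  invisible(x)
}
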