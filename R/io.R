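#' Read a BED3/BED6 file
#'
#' Parses 0-based half-open BED text with validation that reports offending
#' line numbers, returning records sorted by (chrom, start).
#'
#' @param path File path.
#' @param expect_strand If TRUE, require 6 columns and parse strand.
#' @return A data frame with columns `chrom`, `start`, `end` and, when
#'   present, `name`, `score`, `strand`.
#' @export
read_bed <- function(path, expect_strand = FALSE) {
  lines <- readLines(path)
  keep <- !grepl("^(#|track|browser)", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  if (length(lineno) == 0L) stop("no records in ", path)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  ncol <- lengths(fields)
  need <- if (expect_strand) 6L else 3L
  bad <- which(ncol < need)
  if (length(bad) > 0)
    stop(sprintf("line %d: expected at least %d tab-separated fields, found %d",
                 lineno[bad[1]], need, ncol[bad[1]]))
  nc <- min(ncol)
  get <- function(i) vapply(fields, `[`, character(1), i)
  start <- suppressWarnings(as.numeric(get(2)))
  end <- suppressWarnings(as.numeric(get(3)))
  bad <- which(!is.finite(start) | !is.finite(end))
  if (length(bad) > 0)
    stop(sprintf("line %d: non-numeric coordinates", lineno[bad[1]]))
  bad <- which(start < 0)
  if (length(bad) > 0)
    stop(sprintf("line %d: negative start coordinate", lineno[bad[1]]))
  bad <- which(start >= end)
  if (length(bad) > 0)
    stop(sprintf("line %d: start >= end", lineno[bad[1]]))
  out <- data.frame(chrom = get(1), start = start, end = end,
                    stringsAsFactors = FALSE)
  if (nc >= 4L) out$name <- get(4)
  if (nc >= 5L) out$score <- suppressWarnings(as.numeric(get(5)))
  if (nc >= 6L) {
    strand <- get(6)
    bad <- which(!strand %in% c("+", "-", "."))
    if (length(bad) > 0)
      stop(sprintf("line %d: unknown strand symbol '%s'",
                   lineno[bad[1]], strand[bad[1]]))
    out$strand <- strand
  } else if (expect_strand) {
    stop("expect_strand = TRUE but input has fewer than 6 columns")
  }
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a CTCF site track as BED6
#'
#' Serializes a [ctcf_track] as BED6 text: chrom `"sim"`, 0-based half-open
#' one-monomer intervals, the halting probability scaled by 1000 in the
#' score column, and the motif orientation as strand.
#'
#' @param track A [ctcf_track].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ctcf_bed <- function(track, path) {
  stopifnot(inherits(track, "ctcf_track"))
  df <- data.frame("sim", track$position - 1L, track$position,
                   paste0("site", seq_len(nrow(track))),
                   round(track$halt_prob * 1000), track$orientation)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a CTCF site track from BED6
#'
#' @param path BED6 file written by [write_ctcf_bed()].
#' @param n_monomers Lattice size of the track.
#' @return A [ctcf_track].
#' @export
read_ctcf_bed <- function(path, n_monomers) {
  b <- read_bed(path, expect_strand = TRUE)
  ord <- order(b$start)
  ctcf_track(n_monomers, position = b$end[ord],
             orientation = b$strand[ord], halt_prob = b$score[ord] / 1000)
}

#' Write an insulation profile as bedGraph
#'
#' Standard 4-column bedGraph; masked (NA) bins are omitted, preserving the
#' gap. Bins must be contiguous and non-overlapping.
#'
#' @param profile An `insulation_profile` (or data frame with `start`,
#'   `end`, `score`).
#' @param path Output path.
#' @param chrom Chromosome label for the output.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(profile, path, chrom = "sim") {
  df <- as.data.frame(profile)
  stopifnot(all(c("start", "end", "score") %in% names(df)))
  df <- df[order(df$start), , drop = FALSE]
  if (nrow(df) > 1 && any(df$start[-1] < df$end[-nrow(df)]))
    stop("overlapping bins")
  df <- df[is.finite(df$score), , drop = FALSE]
  utils::write.table(data.frame(chrom, df$start, df$end, df$score),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a bedGraph file
#'
#' @param path bedGraph path.
#' @return A data frame with columns `chrom`, `start`, `end`, `score`.
#' @export
read_bedgraph <- function(path) {
  b <- read_bed(path)
  names(b)[4] <- "score"
  b$score <- as.numeric(b$score)
  b
}

#' Write a contact map
#'
#' `format = "rds"` (default) stores the full object in R's serialization
#' format. `format = "txt"` writes a plain-text dump compatible with common
#' Hi-C text formats: metadata header lines (`#bin_size`, `#origin`,
#' `#n_bins`, `#normalized`) followed by three columns `bin_i bin_j value`
#' for the non-zero upper triangle (including the diagonal).
#'
#' @param map A [contact_map].
#' @param path Output path.
#' @param format `"rds"` or `"txt"`.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path, format = c("rds", "txt")) {
  format <- match.arg(format)
  stopifnot(inherits(map, "contact_map"))
  if (format == "rds") {
    saveRDS(map, path)
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c(sprintf("#bin_size\t%g", map$bin_size),
                 sprintf("#origin\t%g", map$origin),
                 sprintf("#n_bins\t%d", nrow(map$matrix)),
                 sprintf("#normalized\t%s", map$normalized)), con)
    ut <- which(upper.tri(map$matrix, diag = TRUE) & map$matrix != 0,
                arr.ind = TRUE)
    utils::write.table(
      data.frame(ut[, 1], ut[, 2],
                 format(map$matrix[ut], digits = 17, trim = TRUE)),
      con, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read a contact map written by [write_contact_map()]
#'
#' @param path Input path.
#' @param format `"rds"` or `"txt"`.
#' @return A [contact_map].
#' @export
read_contact_map <- function(path, format = c("rds", "txt")) {
  format <- match.arg(format)
  if (format == "rds") {
    m <- readRDS(path)
    if (!inherits(m, "contact_map")) stop("not a contact_map rds file")
    return(m)
  }
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- do.call(rbind, strsplit(sub("^#", "", hdr), "\t"))
  val <- stats::setNames(meta[, 2], meta[, 1])
  n <- as.integer(val["n_bins"])
  mat <- matrix(0, n, n)
  body <- lines[!startsWith(lines, "#")]
  if (length(body) > 0) {
    d <- utils::read.table(text = body, sep = "\t")
    mat[cbind(d[, 1], d[, 2])] <- d[, 3]
    mat[cbind(d[, 2], d[, 1])] <- d[, 3]
  }
  contact_map(mat, bin_size = as.numeric(val["bin_size"]),
              origin = as.numeric(val["origin"]),
              normalized = val["normalized"])
}

#' Write a FRAP trace as CSV
#'
#' @param trace A [frap_trace].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_frap_csv <- function(trace, path) {
  stopifnot(inherits(trace, "frap_trace"))
  df <- as.data.frame(trace)
  df$prebleach <- seq_len(nrow(df)) <= attr(trace, "n_prebleach")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a FRAP trace CSV
#'
#' Accepts either a normalized trace (`time_min`, `signal`, optional
#' `prebleach` flag) or raw series (`time_min`, `bleached`, `unbleached`,
#' optional `background`), which are normalized via [normalize_ifrap()].
#'
#' @param path CSV path.
#' @param n_prebleach Pre-bleach frame count for raw input (ignored when a
#'   `prebleach` column is present).
#' @return A [frap_trace].
#' @export
read_frap_csv <- function(path, n_prebleach = NULL) {
  df <- utils::read.csv(path)
  if (all(c("bleached", "unbleached") %in% names(df))) {
    if (is.null(n_prebleach)) stop("n_prebleach is required for raw series")
    return(normalize_ifrap(df$bleached, df$unbleached, n_prebleach,
                           background = df$background,
                           time_min = df$time_min))
  }
  stopifnot(all(c("time_min", "signal") %in% names(df)))
  npb <- if ("prebleach" %in% names(df)) sum(df$prebleach)
         else sum(df$time_min < 0)
  frap_trace(df$time_min, df$signal, n_prebleach = npb)
}

#' Write a loop list as BEDPE
#'
#' @param loops A [loop_list].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bedpe <- function(loops, path) {
  stopifnot(inherits(loops, "loop_list"))
  df <- data.frame(loops$chrom, loops$start1, loops$end1,
                   loops$chrom, loops$start2, loops$end2)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BEDPE loop list
#'
#' @param path BEDPE path (first six columns used; intra-chromosomal only).
#' @return A [loop_list].
#' @export
read_bedpe <- function(path) {
  d <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(d) < 6) stop("BEDPE requires at least 6 columns")
  if (any(d[, 1] != d[, 4])) stop("only intra-chromosomal loops are supported")
  loop_list(d[, 1], d[, 2], d[, 3], d[, 5], d[, 6])
}
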