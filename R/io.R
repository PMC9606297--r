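# File formats. Canonical dialect: tab-separated values with a commented
# header line ("#chrom\tstart\t..."), coordinates 0-based half-open
# (BED-compatible). No reader mutates its input file.

seg_columns <- c("chrom", "start", "end", "raw_minor", "raw_major",
                 "ploidy", "patient", "region")

read_tsv_commented <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  hdr <- sub("^#", "", first)
  nm <- strsplit(hdr, "\t")[[1]]
  if (!all(columns %in% nm))
    stop("header of ", path, " lacks column(s): ",
         paste(setdiff(columns, nm), collapse = ", "))
  out <- utils::read.table(path, sep = "\t", skip = 1L, col.names = nm,
                           stringsAsFactors = FALSE, quote = "",
                           comment.char = "")
  out
}

write_tsv_commented <- function(df, path) {
  hdr <- paste0("#", paste(names(df), collapse = "\t"))
  writeLines(hdr, path)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE, append = TRUE)
  invisible(path)
}

#' Read allele-specific segment profiles from a SEG-like TSV
#'
#' Expects the canonical dialect written by [write_segments()]: a
#' commented header and columns `chrom`, `start`, `end`, `raw_minor`,
#' `raw_major`, `ploidy`, `patient`, `region`, 0-based half-open unless
#' `one_based = TRUE` (then starts are decremented on read). Rows with
#' `raw_minor > raw_major` are swapped with a warning; overlapping
#' segments within a region are a hard error naming the offending rows.
#'
#' @param path TSV file path.
#' @param one_based set when the file uses 1-based inclusive coordinates.
#' @return list of [allelic_segment_profile()], one per patient-region.
#' @export
read_segments <- function(path, one_based = FALSE) {
  tab <- read_tsv_commented(path, seg_columns)
  bad <- which(!is.finite(tab$start) | !is.finite(tab$end) |
                 tab$raw_minor < 0 | tab$raw_major < 0 | tab$ploidy <= 0)
  if (length(bad))
    stop("malformed row(s) at line(s) ", paste(bad + 1L, collapse = ", "),
         " of ", path)
  if (one_based) tab$start <- tab$start - 1L
  key <- paste(tab$patient, tab$region, sep = "_")
  lapply(split(tab, key), function(s) {
    allelic_segment_profile(
      s$patient[1], s$region[1],
      s[, c("chrom", "start", "end", "raw_minor", "raw_major")],
      s$ploidy[1])
  })
}

#' Write allele-specific segment profiles to a SEG-like TSV
#'
#' @param profiles list of [allelic_segment_profile()].
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_segments <- function(profiles, path) {
  rows <- lapply(profiles, function(p) {
    cbind(p$segments, ploidy = p$ploidy, patient = p$patient,
          region = p$region)
  })
  tab <- do.call(rbind, rows)[, seg_columns]
  write_tsv_commented(tab, path)
}

#' Read a BED3 interval file (0-based half-open)
#'
#' @param path BED file path.
#' @return data.frame with `chrom`, `start`, `end`.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE)
  names(tab) <- c("chrom", "start", "end", "name")[seq_len(min(4L,
                                                               ncol(tab)))]
  tab[, seq_len(min(4L, ncol(tab))), drop = FALSE]
}

#' Write intervals as BED (0-based half-open)
#'
#' @param df data.frame with `chrom`, `start`, `end` and optionally `name`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_bed <- function(df, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(df))
  utils::write.table(df[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read drug plates from a CSV
#'
#' Columns: `sample`, `drug`, `dose`, `replicate`, `signal`, `is_control`.
#'
#' @param path CSV path.
#' @return list of [dose_plate()], one per sample x drug.
#' @export
read_plates <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "drug", "dose", "replicate", "signal", "is_control")
  if (!all(need %in% names(tab)))
    stop("plate CSV lacks column(s): ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab$is_control <- as.logical(tab$is_control)
  key <- paste(tab$sample, tab$drug, sep = "|")
  lapply(split(tab, key), function(s)
    dose_plate(s[, c("dose", "replicate", "signal", "is_control")],
               sample_id = s$sample[1], drug_id = s$drug[1]))
}

#' Write drug plates to a CSV
#'
#' @param plates list of [dose_plate()].
#' @param path output CSV path.
#' @return the path, invisibly.
#' @export
write_plates <- function(plates, path) {
  rows <- lapply(plates, function(p)
    cbind(sample = p$sample_id, drug = p$drug_id,
          p$wells[, c("dose", "replicate", "signal", "is_control")]))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a genes x samples matrix from TSV
#'
#' @param path TSV with gene ids in the first column and samples as the
#'   remaining columns.
#' @return numeric matrix with dimnames.
#' @export
read_gene_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE,
                           check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  m
}

#' Write a genes x samples matrix to TSV
#'
#' @param m numeric matrix with dimnames.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_gene_matrix <- function(m, path) {
  df <- data.frame(gene = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write a clonality frequency track as bedGraph
#'
#' One bedGraph file per category column present in the track.
#'
#' @param track a [clonality_frequency_track()] result.
#' @param dir output directory.
#' @return character vector of written paths, invisibly.
#' @export
write_frequency_tracks <- function(track, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cats <- intersect(c("clonal_gain", "subclonal_gain", "clonal_loss",
                      "subclonal_loss", "total_gain", "total_loss"),
                    names(track))
  paths <- vapply(cats, function(cc) {
    p <- file.path(dir, paste0(cc, ".bedgraph"))
    keep <- !is.na(track[[cc]])
    utils::write.table(track[keep, c("chrom", "start", "end", cc)], p,
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
    p
  }, character(1))
  invisible(paths)
}
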