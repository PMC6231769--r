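# Readers and writers for the standard formats: bedGraph tracks (via
# rtracklayer), BED6+summit TF peaks (summit kept in the thickStart
# column, a dialect rtracklayer does not round-trip, hence written
# directly), and tab-separated gene-annotation / TPM tables.

#' Write a per-chromosome track as bedGraph
#'
#' @param track named list of per-bp numeric vectors (one per chromosome).
#' @param path output file.
#' @return The path, invisibly.
#' @export
write_bedgraph <- function(track, path) {
  grl <- lapply(names(track), function(cn) {
    r <- rle(as.numeric(track[[cn]]))
    ends <- cumsum(r$lengths)
    keep <- r$values != 0
    GenomicRanges::GRanges(cn,
      IRanges::IRanges(ends[keep] - r$lengths[keep] + 1L, ends[keep]),
      score = r$values[keep])
  })
  gr <- do.call(c, grl)
  rtracklayer::export.bedGraph(gr, path)
  invisible(path)
}

#' Read a bedGraph file into per-chromosome tracks
#'
#' Intervals are validated as 0-based half-open within chromosome bounds
#' and non-overlapping; unsorted input is accepted with a warning and
#' sorted internally.
#'
#' @param path bedGraph file.
#' @param chrom_lengths named integer vector of chromosome lengths.
#' @return Named list of per-bp numeric vectors.
#' @export
read_bedgraph <- function(path, chrom_lengths) {
  gr <- rtracklayer::import.bedGraph(path)
  out <- lapply(names(chrom_lengths), function(cn) numeric(chrom_lengths[[cn]]))
  names(out) <- names(chrom_lengths)
  cn_all <- as.character(GenomicRanges::seqnames(gr))
  bad <- setdiff(unique(cn_all), names(chrom_lengths))
  if (length(bad)) stop("unknown chromosomes in ", path, ": ",
                        paste(bad, collapse = ","), call. = FALSE)
  for (cn in unique(cn_all)) {
    g <- gr[cn_all == cn]
    if (is.unsorted(BiocGenerics::start(g))) {
      warning("unsorted bedGraph intervals on ", cn, "; sorting")
      g <- g[order(BiocGenerics::start(g))]
    }
    s <- BiocGenerics::start(g); e <- BiocGenerics::end(g)
    if (any(e > chrom_lengths[[cn]]) || any(s < 1L))
      stop("bedGraph interval outside chromosome bounds on ", cn, call. = FALSE)
    if (length(s) > 1L && any(s[-1] <= e[-length(e)]))
      stop("overlapping bedGraph intervals on ", cn, call. = FALSE)
    for (i in seq_along(s)) out[[cn]][s[i]:e[i]] <- g$score[i]
  }
  out
}

#' Write / read TF peaks as BED6 with summit
#'
#' BED6 columns plus the summit as a seventh (thickStart-style) column.
#' On read, a missing summit column falls back to the interval midpoint
#' (flagged with a warning).
#'
#' @param peaks data.table with `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`, `summit`.
#' @param path file path.
#' @return `read_bed_summits` returns the peaks data.table.
#' @export
write_bed_summits <- function(peaks, path) {
  data.table::fwrite(peaks[, c("chrom", "start", "end", "name", "score",
                               "strand", "summit")],
                     path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_bed_summits
#' @export
read_bed_summits <- function(path) {
  dt <- data.table::fread(path, header = FALSE)
  if (ncol(dt) < 6L) stop("expected at least BED6", call. = FALSE)
  if (any(dt[[3]] <= dt[[2]])) stop("BED interval end <= start", call. = FALSE)
  names(dt)[1:6] <- c("chrom", "start", "end", "name", "score", "strand")
  if (ncol(dt) >= 7L) names(dt)[7] <- "summit"
  else {
    warning("no summit column; using interval midpoints")
    dt$summit <- (dt$start + dt$end) %/% 2L
  }
  dt[, c("chrom", "start", "end", "name", "score", "strand", "summit")]
}

#' Write / read a genome model as tab-separated tables
#'
#' Two TSVs: `<prefix>_genes.tsv` and `<prefix>_exons.tsv`, plus
#' `<prefix>_chroms.tsv`.
#'
#' @param genome genome model; `prefix` path prefix.
#' @return `read_gene_table` returns a `wormcis_genome`.
#' @export
write_gene_table <- function(genome, prefix) {
  data.table::fwrite(genome$chromosomes, paste0(prefix, "_chroms.tsv"), sep = "\t")
  data.table::fwrite(genome$genes, paste0(prefix, "_genes.tsv"), sep = "\t")
  data.table::fwrite(genome$exons, paste0(prefix, "_exons.tsv"), sep = "\t")
  invisible(prefix)
}

#' @rdname write_gene_table
#' @export
read_gene_table <- function(prefix) {
  g <- list(chromosomes = data.table::fread(paste0(prefix, "_chroms.tsv")),
            genes = data.table::fread(paste0(prefix, "_genes.tsv")),
            exons = data.table::fread(paste0(prefix, "_exons.tsv")))
  class(g) <- c("wormcis_genome", "list")
  validate_genome(g)
  g
}

#' @noRd
write_table_with_hash <- function(dt, path, cfg_hash) {
  con <- file(path, "w")
  writeLines(paste0("# config_hash: ", cfg_hash), con)
  close(con)
  data.table::fwrite(dt, path, sep = "\t", append = TRUE, col.names = TRUE)
  invisible(path)
}

#' @noRd
bool_str <- function(x) ifelse(x, "True", "False")
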