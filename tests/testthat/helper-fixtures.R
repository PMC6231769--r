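# Shared fixtures, built in code.  The small dataset is cached per test run.

.fixture_env <- new.env(parent = emptyenv())

small_config <- function(seed = 1L) {
  default_config(seed = seed, sim_n_genes = 30L, sim_chrom_length = 3e5,
                 sim_n_promoters = 20L, sim_n_enhancers = 10L,
                 sim_n_inactive = 5L, tf_min_peaks = 1L, sim_hot_n = 5L)
}

small_run <- function() {
  if (is.null(.fixture_env$run))
    .fixture_env$run <- run_pipeline(small_config())
  .fixture_env$run
}

# hand-built toy genome with known geometry (chrom 0..20000)
#  geneA: +, outron 5000 -> first exon [5800,6100) (5' 5800), UTR [5800,5950),
#         non-first exons [6500,6700) and [7000,7200)
#  geneB: -, no outron, first exon [11000,11300) (5' 11299),
#         non-first exon [10400,10600)
#  geneC: tRNA, +, single exon [15000,15100)
toy_genome <- function() {
  genes <- data.table::data.table(
    gene_id = c("geneA", "geneB", "geneC"),
    locus_id = c("a-1", "b-1", "c-1"),
    biotype = c("protein_coding", "protein_coding", "tRNA"),
    strand = c("+", "-", "+"),
    start = c(5800L, 10400L, 15000L),
    end = c(7200L, 11300L, 15100L),
    tss = c(5000L, 11299L, 15000L),
    outron_start = c(5000L, NA_integer_, NA_integer_),
    utr5_start = c(5800L, NA_integer_, NA_integer_),
    utr5_end = c(5950L, NA_integer_, NA_integer_),
    chrom = "chr")
  exons <- data.table::data.table(
    start = c(5800L, 6500L, 7000L, 11000L, 10400L, 15000L),
    end = c(6100L, 6700L, 7200L, 11300L, 10600L, 15100L),
    is_first = c(TRUE, FALSE, FALSE, TRUE, FALSE, TRUE),
    gene_id = c("geneA", "geneA", "geneA", "geneB", "geneB", "geneC"),
    strand = c("+", "+", "+", "-", "-", "+"))
  exons[, fivep := ifelse(strand == "+", start, end - 1L)]
  exons[, chrom := "chr"]
  g <- list(chromosomes = data.table::data.table(name = "chr", length = 20000L),
            genes = genes, exons = exons)
  class(g) <- c("wormcis_genome", "list")
  g
}

# minimal signal bundle: two stages, two replicates, constant long-cap
# coverage `cov_value` everywhere (optionally with a gap), zero elsewhere
toy_signal <- function(cov_value = 2, gap = NULL, length = 20000L,
                       stages = c("wt_emb", "wt_l1")) {
  mk <- function() {
    v <- rep(cov_value, length)
    if (!is.null(gap)) v[gap + 1L] <- 0
    v
  }
  zero <- function() integer(length)
  sig <- list(stages = stages, n_reps = 2L,
              chromosomes = data.table::data.table(name = "chr",
                                                   length = length))
  per_rep <- function(build) stats::setNames(lapply(stages, function(s)
    lapply(1:2, function(r) list(`+` = list(chr = build()),
                                 `-` = list(chr = build())))), stages)
  sig$lcapcov <- per_rep(mk)
  sig$lcap5 <- per_rep(zero)
  sig$atac <- stats::setNames(
    lapply(stages, function(s) list(list(chr = zero()), list(chr = zero()))),
    stages)
  sig$scap5 <- list(list(`+` = list(chr = zero()), `-` = list(chr = zero())),
                    list(`+` = list(chr = zero()), `-` = list(chr = zero())))
  class(sig) <- c("wormcis_signal", "list")
  sig
}
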