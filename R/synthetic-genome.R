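# Synthetic genome and planted-element generators.  All coordinates are
# 0-based half-open; "tss" is the strand-relative 5' end of the transcription
# unit (the outron start for trans-spliced genes).

#' @noRd
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

NCRNA_BIOTYPES <- c("tRNA", "snRNA", "snoRNA", "rRNA", "miRNA")

#' Simulate a toy annotated genome
#'
#' Places non-overlapping genes on a single chromosome (multiple chromosomes
#' are supported by calling once per chromosome and concatenating).  A
#' configurable fraction of protein-coding genes is trans-spliced: their
#' transcription unit starts at an outron 300-1200 bp upstream of the first
#' exon, emulating the distal-promoter geometry of *C. elegans*.  A fraction
#' carries an annotated 5' UTR at the start of the first exon.  When
#' `n_genes` permits, at least one gene of each non-coding biotype (tRNA,
#' snRNA, snoRNA, rRNA, miRNA) and one pseudogene are included.
#'
#' @param n_genes number of genes (>= 1).
#' @param chrom_length chromosome length in bp; genes are placed on a grid of
#'   `chrom_length / n_genes` slots, which must be at least 5 kb.
#' @param seed integer seed; identical seeds give identical models.
#' @param outron_frac fraction of protein-coding genes with an outron.
#' @param utr_frac fraction of protein-coding genes with a 5' UTR.
#' @param chrom_name chromosome name.
#' @return A list of class `wormcis_genome` with elements `chromosomes`
#'   (data.table: name, length), `genes` (data.table: gene_id, locus_id,
#'   biotype, strand, start, end, tss, outron_start, utr5_start, utr5_end)
#'   and `exons` (data.table: gene_id, start, end, strand, is_first, fivep).
#'   Gene `start`/`end` delimit the gene body (first to last exon); the
#'   outron, when present, lies strand-relative upstream of the body.
#' @export
simulate_genome <- function(n_genes, chrom_length, seed = 1L,
                            outron_frac = 0.7, utr_frac = 0.6,
                            chrom_name = "chrI") {
  stopifnot(n_genes >= 1, chrom_length > 0)
  slot <- floor(chrom_length / n_genes)
  if (slot < 5000)
    stop("cannot place ", n_genes, " non-overlapping genes in ", chrom_length,
         " bp at the configured spacing (need >= 5 kb per gene)", call. = FALSE)
  with_seed(seed, {
    # biotype assignment: guarantee one of each rare class when possible
    biotype <- rep("protein_coding", n_genes)
    if (n_genes >= 12) {
      rare <- c(NCRNA_BIOTYPES, "pseudogene")
      idx <- sample(n_genes, length(rare) + max(0L, round(0.03 * n_genes)))
      biotype[idx[seq_along(rare)]] <- rare
      extra <- idx[-seq_along(rare)]
      if (length(extra)) biotype[extra] <- sample(rare, length(extra), replace = TRUE)
    }
    genes <- vector("list", n_genes)
    exons <- vector("list", n_genes)
    for (i in seq_len(n_genes)) {
      slot_start <- (i - 1L) * slot
      strand <- sample(c("+", "-"), 1L)
      bt <- biotype[i]
      if (bt %in% NCRNA_BIOTYPES) {
        len <- sample(80:300, 1L)
        gstart <- slot_start + sample(seq(1500L, slot - len - 1500L), 1L)
        ex <- data.table::data.table(start = gstart, end = gstart + len,
                                     is_first = TRUE)
        outron_start <- NA_integer_; utr <- c(NA_integer_, NA_integer_)
      } else {
        n_ex <- sample(3:5, 1L)
        ex_len <- sample(100:300, n_ex, replace = TRUE)
        intron <- c(sample(350:800, 1L), sample(150:500, max(0L, n_ex - 2L), replace = TRUE))
        body_len <- sum(ex_len) + sum(intron)
        has_outron <- bt == "protein_coding" && stats::runif(1) < outron_frac
        outron_len <- if (has_outron) sample(300:1200, 1L) else 0L
        margin <- 1800L                      # room for promoters/enhancers
        avail <- slot - body_len - outron_len - 2L * margin
        if (avail < 2L)
          stop("gene slot too small for requested gene structure", call. = FALSE)
        pos0 <- slot_start + margin + outron_len + sample(avail, 1L)
        starts <- pos0 + cumsum(c(0L, (ex_len + c(intron, 0L))[-n_ex]))
        ex <- data.table::data.table(start = starts, end = starts + ex_len,
                                     is_first = FALSE)
        if (strand == "+") ex$is_first[1L] <- TRUE else ex$is_first[n_ex] <- TRUE
        outron_start <- if (has_outron) {
          if (strand == "+") pos0 - outron_len else max(ex$end) + outron_len
        } else NA_integer_
        utr <- c(NA_integer_, NA_integer_)
        if (bt == "protein_coding" && stats::runif(1) < utr_frac) {
          ulen <- sample(80:min(200L, min(ex_len) - 20L), 1L)
          utr <- if (strand == "+") c(pos0, pos0 + ulen)
                 else c(max(ex$end) - ulen, max(ex$end))
        }
      }
      gid <- sprintf("gene_%04d", i)
      ex[, `:=`(gene_id = gid, strand = strand)]
      ex[, fivep := ifelse(strand == "+", start, end - 1L)]
      body <- c(min(ex$start), max(ex$end))
      tss <- if (!is.na(outron_start)) outron_start
             else if (strand == "+") body[1] else body[2] - 1L
      genes[[i]] <- data.table::data.table(
        gene_id = gid, locus_id = sprintf("loc-%d", i), biotype = bt,
        strand = strand, start = body[1], end = body[2], tss = as.integer(tss),
        outron_start = as.integer(outron_start),
        utr5_start = as.integer(utr[1]), utr5_end = as.integer(utr[2]))
      exons[[i]] <- ex
    }
    genome <- list(
      chromosomes = data.table::data.table(name = chrom_name,
                                           length = as.integer(chrom_length)),
      genes = data.table::rbindlist(genes),
      exons = data.table::rbindlist(exons, use.names = TRUE))
    genome$genes[, chrom := chrom_name]
    genome$exons[, chrom := chrom_name]
    class(genome) <- c("wormcis_genome", "list")
    validate_genome(genome)
    genome
  })
}

#' @noRd
validate_genome <- function(g) {
  len <- stats::setNames(g$chromosomes$length, g$chromosomes$name)
  with(g$genes, stopifnot(all(start >= 0), all(end > start),
                          all(end <= len[chrom])))
  fe <- g$exons[g$exons$is_first, ]
  gm <- g$genes[match(fe$gene_id, g$genes$gene_id), ]
  stopifnot(all(fe$fivep >= gm$start & fe$fivep < gm$end))
  oo <- g$genes[!is.na(g$genes$outron_start), ]
  if (nrow(oo)) {
    fe1 <- fe[match(oo$gene_id, fe$gene_id), ]
    ok <- ifelse(oo$strand == "+", oo$outron_start < fe1$fivep,
                 oo$outron_start > fe1$fivep)
    stopifnot(all(ok))
  }
  invisible(g)
}

#' Stage-profile archetypes
#'
#' Four temporal accessibility archetypes over a set of stages: early-high
#' declining, late rising, constant, and ageing-rising.  Used as the true
#' cluster structure of planted elements.
#'
#' @param stages character vector of stage names.
#' @param k number of archetypes (<= 4 supported by the default shapes).
#' @return `k x length(stages)` matrix of nonnegative multipliers.
#' @export
archetype_profiles <- function(stages = stage_names(), k = 4L) {
  full <- rbind(
    early   = c(3.0, 2.5, 2.0, 1.2, 0.7, 0.4, 0.4, 0.3, 0.3, 0.2, 0.2),
    late    = c(0.3, 0.4, 0.7, 1.2, 2.2, 3.0, 2.5, 2.0, 1.5, 1.0, 0.8),
    mid     = c(0.4, 1.0, 2.8, 2.8, 1.0, 0.4, 0.3, 0.3, 0.3, 0.3, 0.3),
    ageing  = c(0.8, 0.8, 0.8, 0.8, 0.8, 0.8, 1.0, 1.5, 2.2, 2.8, 3.2))
  stopifnot(k >= 1, k <= nrow(full))
  idx <- match(stages, stage_names())
  if (anyNA(idx)) stop("unknown stage names", call. = FALSE)
  full[seq_len(k), idx, drop = FALSE]
}

#' Plant regulatory elements with known ground truth
#'
#' Coding (and pseudogene) promoters are placed at the gene's outron start
#' when one exists (distal, trans-spliced geometry) and 50 bp strand-relative
#' upstream of the first-exon 5' end otherwise.  Enhancers are placed in
#' introns or intergenic space, more than 250 bp from every exon 5' end and
#' more than 400 bp from every other planted element.  ncRNA sites sit at
#' non-coding-gene 5' ends; inactive elements are placed like enhancers but
#' receive a zero stage profile.  Each active element is assigned one of `k`
#' archetype stage profiles; the archetype index is the true cluster label.
#'
#' @param genome a [simulate_genome()] model.
#' @param class_counts named integer vector over
#'   `coding_promoter`, `pseudogene_promoter`, `enhancer`, `ncRNA_site`,
#'   `inactive` (missing names mean zero).
#' @param seed integer seed.
#' @param k_profiles number of archetypes (true clusters).
#' @return data.table with one row per element: `element_id`, `true_class`,
#'   `chrom`, `center`, `strand` (`+`, `-`, `both` or `none`),
#'   `target_gene_id`, `true_cluster`, and `prof_<stage>` multiplier columns.
#' @export
plant_elements <- function(genome, class_counts, seed = 1L, k_profiles = 4L) {
  allowed <- c("coding_promoter", "pseudogene_promoter", "enhancer",
               "ncRNA_site", "inactive")
  bad <- setdiff(names(class_counts), allowed)
  if (length(bad)) stop("unknown element classes: ", paste(bad, collapse = ", "))
  cnt <- stats::setNames(rep(0L, length(allowed)), allowed)
  cnt[names(class_counts)] <- as.integer(class_counts)
  stages <- stage_names()
  arch <- archetype_profiles(stages, k_profiles)
  genes <- genome$genes
  exons <- genome$exons
  chrom <- genome$chromosomes$name[1]
  clen <- genome$chromosomes$length[1]

  with_seed(seed, {
    rows <- list()
    add_row <- function(class, center, strand, gene, cluster) {
      prof <- if (is.na(cluster)) rep(0, ncol(arch)) else arch[cluster, ]
      rows[[length(rows) + 1L]] <<- data.table::data.table(
        true_class = class, chrom = chrom, center = as.integer(center),
        strand = strand, target_gene_id = gene, true_cluster = cluster,
        t(stats::setNames(prof, paste0("prof_", stages))))
    }
    promoter_center <- function(g) {
      fe <- exons[exons$gene_id == g$gene_id & exons$is_first, ]
      if (!is.na(g$outron_start)) g$outron_start
      else if (g$strand == "+") fe$fivep[1] - 50L else fe$fivep[1] + 50L
    }
    for (cls in c("coding_promoter", "pseudogene_promoter")) {
      n <- cnt[[cls]]
      if (n == 0L) next
      pool <- genes[genes$biotype ==
                      if (cls == "coding_promoter") "protein_coding" else "pseudogene", ]
      if (nrow(pool) < n)
        stop("not enough ", cls, " host genes (", nrow(pool), " < ", n, ")")
      pick <- pool[sample(nrow(pool), n), ]
      for (j in seq_len(n)) {
        g <- pick[j, ]
        add_row(cls, promoter_center(g), g$strand, g$gene_id,
                sample.int(k_profiles, 1L))
      }
    }
    if (cnt[["ncRNA_site"]] > 0L) {
      pool <- genes[genes$biotype %in% NCRNA_BIOTYPES, ]
      if (nrow(pool) < cnt[["ncRNA_site"]])
        stop("not enough non-coding genes for requested ncRNA sites")
      pick <- pool[sample(nrow(pool), cnt[["ncRNA_site"]]), ]
      for (j in seq_len(nrow(pick))) {
        g <- pick[j, ]
        add_row("ncRNA_site", g$tss, g$strand, g$gene_id,
                sample.int(k_profiles, 1L))
      }
    }
    # enhancers and inactive: rejection sampling against geometry constraints
    taken <- if (length(rows)) data.table::rbindlist(rows)$center else integer(0)
    exon5 <- exons$fivep
    nc5 <- genes$tss[genes$biotype %in% NCRNA_BIOTYPES]
    place_free <- function(n, cls, with_profile) {
      placed <- 0L; tries <- 0L
      while (placed < n) {
        tries <- tries + 1L
        if (tries > 200L * n)
          stop("could not place ", cls, " elements under spacing constraints")
        pos <- sample.int(clen - 2000L, 1L) + 1000L
        if (length(exon5) && min(abs(exon5 - pos)) <= 250L) next
        if (length(nc5) && min(abs(nc5 - pos)) <= 300L) next
        if (length(taken) && min(abs(taken - pos)) <= 400L) next
        taken <<- c(taken, pos)
        add_row(cls, pos, if (cls == "enhancer") "both" else "none",
                NA_character_,
                if (with_profile) sample.int(k_profiles, 1L) else NA_integer_)
        placed <- placed + 1L
      }
    }
    place_free(cnt[["enhancer"]], "enhancer", TRUE)
    place_free(cnt[["inactive"]], "inactive", FALSE)
    el <- data.table::rbindlist(rows)
    el[, element_id := sprintf("elem_%04d", seq_len(.N))]
    data.table::setcolorder(el, c("element_id", "true_class", "chrom",
                                  "center", "strand", "target_gene_id",
                                  "true_cluster"))
    el[]
  })
}
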