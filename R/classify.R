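# Element classification: per-strand/stage labels from transcription
# evidence, promoter criteria with outron-aware gene linking, low-confidence
# rescue, strand combination, gene assignment and promoter directionality.

# total order of per-strand labels, rank 1 highest
LABEL_RANKING <- c("coding_promoter", "pseudogene_promoter", "non-coding_RNA",
                   "unassigned_promoter", "transcription_initiation",
                   "no_transcription")

#' @noRd
label_rank <- function(lab) match(lab, LABEL_RANKING)

#' Aggregate per-stage labels into the per-strand label
#'
#' The 'highest' annotation under the fixed ranking (coding_promoter first,
#' no_transcription last); associative and commutative.
#'
#' @param labels character vector of per-stage labels.
#' @return Single label.
#' @export
aggregate_across_stages <- function(labels) {
  stopifnot(all(labels %in% LABEL_RANKING))
  LABEL_RANKING[min(label_rank(labels))]
}

#' Combine strand labels into the final element type
#'
#' coding_promoter on either strand wins, then pseudogene_promoter,
#' non-coding_RNA and unassigned_promoter; transcription_initiation on
#' either strand makes a putative_enhancer; everything else is
#' other_element.
#'
#' @param fwd,rev per-strand aggregated labels.
#' @return Final element type.
#' @export
combine_strands <- function(fwd, rev) {
  top <- LABEL_RANKING[min(label_rank(fwd), label_rank(rev))]
  switch(top,
         coding_promoter = "coding_promoter",
         pseudogene_promoter = "pseudogene_promoter",
         `non-coding_RNA` = "non-coding_RNA",
         unassigned_promoter = "unassigned_promoter",
         transcription_initiation = "putative_enhancer",
         no_transcription = "other_element")
}

#' Closest eligible first exon on one strand
#'
#' Among same-strand first exons whose 5' end is no more than `max_up` bp
#' strand-relative upstream of the summit (downstream without limit), the
#' one minimizing the absolute distance to the summit.
#'
#' @param summit 0-based summit position.
#' @param strand `"+"` or `"-"`.
#' @param genome a genome model.
#' @param chrom chromosome of the site.
#' @param max_up maximum upstream distance in bp (default 250).
#' @return List `gene_id`, `fivep`, `dist` (strand-relative, negative =
#'   exon upstream of summit), or `NULL` when no exon is eligible.
#' @export
closest_first_exon <- function(summit, strand, genome, chrom = NULL,
                               max_up = 250) {
  fe <- genome$exons[genome$exons$is_first & genome$exons$strand == strand, ]
  if (!is.null(chrom)) fe <- fe[fe$chrom == chrom, ]
  if (nrow(fe) == 0L) return(NULL)
  d <- if (strand == "+") fe$fivep - summit else summit - fe$fivep
  elig <- d >= -max_up
  if (!any(elig)) return(NULL)
  fe <- fe[elig, ]; d <- d[elig]
  i <- order(abs(d), d)[1L]
  list(gene_id = fe$gene_id[i], fivep = fe$fivep[i], dist = d[i])
}

# replicate-mean coverage track for one stage/strand/chrom
#' @noRd
stage_mean_cov <- function(signal, stage, strand, chrom) {
  reps <- lapply(seq_len(signal$n_reps), function(r)
    as.numeric(signal$lcapcov[[stage]][[r]][[strand]][[chrom]]))
  Reduce(`+`, reps) / length(reps)
}

#' Evaluate the promoter criteria for one site and strand
#'
#' The four criteria: (1) in at least one stage, initiation together with
#' one elongation test, or both elongation tests; (2) the initiation mode is
#' strand-relative upstream of the closest first exon, or inside an
#' annotated 5' UTR no more than 250 bp downstream of the first-exon 5' end;
#' (3) no same-strand non-first-exon 5' end between summit and first exon;
#' (4) for distal sites (summit more than 250 bp from the first exon),
#' continuous long-cap coverage (replicate-mean >= `continuity_min_cov` in
#' at least one criterion-1 stage) from 250 bp downstream of the summit to
#' the first exon, and more than 250 bp distance from every same-strand
#' non-first exon.
#'
#' @param summit,chrom site position; `strand` tested strand.
#' @param init initiation call (list with `passed`, `mode`).
#' @param jump_passed,incr_passed logical vectors over stages.
#' @param genome genome model; `signal` bundle (for continuity coverage).
#' @param config pipeline configuration.
#' @return List: `pass`, `pass_234` (criteria 2-4 only), `gene_id`,
#'   `fivep`, `dist` (`NA` when no eligible first exon).
#' @export
promoter_criteria <- function(summit, chrom, strand, init, jump_passed,
                              incr_passed, genome, signal,
                              config = default_config()) {
  fail <- list(pass = FALSE, pass_234 = FALSE, gene_id = NA_character_,
               fivep = NA_integer_, dist = NA_integer_)
  cfe <- closest_first_exon(summit, strand, genome, chrom, config$exon_dist)
  if (is.null(cfe)) return(fail)
  c1_stages <- (init$passed & (jump_passed | incr_passed)) |
    (jump_passed & incr_passed)
  c1 <- any(c1_stages)

  mode <- init$mode
  upstream_of <- function(pos, ref) if (strand == "+") pos < ref else pos > ref
  c2 <- upstream_of(mode, cfe$fivep)
  if (!c2) {
    g <- genome$genes[genome$genes$gene_id == cfe$gene_id, ]
    if (!is.na(g$utr5_start)) {
      in_utr <- mode >= g$utr5_start & mode < g$utr5_end
      d_dn <- if (strand == "+") mode - cfe$fivep else cfe$fivep - mode
      c2 <- in_utr && d_dn <= config$exon_dist
    }
  }

  nf <- genome$exons[!genome$exons$is_first & genome$exons$strand == strand &
                       genome$exons$chrom == chrom, ]
  span <- range(c(summit, cfe$fivep))
  c3 <- !any(nf$fivep >= span[1] & nf$fivep <= span[2])

  distal <- abs(cfe$fivep - summit) > config$exon_dist
  c4 <- TRUE
  if (distal) {
    # (b) summit further than 250 bp from every same-strand non-first exon
    if (nrow(nf)) {
      dist_iv <- pmax(nf$start - summit, summit - (nf$end - 1L), 0L)
      c4 <- all(dist_iv > config$exon_dist)
    }
    # (a) continuous coverage from summit+250 (strand-rel downstream) to exon
    if (c4) {
      from <- if (strand == "+") summit + config$exon_dist else cfe$fivep
      to <- if (strand == "+") cfe$fivep else summit - config$exon_dist
      if (from <= to) {
        st_ok <- signal$stages[c1_stages]
        if (length(st_ok) == 0L) c4 <- FALSE
        else {
          idx <- (max(0L, from) + 1L):(to + 1L)
          covered <- rep(FALSE, length(idx))
          for (st in st_ok) {
            cov <- stage_mean_cov(signal, st, strand, chrom)
            covered <- covered | cov[idx] >= config$continuity_min_cov
            if (all(covered)) break
          }
          c4 <- all(covered)
        }
      }
    }
  }
  pass_234 <- c2 && c3 && c4
  list(pass = c1 && pass_234, pass_234 = pass_234, gene_id = cfe$gene_id,
       fivep = cfe$fivep, dist = cfe$dist)
}

#' Per-stage strand label for one site
#'
#' Precedence: coding/pseudogene promoter (promoter criteria with the stage
#' contributing its elongation evidence), non-coding_RNA (summit within 250
#' bp of a same-strand tRNA/snRNA/snoRNA/miRNA/rRNA 5' end),
#' unassigned_promoter (intergenic, more than 250 bp from all exons,
#' initiation and jump passed), then transcription_initiation /
#' no_transcription by initiation.
#'
#' @param promoter_pass did the site pass the promoter criteria (site level)?
#' @param stage_c1 does this stage satisfy criterion 1?
#' @param promoter_biotype biotype of the criteria gene (decides coding vs
#'   pseudogene label).
#' @param near_ncrna,intergenic,far_from_exons geometry flags.
#' @param has_init,jump_passed evidence flags for this stage.
#' @return Label string.
#' @export
strand_stage_label <- function(promoter_pass, stage_c1, promoter_biotype,
                               near_ncrna, intergenic, far_from_exons,
                               has_init, jump_passed) {
  if (promoter_pass && stage_c1) {
    return(if (identical(promoter_biotype, "pseudogene"))
      "pseudogene_promoter" else "coding_promoter")
  }
  if (near_ncrna) return("non-coding_RNA")
  if (intergenic && far_from_exons && has_init && jump_passed)
    return("unassigned_promoter")
  if (has_init) "transcription_initiation" else "no_transcription"
}

#' Classify called sites into the element taxonomy
#'
#' Driver producing one annotation row per site: per-strand aggregated
#' labels, low-confidence promoter rescue, final combined type, gene
#' assignments and promoter directionality.
#'
#' @param sites called sites (`chrom`, `start`, `end`, `summit`).
#' @param evidence from [transcription_evidence()].
#' @param genome genome model; `signal` bundle; `config` configuration.
#' @return data.table of class annotations: `annot_fwd`, `annot_rev`,
#'   `annot`, `promoter_gene_id_fwd/rev`, `low_confidence_fwd/rev`,
#'   `tss_fwd/rev`, `associated_gene_id`, `directionality`.
#' @export
classify_elements <- function(sites, evidence, genome, signal,
                              config = default_config()) {
  n <- nrow(sites)
  stages <- evidence$stages
  genes <- genome$genes
  exons <- genome$exons
  nc5 <- genes[genes$biotype %in% NCRNA_BIOTYPES,
               c("chrom", "strand", "tss")]
  ann <- data.table::copy(sites)
  res <- list()
  for (strand in c("+", "-")) {
    sname <- if (strand == "+") "fwd" else "rev"
    init_tab <- evidence$init[[strand]]
    jump_pass <- vapply(stages, function(st)
      evidence$jump[[strand]][[st]]$passed, logical(n))
    incr_pass <- vapply(stages, function(st)
      evidence$incr[[strand]][[st]]$passed, logical(n))
    if (n == 1L) { jump_pass <- matrix(jump_pass, 1L); incr_pass <- matrix(incr_pass, 1L) }
    crit <- vector("list", n)
    agg <- character(n)
    for (i in seq_len(n)) {
      init_i <- list(passed = init_tab$passed[i], mode = init_tab$mode[i])
      crit[[i]] <- promoter_criteria(sites$summit[i], sites$chrom[i], strand,
                                     init_i, jump_pass[i, ], incr_pass[i, ],
                                     genome, signal, config)
      c1_stages <- (init_i$passed & (jump_pass[i, ] | incr_pass[i, ])) |
        (jump_pass[i, ] & incr_pass[i, ])
      bt <- if (!is.na(crit[[i]]$gene_id))
        genes$biotype[match(crit[[i]]$gene_id, genes$gene_id)] else NA_character_
      nc_i <- nc5[nc5$chrom == sites$chrom[i] & nc5$strand == strand, ]
      near_nc <- nrow(nc_i) > 0 && min(abs(nc_i$tss - sites$summit[i])) <= config$exon_dist
      ex_i <- exons[exons$chrom == sites$chrom[i], ]
      g_i <- genes[genes$chrom == sites$chrom[i], ]
      intergenic <- !any(sites$summit[i] >= g_i$start & sites$summit[i] < g_i$end)
      far_ex <- !nrow(ex_i) ||
        all(pmax(ex_i$start - sites$summit[i],
                 sites$summit[i] - (ex_i$end - 1L), 0L) > config$exon_dist)
      labs <- vapply(seq_along(stages), function(si)
        strand_stage_label(crit[[i]]$pass, c1_stages[si], bt, near_nc,
                           intergenic, far_ex, init_tab$passed[i],
                           jump_pass[i, si]), character(1))
      agg[i] <- aggregate_across_stages(labs)
    }
    res[[sname]] <- list(crit = crit, agg = agg, init = init_tab)
  }

  # low-confidence rescue per gene without a promoter
  low_conf <- list(fwd = rep(FALSE, n), rev = rep(FALSE, n))
  prom_gene <- list(fwd = rep(NA_character_, n), rev = rep(NA_character_, n))
  for (sname in c("fwd", "rev")) {
    crit <- res[[sname]]$crit
    agg <- res[[sname]]$agg
    prom_gene[[sname]] <- ifelse(
      agg %in% c("coding_promoter", "pseudogene_promoter"),
      vapply(crit, `[[`, character(1), "gene_id"), NA_character_)
  }
  assigned <- stats::na.omit(c(prom_gene$fwd, prom_gene$rev))
  cand_genes <- genes[genes$biotype %in% c("protein_coding", "pseudogene") &
                        !(genes$gene_id %in% assigned), ]
  for (gi in seq_len(nrow(cand_genes))) {
    g <- cand_genes[gi, ]
    sname <- if (g$strand == "+") "fwd" else "rev"
    crit <- res[[sname]]$crit
    elig <- which(vapply(seq_len(n), function(i) {
      ci <- crit[[i]]
      if (!identical(ci$gene_id, g$gene_id) || !ci$pass_234) return(FALSE)
      g_i <- genes[genes$chrom == sites$chrom[i], ]
      intergenic <- !any(sites$summit[i] >= g_i$start & sites$summit[i] < g_i$end)
      intergenic || abs(ci$dist) <= config$exon_dist
    }, logical(1)))
    if (!length(elig)) next
    lfc <- evidence$max_jump_lfc[[g$strand]][elig]
    best <- max(lfc)
    if (best <= config$rescue_lfc) next
    top <- elig[lfc == best]
    if (length(top) > 1L) {
      dd <- abs(vapply(crit[top], `[[`, integer(1), "dist"))
      top <- top[order(dd, sites$start[top])]
    }
    i <- top[1L]
    # never demote an existing higher-ranked assignment
    new_lab <- if (g$biotype == "pseudogene") "pseudogene_promoter" else "coding_promoter"
    if (label_rank(res[[sname]]$agg[i]) > label_rank(new_lab)) {
      res[[sname]]$agg[i] <- new_lab
      prom_gene[[sname]][i] <- g$gene_id
      low_conf[[sname]][i] <- TRUE
    }
  }

  ann[, annot_fwd := res$fwd$agg]
  ann[, annot_rev := res$rev$agg]
  ann[, annot := mapply(combine_strands, annot_fwd, annot_rev)]
  ann[, promoter_gene_id_fwd := prom_gene$fwd]
  ann[, promoter_gene_id_rev := prom_gene$rev]
  ann[, low_confidence_fwd := low_conf$fwd]
  ann[, low_confidence_rev := low_conf$rev]
  ann[, tss_fwd := res$fwd$init$mode]
  ann[, tss_rev := res$rev$init$mode]
  ann <- assign_genes(ann, genome)
  dir_res <- promoter_directionality(ann, genome)
  ann[, directionality := dir_res$directionality]
  ann[]
}

#' Assign genes to non-promoter elements
#'
#' Putative enhancers are associated with every gene whose span from its
#' most upstream promoter to its gene end overlaps the site; unassigned
#' promoters and other elements with every gene whose body or outron
#' overlaps the site.  Multiple overlaps are all reported (comma-separated).
#'
#' @param ann annotation table (with per-strand promoter gene ids).
#' @param genome genome model.
#' @return `ann` with an `associated_gene_id` column.
#' @export
assign_genes <- function(ann, genome) {
  genes <- genome$genes
  # most upstream promoter summit per gene
  prom <- data.table::rbindlist(list(
    data.table::data.table(gene_id = ann$promoter_gene_id_fwd, summit = ann$summit),
    data.table::data.table(gene_id = ann$promoter_gene_id_rev, summit = ann$summit)))
  prom <- prom[!is.na(gene_id)]
  spans <- genes[prom, on = "gene_id", nomatch = NULL]
  if (nrow(spans)) {
    spans[, `:=`(sp_start = ifelse(strand == "+", pmin(summit, start), start),
                 sp_end = ifelse(strand == "+", end, pmax(summit + 1L, end)))]
    spans <- spans[, .(sp_start = min(sp_start), sp_end = max(sp_end)),
                   by = .(gene_id, chrom)]
  }
  # gene body + outron span for unassigned/other overlap
  body <- data.table::copy(genes)
  body[, `:=`(b_start = ifelse(!is.na(outron_start) & strand == "+",
                               pmin(outron_start, start), start),
              b_end = ifelse(!is.na(outron_start) & strand == "-",
                             pmax(outron_start + 1L, end), end))]
  assoc <- character(nrow(ann))
  for (i in seq_len(nrow(ann))) {
    type <- ann$annot[i]
    hits <- character(0)
    if (type == "putative_enhancer" && nrow(spans)) {
      sp <- spans[spans$chrom == ann$chrom[i], ]
      hits <- sp$gene_id[sp$sp_start < ann$end[i] & sp$sp_end > ann$start[i]]
    } else if (type %in% c("unassigned_promoter", "other_element")) {
      b <- body[body$chrom == ann$chrom[i], ]
      hits <- b$gene_id[b$b_start < ann$end[i] & b$b_end > ann$start[i]]
    }
    assoc[i] <- paste(sort(unique(hits)), collapse = ",")
  }
  ann[, associated_gene_id := assoc]
  ann
}

#' Promoter directionality and per-gene element counts
#'
#' An element is a divergent promoter when it is a coding promoter on both
#' strands for two distinct, oppositely oriented genes; a coding promoter on
#' one strand (or for a single gene) is unidirectional.
#'
#' @param ann annotation table.
#' @param genome genome model.
#' @return List: `directionality` (per element), `per_gene` (data.table:
#'   gene_id, n_promoters, n_enhancers).
#' @export
promoter_directionality <- function(ann, genome) {
  genes <- genome$genes
  d <- vapply(seq_len(nrow(ann)), function(i) {
    cf <- ann$annot_fwd[i] == "coding_promoter"
    cr <- ann$annot_rev[i] == "coding_promoter"
    if (!cf && !cr) return("not_promoter")
    if (cf && cr) {
      gf <- ann$promoter_gene_id_fwd[i]; gr <- ann$promoter_gene_id_rev[i]
      if (!is.na(gf) && !is.na(gr) && gf != gr) {
        sf <- genes$strand[match(gf, genes$gene_id)]
        sr <- genes$strand[match(gr, genes$gene_id)]
        if (sf != sr) return("divergent")
      }
      return("unidirectional")
    }
    "unidirectional"
  }, character(1))
  prom_counts <- table(stats::na.omit(c(ann$promoter_gene_id_fwd,
                                        ann$promoter_gene_id_rev)))
  enh <- unlist(strsplit(ann$associated_gene_id[ann$annot == "putative_enhancer"],
                         ",", fixed = TRUE))
  enh_counts <- table(enh[nzchar(enh)])
  per_gene <- data.table::data.table(gene_id = genes$gene_id)
  per_gene[, n_promoters := as.integer(prom_counts[gene_id])]
  per_gene[, n_enhancers := as.integer(enh_counts[gene_id])]
  per_gene[is.na(n_promoters), n_promoters := 0L]
  per_gene[is.na(n_enhancers), n_enhancers := 0L]
  list(directionality = d, per_gene = per_gene[])
}
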