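# Promoter criteria, label logic, rescue, gene assignment, directionality
# on a hand-built toy genome (see helper-fixtures.R for its geometry).

test_that("closest_first_exon applies the 250-bp upstream limit", {
  g <- toy_genome()
  # summit 5700: geneA first-exon 5' at 5800 is 100 bp downstream -> eligible
  cf <- closest_first_exon(5700L, "+", g, "chr")
  expect_equal(cf$gene_id, "geneA")
  expect_equal(cf$dist, 100L)
  # only candidate 300 bp upstream -> absent
  g_only_first <- toy_genome()
  g_only_first$exons <- g_only_first$exons[
    g_only_first$exons$gene_id == "geneA" & g_only_first$exons$is_first, ]
  expect_null(closest_first_exon(5800L + 300L, "+", g_only_first, "chr"))
  # two candidates at 50 and 150 bp downstream -> the closer one
  g2 <- toy_genome()
  extra <- data.table::data.table(start = 5850L, end = 6000L, is_first = TRUE,
                                  gene_id = "geneX", strand = "+",
                                  fivep = 5850L, chrom = "chr")
  g2$exons <- rbind(g2$exons, extra)
  cf2 <- closest_first_exon(5750L, "+", g2, "chr")
  expect_equal(cf2$gene_id, "geneA")   # 5800 is 50 bp away, 5850 is 100
})

test_that("promoter criteria: proximal pass, exon block, coverage gap", {
  g <- toy_genome()
  sig <- toy_signal(cov_value = 2)
  cfg <- default_config()
  init <- list(passed = TRUE, mode = 5750L)
  jp <- c(TRUE, FALSE); ip <- c(FALSE, FALSE)

  # proximal site at 5750 (50 bp from first exon), initiation + jump -> pass
  r <- promoter_criteria(5750L, "chr", "+", init, jp, ip, g, sig, cfg)
  expect_true(r$pass)
  expect_equal(r$gene_id, "geneA")

  # distal site at the outron start (800 bp), continuous coverage -> pass
  rd <- promoter_criteria(5000L, "chr", "+", list(passed = TRUE, mode = 4990L),
                          jp, ip, g, sig, cfg)
  expect_true(rd$pass)

  # a 1-bp coverage gap inside the outron span breaks criterion 4a
  sig_gap <- toy_signal(cov_value = 2, gap = 5400L)
  rg <- promoter_criteria(5000L, "chr", "+", list(passed = TRUE, mode = 4990L),
                          jp, ip, g, sig_gap, cfg)
  expect_false(rg$pass)
  expect_false(rg$pass_234)

  # non-first exon 5' end between summit and first exon -> criterion 3 fails
  g3 <- toy_genome()
  blocker <- data.table::data.table(start = 5600L, end = 5700L,
                                    is_first = FALSE, gene_id = "geneA",
                                    strand = "+", fivep = 5600L, chrom = "chr")
  g3$exons <- rbind(g3$exons, blocker)
  rb <- promoter_criteria(5000L, "chr", "+", list(passed = TRUE, mode = 4990L),
                          jp, ip, g3, sig, cfg)
  expect_false(rb$pass)

  # criterion 1 fails without any elongation evidence
  r0 <- promoter_criteria(5750L, "chr", "+", init, c(FALSE, FALSE), ip, g,
                          sig, cfg)
  expect_false(r0$pass)
  expect_true(r0$pass_234)

  # initiation mode downstream of the first exon but inside the UTR passes
  ru <- promoter_criteria(5750L, "chr", "+", list(passed = TRUE, mode = 5900L),
                          jp, ip, g, sig, cfg)
  expect_true(ru$pass)
  # mode downstream and outside any UTR fails criterion 2 (minus-strand gene)
  rv <- promoter_criteria(11350L, "chr", "-", list(passed = TRUE, mode = 11200L),
                          jp, ip, g, sig, cfg)
  expect_false(rv$pass)
})

test_that("label aggregation and strand combination follow the ranking", {
  expect_equal(aggregate_across_stages(c(rep("no_transcription", 10),
                                         "coding_promoter")),
               "coding_promoter")
  expect_equal(aggregate_across_stages(rep("no_transcription", 3)),
               "no_transcription")
  expect_equal(aggregate_across_stages(c("transcription_initiation",
                                         "unassigned_promoter")),
               "unassigned_promoter")
  expect_equal(combine_strands("coding_promoter", "transcription_initiation"),
               "coding_promoter")
  expect_equal(combine_strands("transcription_initiation", "no_transcription"),
               "putative_enhancer")
  expect_equal(combine_strands("no_transcription", "no_transcription"),
               "other_element")
  # order-invariance (associative/commutative min over a total order)
  labs <- c("coding_promoter", "pseudogene_promoter", "non-coding_RNA",
            "unassigned_promoter", "transcription_initiation",
            "no_transcription")
  set.seed(4)
  for (i in 1:20) {
    x <- sample(labs, sample(2:6, 1), replace = TRUE)
    expect_equal(aggregate_across_stages(x),
                 aggregate_across_stages(sample(x)))
    expect_equal(combine_strands(x[1], x[2]), combine_strands(x[2], x[1]))
  }
})

test_that("strand_stage_label precedence", {
  expect_equal(strand_stage_label(TRUE, TRUE, "protein_coding", FALSE, FALSE,
                                  FALSE, TRUE, TRUE), "coding_promoter")
  expect_equal(strand_stage_label(TRUE, TRUE, "pseudogene", FALSE, FALSE,
                                  FALSE, TRUE, TRUE), "pseudogene_promoter")
  # near a tRNA 5' end without a promoter pass
  expect_equal(strand_stage_label(FALSE, FALSE, NA, TRUE, FALSE, FALSE,
                                  FALSE, FALSE), "non-coding_RNA")
  # intergenic, far from exons, initiation + jump
  expect_equal(strand_stage_label(FALSE, FALSE, NA, FALSE, TRUE, TRUE,
                                  TRUE, TRUE), "unassigned_promoter")
  # remaining: initiation only, inside a gene body
  expect_equal(strand_stage_label(FALSE, FALSE, NA, FALSE, FALSE, FALSE,
                                  TRUE, FALSE), "transcription_initiation")
  expect_equal(strand_stage_label(FALSE, FALSE, NA, FALSE, FALSE, FALSE,
                                  FALSE, FALSE), "no_transcription")
})

test_that("end-to-end classification recovers planted truth (small fixture)", {
  res <- small_run()
  el <- res$dataset$elements
  ann <- res$annotation
  pr <- el[el$true_class == "coding_promoter"]
  hit <- vapply(seq_len(nrow(pr)), function(i) {
    j <- which(abs(ann$summit - pr$center[i]) <= 75)
    length(j) > 0 && any(ann$annot[j] == "coding_promoter" &
      (ann$promoter_gene_id_fwd[j] %in% pr$target_gene_id[i] |
       ann$promoter_gene_id_rev[j] %in% pr$target_gene_id[i]))
  }, logical(1))
  expect_gte(mean(hit), 0.85)
  en <- el[el$true_class == "enhancer"]
  ehit <- vapply(seq_len(nrow(en)), function(i) {
    j <- which(abs(ann$summit - en$center[i]) <= 75)
    length(j) > 0 && any(ann$annot[j] == "putative_enhancer")
  }, logical(1))
  expect_gte(mean(ehit), 0.9)
  # no element promoter- and enhancer-assigned to the same gene+strand
  enh_genes <- unlist(strsplit(ann$associated_gene_id[
    ann$annot == "putative_enhancer"], ","))
  for (i in which(ann$annot == "coding_promoter")) {
    gf <- ann$promoter_gene_id_fwd[i]
    if (!is.na(gf))
      expect_false(nzchar(ann$associated_gene_id[i]) &&
                     gf %in% strsplit(ann$associated_gene_id[i], ",")[[1]])
  }
})

test_that("directionality distinguishes divergent and unidirectional", {
  g <- toy_genome()
  ann <- data.table::data.table(
    chrom = "chr", start = c(100L, 300L, 500L), end = c(251L, 451L, 651L),
    summit = c(175L, 375L, 575L),
    annot_fwd = c("coding_promoter", "coding_promoter", "coding_promoter"),
    annot_rev = c("no_transcription", "coding_promoter", "coding_promoter"),
    annot = "coding_promoter",
    promoter_gene_id_fwd = c("geneA", "geneA", "geneA"),
    promoter_gene_id_rev = c(NA, "geneA", "geneB"),
    associated_gene_id = "")
  d <- promoter_directionality(ann, g)$directionality
  expect_equal(d, c("unidirectional", "unidirectional", "divergent"))
})

test_that("rescue assigns a single low-confidence promoter when lfc > 1", {
  g <- toy_genome()
  sig <- toy_signal(cov_value = 2)
  stages <- sig$stages
  # one site 50 bp upstream of geneA's first exon; no initiation, jump
  # never passes, but criteria 2-4 hold (best-guess mode in the UTR)
  sites <- data.table::data.table(chrom = "chr", start = 5675L, end = 5826L,
                                  summit = 5750L)
  mk_ev <- function(max_lfc) {
    ev <- list(stages = stages, jump = list(), incr = list(), init = list(),
               max_jump_lfc = list())
    for (sd in c("+", "-")) {
      ev$jump[[sd]] <- stats::setNames(lapply(stages, function(s)
        data.table::data.table(lfc = if (sd == "+") max_lfc else 0,
                               p = 1, padj = 1, passed = FALSE)), stages)
      ev$incr[[sd]] <- stats::setNames(lapply(stages, function(s)
        data.table::data.table(passed = FALSE)), stages)
      ev$init[[sd]] <- data.table::data.table(
        passed = FALSE,
        mode = if (sd == "+") 5810L else 5690L,
        provenance = "best_guess")
      ev$max_jump_lfc[[sd]] <- if (sd == "+") max_lfc else 0
    }
    ev
  }
  ann <- classify_elements(data.table::copy(sites), mk_ev(1.2), g, sig)
  expect_equal(ann$annot, "coding_promoter")
  expect_equal(ann$promoter_gene_id_fwd, "geneA")
  expect_true(ann$low_confidence_fwd)

  # max lfc below 1: no assignment
  ann2 <- classify_elements(data.table::copy(sites), mk_ev(0.9), g, sig)
  expect_false(ann2$annot %in% c("coding_promoter", "pseudogene_promoter"))
  expect_false(ann2$low_confidence_fwd)
})
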