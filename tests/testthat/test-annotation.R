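test_that("novel-transcript filter applies length and exon rules", {
  t200 <- make_tm("t200", cbind(c(1, 201), c(100, 300)))   # spliced 200
  t500_1 <- make_tm("t500_1", cbind(1, 500))               # 1 exon
  t500_2 <- make_tm("t500_2", cbind(c(1, 301), c(250, 550))) # 2 ex, 500 nt
  kept <- filter_novel_transcripts(list(t200, t500_1, t500_2))
  expect_equal(vapply(kept, function(m) m$id, character(1)), "t500_2")
  # literal '>2 exons' reading via the switch
  expect_length(filter_novel_transcripts(list(t500_2), min_exons = 3), 0)
})

test_that("lncRNA classifier follows the five-rule precedence", {
  g <- ref_gene("+") # exons 1001-1500, 2301-2800, 3601-4100
  genes <- list(g)

  sense <- make_tm("s", cbind(c(1400, 1700), c(1550, 1800)), "+")
  expect_equal(classify_lncrna(sense, genes), "sense")
  # same exonic overlap but opposite strand -> antisense wins over intronic
  anti <- make_tm("a", cbind(c(1400, 1700), c(1550, 1800)), "-")
  expect_equal(classify_lncrna(anti, genes), "antisense")
  # fully inside intron 1 (1501-2300), same strand
  intr <- make_tm("i", cbind(c(1600, 1900), c(1750, 2050)), "+")
  expect_equal(classify_lncrna(intr, genes), "intronic")
  # same span, opposite strand: still inside the gene span -> antisense
  intr_as <- make_tm("ia", cbind(c(1600, 1900), c(1750, 2050)), "-")
  expect_equal(classify_lncrna(intr_as, genes), "antisense")

  # derived example: a '-' strand lncRNA whose TSS (its end) sits 500 nt
  # upstream of the coding TSS at 1001 -> bidirectional; the same shape
  # 1500 nt away -> intergenic
  bid <- make_tm("b", cbind(c(200, 400), c(350, 501)), "-")
  expect_equal(classify_lncrna(bid, genes), "bidirectional")
  g2 <- make_gene("g2", cbind(c(10001, 11301, 12601),
                              c(10500, 11800, 13100)), "+")
  far <- make_tm("f", cbind(c(8300, 8420), c(8400, 8501)), "-") # TSS 8501
  expect_equal(classify_lncrna(far, list(g2)), "intergenic") # 1500 nt away
  near <- make_tm("n", cbind(c(9300, 9420), c(9400, 9501)), "-") # TSS 9501
  expect_equal(classify_lncrna(near, list(g2)), "bidirectional")
  # same-strand upstream neighbor is not divergent -> intergenic
  tandem <- make_tm("t", cbind(c(200, 400), c(350, 501)), "+")
  expect_equal(classify_lncrna(tandem, genes), "intergenic")

  expect_error(classify_lncrna(make_tm("x", cbind(1, 300), chrom = "chrX"),
                               genes), "chromosome")
})

test_that("classifier is a total function on generated fixtures", {
  for (seed in 1:3) {
    models <- generate_gene_models(tiny_config(seed))
    cats <- classify_lncrnas(models$lncrnas, models$genes)
    expect_true(all(cats %in%
                      c("sense", "antisense", "intronic", "bidirectional",
                        "intergenic")))
    expect_length(cats, length(models$lncrnas))
    # round trip against the planted categories
    expect_equal(cats[names(models$lnc_categories)],
                 models$lnc_categories)
  }
})

test_that("sRNA cascade respects the printed priority order", {
  tag <- srna_tag("ACGUACGUACGUACGUACGU", count = 3,
                  matches = data.frame(chromosome = "chr1",
                                       start = 100, end = 119))
  tracks <- list(
    rrna_etc = list(intervals = data.frame(chromosome = "chr1",
                                           start = 50, end = 150)),
    exon = list(intervals = data.frame(chromosome = "chr1",
                                       start = 90, end = 200))
  )
  expect_equal(annotate_srna(tag, tracks), "rrna_etc")
  # priority beats listing order: permuting the track list changes nothing
  expect_equal(annotate_srna(tag, rev(tracks)), "rrna_etc")
  expect_equal(annotate_srna(tag, list()), "unannotated")

  # one internal substitution against a known mature miRNA, also matching
  # a repeat track -> existing_mirna_edit wins by priority
  mature <- "UGAGGUAGUAGGUUGUAUAGUU"
  edited <- "UGAGGUAGUACGUUGUAUAGUU" # position 11 substituted
  tag2 <- srna_tag(edited, matches = data.frame(chromosome = "chr2",
                                                start = 5, end = 26))
  tracks2 <- list(
    existing_mirna = list(sequences = mature),
    `repeat` = list(intervals = data.frame(chromosome = "chr2",
                                           start = 1, end = 100))
  )
  expect_equal(annotate_srna(tag2, tracks2), "existing_mirna_edit")
  # the exact mature sequence is existing_mirna, not an edit
  expect_equal(annotate_srna(srna_tag(mature), tracks2), "existing_mirna")
  expect_error(annotate_srna(tag2, list(bogus = list())), "unknown")
})

test_that("length distribution is count-weighted with small-length ties", {
  tags <- list(srna_tag(strrep("A", 21)),
               srna_tag(strrep("C", 22)),
               srna_tag(strrep("G", 22)))
  expect_equal(length_distribution(tags)$mode, 22L)
  # uniform -> smallest length wins the tie
  tags_u <- list(srna_tag(strrep("A", 23)), srna_tag(strrep("C", 21)),
                 srna_tag(strrep("G", 22)))
  expect_equal(length_distribution(tags_u)$mode, 21L)
  # count weighting can override tag multiplicity
  tags_w <- list(srna_tag(strrep("A", 21), count = 10),
                 srna_tag(strrep("C", 23)), srna_tag(strrep("G", 23)))
  expect_equal(length_distribution(tags_w)$mode, 21L)
  expect_error(length_distribution(list()), "no tags")
})
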