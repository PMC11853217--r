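make_ann <- function() {
  tibble::tibble(
    chrom = "chr1",
    start = c(100L, 150L, 300L, 260L, 360L, 500L, 550L, 700L),
    end = c(200L, 250L, 360L, 300L, 420L, 550L, 700L, 800L),
    name = "f", score = 0L, strand = "+",
    feature_class = c("promoter", "island", "island", "shore", "shore",
                      "promoter", "exon", "intron"),
    gene_id = c("gA", NA, NA, NA, NA, "gB", "gB", "gB")
  )
}

test_that("context assignment follows the precedence rules", {
  ann <- make_ann()
  tb <- tibble::tibble(chrom = "chr1",
                       pos = c(160L, 120L, 320L, 280L, 600L, 750L, 950L))
  ctx <- assign_context(tb, ann)
  # 160 is in both promoter [100,200) and island [150,250): promoter wins
  expect_identical(ctx$context,
                   c("promoter", "promoter", "island", "shore", "exon",
                     "intron", "intergenic"))
  expect_identical(ctx$gene_id[1], "gA")
  expect_true(is.na(ctx$gene_id[7]))
})

test_that("context assignment agrees with a brute-force interval scan", {
  set.seed(51)
  ann <- simulate_annotation(1:5000, n_genes = 15L, seed = 51)
  pos <- sort(sample.int(5500, 400))
  tb <- tibble::tibble(chrom = "chrSim", pos = pos)
  ctx <- assign_context(tb, ann)
  precedence <- c("promoter", "island", "shore", "shelf", "exon", "intron")
  brute <- vapply(pos, function(p) {
    hit <- ann$feature_class[ann$start < p & p <= ann$end]
    if (length(hit) == 0) return("intergenic")
    precedence[min(match(hit, precedence))]
  }, character(1))
  expect_identical(ctx$context, brute)
})

test_that("malformed annotation intervals fail at load", {
  bad <- make_ann()
  bad$end[1] <- bad$start[1]
  expect_error(validate_annotation(bad), class = "methaft_validation_error")
  bad2 <- make_ann()
  bad2$feature_class[1] <- "enhancer"
  expect_error(validate_annotation(bad2), class = "methaft_validation_error")
})

test_that("genes with exons on both strands are dropped at load", {
  ann <- make_ann()
  extra <- ann[7, ]
  extra$strand <- "-"
  ann2 <- dplyr::bind_rows(ann, extra)
  out <- validate_annotation(ann2)
  expect_identical(attr(out, "dropped_genes"), 1L)
  expect_false(any(out$gene_id %in% "gB", na.rm = TRUE))
})

test_that("DMG calling aggregates promoter DMCs with majority direction", {
  ctx <- tibble::tibble(
    chrom = "chr1", pos = 1:8,
    call = c("hyper", "hyper", "hyper", "NDMC", "hypo", "hyper", "NDMC", "hypo"),
    context = c("promoter", "promoter", "promoter", "promoter", "promoter",
                "promoter", "island", "promoter"),
    gene_id = c("g1", "g1", "g1", "g2", "g3", "g3", NA, "g3")
  )
  dmg <- call_dmgs(ctx)
  expect_identical(sort(dmg$gene_id), c("g1", "g3"))
  expect_identical(dmg$direction[dmg$gene_id == "g1"], "hyper")
  # g3: 1 hyper + 2 hypo -> hypo
  expect_identical(dmg$direction[dmg$gene_id == "g3"], "hypo")
  # counts recompute from the DMC table
  expect_identical(dmg$n_dmc[dmg$gene_id == "g1"],
                   sum(ctx$gene_id %in% "g1" & ctx$call != "NDMC" &
                         ctx$context == "promoter"))
  # tie -> mixed
  ctx2 <- ctx[5:6, ]
  dmg2 <- call_dmgs(ctx2)
  expect_identical(dmg2$direction, "mixed")
  # gene with zero significant promoter CpGs is not a DMG
  expect_false("g2" %in% dmg$gene_id)
})

test_that("agreement percentages reproduce the worked examples", {
  # perfect agreement: both capture percentages are 100
  perfect <- agreement_percentages(matrix(c(10, 0, 0, 5), 2))
  expect_equal(perfect$pct_of_total[perfect$cell == "pct_of_B_DMC_captured"], 100)
  expect_equal(perfect$pct_of_total[perfect$cell == "pct_of_B_NDMC_captured"], 100)
  # cells sum to the co-tested total
  cnt <- matrix(c(50, 7, 3, 12), 2)
  out <- agreement_percentages(cnt)
  expect_equal(sum(out$count[1:4]), sum(cnt))
  expect_equal(sum(out$pct_of_total[1:4]), 100, tolerance = 0.02)
})

test_that("agreement_table cross-tabulates co-tested positions only", {
  base <- tibble::tibble(chrom = "c", pos = 1:6,
                         testable = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))
  a <- dplyr::mutate(base, call = c("hyper", "NDMC", "hypo", "NDMC", "hyper", "NDMC"))
  b <- dplyr::mutate(base, call = c("hyper", "NDMC", "NDMC", "hyper", "hyper", "hyper"))
  at <- agreement_table(a, b)
  expect_identical(sum(at$counts), 5L)          # untestable row excluded
  expect_identical(at$counts["DMC", "DMC"], 2L) # positions 1 and 5
  expect_identical(at$counts["DMC", "NDMC"], 1L)
  mismatch <- dplyr::mutate(base, pos = pos + 1L, call = a$call)
  expect_error(agreement_table(a, mismatch), class = "methaft_validation_error")
})

test_that("overlap summary computes direction-consistency shares", {
  a <- tibble::tibble(gene_id = paste0("g", 1:6),
                      direction = c("hyper", "hyper", "hypo", "hyper", "hypo", "hyper"))
  b <- tibble::tibble(gene_id = paste0("g", c(1:4, 7)),
                      direction = c("hyper", "hypo", "hypo", "hyper", "hyper"))
  ov <- overlap_summary(a, b)
  expect_identical(ov$shares$n_overlap, 4L)
  expect_identical(ov$shares$n_consistent, 3L)
  expect_equal(ov$shares$pct_consistent, 75.0)
  expect_equal(ov$shares$pct_hyper, round(100 * 2 / 3, 1))
  # disjoint sets: NA shares
  dis <- overlap_summary(a, tibble::tibble(gene_id = "gx", direction = "hyper"))
  expect_identical(dis$shares$n_overlap, 0L)
  expect_true(is.na(dis$shares$pct_consistent))
})

test_that("venn counts satisfy inclusion-exclusion on toy sets", {
  sets <- list(A = c("a", "b", "c"), B = c("b", "c", "d"), C = c("c", "e"))
  vc <- venn_counts(sets)
  get <- function(r) vc$count[vc$region == r]
  expect_identical(get("A"), 1L)        # only a
  expect_identical(get("A&B"), 1L)      # only b
  expect_identical(get("A&B&C"), 1L)    # c
  expect_identical(get("C"), 1L)        # e
  expect_identical(sum(vc$count), 5L)   # |A u B u C|
  # two-set identity: |A| = exclusive(A) + shared
  vc2 <- venn_counts(sets[1:2])
  expect_identical(vc2$count[vc2$region == "A"] + vc2$count[vc2$region == "A&B"],
                   3L)
})
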