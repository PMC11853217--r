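feature_classes <- c("promoter", "island", "shore", "shelf", "exon", "intron")
context_precedence <- c(feature_classes, "intergenic")

#' Read a BED6+2 feature annotation
#'
#' Expects tab-separated columns `chrom`, `start` (0-based), `end`, `name`,
#' `score`, `strand`, `feature_class`, `gene_id` (with a header line).
#' Intervals are validated (`start < end`, known feature classes), and genes
#' whose exons lie on both strands or on more than one reference sequence
#' are dropped, with the count recorded in the `dropped_genes` attribute.
#'
#' @param path TSV path.
#' @return A validated annotation tibble.
#' @export
read_annotation <- function(path) {
  ann <- readr::read_tsv(path, show_col_types = FALSE)
  validate_annotation(ann)
}

#' @rdname read_annotation
#' @param ann An annotation tibble in BED6+2 layout (e.g. from
#'   [simulate_annotation()]).
#' @export
validate_annotation <- function(ann) {
  need <- c("chrom", "start", "end", "feature_class", "gene_id")
  if (!all(need %in% names(ann)))
    stop_validation("annotation must have chrom, start, end, feature_class, gene_id")
  if (any(ann$start >= ann$end))
    stop_validation("annotation intervals must satisfy start < end")
  if (!all(ann$feature_class %in% feature_classes))
    stop_validation(paste("feature_class must be one of:",
                          paste(feature_classes, collapse = ", ")))
  if (!"strand" %in% names(ann)) ann$strand <- "+"
  # drop genes with exons on both strands or on multiple reference sequences
  exons <- ann |> dplyr::filter(.data$feature_class == "exon",
                                !is.na(.data$gene_id))
  bad <- exons |>
    dplyr::group_by(.data$gene_id) |>
    dplyr::summarise(n_strand = dplyr::n_distinct(.data$strand),
                     n_chrom = dplyr::n_distinct(.data$chrom)) |>
    dplyr::filter(.data$n_strand > 1 | .data$n_chrom > 1) |>
    dplyr::pull(.data$gene_id)
  out <- ann |> dplyr::filter(is.na(.data$gene_id) | !(.data$gene_id %in% bad))
  attr(out, "dropped_genes") <- length(bad)
  out
}

# GRanges from 0-based half-open BED rows (internal convention)
ann_granges <- function(ann) {
  GenomicRanges::GRanges(
    seqnames = ann$chrom,
    ranges = IRanges::IRanges(start = ann$start + 1L, end = ann$end)
  )
}

#' Assign each CpG a single genomic context
#'
#' Each CpG receives exactly one context by the precedence
#' promoter > island > shore > shelf > exon > intron; positions outside all
#' intervals fall through to `"intergenic"`. Promoter/exon/intron hits also
#' carry the overlapping gene id (first by precedence order, ties broken by
#' interval order).
#'
#' @param dmc_table A tibble with `chrom` and 1-based `pos` columns (e.g.
#'   from [call_dmcs()]).
#' @param annotation A validated annotation tibble (see
#'   [validate_annotation()]).
#' @return `dmc_table` with `context` and `gene_id` columns appended.
#' @export
assign_context <- function(dmc_table, annotation) {
  annotation <- validate_annotation(annotation)
  gr_pos <- GenomicRanges::GRanges(
    seqnames = dmc_table$chrom,
    ranges = IRanges::IRanges(start = dmc_table$pos, width = 1L)
  )
  n <- nrow(dmc_table)
  context <- rep("intergenic", n)
  gene_id <- rep(NA_character_, n)
  unassigned <- rep(TRUE, n)
  for (fc in feature_classes) {
    sub <- annotation[annotation$feature_class == fc, , drop = FALSE]
    if (nrow(sub) == 0 || !any(unassigned)) next
    hits <- GenomicRanges::findOverlaps(gr_pos, ann_granges(sub),
                                        select = "first")
    hit <- !is.na(hits) & unassigned
    context[hit] <- fc
    gene_id[hit] <- sub$gene_id[hits[hit]]
    unassigned[hit] <- FALSE
  }
  dplyr::bind_cols(dmc_table, tibble::tibble(context = context,
                                             gene_id = gene_id))
}

#' Call differentially methylated genes from promoter DMCs
#'
#' A gene is a DMG when at least `min_promoter_dmcs` of its promoter CpGs
#' are significant calls; the gene's direction is the majority direction of
#' those calls, with ties reported as `"mixed"`.
#'
#' @param context_table Output of [assign_context()] on a DMC table.
#' @param min_promoter_dmcs Minimum significant promoter CpGs (default 1).
#' @return A `dmg_table` tibble: `gene_id`, `n_promoter_cpgs`, `n_dmc`,
#'   `n_hyper`, `n_hypo`, `direction`.
#' @export
call_dmgs <- function(context_table, min_promoter_dmcs = 1L) {
  prom <- context_table |>
    dplyr::filter(.data$context == "promoter", !is.na(.data$gene_id))
  out <- prom |>
    dplyr::group_by(gene_id = .data$gene_id) |>
    dplyr::summarise(
      n_promoter_cpgs = dplyr::n(),
      n_hyper = sum(.data$call == "hyper"),
      n_hypo = sum(.data$call == "hypo")
    ) |>
    dplyr::mutate(
      n_dmc = .data$n_hyper + .data$n_hypo,
      direction = dplyr::case_when(
        n_dmc < min_promoter_dmcs ~ NA_character_,
        n_hyper > n_hypo ~ "hyper",
        n_hypo > n_hyper ~ "hypo",
        TRUE ~ "mixed"
      )
    ) |>
    dplyr::filter(.data$n_dmc >= min_promoter_dmcs) |>
    dplyr::select("gene_id", "n_promoter_cpgs", "n_dmc", "n_hyper",
                  "n_hypo", "direction")
  class(out) <- c("dmg_table", class(out))
  out
}

#' Two-method agreement table with derived percentages
#'
#' Cross-tabulates the calls of two methods over the positions tested by
#' both (optionally restricted to one genomic context) and derives the
#' percentage summaries used in method-comparison reporting: each cell as a
#' percentage of the co-tested total, the share of method B's non-calls also
#' called by method A, and the share of method B's calls captured by
#' method A. All percentages are recomputed from the integer counts and
#' rounded to 2 decimals.
#'
#' @param calls_a,calls_b `dmc_table` tibbles indexed by identical
#'   `chrom`/`pos` (an index mismatch is an error). Calls are significant
#'   when `call != "NDMC"`.
#' @param context_filter Optional context label; requires a `context` column
#'   (see [assign_context()]).
#' @return An `agreement_table` list: `counts` (2 x 2 integer matrix, rows =
#'   method A NDMC/DMC, columns = method B NDMC/DMC) and `percentages` (see
#'   [agreement_percentages()]).
#' @export
agreement_table <- function(calls_a, calls_b, context_filter = NULL) {
  if (nrow(calls_a) != nrow(calls_b) ||
      any(calls_a$pos != calls_b$pos) ||
      any(calls_a$chrom != calls_b$chrom))
    stop_validation("call sets must be indexed by identical positions")
  keep <- calls_a$testable & calls_b$testable
  if (!is.null(context_filter)) {
    if (!"context" %in% names(calls_a))
      stop_validation("`context_filter` requires a `context` column (assign_context)")
    keep <- keep & calls_a$context == context_filter
  }
  a_dmc <- calls_a$call[keep] != "NDMC"
  b_dmc <- calls_b$call[keep] != "NDMC"
  counts <- matrix(
    c(sum(!a_dmc & !b_dmc), sum(a_dmc & !b_dmc),
      sum(!a_dmc & b_dmc), sum(a_dmc & b_dmc)),
    nrow = 2, dimnames = list(A = c("NDMC", "DMC"), B = c("NDMC", "DMC"))
  )
  structure(list(counts = counts,
                 percentages = agreement_percentages(counts)),
            class = "agreement_table")
}

#' Percentage summaries of a 2 x 2 agreement count matrix
#'
#' Given integer counts with rows = method A (NDMC, DMC) and columns =
#' method B (NDMC, DMC), returns each cell as a percentage of the total plus
#' three column summaries: the share of B's NDMC also non-called by A
#' (`pct_of_B_NDMC_captured`), the share of B's DMCs also called by A
#' (`pct_of_B_DMC_captured`), and the share of B's NDMC that A upgrades to a
#' call (`pct_of_B_NDMC_called_DMC`). Rounded to 2 decimals; recomputable
#' exactly from the counts.
#'
#' @param counts 2 x 2 matrix: `counts[i, j]` with i = A call (1 = NDMC,
#'   2 = DMC), j = B call.
#' @return A tibble with `cell`, `count`, `pct_of_total` rows for the four
#'   cells and the three column summaries.
#' @export
agreement_percentages <- function(counts) {
  counts <- as.matrix(counts)
  if (!all(dim(counts) == c(2, 2)) || any(counts < 0))
    stop_validation("`counts` must be a non-negative 2 x 2 matrix")
  total <- sum(counts)
  cells <- tibble::tibble(
    cell = c("A_NDMC_B_NDMC", "A_DMC_B_NDMC", "A_NDMC_B_DMC", "A_DMC_B_DMC"),
    count = as.numeric(counts),
    pct_of_total = round(100 * as.numeric(counts) / total, 2)
  )
  ndmc_col <- counts[1, 1] + counts[2, 1]
  dmc_col <- counts[1, 2] + counts[2, 2]
  pct_of <- function(num, den) {
    if (den > 0) round(100 * num / den, 2) else NA_real_
  }
  capture <- tibble::tibble(
    cell = c("pct_of_B_NDMC_captured", "pct_of_B_DMC_captured",
             "pct_of_B_NDMC_called_DMC"),
    count = c(counts[1, 1], counts[2, 2], counts[2, 1]),
    pct_of_total = c(pct_of(counts[1, 1], ndmc_col),
                     pct_of(counts[2, 2], dmc_col),
                     pct_of(counts[2, 1], ndmc_col))
  )
  dplyr::bind_rows(cells, capture)
}

#' @export
print.agreement_table <- function(x, ...) {
  cat("<agreement_table>\n")
  print(x$counts)
  print(x$percentages)
  invisible(x)
}

#' Overlap and direction-consistency summary of two call sets
#'
#' Intersects two directed call sets (DMCs keyed by position or DMGs keyed
#' by gene), flags direction consistency, and derives the consistency
#' percentages: consistent share of the overlap (1 decimal) and the hyper /
#' hypo shares of the consistent calls (1 decimal). Disjoint sets yield an
#' empty overlap with `NA` shares.
#'
#' @param calls_a,calls_b Tibbles with a key column (`pos` or `gene_id`) and
#'   a direction column (`call` or `direction`); only significant calls
#'   (direction `"hyper"` or `"hypo"`) participate.
#' @return An `overlap_summary` list: `overlap` tibble (key, direction in
#'   each set, `consistent` flag) and `shares` (n_overlap, n_consistent,
#'   pct_consistent, n_hyper, pct_hyper, n_hypo, pct_hypo).
#' @export
overlap_summary <- function(calls_a, calls_b) {
  key <- if ("gene_id" %in% names(calls_a)) "gene_id" else "pos"
  dir_col <- if ("direction" %in% names(calls_a)) "direction" else "call"
  pick <- function(d) {
    tibble::tibble(key = d[[key]], direction = d[[dir_col]]) |>
      dplyr::filter(.data$direction %in% c("hyper", "hypo"))
  }
  a <- pick(calls_a)
  b <- pick(calls_b)
  ov <- dplyr::inner_join(a, b, by = "key", suffix = c("_a", "_b")) |>
    dplyr::mutate(consistent = .data$direction_a == .data$direction_b)
  shares <- overlap_shares(
    n_overlap = nrow(ov),
    n_consistent = sum(ov$consistent),
    n_hyper = sum(ov$consistent & ov$direction_a == "hyper")
  )
  structure(list(overlap = ov, shares = shares), class = "overlap_summary")
}

#' Consistency shares from printed overlap counts
#'
#' The arithmetic behind the overlap reporting, exposed directly so the
#' percentages can be recomputed from integer counts: consistent share of
#' the overlap, and hyper / hypo shares of the consistent calls, each
#' rounded to 1 decimal. Undefined shares (zero denominators) are `NA`.
#'
#' @param n_overlap Number of overlapping calls.
#' @param n_consistent Number with consistent direction.
#' @param n_hyper Number of consistent calls that are hyper-methylated.
#' @return A one-row tibble with counts and percentage shares.
#' @export
overlap_shares <- function(n_overlap, n_consistent, n_hyper) {
  if (n_consistent > n_overlap || n_hyper > n_consistent)
    stop_validation("counts must be nested: n_hyper <= n_consistent <= n_overlap")
  tibble::tibble(
    n_overlap = n_overlap,
    n_consistent = n_consistent,
    pct_consistent = if (n_overlap > 0)
      round(100 * n_consistent / n_overlap, 1) else NA_real_,
    n_hyper = n_hyper,
    pct_hyper = if (n_consistent > 0)
      round(100 * n_hyper / n_consistent, 1) else NA_real_,
    n_hypo = n_consistent - n_hyper,
    pct_hypo = if (n_consistent > 0)
      round(100 * (n_consistent - n_hyper) / n_consistent, 1) else NA_real_
  )
}

#' @export
print.overlap_summary <- function(x, ...) {
  cat("<overlap_summary>\n")
  print(x$shares)
  invisible(x)
}

#' Venn region counts over gene sets
#'
#' Exact set algebra: for every non-empty combination of the input sets,
#' the number of identifiers in exactly that combination.
#'
#' @param sets Named list of >= 2 character vectors.
#' @return A tibble with `region` (e.g. `"A&B"`) and `count`, one row per
#'   combination, including zero counts.
#' @export
venn_counts <- function(sets) {
  if (length(sets) < 2) stop_validation("`sets` must contain at least 2 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    names(sets) <- LETTERS[seq_along(sets)]
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s,
                   logical(length(universe)))
  member <- matrix(member, ncol = length(sets),
                   dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  names(combos) <- names(sets)
  region <- apply(combos, 1, function(r) paste(names(sets)[as.logical(r)],
                                               collapse = "&"))
  count <- apply(combos, 1, function(r) {
    if (length(universe) == 0) return(0L)
    sum(apply(member, 1, function(mb) all(mb == as.logical(r))))
  })
  tibble::tibble(region = region, count = as.integer(count))
}
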