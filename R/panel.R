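#' Construct a methylation count panel
#'
#' The container consumed by the smoothing stage: per-CpG methylated read
#' counts and read-depths for a set of case and control samples, with an
#' explicit missingness mask. Entries whose depth exceeds `depth_cap` are
#' masked missing at construction time (the preprocessing filter against
#' PCR-amplification bias).
#'
#' @param chrom Chromosome name (single string).
#' @param positions Strictly increasing integer vector of CpG positions
#'   (1-based).
#' @param counts,depths `L x n` integer matrices of methylated read counts
#'   and read-depths.
#' @param missing Optional `L x n` logical mask; `NA` entries in
#'   `counts`/`depths` are also treated as missing.
#' @param groups Character vector of per-sample labels, `"case"` or
#'   `"control"`.
#' @param sample_ids Optional sample names; defaults to `group` plus index.
#' @param depth_cap Depth filter threshold (default 500).
#' @return An object of class `methylation_panel`.
#' @export
methylation_panel <- function(chrom, positions, counts, depths, missing = NULL,
                              groups, sample_ids = NULL, depth_cap = 500L) {
  counts <- as.matrix(counts)
  depths <- as.matrix(depths)
  L <- length(positions)
  n <- ncol(counts)
  if (L < 1) stop_validation("panel must contain at least one position")
  if (is.unsorted(positions, strictly = TRUE))
    stop_validation("`positions` must be strictly increasing")
  if (!all(dim(counts) == c(L, n)) || !all(dim(depths) == c(L, n)))
    stop_validation("`counts` and `depths` must be L x n matrices")
  if (length(groups) != n || !all(groups %in% c("case", "control")))
    stop_validation("`groups` must label each sample 'case' or 'control'")
  if (is.null(missing)) missing <- matrix(FALSE, L, n)
  missing <- missing | is.na(counts) | is.na(depths)
  # depth filter: mask PCR-bias-suspect entries rather than discarding rows
  missing <- missing | (!is.na(depths) & depths > depth_cap)
  obs <- !missing
  if (any(depths[obs] < 0)) stop_validation("depths must be non-negative")
  if (any(counts[obs] < 0 | counts[obs] > depths[obs]))
    stop_validation("counts must satisfy 0 <= y <= depth where observed")
  counts[missing] <- NA
  depths[missing] <- NA
  storage.mode(counts) <- "integer"
  storage.mode(depths) <- "integer"
  storage.mode(missing) <- "logical"
  if (is.null(sample_ids))
    sample_ids <- paste0(groups, "_", stats::ave(seq_len(n), groups, FUN = seq_along))
  colnames(counts) <- colnames(depths) <- colnames(missing) <- sample_ids
  structure(
    list(chrom = as.character(chrom)[1], positions = as.integer(positions),
         counts = counts, depths = depths, missing = missing,
         groups = as.character(groups), sample_ids = as.character(sample_ids),
         depth_cap = as.integer(depth_cap)),
    class = "methylation_panel"
  )
}

#' @export
print.methylation_panel <- function(x, ...) {
  cat("<methylation_panel> ", x$chrom, ": ", length(x$positions),
      " positions x ", length(x$sample_ids), " samples (",
      sum(x$groups == "case"), " case / ", sum(x$groups == "control"),
      " control), ", round(100 * mean(x$missing), 1), "% missing\n", sep = "")
  invisible(x)
}

#' @export
dim.methylation_panel <- function(x) c(length(x$positions), length(x$sample_ids))

#' Tidy a methylation panel into long format
#'
#' @param x A `methylation_panel`.
#' @param ... Unused.
#' @return A tibble with one row per (position, sample).
#' @export
as_tibble.methylation_panel <- function(x, ...) {
  tibble::tibble(
    chrom = x$chrom,
    pos = rep(x$positions, times = length(x$sample_ids)),
    sample_id = rep(x$sample_ids, each = length(x$positions)),
    group = rep(x$groups, each = length(x$positions)),
    meth_count = as.vector(x$counts),
    depth = as.vector(x$depths)
  )
}

#' Write / read a panel as a tab-separated table
#'
#' One row per position: `chrom`, `pos` (1-based), then one
#' `meth_count,depth` pair column per sample; missing entries are encoded
#' `NA,NA`. Group labels are carried in a `#groups=` header comment so the
#' file round-trips.
#'
#' @param panel A `methylation_panel`.
#' @param path File path.
#' @return `write_panel()` returns `path` invisibly; `read_panel()` returns
#'   a `methylation_panel`.
#' @export
write_panel <- function(panel, path) {
  pair <- matrix(paste0(ifelse(panel$missing, "NA", panel$counts), ",",
                        ifelse(panel$missing, "NA", panel$depths)),
                 nrow = length(panel$positions))
  colnames(pair) <- panel$sample_ids
  header <- paste0("#groups=", paste(panel$groups, collapse = ","))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(header, con)
  writeLines(paste(c("chrom", "pos", panel$sample_ids), collapse = "\t"), con)
  body <- cbind(panel$chrom, panel$positions, pair)
  writeLines(apply(body, 1, paste, collapse = "\t"), con)
  invisible(path)
}

#' @rdname write_panel
#' @param depth_cap Depth filter applied at load time.
#' @export
read_panel <- function(path, depth_cap = 500L) {
  first <- readLines(path, n = 1)
  if (!startsWith(first, "#groups="))
    stop_validation("panel file must start with a '#groups=' header")
  groups <- strsplit(sub("^#groups=", "", first), ",")[[1]]
  tab <- readr::read_tsv(path, comment = "#", show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  sample_ids <- names(tab)[-(1:2)]
  if (length(groups) != length(sample_ids))
    stop_validation("group header does not match sample columns")
  split_pair <- function(col, idx) {
    parts <- strsplit(col, ",", fixed = TRUE)
    vapply(parts, function(p) suppressWarnings(as.integer(p[idx])), integer(1))
  }
  counts <- matrix(vapply(tab[-(1:2)], split_pair, integer(nrow(tab)), idx = 1L),
                   nrow = nrow(tab))
  depths <- matrix(vapply(tab[-(1:2)], split_pair, integer(nrow(tab)), idx = 2L),
                   nrow = nrow(tab))
  methylation_panel(chrom = tab$chrom[1],
                    positions = as.integer(tab$pos),
                    counts = counts, depths = depths,
                    groups = groups, sample_ids = sample_ids,
                    depth_cap = depth_cap)
}
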