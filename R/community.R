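#' Coerce to a samples-by-ASV count matrix
#'
#' Accepts either an integer matrix with sample ids as row names and ASV
#' ids as column names, or a data frame whose first column (or a column
#' named `sample_id`) holds the sample ids.
#'
#' @param x Matrix or data frame of non-negative counts.
#' @return An integer-valued matrix, samples in rows.
#' @export
as_asv_matrix <- function(x) {
  if (is.data.frame(x)) {
    idcol <- if ("sample_id" %in% names(x)) "sample_id" else names(x)[1]
    ids <- as.character(x[[idcol]])
    m <- as.matrix(x[setdiff(names(x), idcol)])
    rownames(m) <- ids
    x <- m
  }
  if (!is.matrix(x) || !is.numeric(x)) {
    abort("`x` must be a numeric matrix or a data frame of counts.")
  }
  if (any(x < 0) || any(x != floor(x))) {
    abort("Counts must be non-negative integers.")
  }
  if (is.null(rownames(x)) || is.null(colnames(x))) {
    abort("Sample ids (rows) and ASV ids (columns) are required.")
  }
  if (anyDuplicated(rownames(x)) || anyDuplicated(colnames(x))) {
    abort("Sample and ASV ids must be unique.")
  }
  if (any(rowSums(x) == 0)) abort("Every sample must have a positive total.")
  storage.mode(x) <- "double"
  x
}

#' Rarefy an ASV table to a fixed depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric) to exactly `depth` reads, reproducibly for a given seed.
#' A sample already at `depth` is returned unchanged.
#'
#' @param table Samples-by-ASV count matrix or data frame
#'   (see [as_asv_matrix()]).
#' @param depth Target reads per sample; must not exceed any sample total.
#' @param seed Integer seed making the subsampling deterministic.
#' @return A rarefied count matrix with every row summing to `depth`.
#' @export
rarefy <- function(table, depth, seed) {
  m <- as_asv_matrix(table)
  check_scalar_num(depth, "depth"); check_scalar_num(seed, "seed")
  totals <- rowSums(m)
  short <- totals < depth
  if (any(short)) {
    abort(paste0("Depth ", depth, " exceeds the total reads of sample(s): ",
                 paste(rownames(m)[short], collapse = ", ")))
  }
  withr::with_seed(as.integer(seed), {
    out <- t(apply(m, 1, function(counts) {
      if (sum(counts) == depth) return(counts)
      pool <- rep.int(seq_along(counts), counts)
      picked <- sample(pool, depth, replace = FALSE)
      tabulate(picked, nbins = length(counts))
    }))
  })
  dimnames(out) <- dimnames(m)
  out
}

#' Alpha diversity of ASV samples
#'
#' Observed richness, Shannon entropy and inverse Simpson index per
#' sample, computed from relative abundances `p_i = c_i / sum(c)`:
#' richness is the number of ASVs with positive count, Shannon is
#' `-sum(p_i * log(p_i))` over positive `p_i` (natural log by default) and
#' inverse Simpson is `1 / sum(p_i^2)`.
#'
#' @param table Samples-by-ASV count matrix/data frame, or a single
#'   sample's count vector.
#' @param log_base Base of the Shannon logarithm (default `exp(1)`, nats).
#' @return A tibble with columns `sample_id`, `richness`, `shannon`,
#'   `inv_simpson`.
#' @examples
#' alpha_diversity(c(a = 50, b = 30, c = 20))
#' @export
alpha_diversity <- function(table, log_base = exp(1)) {
  if (is.null(dim(table))) {
    m <- matrix(table, nrow = 1,
                dimnames = list("sample", names(table) %||%
                                  paste0("asv", seq_along(table))))
    if (any(m < 0)) abort("Counts must be non-negative.")
    if (sum(m) == 0) abort("All-zero sample.")
  } else {
    m <- as_asv_matrix(table)
  }
  one <- function(counts) {
    p <- counts[counts > 0] / sum(counts)
    c(richness = length(p),
      shannon = -sum(p * log(p, base = log_base)),
      inv_simpson = 1 / sum(p^2))
  }
  res <- t(apply(m, 1, one))
  tibble::tibble(sample_id = rownames(m),
                 richness = unname(res[, "richness"]),
                 shannon = unname(res[, "shannon"]),
                 inv_simpson = unname(res[, "inv_simpson"]))
}

#' Parse QIIME2-style taxonomy lineage strings
#'
#' Splits strings of the form `"d__Bacteria; p__...; g__Burkholderia"`
#' into a rank table. Empty ranks (`g__` with nothing after) and absent
#' ranks become `NA`.
#'
#' @param taxon Character vector of lineage strings.
#' @return A tibble with columns `domain`, `phylum`, `class`, `order`,
#'   `family`, `genus`.
#' @export
parse_qiime2_taxonomy <- function(taxon) {
  prefixes <- c(domain = "d", phylum = "p", class = "c",
                order = "o", family = "f", genus = "g")
  parts <- stringr::str_split(taxon, ";\\s*")
  rows <- purrr::map(parts, function(pp) {
    vals <- purrr::map_chr(prefixes, function(pref) {
      hit <- pp[startsWith(pp, paste0(pref, "__"))]
      if (length(hit) == 0) return(NA_character_)
      v <- sub("^.__", "", hit[1])
      if (v == "") NA_character_ else v
    })
    tibble::as_tibble_row(setNames(as.list(vals), names(prefixes)))
  })
  dplyr::bind_rows(rows)
}

#' Genus-level community composition
#'
#' Per-sample relative abundance (%) of each genus. ASVs without a genus
#' assignment are pooled into the `"NA"` category. Percentages within each
#' sample sum to 100.
#'
#' @param table Samples-by-ASV count matrix/data frame (rarefied or raw,
#'   at the caller's discretion).
#' @param taxonomy A data frame mapping ASVs to genera: either columns
#'   `asv_id` and `genus`, or QIIME2 export columns `Feature ID` and
#'   `Taxon` (parsed with [parse_qiime2_taxonomy()]). Every ASV in the
#'   table must have an entry.
#' @return A long tibble: `sample_id`, `genus`, `reads`, `pct`.
#' @seealso [collapse_rare_genera()] for display aggregation.
#' @export
genus_composition <- function(table, taxonomy) {
  m <- as_asv_matrix(table)
  tax <- normalize_taxonomy(taxonomy)
  missing <- setdiff(colnames(m), tax$asv_id)
  if (length(missing)) {
    abort(paste0("No taxonomy entry for ASV(s): ",
                 paste(head(missing, 10), collapse = ", "),
                 if (length(missing) > 10) " ..."))
  }
  genus <- tax$genus[match(colnames(m), tax$asv_id)]
  genus[is.na(genus)] <- "NA"
  tibble::as_tibble(m, rownames = "sample_id") |>
    tidyr::pivot_longer(-"sample_id", names_to = "asv_id",
                        values_to = "reads") |>
    dplyr::mutate(genus = genus[match(.data$asv_id, colnames(m))]) |>
    dplyr::group_by(.data$sample_id, .data$genus) |>
    dplyr::summarise(reads = sum(.data$reads), .groups = "drop_last") |>
    dplyr::mutate(pct = 100 * .data$reads / sum(.data$reads)) |>
    dplyr::ungroup() |>
    dplyr::arrange(.data$sample_id, dplyr::desc(.data$pct))
}

#' Aggregate rare genera for display
#'
#' Genera whose relative abundance stays below `threshold` (%) in every
#' sample are pooled into an `"Other"` category, the usual convention of
#' stacked composition bar plots. The input (full) composition table is
#' what analyses should use; this is a display transform.
#'
#' @param composition Output of [genus_composition()].
#' @param threshold Display threshold in percent (default 0.1).
#' @return A tibble with the same columns, rare genera pooled.
#' @export
collapse_rare_genera <- function(composition, threshold = 0.1) {
  keep <- composition |>
    dplyr::group_by(.data$genus) |>
    dplyr::summarise(max_pct = max(.data$pct), .groups = "drop") |>
    dplyr::filter(.data$max_pct > threshold) |>
    dplyr::pull("genus")
  composition |>
    dplyr::mutate(genus = ifelse(.data$genus %in% keep, .data$genus,
                                 "Other")) |>
    dplyr::group_by(.data$sample_id, .data$genus) |>
    dplyr::summarise(reads = sum(.data$reads), pct = sum(.data$pct),
                     .groups = "drop")
}

#' ASV overlap between two samples
#'
#' Venn-style presence/absence overlap: an ASV is present when its count
#' is positive (conventionally after rarefaction).
#'
#' @param table Samples-by-ASV count matrix/data frame.
#' @param sample_a,sample_b Sample ids to compare.
#' @return A one-row tibble: `shared`, `only_a`, `only_b`, `union`,
#'   `pct_shared` (unrounded, `100 * shared / union`).
#' @examples
#' m <- rbind(before = c(1, 2, 0, 5), after = c(0, 3, 4, 1))
#' colnames(m) <- paste0("asv", 1:4)
#' venn_overlap(m, "before", "after")
#' @export
venn_overlap <- function(table, sample_a, sample_b) {
  m <- as_asv_matrix(table)
  for (s in c(sample_a, sample_b)) {
    if (!s %in% rownames(m)) abort(paste0("Unknown sample id: ", s))
  }
  a <- m[sample_a, ] > 0
  b <- m[sample_b, ] > 0
  shared <- sum(a & b)
  only_a <- sum(a & !b)
  only_b <- sum(!a & b)
  union <- shared + only_a + only_b
  tibble::tibble(shared = shared, only_a = only_a, only_b = only_b,
                 union = union, pct_shared = 100 * shared / union)
}

#' Stacked bar plot of genus composition
#'
#' @param composition Output of [genus_composition()] or
#'   [collapse_rare_genera()].
#' @return A ggplot object.
#' @export
plot_genus_composition <- function(composition) {
  ggplot2::ggplot(composition,
                  ggplot2::aes(.data$sample_id, .data$pct,
                               fill = .data$genus)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Relative abundance (%)", fill = "Genus") +
    ggplot2::theme_minimal()
}

normalize_taxonomy <- function(taxonomy) {
  if (!is.data.frame(taxonomy)) abort("`taxonomy` must be a data frame.")
  if (all(c("asv_id", "genus") %in% names(taxonomy))) {
    return(tibble::tibble(asv_id = as.character(taxonomy$asv_id),
                          genus = as.character(taxonomy$genus)))
  }
  if (all(c("Feature ID", "Taxon") %in% names(taxonomy))) {
    ranks <- parse_qiime2_taxonomy(taxonomy$Taxon)
    return(tibble::tibble(asv_id = as.character(taxonomy[["Feature ID"]]),
                          genus = ranks$genus))
  }
  abort("`taxonomy` needs columns `asv_id`+`genus` or `Feature ID`+`Taxon`.")
}
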