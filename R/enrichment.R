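#' Read and write GMT gene-set files
#'
#' Standard GMT format: one set per line, tab-separated — set name,
#' description, then member gene IDs.
#'
#' @param path File path.
#' @param sets Named list of character vectors.
#' @param descriptions Optional character vector of per-set descriptions.
#' @return `read_gmt()`: a named list of character vectors with a
#'   `description` attribute. `write_gmt()`: `path`, invisibly.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- lengths(parts) < 3
  if (any(bad)) {
    abort(sprintf("GMT line(s) with fewer than 3 fields: %s",
                  paste(head(which(bad), 5), collapse = ", ")))
  }
  sets <- lapply(parts, function(x) unique(x[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  attr(sets, "description") <- vapply(parts, `[[`, "", 2)
  sets
}

#' @rdname read_gmt
#' @export
write_gmt <- function(sets, path, descriptions = NULL) {
  if (is.null(descriptions)) descriptions <- rep("na", length(sets))
  lines <- vapply(seq_along(sets), function(i) {
    paste(c(names(sets)[i], descriptions[i], sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

filter_sets_by_size <- function(collection, background, set_size) {
  trimmed <- lapply(collection, intersect, y = background)
  sz <- lengths(trimmed)
  trimmed[sz >= set_size[1] & sz <= set_size[2]]
}

#' Gene-level over-representation analysis (hypergeometric)
#'
#' One-sided over-representation test of a hit list against each gene set:
#' `p = P(X >= overlap)` for X hypergeometric with the set's in-background
#' size, the background size, and the number of hits. Sets are restricted to
#' those with 10 to 500 members in the background (both bounds inclusive) to
#' limit the type-I error rate; BH-FDR is computed across the tested sets.
#'
#' @param hits Character vector of hit genes (must be a subset of
#'   `background`).
#' @param background Character vector: the tested gene universe.
#' @param collection Named list of gene sets (e.g. from [read_gmt()]).
#' @param set_size Inclusive size bounds applied after intersecting each set
#'   with the background; default `c(10, 500)`.
#' @return `enrich_tbl` tibble: `set`, `overlap`, `set_size`, `n_hits`,
#'   `n_background`, `odds`, `p`, `q`.
#' @export
ora_hypergeometric <- function(hits, background, collection,
                               set_size = c(10, 500)) {
  hits <- unique(hits); background <- unique(background)
  stray <- setdiff(hits, background)
  if (length(stray) > 0) {
    abort(paste0("hits not in background: ",
                 paste(head(stray, 10), collapse = ", ")))
  }
  sets <- filter_sets_by_size(collection, background, set_size)
  N <- length(background); n <- length(hits)
  out <- purrr::imap_dfr(sets, function(members, nm) {
    K <- length(members)
    ov <- length(intersect(members, hits))
    tibble::tibble(set = nm, overlap = ov, set_size = K, n_hits = n,
                   n_background = N, odds = 1,
                   p = phyper(ov - 1, K, N - K, n, lower.tail = FALSE))
  })
  if (nrow(out) > 0) out$q <- bh_fdr(out$p) else out$q <- double()
  structure(dplyr::arrange(out, .data$p),
            class = c("enrich_tbl", class(out)))
}

# Collapse probe-level IDs to gene level: a gene is a hit iff >= 1 of its
# probes is a hit; probe counts are tallied over the background only.
collapse_probes_to_genes <- function(hit_cpgs, background_cpgs, probe_gene_map) {
  map_bg <- dplyr::filter(probe_gene_map, .data$feature %in% background_cpgs)
  gene_counts <- map_bg |>
    dplyr::distinct(.data$feature, .data$gene) |>
    dplyr::count(.data$gene, name = "n_probes")
  hit_genes <- map_bg |>
    dplyr::filter(.data$feature %in% hit_cpgs) |>
    dplyr::pull(.data$gene) |>
    unique()
  list(gene_counts = gene_counts, hit_genes = hit_genes)
}

#' Probe-count-bias-adjusted over-representation for methylation
#'
#' Gene-set testing on CpG hit lists is biased: genes carrying many probes
#' are more likely to contain at least one significant CpG under the null.
#' This test collapses probes to genes (a gene is a hit iff at least one of
#' its probes is a hit), then models hit-gene selection as a biased urn in
#' which a gene's sampling weight is proportional to its probe count,
#' summarised as a single odds ratio: mean probe count of in-set genes over
#' mean probe count of out-of-set genes. The per-set p-value is the
#' Wallenius noncentral hypergeometric upper tail at that odds.
#'
#' @param hit_cpgs Significant CpGs (subset of `background_cpgs`).
#' @param background_cpgs All tested CpGs.
#' @param probe_gene_map Tibble with `feature`, `gene` columns (many-to-many
#'   allowed; multi-gene probes contribute a hit to every annotated gene).
#' @param collection Named list of gene sets.
#' @param set_size Inclusive size bounds in the gene background, default
#'   `c(10, 500)`.
#' @return `enrich_tbl` tibble as in [ora_hypergeometric()], with `odds` the
#'   bias parameter used per set.
#' @export
ora_methylation <- function(hit_cpgs, background_cpgs, probe_gene_map,
                            collection, set_size = c(10, 500)) {
  stray <- setdiff(hit_cpgs, background_cpgs)
  if (length(stray) > 0) {
    abort(paste0("hit CpGs not in background: ",
                 paste(head(stray, 10), collapse = ", ")))
  }
  unmapped <- setdiff(background_cpgs, probe_gene_map$feature)
  if (length(unmapped) > 0) {
    message(sprintf("%d background CpG(s) without gene annotation ignored",
                    length(unmapped)))
  }
  cl <- collapse_probes_to_genes(hit_cpgs, background_cpgs, probe_gene_map)
  background_genes <- cl$gene_counts$gene
  counts <- setNames(cl$gene_counts$n_probes, background_genes)
  hit_genes <- cl$hit_genes
  sets <- filter_sets_by_size(collection, background_genes, set_size)
  N <- length(background_genes); n <- length(hit_genes)
  out <- purrr::imap_dfr(sets, function(members, nm) {
    K <- length(members)
    ov <- length(intersect(members, hit_genes))
    out_genes <- setdiff(background_genes, members)
    odds <- if (length(out_genes) == 0) 1 else
      mean(counts[members]) / mean(counts[out_genes])
    tibble::tibble(set = nm, overlap = ov, set_size = K, n_hits = n,
                   n_background = N, odds = odds,
                   p = wallenius_upper_tail(ov, K, N - K, n, odds))
  })
  if (nrow(out) > 0) out$q <- bh_fdr(out$p) else out$q <- double()
  structure(dplyr::arrange(out, .data$p),
            class = c("enrich_tbl", class(out)))
}

#' Over-representation of the overlap between two feature lists
#'
#' Tests whether two lists (e.g. differentially methylated genes and
#' differentially expressed genes) share more members than expected by
#' chance, via the hypergeometric upper tail on their intersection within a
#' common universe. Symmetric in the two lists.
#'
#' @param list_a,list_b Character vectors, both subsets of `universe`.
#' @param universe The common feature universe.
#' @return One-row tibble: `overlap`, `n_a`, `n_b`, `n_universe`, `p`.
#' @export
#' @examples
#' overlap_test(paste0("g", 1:10), paste0("g", 6:25), paste0("g", 1:100))
overlap_test <- function(list_a, list_b, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("empty universe")
  list_a <- unique(list_a); list_b <- unique(list_b)
  stray <- c(setdiff(list_a, universe), setdiff(list_b, universe))
  if (length(stray) > 0) {
    abort(paste0("list members outside the universe: ",
                 paste(head(stray, 10), collapse = ", ")))
  }
  ov <- length(intersect(list_a, list_b))
  p <- phyper(ov - 1, length(list_a), length(universe) - length(list_a),
              length(list_b), lower.tail = FALSE)
  tibble::tibble(overlap = ov, n_a = length(list_a), n_b = length(list_b),
                 n_universe = length(universe), p = p)
}

#' Cell-type-marker confound check
#'
#' Runs the same over-representation machinery against a collection of
#' cell-type marker gene sets: enrichment of age-related features in marker
#' sets would suggest that apparent age effects reflect shifting cell-type
#' proportions rather than cell-intrinsic change. Uses the probe-count-bias
#' adjusted test when a probe-to-gene map is supplied (methylation), the
#' plain hypergeometric otherwise (expression).
#'
#' @param hits,background Feature lists (CpGs with a map, genes without).
#' @param marker_collection Named list of marker gene sets.
#' @param probe_gene_map Optional tibble `feature`/`gene`.
#' @param set_size Inclusive size bounds, default `c(10, 500)`.
#' @return `enrich_tbl` tibble.
#' @export
celltype_confound_check <- function(hits, background, marker_collection,
                                    probe_gene_map = NULL,
                                    set_size = c(10, 500)) {
  if (is.null(probe_gene_map)) {
    ora_hypergeometric(hits, background, marker_collection, set_size)
  } else {
    ora_methylation(hits, background, probe_gene_map, marker_collection,
                    set_size)
  }
}
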