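#' Read a GMT gene-set file
#'
#' Standard GMT format: one set per line, tab-separated fields
#' `name<TAB>description<TAB>gene1<TAB>gene2...`.
#'
#' @param path Path to the GMT file.
#' @return Named list of character vectors (set name -> gene ids).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("GMT file is empty")
  sets <- lapply(lines, function(l) {
    parts <- strsplit(l, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3)
      stop("malformed GMT line (need name, description, >= 1 gene): ",
           substr(l, 1, 60))
    unique(parts[-(1:2)])
  })
  names(sets) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1]][1], "")
  if (anyDuplicated(names(sets))) stop("duplicate set names in GMT")
  sets
}

#' Gene-set collection with an explicit universe
#'
#' Harmonizes sets against a universe: genes outside the universe are
#' dropped from every set, and empty sets are removed. The universe
#' should be the set of genes actually tested — typically the genes
#' surviving [detection_filter()], mirroring the below-detection
#' exclusion applied before querying.
#'
#' @param sets Named list of gene sets (e.g. from [read_gmt()]).
#' @param universe Character vector of gene ids.
#' @return A `GeneSetCollection` list with elements `sets` and
#'   `universe`.
#' @export
gene_set_collection <- function(sets, universe) {
  if (!length(sets)) stop("empty collection")
  universe <- unique(universe)
  if (!length(universe)) stop("empty universe")
  harmonized <- lapply(sets, function(s) intersect(unique(s), universe))
  harmonized <- harmonized[lengths(harmonized) > 0]
  if (!length(harmonized))
    stop("no set overlaps the universe")
  structure(list(sets = harmonized, universe = universe),
            class = "GeneSetCollection")
}

#' Hypergeometric over-representation analysis
#'
#' One-sided hypergeometric test per gene set: the p-value is the
#' probability of drawing at least the observed overlap when
#' `|query ∩ universe|` genes are drawn without replacement from the
#' universe, with the set's genes as successes. Benjamini-Hochberg
#' adjusted p-values are reported alongside the raw ones.
#'
#' @param query Character vector of gene ids.
#' @param collection A [gene_set_collection()].
#' @return Data frame sorted by p: `set`, `set_size`, `query_size`,
#'   `overlap`, `p`, `p_adjusted`, `contributing_genes`
#'   (comma-separated).
#' @export
overrepresentation <- function(query, collection) {
  stopifnot(inherits(collection, "GeneSetCollection"))
  q <- intersect(unique(query), collection$universe)
  if (!length(q)) stop("query does not overlap the universe")
  n_univ <- length(collection$universe)
  rows <- lapply(names(collection$sets), function(nm) {
    s <- collection$sets[[nm]]
    hit <- intersect(q, s)
    p <- stats::phyper(length(hit) - 1, length(s), n_univ - length(s),
                       length(q), lower.tail = FALSE)
    data.frame(set = nm, set_size = length(s), query_size = length(q),
               overlap = length(hit), p = p,
               contributing_genes = paste(sort(hit), collapse = ","),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- stats::p.adjust(out$p, method = "BH")
  out <- out[order(out$p, out$set), c("set", "set_size", "query_size",
                                      "overlap", "p", "p_adjusted",
                                      "contributing_genes")]
  rownames(out) <- NULL
  out
}
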