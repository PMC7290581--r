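# Downstream interpretation of candidate miRNAs: score-based filtering of
# predicted target genes, hypergeometric over-representation of pathway
# gene sets, and overlap counts of targets against expressed-gene lists.

#' Gene set collection with a universe
#'
#' @param sets named list of character vectors (gene sets).
#' @param universe character vector containing every gene of every set.
#' @return An object of class `gene_set_collection`.
#' @export
gene_set_collection <- function(sets, universe) {
  stopifnot(is.list(sets), !is.null(names(sets)), is.character(universe))
  universe <- unique(universe)
  sets <- lapply(sets, unique)
  outside <- vapply(sets, function(s) any(!s %in% universe), logical(1))
  if (any(outside)) {
    stop(sprintf("set(s) not contained in the universe: %s",
                 paste(names(sets)[outside], collapse = ", ")),
         call. = FALSE)
  }
  structure(list(sets = sets, universe = universe),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d sets, universe of %d genes\n",
              length(x$sets), length(x$universe)))
  invisible(x)
}

#' Read / write gene sets in GMT format
#'
#' Reading is delegated to [fgsea::gmtPathways]; the universe defaults to
#' the union of all sets unless supplied.
#'
#' @param path GMT file path.
#' @param universe optional explicit gene universe.
#' @return `read_gmt` returns a [gene_set_collection]; `write_gmt` returns
#'   `path` invisibly.
#' @export
read_gmt <- function(path, universe = NULL) {
  sets <- fgsea::gmtPathways(path)
  if (is.null(universe)) universe <- unique(unlist(sets))
  gene_set_collection(sets, universe)
}

#' @rdname read_gmt
#' @param collection a [gene_set_collection].
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(names(collection$sets), function(nm) {
    paste(c(nm, "na", collection$sets[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Filter predicted targets by context and aggregate score
#'
#' Keeps genes whose cumulative weighted context score is strictly below
#' `context_max` (more negative = stronger predicted repression) and whose
#' aggregate score is at least `aggregate_min`.
#'
#' @param records data frame with columns `gene`, `context_score`,
#'   `aggregate_score`.
#' @param context_max strict upper bound on the context score (default
#'   -0.3).
#' @param aggregate_min inclusive lower bound on the aggregate score
#'   (default 0.3).
#' @return Character vector of retained gene ids.
#' @export
filter_targets <- function(records, context_max = -0.3, aggregate_min = 0.3) {
  stopifnot(all(c("gene", "context_score", "aggregate_score") %in%
                  names(records)),
            is.finite(context_max), is.finite(aggregate_min))
  keep <- records$context_score < context_max &
    records$aggregate_score >= aggregate_min
  unique(records$gene[keep])
}

#' Hypergeometric over-representation of gene sets in a target list
#'
#' For each set of size `K` in a universe of size `N`, with `n` targets
#' drawn and `k` of them in the set, the enrichment p-value is the
#' upper-tail hypergeometric probability `P(X >= k)`, computed with
#' [stats::phyper]; Benjamini-Hochberg adjustment is applied across sets.
#'
#' @param targets character vector of target genes (must lie in the
#'   collection's universe).
#' @param collection a [gene_set_collection].
#' @return Data frame per set: `set`, `overlap` (k), `set_size` (K),
#'   `n_targets` (n), `universe` (N), `p`, `p_adj`, sorted by `p`.
#' @export
hypergeom_enrichment <- function(targets, collection) {
  stopifnot(inherits(collection, "gene_set_collection"))
  targets <- unique(targets)
  if (length(collection$universe) == 0L) {
    stop("empty universe", call. = FALSE)
  }
  if (any(!targets %in% collection$universe)) {
    stop("targets must be contained in the universe", call. = FALSE)
  }
  N <- length(collection$universe)
  n <- length(targets)
  rows <- lapply(names(collection$sets), function(nm) {
    set <- collection$sets[[nm]]
    K <- length(set)
    k <- length(intersect(targets, set))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(set = nm, overlap = k, set_size = K, n_targets = n,
               universe = N, p = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- bh_adjust(out$p)
  out[order(out$p), , drop = FALSE]
}

#' Overlap of targets with expressed-gene lists and curated sets
#'
#' Counts, per cell type, how many target genes appear in that cell type's
#' expressed-gene list; the number expressed in every cell type; and an
#' optional cross-tabulation against curated gene lists (e.g.
#' athero-protective / athero-prone sets). Identifiers are matched exactly
#' after upper-casing.
#'
#' @param targets character vector of target genes.
#' @param expressed named list of expressed-gene vectors, one per cell
#'   type.
#' @param curated optional named list of curated gene lists.
#' @return A list with `per_cell_type` (named counts), `in_all` (count
#'   expressed in every cell type), `n_targets`, and (when `curated` is
#'   given) `curated_counts`: a data frame of curated-list overlaps per
#'   cell type.
#' @export
expressed_overlap <- function(targets, expressed, curated = NULL) {
  norm <- function(x) unique(toupper(x))
  targets <- norm(targets)
  expressed <- lapply(expressed, norm)
  per_ct <- vapply(expressed, function(e) length(intersect(targets, e)),
                   integer(1))
  in_all <- length(Reduce(intersect, c(list(targets), expressed)))
  out <- list(per_cell_type = per_ct, in_all = in_all,
              n_targets = length(targets))
  if (!is.null(curated)) {
    curated <- lapply(curated, norm)
    rows <- list()
    for (ct in names(expressed)) {
      expressed_targets <- intersect(targets, expressed[[ct]])
      for (cl in names(curated)) {
        rows[[paste(ct, cl)]] <- data.frame(
          cell_type = ct, curated_list = cl,
          overlap = length(intersect(expressed_targets, curated[[cl]])),
          stringsAsFactors = FALSE)
      }
    }
    out$curated_counts <- do.call(rbind, c(rows, make.row.names = FALSE))
  }
  out
}
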