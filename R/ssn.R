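#' @include align.R
NULL

# union-find with path compression; edges as 2-column integer matrix
.union_find <- function(n, edges) {
  if (length(edges)) storage.mode(edges) <- "integer"
  parent <- seq_len(n)
  find <- function(x) {
    root <- x
    while (parent[root] != root) root <- parent[root]
    while (parent[x] != root) {
      nxt <- parent[x]
      parent[x] <<- root
      x <- nxt
    }
    root
  }
  if (length(edges)) {
    for (k in seq_len(nrow(edges))) {
      ri <- find(edges[k, 1])
      rj <- find(edges[k, 2])
      if (ri != rj) parent[rj] <- ri
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  match(roots, unique(roots))
}

#' Build a sequence similarity network of core peptides
#'
#' Nodes are unique sequences; an edge joins two nodes whose global-alignment
#' identity reaches the threshold. Connected components are computed by
#' union-find. The identity threshold (default 70 percent) plays the role a
#' BLAST E-value cutoff plays in database-backed similarity networks: it
#' groups near-identical family variants while separating distant ones, and
#' it is a tunable parameter, not a statistical equivalent.
#'
#' @param seqs Named character vector or \code{AAStringSet} of unique
#'   sequences (duplicates are an error; run \code{\link{dedupExact}}
#'   first).
#' @param metadata Optional data frame aligned with \code{seqs} (e.g. genome
#'   ids, genera); carried onto the nodes.
#' @param edgeThresholdIdentity Identity threshold in percent (default 70).
#' @return List of class \code{SSNGraph}: \code{nodes} (data frame with
#'   \code{id}, \code{sequence}, \code{component}, any metadata), and
#'   \code{edges} (data frame \code{from}, \code{to}, \code{identity_pct}
#'   with \code{from < to} by node index; no self-edges).
#' @export
buildSSN <- function(seqs, metadata = NULL, edgeThresholdIdentity = 70) {
  seqs <- .as_chr_seqs(seqs)
  if (length(seqs) == 0) .stopf("need at least 1 sequence")
  if (anyDuplicated(toupper(seqs))) {
    .stopf("sequences must be unique (dedupExact first)")
  }
  n <- length(seqs)
  edges <- list()
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        pid <- globalAlign(seqs[[i]], seqs[[j]])$identity_pct
        if (pid >= edgeThresholdIdentity) {
          edges[[length(edges) + 1]] <- c(i, j, pid)
        }
      }
    }
  }
  em <- if (length(edges)) do.call(rbind, edges) else
    matrix(numeric(0), ncol = 3)
  comp <- .union_find(n, em[, 1:2, drop = FALSE])
  nodes <- data.frame(id = names(seqs), sequence = unname(seqs),
                      component = comp, stringsAsFactors = FALSE)
  if (!is.null(metadata)) nodes <- cbind(nodes, metadata)
  edges_df <- data.frame(
    from = names(seqs)[em[, 1]], to = names(seqs)[em[, 2]],
    identity_pct = if (nrow(em)) em[, 3] else numeric(0),
    stringsAsFactors = FALSE)
  structure(list(nodes = nodes, edges = edges_df,
                 threshold = edgeThresholdIdentity),
            class = "SSNGraph")
}

#' @export
print.SSNGraph <- function(x, ...) {
  cat("SSNGraph:", nrow(x$nodes), "node(s),", nrow(x$edges), "edge(s),",
      length(unique(x$nodes$component)), "component(s); identity threshold",
      x$threshold, "%\n")
  invisible(x)
}

#' Genus-sharing table of core peptides
#'
#' Counts occurrences of each core per genus and keeps only cores whose
#' total occurrence count is strictly above ten (the display rule for
#' genus-sharing summaries: "above ten" is strict). Rows are sorted by core
#' then count descending.
#'
#' @param coreOccurrences Data frame with columns \code{core_id} and
#'   \code{genus}, one row per occurrence.
#' @return Data frame with \code{core_id}, \code{genus}, \code{count}.
#' @export
genusSharingTable <- function(coreOccurrences) {
  empty <- data.frame(core_id = character(), genus = character(),
                      count = integer(), stringsAsFactors = FALSE)
  if (is.null(coreOccurrences) || nrow(coreOccurrences) == 0) return(empty)
  tab <- as.data.frame(table(core_id = coreOccurrences$core_id,
                             genus = coreOccurrences$genus),
                       stringsAsFactors = FALSE)
  names(tab)[3] <- "count"
  tab <- tab[tab$count > 0, , drop = FALSE]
  totals <- tapply(tab$count, tab$core_id, sum)
  keep_cores <- names(totals)[totals > 10]
  tab <- tab[tab$core_id %in% keep_cores, , drop = FALSE]
  if (nrow(tab) == 0) return(empty)
  tab <- tab[order(tab$core_id, -tab$count, tab$genus), , drop = FALSE]
  rownames(tab) <- NULL
  tab$count <- as.integer(tab$count)
  tab
}

#' Percentage of genomes matching a filter
#'
#' Reports numerator count, denominator count and the percentage rounded
#' half-up to one decimal, the convention used for printed cohort
#' percentages.
#'
#' @param countNum Numerator count (or, with \code{metadata}, a predicate
#'   function over metadata rows).
#' @param countDen Denominator count (or a predicate; \code{NULL} means all
#'   rows).
#' @param metadata Optional data frame of genome metadata records; when
#'   given, \code{countNum}/\code{countDen} are predicate functions applied
#'   to it.
#' @return List with \code{count_num}, \code{count_den}, \code{pct}.
#' @examples
#' metadataPercentage(237, 294)$pct  # 80.6
#' @export
metadataPercentage <- function(countNum, countDen, metadata = NULL) {
  if (!is.null(metadata)) {
    den_rows <- if (is.null(countDen)) rep(TRUE, nrow(metadata)) else
      countDen(metadata)
    num_rows <- countNum(metadata) & den_rows
    countNum <- sum(num_rows)
    countDen <- sum(den_rows)
  }
  if (countDen <= 0) .stopf("denominator must be positive")
  list(count_num = as.integer(countNum), count_den = as.integer(countDen),
       pct = roundHalfUp(100 * countNum / countDen, 1))
}
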