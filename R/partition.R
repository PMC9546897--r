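#' Coerce to a partition tibble
#'
#' A partition maps every node to exactly one (opaque) community label.  It
#' is represented as a tibble with character columns `node` and `community`.
#'
#' @param x A tibble/data.frame with columns `node` and `community`, or a
#'   vector of labels named by node.
#' @return A tibble with columns `node` and `community`, sorted by node.
#' @export
as_partition <- function(x) {
  if (is.data.frame(x)) {
    if (!all(c("node", "community") %in% names(x))) {
      stop("a partition data frame needs columns `node` and `community`",
           call. = FALSE)
    }
    out <- tibble::tibble(node = as.character(x$node),
                          community = as.character(x$community))
  } else if (is.vector(x) && !is.null(names(x))) {
    out <- tibble::tibble(node = names(x), community = as.character(x))
  } else {
    stop("cannot interpret `x` as a partition", call. = FALSE)
  }
  if (anyDuplicated(out$node)) {
    stop("partition assigns more than one community to a node", call. = FALSE)
  }
  dplyr::arrange(out, .data$node)
}

# membership vector (integer codes) aligned with the graph's vertex order;
# errors if any node is missing from the partition
partition_membership <- function(graph, partition) {
  nm <- igraph::V(graph)$name
  idx <- match(nm, partition$node)
  if (anyNA(idx)) {
    stop("partition is missing node(s): ",
         paste(utils::head(nm[is.na(idx)], 5), collapse = ", "), call. = FALSE)
  }
  as.integer(factor(partition$community[idx]))
}

#' Read / write partitions
#'
#' Partitions are exchanged as two-column TSV (`node<TAB>label`, no header)
#' or as a JSON object mapping node to label.
#'
#' @param path File path; format decided by extension (`.json` vs TSV).
#' @return [read_partition()] returns a partition tibble;
#'   [write_partition()] returns `path` invisibly.
#' @export
read_partition <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- tibble::tibble(node = names(m), community = as.character(unlist(m)))
  } else {
    df <- utils::read.table(path, sep = "\t", header = FALSE,
                            colClasses = "character", quote = "",
                            col.names = c("node", "community"))
    out <- tibble::as_tibble(df)
  }
  as_partition(out)
}

#' @param partition A partition (see [as_partition()]).
#' @rdname read_partition
#' @export
write_partition <- function(partition, path) {
  partition <- as_partition(partition)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    m <- as.list(stats::setNames(partition$community, partition$node))
    jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE)
  } else {
    utils::write.table(partition, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Adjusted Rand index between two partitions
#'
#' Hubert-Arabie chance-corrected agreement computed from the contingency
#' table of the two labelings.  Equals 1 for identical partitions (up to
#' label permutation) and is close to 0 for independent random assignments.
#'
#' @param p1,p2 Partitions over the same node set (see [as_partition()]).
#' @return A single number \eqn{\le 1}.
#' @export
adjusted_rand_index <- function(p1, p2) {
  p1 <- as_partition(p1)
  p2 <- as_partition(p2)
  if (!identical(p1$node, p2$node)) {
    stop("partitions are defined on different node sets", call. = FALSE)
  }
  n <- nrow(p1)
  tab <- table(p1$community, p2$community)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  expected <- sum_a * sum_b / choose2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)   # both partitions trivial
  (sum_ij - expected) / (max_index - expected)
}
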