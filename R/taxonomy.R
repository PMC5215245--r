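#' Load a taxonomy tree
#'
#' Reads a rooted taxonomy from either the NCBI dump dialect (`nodes.dmp`,
#' fields separated by `"\t|\t"`, optionally paired with `names.dmp`) or a
#' compact 4-column TSV (`taxid  parent  rank  name`, header required).
#' The format is auto-detected from the first line.
#'
#' The returned tree is validated: every `parent` must refer to an existing
#' node, exactly one node is its own parent (the root), and every node must
#' reach the root by parent traversal (no cycles).
#'
#' @param nodes_source Path to `nodes.dmp` or to a compact TSV.
#' @param names_source Path to `names.dmp` (scientific names). Ignored for
#'   the compact format, which carries names inline. Optional; without it a
#'   dmp-loaded tree has taxid strings as names.
#' @param merged_source Optional path to `merged.dmp` (old taxid -> new
#'   taxid remapping); remapped ids are resolvable through
#'   [resolve_taxid()].
#' @return A `taxonomy_tree` object: list with `nodes` (data.frame of
#'   `taxid`, `parent`, `rank`, `name`), `root` (taxid), and internal
#'   lookup indexes.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' writeLines(c("taxid\tparent\trank\tname",
#'              "1\t1\tno rank\troot",
#'              "10\t1\tfamily\tExamplaceae",
#'              "11\t10\tgenus\tExamplus"), tsv)
#' tree <- load_taxonomy(tsv)
#' ancestor_at_rank(tree, 11, "family")
#' @export
load_taxonomy <- function(nodes_source, names_source = NULL,
                          merged_source = NULL) {
  lines <- readLines(nodes_source, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty taxonomy file: ", nodes_source)

  if (grepl("\t\\|", lines[[1L]])) {
    nodes <- parse_nodes_dmp(lines)
    if (!is.null(names_source)) {
      nm <- parse_names_dmp(readLines(names_source, warn = FALSE))
      idx <- match(nodes$taxid, nm$taxid)
      nodes$name <- ifelse(is.na(idx), as.character(nodes$taxid), nm$name[idx])
    } else {
      nodes$name <- as.character(nodes$taxid)
    }
  } else {
    nodes <- parse_nodes_tsv(lines)
  }

  merged <- integer(0)
  if (!is.null(merged_source)) {
    ml <- readLines(merged_source, warn = FALSE)
    ml <- ml[nzchar(ml)]
    parts <- strsplit(ml, "\t\\|\t?|\t")
    old <- as.integer(vapply(parts, `[[`, "", 1L))
    new <- as.integer(vapply(parts, `[[`, "", 2L))
    merged <- stats::setNames(new, as.character(old))
  }

  new_taxonomy_tree(nodes, merged)
}

parse_nodes_dmp <- function(lines) {
  parts <- strsplit(sub("\t\\|$", "", lines), "\t\\|\t")
  data.frame(
    taxid  = as.integer(vapply(parts, `[[`, "", 1L)),
    parent = as.integer(vapply(parts, `[[`, "", 2L)),
    rank   = trimws(vapply(parts, `[[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

parse_names_dmp <- function(lines) {
  lines <- lines[nzchar(lines)]
  parts <- strsplit(sub("\t\\|$", "", lines), "\t\\|\t")
  keep <- vapply(parts, function(p)
    length(p) < 4L || trimws(p[[4L]]) == "scientific name", TRUE)
  parts <- parts[keep]
  data.frame(
    taxid = as.integer(vapply(parts, `[[`, "", 1L)),
    name  = trimws(vapply(parts, `[[`, "", 2L)),
    stringsAsFactors = FALSE
  )
}

parse_nodes_tsv <- function(lines) {
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  want <- c("taxid", "parent", "rank", "name")
  if (!all(want %in% tolower(header)))
    stop("compact taxonomy TSV must have header columns: ",
         paste(want, collapse = ", "))
  col <- match(want, tolower(header))
  parts <- strsplit(lines[-1L], "\t", fixed = TRUE)
  if (length(parts) == 0L) stop("taxonomy TSV has a header but no rows")
  data.frame(
    taxid  = as.integer(vapply(parts, `[[`, "", col[[1L]])),
    parent = as.integer(vapply(parts, `[[`, "", col[[2L]])),
    rank   = vapply(parts, `[[`, "", col[[3L]]),
    name   = vapply(parts, `[[`, "", col[[4L]]),
    stringsAsFactors = FALSE
  )
}

new_taxonomy_tree <- function(nodes, merged = integer(0)) {
  if (anyDuplicated(nodes$taxid))
    stop("duplicate taxid in taxonomy: ",
         paste(unique(nodes$taxid[duplicated(nodes$taxid)]), collapse = ", "))
  key <- as.character(nodes$taxid)
  parent_of <- stats::setNames(nodes$parent, key)
  dangling <- setdiff(nodes$parent, nodes$taxid)
  if (length(dangling))
    stop("dangling parent taxid(s) in taxonomy: ",
         paste(dangling, collapse = ", "))
  roots <- nodes$taxid[nodes$taxid == nodes$parent]
  if (length(roots) != 1L)
    stop("taxonomy must have exactly one root (self-parent node), found ",
         length(roots))
  root <- roots[[1L]]

  # depth by parent traversal; a node that cannot reach the root in n steps
  # sits on a cycle
  n <- nrow(nodes)
  depth <- stats::setNames(rep.int(NA_integer_, n), key)
  depth[as.character(root)] <- 0L
  for (i in seq_len(n)) {
    if (!anyNA(depth)) break
    pd <- depth[as.character(parent_of)]
    newly <- is.na(depth) & !is.na(pd)
    depth[newly] <- pd[newly] + 1L
  }
  if (anyNA(depth))
    stop("cycle detected in taxonomy (nodes not reaching root): ",
         paste(names(depth)[is.na(depth)], collapse = ", "))

  structure(
    list(
      nodes = nodes,
      root = root,
      parent_of = parent_of,
      rank_of = stats::setNames(nodes$rank, key),
      name_of = stats::setNames(nodes$name, key),
      depth_of = depth,
      name_index = split(nodes$taxid, tolower(nodes$name)),
      merged = merged
    ),
    class = "taxonomy_tree"
  )
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("taxonomy_tree:", nrow(x$nodes), "nodes, root taxid", x$root, "\n")
  cat("ranks:", paste(sort(unique(x$nodes$rank)), collapse = ", "), "\n")
  invisible(x)
}

has_taxid <- function(tree, taxid) {
  as.character(taxid) %in% names(tree$parent_of)
}

#' Resolve a taxid through the merged-id remapping
#'
#' @param tree A `taxonomy_tree`.
#' @param taxid Integer taxid, possibly retired and remapped.
#' @return The current taxid, or `NA` if unknown.
#' @export
resolve_taxid <- function(tree, taxid) {
  key <- as.character(taxid)
  out <- ifelse(key %in% names(tree$parent_of), taxid,
                unname(tree$merged[key]))
  as.integer(out)
}

#' Resolve a scientific name to a taxid
#'
#' Exact, case-insensitive match on scientific names. When a name maps to
#' several nodes the shallowest node wins and a warning is emitted; with
#' `strict = TRUE` an unresolvable name is an error instead of `NA`.
#'
#' @param tree A `taxonomy_tree`.
#' @param name Scientific name string.
#' @param strict Error on unresolvable names instead of returning `NA`.
#' @return Integer taxid or `NA`.
#' @export
resolve_name <- function(tree, name, strict = FALSE) {
  hits <- tree$name_index[[tolower(name)]]
  if (is.null(hits)) {
    if (strict) stop("unresolvable taxon name: ", name)
    return(NA_integer_)
  }
  if (length(hits) > 1L) {
    hits <- hits[order(tree$depth_of[as.character(hits)], hits)]
    warning("ambiguous taxon name '", name, "' (",
            length(hits), " nodes); using shallowest taxid ", hits[[1L]])
  }
  hits[[1L]]
}

root_path <- function(tree, taxid) {
  key <- as.character(taxid)
  path <- integer(0)
  repeat {
    path <- c(path, as.integer(key))
    parent <- tree$parent_of[[key]]
    if (parent == as.integer(key)) break
    key <- as.character(parent)
  }
  path
}

#' Ancestor of a taxon at a fixed rank
#'
#' Walks the parent chain from `taxid` (inclusive) to the root and returns
#' the first node whose rank equals `rank`, or `NA` when no ancestor has
#' that rank. Inclusive: a node that already has the requested rank returns
#' itself. Vectorised over `taxid`.
#'
#' @param tree A `taxonomy_tree`.
#' @param taxid Integer taxid(s); must exist in the tree.
#' @param rank Target rank label, e.g. `"family"` or `"genus"`.
#' @return Integer taxid(s) or `NA` where no ancestor carries the rank.
#' @export
ancestor_at_rank <- function(tree, taxid, rank) {
  vapply(taxid, function(tx) {
    key <- as.character(tx)
    if (!key %in% names(tree$parent_of))
      stop("unknown taxid: ", tx)
    repeat {
      if (tree$rank_of[[key]] == rank) return(as.integer(key))
      parent <- tree$parent_of[[key]]
      if (parent == as.integer(key)) return(NA_integer_)
      key <- as.character(parent)
    }
  }, integer(1))
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node lying on every member's path to the root; a singleton
#' set returns its element.
#'
#' @param tree A `taxonomy_tree`.
#' @param taxids Non-empty vector of taxids, all present in the tree.
#' @return Integer taxid of the LCA.
#' @export
lowest_common_ancestor <- function(tree, taxids) {
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0L) stop("lowest_common_ancestor: empty taxid set")
  for (tx in taxids)
    if (!has_taxid(tree, tx)) stop("unknown taxid: ", tx)
  common <- Reduce(intersect, lapply(taxids, root_path, tree = tree))
  common[which.max(tree$depth_of[as.character(common)])]
}

#' Normalize taxonomic assignments to a fixed rank
#'
#' Projects every classified entry of an assignment table onto its ancestor
#' at `rank`. Entries whose lineage has no node at that rank (calls made
#' above the rank, e.g. an order-level call normalized to family) become
#' `unclassified`; existing `unclassified`/`discarded` rows pass through
#' untouched. Rows carrying a `name` instead of a taxid are resolved
#' through [resolve_name()] first.
#'
#' @param tree A `taxonomy_tree`.
#' @param raw Assignment table: data.frame with columns `read_id`,
#'   `status` (`classified`/`unclassified`/`discarded`) and `taxid`
#'   (and/or `name` for name-based pipelines).
#' @param rank Target rank label.
#' @param strict Error on unresolvable names/taxids; otherwise they are
#'   downgraded to `unclassified` with a message.
#' @return An assignment table of the same number of rows, all classified
#'   taxids at `rank`.
#' @export
normalize_assignments <- function(tree, raw, rank, strict = FALSE) {
  raw <- as_assignment_table(raw)
  out <- raw
  cls <- which(raw$status == "classified")
  if (length(cls) == 0L) return(out)

  taxid <- raw$taxid[cls]
  if ("name" %in% names(raw)) {
    need <- is.na(taxid) & !is.na(raw$name[cls]) & nzchar(raw$name[cls])
    if (any(need))
      taxid[need] <- vapply(raw$name[cls][need], function(nm)
        resolve_name(tree, nm, strict = strict), integer(1))
  }
  taxid <- resolve_taxid(tree, taxid)

  unresolved <- is.na(taxid) | !vapply(taxid, function(tx)
    isTRUE(has_taxid(tree, tx)), TRUE)
  if (any(unresolved)) {
    if (strict)
      stop("unresolvable assignment taxid(s) for read(s): ",
           paste(utils::head(raw$read_id[cls][unresolved], 5L), collapse = ", "))
    message(sum(unresolved), " assignment(s) unresolvable; marked unclassified")
  }

  proj <- rep(NA_integer_, length(taxid))
  ok <- !unresolved
  if (any(ok)) proj[ok] <- ancestor_at_rank(tree, taxid[ok], rank)

  got <- !is.na(proj)
  out$taxid[cls] <- proj
  out$status[cls][!got] <- "unclassified"
  out$taxid[cls][!got] <- NA_integer_
  out
}

#' Coerce a data.frame to a validated assignment table
#'
#' @param x data.frame with `read_id`, `status`, `taxid` (taxid required
#'   iff status is `classified`; a `name` column may stand in for taxids).
#' @return The validated data.frame.
#' @export
as_assignment_table <- function(x) {
  x <- as.data.frame(x, stringsAsFactors = FALSE)
  need <- c("read_id", "status")
  if (!all(need %in% names(x)))
    stop("assignment table needs columns: ", paste(need, collapse = ", "))
  if (!"taxid" %in% names(x)) x$taxid <- NA_integer_
  x$taxid <- suppressWarnings(as.integer(x$taxid))
  bad <- !x$status %in% c("classified", "unclassified", "discarded")
  if (any(bad))
    stop("invalid status at row(s): ",
         paste(utils::head(which(bad), 5L), collapse = ", "))
  if (anyDuplicated(x$read_id))
    stop("duplicate read_id(s) in assignment table")
  has_name <- if ("name" %in% names(x)) {
    !is.na(x$name) & nzchar(x$name)
  } else rep(FALSE, nrow(x))
  no_tax <- x$status == "classified" & is.na(x$taxid) & !has_name
  if (any(no_tax))
    stop("classified rows must carry a taxid (or a name column)")
  x
}

#' Read an assignment TSV (read_id, status, taxid[, name])
#' @param path TSV path with header.
#' @return Assignment table data.frame.
#' @export
read_assignments <- function(path) {
  as_assignment_table(utils::read.delim(path, stringsAsFactors = FALSE))
}
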