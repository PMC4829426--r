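#' The seven canonical taxonomic ranks
#'
#' All classifiers in this package vote over the same seven ranks, ordered
#' from shallowest to deepest: superkingdom, phylum, class, order, family,
#' genus, species. A synthetic rank-less root sits above superkingdom so
#' that "unclassified" is representable as an empty lineage.
#'
#' @return Character vector of the seven rank names in order.
#' @export
#' @examples
#' tax_ranks()
tax_ranks <- function() {
  c("superkingdom", "phylum", "class", "order", "family", "genus", "species")
}

#' Build a seven-rank taxonomy from nodes and names tables
#'
#' Reads NCBI-taxdump-like tables (`taxon_id`, `parent_id`, `rank` and
#' optionally `taxon_id`, `name`) and returns a validated taxonomy object.
#' Nodes at non-canonical ranks (e.g. suborder, tribe, "no rank") are
#' projected out: their children are re-attached to the nearest ancestor at
#' one of the seven canonical ranks (or to the root). After projection every
#' non-root node's parent must be exactly one rank shallower.
#'
#' The root is the unique node whose `parent_id` is missing, empty, or equal
#' to its own `taxon_id`. A second self-parented node is reported as a cycle.
#'
#' @param nodes Data frame with columns `taxon_id`, `parent_id`, `rank`, or
#'   the path of a tab-separated file with those columns (header optional,
#'   columns in that order).
#' @param names Optional data frame with columns `taxon_id`, `name`, or a
#'   TSV path. Taxa without a name entry use their id as name.
#' @return An object of class `taxonomy`: a list with `nodes` (tibble of
#'   `taxon_id`, `parent_id`, `rank`, `name` for the seven-rank projection),
#'   `root_id`, and an internal ancestor table used by [lineage_of()].
#' @seealso [lineage_of()], [lca()], [lineage_names()]
#' @export
#' @examples
#' nodes <- data.frame(
#'   taxon_id  = c("1", "2", "3"),
#'   parent_id = c("1", "1", "2"),
#'   rank      = c("root", "superkingdom", "phylum")
#' )
#' nms <- data.frame(taxon_id = c("2", "3"),
#'                   name = c("Bacteria", "Bacteroidetes"))
#' tree <- load_taxonomy(nodes, nms)
#' lineage_of(tree, "3")
load_taxonomy <- function(nodes, names = NULL) {
  nodes <- read_tax_table(nodes, c("taxon_id", "parent_id", "rank"))
  names_tbl <- if (is.null(names)) {
    tibble(taxon_id = character(), name = character())
  } else {
    read_tax_table(names, c("taxon_id", "name"))
  }

  id <- as.character(nodes$taxon_id)
  parent <- as.character(nodes$parent_id)
  rank <- tolower(trimws(as.character(nodes$rank)))

  if (anyDuplicated(id)) {
    abort(paste0("duplicate taxon_id(s): ",
                 paste(unique(id[duplicated(id)]), collapse = ", ")))
  }

  is_root_like <- is.na(parent) | parent == "" | parent == id
  if (sum(is_root_like) == 0) {
    abort("no root node found (expect one node with parent_id missing or equal to its taxon_id)")
  }
  if (sum(is_root_like) > 1) {
    abort(paste0("multiple roots or self-parent cycle detected: taxon_id(s) ",
                 paste(id[is_root_like], collapse = ", ")))
  }
  root_id <- id[is_root_like]
  parent[is_root_like] <- NA_character_
  if (rank[is_root_like] %in% tax_ranks()) {
    # the table's top node has a canonical rank (e.g. a bare superkingdom
    # chain): insert the synthetic rank-less root above it
    synthetic <- if ("root" %in% id) "__root__" else "root"
    parent[is_root_like] <- synthetic
    id <- c(synthetic, id)
    parent <- c(NA_character_, parent)
    rank <- c("root", rank)
    root_id <- synthetic
  }

  unknown <- !is.na(parent) & !(parent %in% id)
  if (any(unknown)) {
    abort(paste0("unknown parent_id for taxon_id(s): ",
                 paste(id[unknown], collapse = ", ")))
  }

  parent_of <- setNames(parent, id)

  # walk each node to the root; more steps than nodes implies a cycle
  n <- length(id)
  for (i in seq_len(n)) {
    cur <- id[i]
    steps <- 0L
    while (!is.na(parent_of[[cur]])) {
      cur <- parent_of[[cur]]
      steps <- steps + 1L
      if (steps > n) abort(paste0("cycle detected involving taxon_id ", id[i]))
    }
  }

  ranks7 <- tax_ranks()
  rank_of <- setNames(rank, id)
  canonical <- rank %in% ranks7

  # project: re-parent every node to its nearest canonical (or root) ancestor
  nearest_canonical <- function(x) {
    p <- parent_of[[x]]
    while (!is.na(p) && !(rank_of[[p]] %in% ranks7) && p != root_id) {
      p <- parent_of[[p]]
    }
    if (is.na(p)) NA_character_ else p
  }
  keep <- canonical | id == root_id
  proj_parent <- vapply(id[keep], nearest_canonical, character(1))

  kid <- id[keep]
  krank <- rank[keep]
  ord <- match(krank, ranks7)          # NA for the root
  ord[kid == root_id] <- 0L

  parent_ord <- ord[match(proj_parent, kid)]
  parent_ord[is.na(proj_parent)] <- -1L  # root itself
  bad <- !is.na(ord) & ord > 0L & parent_ord != ord - 1L
  if (any(bad)) {
    abort(paste0(
      "rank gap after projection: taxon_id(s) ",
      paste(kid[bad], collapse = ", "),
      " are not exactly one rank below their parent"))
  }

  name_of <- setNames(kid, kid)
  hit <- match(kid, as.character(names_tbl$taxon_id))
  name_of[!is.na(hit)] <- as.character(names_tbl$name)[hit[!is.na(hit)]]

  # ancestor table: row per taxon, column per rank, entries are taxon ids
  anc <- matrix(NA_character_, nrow = length(kid), ncol = 7,
                dimnames = list(kid, ranks7))
  pp <- setNames(proj_parent, kid)
  for (i in order(ord)) {                 # parents before children
    if (ord[i] == 0L) next
    x <- kid[i]
    p <- pp[[x]]
    if (!is.na(p) && p != root_id) anc[x, ] <- anc[p, ]
    anc[x, ord[i]] <- x
  }

  structure(
    list(
      nodes = tibble(
        taxon_id = kid,
        parent_id = unname(ifelse(is.na(pp), NA_character_, pp)),
        rank = ifelse(ord == 0L, "root", krank),
        name = unname(name_of[kid])
      ),
      root_id = root_id,
      ancestors = anc,
      depth = setNames(ord, kid),
      name_of = name_of
    ),
    class = "taxonomy"
  )
}

read_tax_table <- function(x, cols) {
  if (is.character(x) && length(x) == 1 && file.exists(x)) {
    first <- readr::read_lines(x, n_max = 1)
    has_header <- grepl(cols[1], first, fixed = TRUE)
    x <- readr::read_tsv(
      x, col_names = has_header, show_col_types = FALSE,
      col_types = readr::cols(.default = readr::col_character())
    )
    if (!has_header) x <- setNames(x[, seq_along(cols)], cols)
  }
  x <- as_tibble(x)
  missing_cols <- setdiff(cols, names(x))
  if (length(missing_cols) > 0 && ncol(x) >= length(cols) &&
      !any(cols %in% names(x))) {
    x <- setNames(x[, seq_along(cols)], cols)
  } else if (length(missing_cols) > 0) {
    abort(paste0("missing column(s): ", paste(missing_cols, collapse = ", ")))
  }
  x
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", nrow(x$nodes) - 1L, " taxa over ",
      length(tax_ranks()), " ranks (root: ", x$root_id, ")\n", sep = "")
  invisible(x)
}

#' Root-to-taxon lineage of a taxon
#'
#' Returns the taxon's full lineage as an ordered character vector of taxon
#' ids from superkingdom down to the taxon's own rank (length 0 for the
#' root, length 7 for a species).
#'
#' @param tree A `taxonomy` from [load_taxonomy()].
#' @param taxon_id Single taxon id present in the tree.
#' @return Character vector of taxon ids (possibly empty).
#' @export
lineage_of <- function(tree, taxon_id) {
  stopifnot(inherits(tree, "taxonomy"))
  taxon_id <- as.character(taxon_id)
  if (!(taxon_id %in% rownames(tree$ancestors))) {
    abort(paste0("unknown taxon_id: ", taxon_id))
  }
  d <- tree$depth[[taxon_id]]
  if (d == 0L) return(character(0))
  unname(tree$ancestors[taxon_id, seq_len(d)])
}

#' Lowest common ancestor of a set of lineages
#'
#' The LCA of lineages (each an ordered vector of taxon ids, superkingdom
#' first) is their longest common prefix. An empty lineage among the inputs
#' absorbs everything: the result is empty.
#'
#' @param lineages Non-empty list of lineage vectors from one tree.
#' @return A lineage (character vector, possibly empty).
#' @export
#' @examples
#' lca(list(c("b", "p", "c1"), c("b", "p", "c2")))  # c("b", "p")
lca <- function(lineages) {
  if (!is.list(lineages) || length(lineages) == 0) {
    abort("lca() needs a non-empty list of lineages")
  }
  Reduce(function(a, b) {
    k <- min(length(a), length(b))
    if (k == 0) return(character(0))
    same <- a[seq_len(k)] == b[seq_len(k)]
    m <- if (all(same)) k else which(!same)[1] - 1L
    if (m == 0) character(0) else a[seq_len(m)]
  }, lineages)
}

#' Translate a lineage of taxon ids to taxon names
#'
#' @param tree A `taxonomy`.
#' @param lineage Character vector of taxon ids.
#' @return Character vector of names, same length.
#' @export
lineage_names <- function(tree, lineage) {
  stopifnot(inherits(tree, "taxonomy"))
  unname(tree$name_of[as.character(lineage)])
}

#' Serialise / parse semicolon-joined lineage strings
#'
#' `lineage_string()` joins a lineage's taxon names with `";"` (empty
#' lineage gives `""`); `parse_lineage()` resolves such a string back to
#' taxon ids, requiring each name to be unambiguous in the tree.
#'
#' @param tree A `taxonomy`.
#' @param lineage Character vector of taxon ids.
#' @param string Semicolon-joined taxon names.
#' @return `lineage_string()`: a single string. `parse_lineage()`: a
#'   character vector of taxon ids.
#' @export
lineage_string <- function(tree, lineage) {
  paste(lineage_names(tree, lineage), collapse = ";")
}

#' @rdname lineage_string
#' @export
parse_lineage <- function(tree, string) {
  stopifnot(inherits(tree, "taxonomy"))
  if (is.na(string) || string == "") return(character(0))
  nms <- strsplit(string, ";", fixed = TRUE)[[1]]
  ids <- character(length(nms))
  for (i in seq_along(nms)) {
    hits <- tree$nodes$taxon_id[tree$nodes$name == nms[i]]
    if (length(hits) == 0) abort(paste0("unknown taxon name: ", nms[i]))
    if (length(hits) > 1) abort(paste0("ambiguous taxon name: ", nms[i]))
    ids[i] <- hits
  }
  ids
}

# lineage (id vector) -> padded 7-slot vector, NA beyond depth
lineage_pad <- function(lineage) {
  out <- rep(NA_character_, 7)
  if (length(lineage) > 0) out[seq_along(lineage)] <- lineage
  out
}
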