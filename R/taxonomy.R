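#' @import data.table
NULL

# The seven named ranks reported by the pipeline, deepest first.
NAMED_RANKS <- c("species", "genus", "family", "order", "class", "phylum",
                 "superkingdom")

#' Load an NCBI-style taxonomy
#'
#' Reads `nodes.dmp` / `names.dmp` dialect files (fields separated by
#' `"\t|\t"`, records terminated by `"\t|"`) into an in-memory tree that
#' supports lineage, rank and lowest-common-ancestor queries. Ranks outside
#' the seven named levels (species, genus, family, order, class, phylum,
#' superkingdom) are mapped to `"no_rank"`. Taxid 0 is reserved for
#' "unclassified" and is never a member of the tree.
#'
#' @param nodes_path Path to a nodes.dmp-style file
#'   (taxid | parent taxid | rank | ...).
#' @param names_path Path to a names.dmp-style file
#'   (taxid | name | unique name | name class). When several names exist for a
#'   taxid the `scientific name` class is preferred.
#' @return An object of class `taxonomy_tree`: a list with integer vector
#'   `taxid`, named integer vector `parent`, named character vectors `rank`
#'   and `name` (names are taxids as character), and scalar `root`.
#' @export
load_taxonomy <- function(nodes_path, names_path) {
  nodes <- parse_dmp(nodes_path)
  if (ncol(nodes) < 3L)
    stop("nodes file must have at least 3 fields (taxid, parent, rank)")
  taxid  <- as.integer(nodes[[1]])
  parent <- as.integer(nodes[[2]])
  rank   <- as.character(nodes[[3]])
  rank[!(rank %in% NAMED_RANKS)] <- "no_rank"

  nm <- parse_dmp(names_path)
  name <- rep(NA_character_, length(taxid))
  names(name) <- as.character(taxid)
  if (nrow(nm) > 0L) {
    cls <- if (ncol(nm) >= 4L) as.character(nm[[4]]) else
      rep("scientific name", nrow(nm))
    ord <- order(cls != "scientific name")  # scientific names first
    nm_tax <- as.character(as.integer(nm[[1]]))[ord]
    nm_txt <- as.character(nm[[2]])[ord]
    keep <- !duplicated(nm_tax)
    hit <- nm_tax[keep] %in% names(name)
    name[nm_tax[keep][hit]] <- nm_txt[keep][hit]
  }
  name[is.na(name)] <- paste0("taxid_", names(name)[is.na(name)])

  tree <- structure(
    list(taxid = taxid,
         parent = stats::setNames(parent, as.character(taxid)),
         rank = stats::setNames(rank, as.character(taxid)),
         name = stats::setNames(name, as.character(taxid)),
         root = NA_integer_),
    class = "taxonomy_tree")
  validate_taxonomy(tree)
}

# Split a dmp file on the NCBI "\t|\t" delimiter; trailing "\t|" stripped.
parse_dmp <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  lines <- sub("\t\\|$", "", lines)
  parts <- strsplit(lines, "\t\\|\t", fixed = FALSE)
  n <- if (length(parts)) max(lengths(parts)) else 0L
  cols <- lapply(seq_len(n), function(i)
    vapply(parts, function(p) if (length(p) >= i) p[[i]] else NA_character_, ""))
  data.table::as.data.table(cols)
}

validate_taxonomy <- function(tree) {
  if (anyDuplicated(tree$taxid))
    stop("duplicate taxid in nodes file: ",
         tree$taxid[duplicated(tree$taxid)][1])
  if (any(tree$taxid <= 0L))
    stop("taxids must be positive integers (taxid 0 is reserved for unclassified)")
  is_root <- tree$parent == tree$taxid
  if (sum(is_root) != 1L)
    stop("taxonomy must have exactly one root (parent == taxid), found ",
         sum(is_root))
  tree$root <- tree$taxid[is_root]
  missing_parent <- setdiff(tree$parent, tree$taxid)
  if (length(missing_parent))
    stop("taxonomy parse error: node(s) with absent parent taxid ",
         paste(missing_parent, collapse = ", "))
  # cycle check: every lineage must reach root within |nodes| steps
  for (t in tree$taxid) {
    cur <- t
    for (i in seq_len(length(tree$taxid) + 1L)) {
      if (cur == tree$root) break
      cur <- tree$parent[[as.character(cur)]]
      if (i > length(tree$taxid))
        stop("cycle detected in taxonomy at taxid ", t)
    }
  }
  tree
}

has_taxid <- function(tree, taxid) {
  as.character(taxid) %in% names(tree$parent)
}

#' Lineage of a taxid (root first)
#'
#' @param tree A `taxonomy_tree`.
#' @param taxid A single taxid present in the tree.
#' @return Integer vector of taxids ordered root -> `taxid`; consecutive
#'   elements are parent -> child.
#' @export
lineage <- function(tree, taxid) {
  taxid <- as.integer(taxid)
  if (length(taxid) != 1L || !has_taxid(tree, taxid))
    stop("unknown taxid: ", taxid)
  path <- integer(0)
  cur <- taxid
  repeat {
    path <- c(cur, path)
    if (cur == tree$root) break
    cur <- tree$parent[[as.character(cur)]]
  }
  path
}

#' Lowest common ancestor of a set of taxids
#'
#' @param tree A `taxonomy_tree`.
#' @param taxids Nonempty vector of taxids, all present in the tree.
#' @return The deepest taxid present on every input lineage.
#' @export
lca <- function(tree, taxids) {
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0L) stop("lca() requires a nonempty set of taxids")
  lins <- lapply(taxids, function(t) lineage(tree, t))
  common <- Reduce(intersect, lins)
  # lineages share a root-anchored prefix, so the last common element is deepest
  common[length(common)]
}

#' Rank of a taxid
#' @param tree A `taxonomy_tree`.
#' @param taxid Vector of taxids.
#' @return Character vector of ranks (`"no_rank"` for unnamed levels).
#' @export
taxon_rank <- function(tree, taxid) {
  unname(tree$rank[as.character(taxid)])
}

#' Scientific name of a taxid
#' @inheritParams taxon_rank
#' @return Character vector of names; taxid 0 maps to `"Unclassified"`.
#' @export
taxon_name <- function(tree, taxid) {
  out <- unname(tree$name[as.character(taxid)])
  out[taxid == 0L] <- "Unclassified"
  out
}

# Nearest ancestor (including self) carrying a named rank; NA if none below root.
named_rank_ancestor <- function(tree, taxid) {
  lin <- lineage(tree, taxid)
  ranks <- taxon_rank(tree, lin)
  named <- lin[ranks %in% NAMED_RANKS]
  if (length(named)) named[length(named)] else NA_integer_
}

# Ancestor of `taxid` at exactly `rank`, or NA.
ancestor_at_rank <- function(tree, taxid, rank) {
  lin <- lineage(tree, taxid)
  hit <- lin[taxon_rank(tree, lin) == rank]
  if (length(hit)) hit[length(hit)] else NA_integer_
}

#' Load an accession-to-taxid map
#'
#' Reads the NCBI accession2taxid 4-column layout (accession,
#' accession.version, taxid, gi), with or without a header row. Both the bare
#' accession and the versioned accession are indexed.
#'
#' @param path Path to the TSV file.
#' @return Named integer vector mapping accession (and accession.version)
#'   to taxid.
#' @export
load_accession_map <- function(path) {
  dt <- data.table::fread(path, header = "auto", sep = "\t",
                          colClasses = "character")
  if (ncol(dt) < 3L) stop("accession map must have >= 3 columns")
  # drop header row if fread kept it as data
  if (suppressWarnings(is.na(as.integer(dt[[3]][1])))) dt <- dt[-1]
  taxid <- as.integer(dt[[3]])
  m <- c(stats::setNames(taxid, dt[[1]]), stats::setNames(taxid, dt[[2]]))
  m[!duplicated(names(m))]
}

#' Look up the taxid for a gene/protein identifier
#'
#' The accession token is the identifier up to the first `|`, space or `_`
#' separator; the versioned and unversioned forms are both tried. Unmapped
#' accessions yield taxid 0 (unclassified).
#'
#' @param gene_id Character vector of gene or protein identifiers.
#' @param accession_map Named integer vector from [load_accession_map()].
#' @return Integer vector of taxids (0 where unmapped).
#' @export
accession_taxid <- function(gene_id, accession_map) {
  acc <- sub("[| _].*$", "", gene_id)
  bare <- sub("\\.\\d+$", "", acc)
  out <- accession_map[acc]
  miss <- is.na(out)
  out[miss] <- accession_map[bare[miss]]
  out[is.na(out)] <- 0L
  stats::setNames(as.integer(out), gene_id)
}
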