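# Lin's information-content similarity over a generic rooted concept taxonomy.
# Objects are mapped to taxonomy leaves; similarity between two objects is
# 2*IC(lcs) / (IC(a) + IC(b)) with IC(c) = -log(cumFreq(c) / cumFreq(root)).

#' Construct a concept taxonomy
#'
#' A taxonomy is a rooted tree of concepts with nonnegative corpus frequencies.
#' It is the substrate for information content and Lin similarity; objects in
#' an inventory point at its leaves.
#'
#' @param id character vector of concept identifiers (unique).
#' @param parent character vector, same length, the parent concept of each
#'   entry; `NA` for the single root.
#' @param frequency numeric vector of nonnegative corpus counts.
#' @return An object of class `taxonomy` with elements `id`, `parent`
#'   (named by `id`), `frequency` (named), `children` (list, named) and
#'   `root`.
#' @examples
#' tx <- taxonomy(
#'   id = c("root", "tool", "hammer", "saw"),
#'   parent = c(NA, "root", "tool", "tool"),
#'   frequency = c(0, 10, 5, 5)
#' )
#' taxonomy_leaves(tx)
#' @export
taxonomy <- function(id, parent, frequency) {
  id <- as.character(id)
  parent <- as.character(parent)
  frequency <- as.numeric(frequency)
  if (length(id) != length(parent) || length(id) != length(frequency)) {
    stop("id, parent and frequency must have equal length")
  }
  if (anyDuplicated(id)) {
    stop("duplicate concept ids: ", paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  if (any(frequency < 0, na.rm = TRUE) || anyNA(frequency)) {
    stop("frequencies must be nonnegative and non-missing")
  }
  is_root <- is.na(parent)
  if (sum(is_root) != 1L) {
    stop("taxonomy must have exactly one root (parent = NA), found ", sum(is_root))
  }
  root <- id[is_root]
  missing_parent <- setdiff(parent[!is_root], id)
  if (length(missing_parent)) {
    stop("parent concepts not in taxonomy: ", paste(missing_parent, collapse = ", "))
  }
  names(parent) <- id
  names(frequency) <- id
  # cycle check: every concept must reach the root
  depth <- .taxonomy_depths(id, parent, root)
  children <- split(id[!is_root], parent[!is_root])
  structure(
    list(id = id, parent = parent, frequency = frequency,
         children = children, root = root, depth = depth),
    class = "taxonomy"
  )
}

# depth of every concept; errors on cycles (walk length bounded by n)
.taxonomy_depths <- function(id, parent, root) {
  n <- length(id)
  depth <- stats::setNames(rep(NA_integer_, n), id)
  depth[root] <- 0L
  for (c0 in id) {
    if (!is.na(depth[[c0]])) next
    chain <- character(0)
    c <- c0
    while (is.na(depth[[c]])) {
      if (c %in% chain || length(chain) > n) {
        stop("cycle detected in taxonomy parent map")
      }
      chain <- c(chain, c)
      c <- parent[[c]]
    }
    base <- depth[[c]]
    for (k in seq_along(chain)) {
      depth[chain[k]] <- base + (length(chain) - k + 1L)
    }
  }
  depth
}

#' @rdname taxonomy
#' @param x a `taxonomy` object.
#' @export
taxonomy_leaves <- function(x) {
  stopifnot(inherits(x, "taxonomy"))
  setdiff(x$id, names(x$children))
}

#' @export
print.taxonomy <- function(x, ...) {
  cat("<taxonomy> ", length(x$id), " concepts, ",
      length(taxonomy_leaves(x)), " leaves, root '", x$root, "'\n", sep = "")
  invisible(x)
}

#' Read / write a taxonomy as JSON
#'
#' The file holds `{"concepts": [{"id", "parent", "frequency"}, ...]}`; the
#' root is the single concept with a null or absent parent.
#'
#' @param path file path.
#' @return `load_taxonomy()` returns a [taxonomy]; `save_taxonomy()` returns
#'   `path` invisibly.
#' @export
load_taxonomy <- function(path) {
  if (!file.exists(path)) stop("taxonomy file not found: ", path)
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(raw$concepts)) stop("taxonomy JSON must contain a 'concepts' array")
  df <- as.data.frame(raw$concepts)
  if (is.null(df$parent)) df$parent <- NA_character_
  taxonomy(df$id, df$parent, df$frequency)
}

#' @rdname load_taxonomy
#' @param tax a [taxonomy] object.
#' @export
save_taxonomy <- function(tax, path) {
  stopifnot(inherits(tax, "taxonomy"))
  df <- data.frame(id = tax$id, parent = unname(tax$parent),
                   frequency = unname(tax$frequency),
                   stringsAsFactors = FALSE)
  jsonlite::write_json(list(concepts = df), path, auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

# cumulative frequency: own count plus all descendants'
.cumulative_frequency <- function(tax) {
  cum <- tax$frequency
  ord <- names(sort(tax$depth, decreasing = TRUE))  # leaves first
  for (c in ord) {
    p <- tax$parent[[c]]
    if (!is.na(p)) cum[p] <- cum[p] + cum[c]
  }
  cum
}

#' Information content of every taxonomy concept
#'
#' IC(c) = -log(cumFreq(c) / cumFreq(root)), natural logarithm, where the
#' cumulative frequency of a concept is its own corpus count plus that of all
#' its descendants. The root always has IC 0; concepts with zero cumulative
#' frequency get `Inf` with a warning (they carry no probability mass).
#'
#' @param tax a [taxonomy].
#' @return An object of class `information_content`: a named numeric vector
#'   of IC values with the taxonomy attached as attribute `taxonomy`.
#' @examples
#' tx <- taxonomy(c("root", "a"), c(NA, "root"), c(75, 25))
#' ic <- compute_ic(tx)
#' ic[["a"]]  # -log(25/100)
#' @export
compute_ic <- function(tax) {
  stopifnot(inherits(tax, "taxonomy"))
  cum <- .cumulative_frequency(tax)
  total <- cum[[tax$root]]
  if (total <= 0) stop("taxonomy has zero total frequency; IC undefined")
  ic <- -log(cum / total)
  ic[cum == 0] <- Inf
  if (any(cum == 0)) {
    warning(sum(cum == 0), " concept(s) with zero cumulative frequency; IC set to Inf")
  }
  structure(ic, class = "information_content", taxonomy = tax)
}

# ancestor path from a concept up to (and including) the root
.ancestor_path <- function(tax, a) {
  path <- a
  while (!is.na(tax$parent[[a]])) {
    a <- tax$parent[[a]]
    path <- c(path, a)
  }
  path
}

# lowest common subsumer on a tree: deepest shared ancestor
.lcs <- function(tax, a, b) {
  pa <- .ancestor_path(tax, a)
  for (c in .ancestor_path(tax, b)) if (c %in% pa) return(c)
  tax$root
}

#' Lin similarity between two concepts
#'
#' `sim(a, b) = 2 * IC(lcs(a, b)) / (IC(a) + IC(b))` where `lcs` is the
#' lowest common subsumer (deepest shared ancestor). The measure lies in
#' `[0, 1]`: 1 for identical concepts with positive IC, 0 when the only
#' shared ancestor is the root.
#'
#' @param ic an [compute_ic()] result.
#' @param tax the taxonomy the IC was computed from.
#' @param a,b concept identifiers.
#' @return similarity in `[0, 1]`.
#' @export
lin_similarity <- function(ic, tax, a, b) {
  stopifnot(inherits(tax, "taxonomy"))
  for (c in c(a, b)) {
    if (!c %in% tax$id) stop("unknown concept: ", c)
  }
  ia <- ic[[a]]; ib <- ic[[b]]
  if (!is.finite(ia) || !is.finite(ib)) {
    stop("Lin similarity requires finite IC for both concepts")
  }
  if (a == b) {
    if (ia > 0) return(1)
    return(0)  # both sit at zero IC (root-level); no shared information
  }
  denom <- ia + ib
  if (denom == 0) return(0)
  2 * ic[[.lcs(tax, a, b)]] / denom
}

#' Pairwise Lin similarity matrix for an object inventory
#'
#' Maps every object to its taxonomy leaf and evaluates Lin similarity for
#' each of the `N(N-1)/2` unordered object pairs (1035 for the default
#' 46-object universe).
#'
#' @param inventory an [object_inventory].
#' @param tax the [taxonomy] the inventory's leaves live in.
#' @return A symmetric numeric matrix with unit diagonal, dimnames =
#'   object ids, class `similarity_matrix`.
#' @export
similarity_matrix <- function(inventory, tax) {
  stopifnot(inherits(inventory, "object_inventory"), inherits(tax, "taxonomy"))
  ic <- compute_ic(tax)
  ids <- inventory$object_id
  leaves <- inventory$taxonomy_leaf
  bad <- setdiff(leaves, tax$id)
  if (length(bad)) stop("taxonomy_leaf not in taxonomy: ", paste(bad, collapse = ", "))
  n <- length(ids)
  m <- diag(1, n)
  dimnames(m) <- list(ids, ids)
  if (n >= 2) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        s <- lin_similarity(ic, tax, leaves[i], leaves[j])
        m[i, j] <- s
        m[j, i] <- s
      }
    }
  }
  for (i in seq_len(n)) m[i, i] <- lin_similarity(ic, tax, leaves[i], leaves[i])
  class(m) <- c("similarity_matrix", class(m))
  m
}
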