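# Semantic reference list: the ordering of all objects that maximizes the
# summed pairwise similarity along an open path through the complete
# similarity graph -- an open-tour travelling-salesman problem. An exact
# dynamic program over vertex subsets handles small instances; greedy
# nearest-neighbour plus 2-opt handles the rest. Ties break by object-id
# lexicographic order throughout, so results are reproducible.

#' Maximum-similarity Hamiltonian path
#'
#' Finds an ordering of all objects (an open path, no return edge) that
#' maximizes the sum of pairwise similarities over consecutive pairs,
#' optionally constrained to begin at a given object.
#'
#' Exact mode runs a Held-Karp style dynamic program over vertex subsets and
#' is globally optimal; among co-optimal orderings the lexicographically
#' smallest (by object id) is returned. Heuristic mode seeds with greedy
#' nearest-neighbour from the constrained start (best over all starts when
#' unconstrained) and improves with 2-opt segment reversals until no swap
#' helps, so its total is never below the greedy baseline. `"auto"` uses the
#' exact solver up to `exact_limit` objects.
#'
#' @param sim square symmetric similarity matrix with object ids as dimnames.
#' @param start object id the path must begin at, or `NULL` for a free start.
#' @param mode `"exact"`, `"heuristic"` or `"auto"`.
#' @param exact_limit largest N the exact subset DP will accept (default 13).
#' @return An object of class `reference_list`: list with `ordering`
#'   (character vector of object ids), `total_similarity`,
#'   `start_constraint`, `mode`.
#' @export
max_similarity_path <- function(sim, start = NULL,
                                mode = c("auto", "exact", "heuristic"),
                                exact_limit = 13L) {
  mode <- match.arg(mode)
  sim <- .check_sim(sim)
  ids <- rownames(sim)
  n <- length(ids)
  if (!is.null(start)) {
    start <- as.character(start)
    if (!start %in% ids) stop("start object '", start, "' not in similarity matrix")
  }
  if (mode == "auto") mode <- if (n <= exact_limit) "exact" else "heuristic"
  if (mode == "exact" && n > exact_limit) {
    stop("exact mode supports at most ", exact_limit, " objects (got ", n,
         "); use mode = 'heuristic' or raise exact_limit")
  }
  ordering <- if (n == 1) ids else if (mode == "exact") {
    .exact_path(sim, start)
  } else {
    .two_opt(sim, .greedy_path(sim, start), fixed_start = !is.null(start))
  }
  structure(
    list(ordering = ordering,
         total_similarity = path_total(sim, ordering),
         start_constraint = if (is.null(start)) NA_character_ else start,
         mode = mode),
    class = "reference_list"
  )
}

#' @rdname max_similarity_path
#' @param ordering character vector of object ids.
#' @return `path_total()` returns the summed similarity over consecutive pairs.
#' @export
path_total <- function(sim, ordering) {
  if (length(ordering) < 2) return(0)
  sum(sim[cbind(ordering[-length(ordering)], ordering[-1])])
}

#' @export
print.reference_list <- function(x, ...) {
  cat("<reference_list> ", length(x$ordering), " objects, total similarity ",
      format(x$total_similarity, digits = 6), ", start ",
      if (is.na(x$start_constraint)) "free" else x$start_constraint,
      " (", x$mode, ")\n", sep = "")
  invisible(x)
}

.check_sim <- function(sim) {
  if (!is.matrix(sim)) sim <- as.matrix(sim)
  if (nrow(sim) != ncol(sim)) stop("similarity matrix must be square")
  if (is.null(rownames(sim))) {
    rownames(sim) <- colnames(sim) <- sprintf("v%03d", seq_len(nrow(sim)))
  }
  if (!isTRUE(all.equal(unname(sim), unname(t(sim)), tolerance = 1e-9))) {
    stop("similarity matrix must be symmetric")
  }
  # internal vertex order: object-id lexicographic, the global tie-break order
  ord <- order(rownames(sim))
  sim[ord, ord, drop = FALSE]
}

# Subset DP: f[S, v] = best total of a path that starts at v and visits
# exactly the vertex set S (v in S). Reconstruction walks forward picking the
# smallest-id next vertex that preserves optimality, which yields the
# lexicographically smallest optimal ordering for a fixed start.
.exact_path <- function(sim, start) {
  ids <- rownames(sim)
  n <- length(ids)
  nmask <- bitwShiftL(1L, n)
  f <- matrix(-Inf, nrow = nmask - 1L, ncol = n)
  bit <- bitwShiftL(1L, seq_len(n) - 1L)
  for (v in seq_len(n)) f[bit[v], v] <- 0
  for (mask in seq_len(nmask - 1L)) {
    members <- which(bitwAnd(mask, bit) > 0L)
    if (length(members) < 2) next
    for (v in members) {
      rest <- mask - bit[v]
      others <- members[members != v]
      f[mask, v] <- max(sim[v, others] + f[rest, others])
    }
  }
  full <- nmask - 1L
  tol <- 1e-9
  v <- if (is.null(start)) {
    best <- max(f[full, ])
    min(which(f[full, ] >= best - tol))  # smallest id among optimal starts
  } else {
    match(start, ids)
  }
  path <- v
  mask <- full
  while (mask != bit[v]) {
    rest <- mask - bit[v]
    members <- which(bitwAnd(rest, bit) > 0L)
    vals <- sim[v, members] + f[rest, members]
    u <- members[min(which(vals >= f[mask, v] - tol))]
    path <- c(path, u)
    mask <- rest
    v <- u
  }
  ids[path]
}

# greedy nearest-neighbour; ties to the smallest object id (ids are sorted,
# so which.max already picks the first = smallest)
.greedy_path <- function(sim, start) {
  ids <- rownames(sim)
  n <- length(ids)
  run_from <- function(s) {
    path <- s
    left <- setdiff(seq_len(n), s)
    v <- s
    while (length(left)) {
      u <- left[which.max(sim[v, left])]
      path <- c(path, u)
      left <- setdiff(left, u)
      v <- u
    }
    path
  }
  if (!is.null(start)) return(ids[run_from(match(start, ids))])
  best <- NULL
  best_total <- -Inf
  for (s in seq_len(n)) {
    p <- run_from(s)
    tot <- path_total(sim, ids[p])
    if (tot > best_total + 1e-12) {
      best <- p
      best_total <- tot
    }
  }
  ids[best]
}

# 2-opt for open paths: reverse ordering[i..j]; only edges at the segment
# boundaries change. With a fixed start, i >= 2.
.two_opt <- function(sim, ordering, fixed_start) {
  n <- length(ordering)
  if (n < 3) return(ordering)
  imin <- if (fixed_start) 2L else 1L
  repeat {
    best_delta <- 1e-9
    best_ij <- NULL
    for (i in imin:(n - 1L)) {
      left <- if (i > 1) sim[ordering[i - 1L], ordering[i:n]] else numeric(n - i + 1L)
      for (j in i:n) {
        if (i == 1L && j == n) next
        delta <- 0
        if (i > 1) delta <- delta + left[j - i + 1L] - left[1L]
        if (j < n) {
          delta <- delta + sim[ordering[i], ordering[j + 1L]] -
            sim[ordering[j], ordering[j + 1L]]
        }
        if (delta > best_delta) {
          best_delta <- delta
          best_ij <- c(i, j)
        }
      }
    }
    if (is.null(best_ij)) break
    i <- best_ij[1]; j <- best_ij[2]
    ordering[i:j] <- ordering[j:i]
  }
  ordering
}

#' Build the two start-constrained semantic reference lists
#'
#' Recall starting points in free recall concentrate on the first and last
#' presented objects, so the semantic reference is compiled twice: once
#' constrained to begin at the object presented first, once at the object
#' presented last. Semantic clustering is later scored against both and
#' averaged.
#'
#' @param sim a [similarity_matrix] over the inventory's objects.
#' @param inventory the [object_inventory] (supplies presentation positions).
#' @param mode,exact_limit passed to [max_similarity_path()].
#' @return A list with elements `first` and `last`, each a `reference_list`.
#' @export
build_reference_lists <- function(sim, inventory, mode = c("auto", "exact", "heuristic"),
                                  exact_limit = 13L) {
  mode <- match.arg(mode)
  stopifnot(inherits(inventory, "object_inventory"))
  first_id <- inventory$object_id[inventory$position == 1L]
  last_id <- inventory$object_id[inventory$position == n_objects(inventory)]
  list(first = max_similarity_path(sim, start = first_id, mode = mode,
                                   exact_limit = exact_limit),
       last = max_similarity_path(sim, start = last_id, mode = mode,
                                  exact_limit = exact_limit))
}

#' Export a reference list as CSV plus JSON sidecar
#'
#' @param ref a `reference_list`.
#' @param path output CSV path (one object id per row, in order); a sidecar
#'   `<path>.json` records the total similarity and the start constraint.
#' @return `path`, invisibly.
#' @export
write_reference_list <- function(ref, path) {
  stopifnot(inherits(ref, "reference_list"))
  utils::write.csv(data.frame(object_id = ref$ordering), path, row.names = FALSE)
  jsonlite::write_json(
    list(total_similarity = ref$total_similarity,
         start_constraint = ref$start_constraint, mode = ref$mode),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
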