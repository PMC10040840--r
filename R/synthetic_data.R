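# Synthetic studies with known ground truth. Recall generation factorizes
# into (1) sampling the recalled subset -- inclusion odds scale with a
# per-trial learning curve and primacy/recency boosts -- and (2) ordering
# the subset by a Markov walk mixing serial-adjacent, semantic-nearest-
# neighbour and random transitions. The clustering indices depend only on
# the order given r, so the two stages make the ground truth interpretable.

#' Strategy profile for a simulated group
#'
#' @param p_serial probability that a transition targets a serially adjacent
#'   recalled object (presentation distance 1), when one is available.
#' @param p_semantic probability that a transition targets the most similar
#'   not-yet-recalled object; `p_serial + p_semantic <= 1`, the rest is
#'   uniform random. Unavailable strategy mass falls through to random.
#' @param primacy_boost,recency_boost multiplicative recall-odds factors for
#'   the first `primacy_len` / last `recency_len` presentation positions.
#' @param primacy_len,recency_len region lengths (defaults 7 and 3).
#' @param learning_curve length-5 vector of expected recall fractions per
#'   trial (3 learning trials, short and long delayed recall), values in
#'   (0, 1], non-decreasing over the learning trials.
#' @param semantic_mode `"nearest"` (deterministic nearest neighbour) or
#'   `"proportional"` (similarity-proportional sampling).
#' @return An object of class `strategy_profile`.
#' @export
strategy_profile <- function(p_serial = 0.1, p_semantic = 0.2,
                             primacy_boost = 1.5, recency_boost = 1.5,
                             primacy_len = 7L, recency_len = 3L,
                             learning_curve = c(0.33, 0.48, 0.60, 0.57, 0.55),
                             semantic_mode = c("nearest", "proportional")) {
  semantic_mode <- match.arg(semantic_mode)
  if (p_serial < 0 || p_semantic < 0 || p_serial + p_semantic > 1) {
    stop("need p_serial, p_semantic >= 0 and p_serial + p_semantic <= 1")
  }
  if (length(learning_curve) != 5 || any(learning_curve <= 0) ||
      any(learning_curve > 1)) {
    stop("learning_curve must have 5 values in (0, 1]")
  }
  if (is.unsorted(learning_curve[1:3])) {
    stop("learning_curve must be non-decreasing over the learning trials")
  }
  if (primacy_boost <= 0 || recency_boost <= 0) stop("boosts must be positive")
  structure(
    list(p_serial = p_serial, p_semantic = p_semantic,
         p_random = 1 - p_serial - p_semantic,
         primacy_boost = primacy_boost, recency_boost = recency_boost,
         primacy_len = as.integer(primacy_len),
         recency_len = as.integer(recency_len),
         learning_curve = learning_curve, semantic_mode = semantic_mode),
    class = "strategy_profile")
}

#' Generate a synthetic object inventory
#'
#' Objects receive a seeded pseudo-random presentation order, context
#' typicality flags at the requested fraction, round-robin-then-shuffled
#' spatial zones, and one taxonomy leaf each (`leaf01`, `leaf02`, ...,
#' matching [generate_taxonomy()]).
#'
#' @param n_objects number of objects (study default 46).
#' @param frac_context_typical fraction of context-typical objects.
#' @param n_zones number of spatial zones.
#' @param seed integer RNG seed.
#' @return An [object_inventory].
#' @export
generate_inventory <- function(n_objects = 46L, frac_context_typical = 0.5,
                               n_zones = 6L, seed = 1L) {
  if (n_objects < 2) stop("n_objects must be >= 2")
  if (frac_context_typical < 0 || frac_context_typical > 1) {
    stop("frac_context_typical must lie in [0, 1]")
  }
  set.seed(as.integer(seed))
  n <- as.integer(n_objects)
  ids <- sprintf("obj%02d", seq_len(n))
  n_typical <- round(frac_context_typical * n)
  typical <- rep(FALSE, n)
  typical[sample.int(n, n_typical)] <- TRUE
  zones <- sample(rep_len(sprintf("zone%d", seq_len(n_zones)), n))
  object_inventory(data.frame(
    object_id = ids,
    label = sprintf("object %02d", seq_len(n)),
    position = sample.int(n),
    zone = zones,
    is_context_typical = typical,
    taxonomy_leaf = sprintf("leaf%02d", seq_len(n)),
    stringsAsFactors = FALSE))
}

#' Generate a random concept taxonomy
#'
#' Builds a rooted tree by recursively splitting the leaf set into at most
#' `branching` groups down to `depth` levels, then draws heavy-tailed
#' (log-normal) corpus frequencies so information content varies across
#' concepts. Leaves are named `leaf01..leafNN` to pair with
#' [generate_inventory()].
#'
#' @param n_leaves number of leaves; must satisfy `branching^depth >=
#'   n_leaves`.
#' @param branching maximum children per internal node.
#' @param depth maximum tree depth.
#' @param seed integer RNG seed.
#' @return A [taxonomy].
#' @export
generate_taxonomy <- function(n_leaves = 46L, branching = 3L, depth = 4L,
                              seed = 1L) {
  if (branching < 2) stop("branching must be >= 2")
  if (branching^depth < n_leaves) {
    stop("infeasible shape: branching^depth = ", branching^depth,
         " < n_leaves = ", n_leaves)
  }
  set.seed(as.integer(seed))
  leaves <- sprintf("leaf%02d", seq_len(n_leaves))
  nodes <- data.frame(id = "root", parent = NA_character_,
                      stringsAsFactors = FALSE)
  counter <- 0L
  split_set <- function(ids, parent, level) {
    if (length(ids) == 1L) {
      nodes <<- rbind(nodes, data.frame(id = ids, parent = parent))
      return(invisible())
    }
    if (level >= depth) {
      # depth budget exhausted: attach all remaining leaves directly
      nodes <<- rbind(nodes, data.frame(id = ids, parent = parent))
      return(invisible())
    }
    k <- min(length(ids), sample(2:branching, 1))
    grp <- sort(rep_len(seq_len(k), length(ids)))
    for (g in split(ids, grp)) {
      if (length(g) == 1L) {
        nodes <<- rbind(nodes, data.frame(id = g, parent = parent))
      } else {
        counter <<- counter + 1L
        nid <- sprintf("n%03d", counter)
        nodes <<- rbind(nodes, data.frame(id = nid, parent = parent))
        split_set(g, nid, level + 1L)
      }
    }
  }
  split_set(sample(leaves), "root", 1L)
  freq <- ceiling(stats::rlnorm(nrow(nodes), meanlog = 3, sdlog = 1.2))
  freq[nodes$id == "root"] <- 1
  taxonomy(nodes$id, nodes$parent, freq)
}

# inclusion odds multiplier per position
.position_boost <- function(position, N, profile) {
  b <- rep(1, length(position))
  b[position <= profile$primacy_len] <- profile$primacy_boost
  b[position > N - profile$recency_len] <- profile$recency_boost
  b
}

# order a recalled subset by the strategy Markov walk; a serial strategist
# starts at the earliest presented recalled object (rote recall walks the
# list from its beginning), otherwise the start is boost-weighted random
.order_recalls <- function(recalled_idx, position, sim, profile) {
  if (length(recalled_idx) <= 1) return(recalled_idx)
  current <- if (stats::runif(1) < profile$p_serial) {
    recalled_idx[which.min(position[recalled_idx])]
  } else {
    boosts <- .position_boost(position[recalled_idx], length(position), profile)
    recalled_idx[sample.int(length(recalled_idx), 1, prob = boosts)]
  }
  left <- setdiff(recalled_idx, current)
  path <- current
  while (length(left)) {
    u <- stats::runif(1)
    nxt <- NULL
    if (u < profile$p_serial) {
      neigh <- left[abs(position[left] - position[current]) == 1L]
      if (length(neigh)) nxt <- if (length(neigh) == 1) neigh else sample(neigh, 1)
    } else if (u < profile$p_serial + profile$p_semantic) {
      s <- sim[current, left]
      nxt <- if (profile$semantic_mode == "nearest") {
        left[which.max(s)]
      } else if (sum(s) > 0) {
        left[sample.int(length(left), 1, prob = s)]
      } else NULL
    }
    if (is.null(nxt)) nxt <- if (length(left) == 1) left else sample(left, 1)
    path <- c(path, nxt)
    left <- setdiff(left, nxt)
    current <- nxt
  }
  path
}

#' Simulate recall protocols for one or more groups
#'
#' Per participant and trial, (1) each object enters the recalled subset
#' with odds proportional to the trial's learning-curve value times its
#' primacy/recency boost, and (2) the subset is ordered by a Markov walk:
#' start at a boost-weighted random recalled object, then move serially
#' (presentation distance 1), semantically (most similar remaining), or
#' uniformly at random according to the profile probabilities, with
#' unavailable strategies falling through to random. Fully seeded.
#'
#' @param inventory an [object_inventory].
#' @param sim a [similarity_matrix] over its objects.
#' @param profiles named list of [strategy_profile]s, one per group.
#' @param n_per_group named integer vector of group sizes (same names).
#' @param seed integer RNG seed.
#' @return A list with `dataset` (a [study_dataset]) and `truth` (a
#'   `ground_truth` list: profiles, seed, group sizes).
#' @export
simulate_recall <- function(inventory, sim, profiles, n_per_group, seed) {
  stopifnot(inherits(inventory, "object_inventory"))
  if (!all(vapply(profiles, inherits, logical(1), "strategy_profile"))) {
    stop("profiles must be strategy_profile objects")
  }
  if (is.null(names(profiles)) || !setequal(names(profiles), names(n_per_group))) {
    stop("profiles and n_per_group must be named by the same groups")
  }
  if (any(n_per_group < 1)) stop("n_per_group must be >= 1 per group")
  set.seed(as.integer(seed))
  ids <- inventory$object_id
  position <- inventory$position
  N <- length(ids)
  simm <- unclass(sim)[ids, ids]
  protocols <- list()
  for (grp in sort(names(profiles))) {
    profile <- profiles[[grp]]
    for (subj in seq_len(n_per_group[[grp]])) {
      pid <- sprintf("%s_p%02d", grp, subj)
      for (trial in 1:5) {
        lc <- profile$learning_curve[trial]
        odds <- lc / (1 - lc + 1e-12) * .position_boost(position, N, profile)
        prob <- pmin(odds / (1 + odds), 1)
        recalled <- which(stats::runif(N) < prob)
        ordered <- .order_recalls(recalled, position, simm, profile)
        protocols[[length(protocols) + 1L]] <- suppressWarnings(
          recall_protocol(grp, pid, trial, ids[ordered], inventory))
      }
    }
  }
  truth <- structure(
    list(profiles = profiles, seed = as.integer(seed),
         n_per_group = n_per_group,
         object_ids = ids),
    class = "ground_truth")
  list(dataset = study_dataset(inventory, protocols), truth = truth)
}

#' Generate a complete study shaped like the source design
#'
#' Two groups -- `HOA` (healthy older adults, 18 participants, semantic-
#' leaning profile) and `YA` (young adults, 30 participants, serial-leaning
#' profile with a stronger primacy boost) -- recalling 46 objects over 3
#' learning trials plus short- and long-delay free recall, with a shared
#' synthetic taxonomy and Lin similarity matrix.
#'
#' @param seed integer RNG seed driving inventory, taxonomy and recall.
#' @return A list: `dataset`, `truth`, `inventory`, `taxonomy`, `sim`,
#'   `profiles`.
#' @export
make_paper_like_study <- function(seed = 1L) {
  seed <- as.integer(seed)
  tax <- generate_taxonomy(46L, branching = 3L, depth = 5L, seed = seed)
  inventory <- generate_inventory(46L, frac_context_typical = 0.5,
                                  n_zones = 6L, seed = seed + 1L)
  sim <- similarity_matrix(inventory, tax)
  profiles <- list(
    HOA = strategy_profile(p_serial = 0.08, p_semantic = 0.35,
                           primacy_boost = 1.5, recency_boost = 1.5),
    YA = strategy_profile(p_serial = 0.22, p_semantic = 0.18,
                          primacy_boost = 3.0, recency_boost = 1.5))
  out <- simulate_recall(inventory, sim, profiles,
                         c(HOA = 18L, YA = 30L), seed = seed + 2L)
  c(out, list(inventory = inventory, taxonomy = tax, sim = sim,
              profiles = profiles))
}

#' Write the ground-truth sidecar JSON
#'
#' @param truth a `ground_truth` object from [simulate_recall()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(
    list(seed = truth$seed, n_per_group = as.list(truth$n_per_group),
         profiles = lapply(truth$profiles, unclass)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
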