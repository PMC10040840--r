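# Serial and semantic list-based clustering (LBC) indices. The observed
# count is the number of consecutive recall pairs adjacent (either
# direction) in a reference ordering -- the presentation order for the
# serial index, the similarity-optimized reference list for the semantic
# index. The chance expectation for bidirectional adjacency is
# 2*(r - 1)/N, and the index is observed minus expected.

#' Chance-expected list-based cluster count
#'
#' `2 * (r - 1) / N` for `r` correct recalls from an `N`-item list, the
#' expected number of recall transitions that land on a bidirectionally
#' adjacent reference pair under random ordering; clamped to 0 for `r <= 1`
#' (no transition exists). At full recall of a 46-object list this is
#' `2 * 45 / 46 = 1.96`.
#'
#' @param r integer number of correct unique recalls, `0 <= r <= N`.
#' @param N total number of objects in the list.
#' @return the expectation, a nonnegative real.
#' @export
lbc_expected <- function(r, N) {
  if (N < 1) stop("N must be >= 1")
  if (r < 0 || r > N) stop("r must lie in 0..N, got r = ", r, ", N = ", N)
  if (r <= 1) return(0)
  2 * (r - 1) / N
}

#' Observed serial cluster count
#'
#' Number of consecutive recall pairs whose presentation positions differ by
#' exactly 1, in either direction. Chains count per transition: a run of k
#' serially adjacent recalls scores k - 1.
#'
#' @param protocol a [recall_protocol] (already cleaned).
#' @param inventory the [object_inventory] supplying positions.
#' @return nonnegative integer count.
#' @export
serial_cluster_count <- function(protocol, inventory) {
  stopifnot(inherits(protocol, "recall_protocol"),
            inherits(inventory, "object_inventory"))
  pos <- inventory$position[match(protocol$recalls, inventory$object_id)]
  if (anyNA(pos)) {
    stop("protocol recalls objects absent from the inventory: ",
         paste(protocol$recalls[is.na(pos)], collapse = ", "))
  }
  .adjacent_transitions(pos)
}

.adjacent_transitions <- function(rank) {
  if (length(rank) < 2) return(0L)
  sum(abs(diff(rank)) == 1L)
}

#' Observed semantic cluster count
#'
#' Number of consecutive recall pairs that sit adjacently (either direction)
#' in the semantic reference ordering.
#'
#' @param protocol a [recall_protocol].
#' @param reference a `reference_list` covering every recalled object.
#' @return nonnegative integer count.
#' @export
semantic_cluster_count <- function(protocol, reference) {
  stopifnot(inherits(protocol, "recall_protocol"),
            inherits(reference, "reference_list"))
  rank <- match(protocol$recalls, reference$ordering)
  if (anyNA(rank)) {
    stop("protocol recalls objects absent from the reference list: ",
         paste(protocol$recalls[is.na(rank)], collapse = ", "))
  }
  .adjacent_transitions(rank)
}

#' Clustering index for one protocol
#'
#' Serial: observed serial cluster count minus the chance expectation.
#' Semantic: the observed count is the mean of the counts under the two
#' start-constrained reference lists (so it may be half-integral); the same
#' expectation is subtracted once.
#'
#' @param protocol a [recall_protocol].
#' @param inventory the [object_inventory].
#' @param references list with `reference_list` elements `first` and `last`
#'   (see [build_reference_lists()]); required for the semantic index.
#' @param index_type `"serial"` or `"semantic"`.
#' @return A one-row data frame (a clustering record) with columns `group`,
#'   `participant_id`, `trial`, `index_type`, `lbc_obs`, `lbc_exp`, `index`,
#'   `r`.
#' @export
clustering_index <- function(protocol, inventory, references = NULL,
                             index_type = c("serial", "semantic")) {
  index_type <- match.arg(index_type)
  obs <- if (index_type == "serial") {
    serial_cluster_count(protocol, inventory)
  } else {
    if (is.null(references) || is.null(references$first) || is.null(references$last)) {
      stop("semantic index requires both start-constrained reference lists")
    }
    (semantic_cluster_count(protocol, references$first) +
       semantic_cluster_count(protocol, references$last)) / 2
  }
  exp <- lbc_expected(protocol$r, n_objects(inventory))
  data.frame(group = protocol$group, participant_id = protocol$participant_id,
             trial = protocol$trial, index_type = index_type,
             lbc_obs = as.numeric(obs), lbc_exp = exp, index = obs - exp,
             r = protocol$r, stringsAsFactors = FALSE)
}

#' Clustering records for a whole dataset
#'
#' One record per protocol per index type, ordered by group, participant,
#' trial and index type.
#'
#' @param dataset a [study_dataset].
#' @param references the pair of reference lists from
#'   [build_reference_lists()].
#' @return A data frame of clustering records (see [clustering_index()]).
#' @export
index_table <- function(dataset, references) {
  stopifnot(inherits(dataset, "study_dataset"))
  if (length(dataset$protocols) == 0) {
    return(data.frame(group = character(), participant_id = character(),
                      trial = integer(), index_type = character(),
                      lbc_obs = numeric(), lbc_exp = numeric(),
                      index = numeric(), r = integer()))
  }
  rows <- lapply(dataset$protocols, function(p) {
    rbind(clustering_index(p, dataset$inventory, references, "serial"),
          clustering_index(p, dataset$inventory, references, "semantic"))
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  out[order(out$group, out$participant_id, out$trial, out$index_type), ,
      drop = FALSE]
}

#' Nonparametric group comparison of a clustering index at one trial
#'
#' Wilcoxon rank-sum (Mann-Whitney) with the normal approximation and tie
#' correction; the effect size is `z / sqrt(n_total)`. The sign of z refers
#' to the alphabetically first group (positive = its values rank higher).
#'
#' @param records data frame of clustering records ([index_table()]).
#' @param index_type `"serial"` or `"semantic"`.
#' @param trial trial number 1..5 (or label).
#' @return A list of class `group_comparison`: `groups`, `n`, `median`,
#'   `iqr` (2 x 2 matrix, rows = groups), `z`, `effect_size`, `p`.
#' @export
compare_groups <- function(records, index_type = c("serial", "semantic"), trial) {
  index_type <- match.arg(index_type)
  trial <- .trial_number(trial)
  sel <- records[records$index_type == index_type & records$trial == trial, ,
                 drop = FALSE]
  groups <- sort(unique(sel$group))
  if (length(groups) != 2) {
    stop("exactly two groups required at trial ", trial, "; found ",
         length(groups))
  }
  xs <- split(sel$index, factor(sel$group, levels = groups))
  n1 <- length(xs[[1]]); n2 <- length(xs[[2]])
  if (n1 == 0 || n2 == 0) stop("a group has no records at trial ", trial)
  if (min(n1, n2) < 2) warning("a group has fewer than 2 observations; test is low-powered")
  rs <- .rank_sum(xs[[1]], xs[[2]])
  med <- vapply(xs, stats::median, 0)
  iqr <- t(vapply(xs, stats::quantile, numeric(2), probs = c(0.25, 0.75)))
  structure(
    list(index_type = index_type, trial = trial, groups = groups,
         n = c(n1, n2), median = med, iqr = iqr,
         z = rs$z, effect_size = rs$z / sqrt(n1 + n2), p = rs$p),
    class = "group_comparison"
  )
}

# rank-sum z with tie correction; z > 0 means x ranks above y
.rank_sum <- function(x, y) {
  n1 <- length(x); n2 <- length(y); n <- n1 + n2
  rk <- rank(c(x, y))
  R1 <- sum(rk[seq_len(n1)])
  mu <- n1 * (n + 1) / 2
  ties <- table(rk)
  tie_term <- sum(ties^3 - ties)
  v <- n1 * n2 / 12 * ((n + 1) - tie_term / (n * (n - 1)))
  if (v <= 0) return(list(z = 0, p = 1))
  z <- (R1 - mu) / sqrt(v)
  list(z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' @export
print.group_comparison <- function(x, ...) {
  cat("<group_comparison> ", x$index_type, " index, trial ", x$trial, "\n", sep = "")
  for (k in 1:2) {
    cat("  ", x$groups[k], " (n=", x$n[k], "): median ",
        format(x$median[k], digits = 3), " IQR [",
        format(x$iqr[k, 1], digits = 3), "; ",
        format(x$iqr[k, 2], digits = 3), "]\n", sep = "")
  }
  cat("  z = ", format(x$z, digits = 3), ", effect size z/sqrt(n) = ",
      format(x$effect_size, digits = 3), ", p = ", format(x$p, digits = 3),
      "\n", sep = "")
  invisible(x)
}

#' Per-trial comparison table across both indices
#'
#' Convenience wrapper mirroring the published per-trial layout: one row per
#' index type x trial with group medians, IQRs, effect size and p value.
#'
#' @param records data frame of clustering records.
#' @return A data frame.
#' @export
comparison_table <- function(records) {
  rows <- list()
  for (it in c("serial", "semantic")) {
    for (tr in sort(unique(records$trial[records$index_type == it]))) {
      cm <- compare_groups(records, it, tr)
      rows[[length(rows) + 1L]] <- data.frame(
        index_type = it, trial = tr,
        group1 = cm$groups[1], median1 = unname(cm$median[1]),
        iqr1_lo = cm$iqr[1, 1], iqr1_hi = cm$iqr[1, 2],
        group2 = cm$groups[2], median2 = unname(cm$median[2]),
        iqr2_lo = cm$iqr[2, 1], iqr2_hi = cm$iqr[2, 2],
        effect_size = cm$effect_size, p = cm$p, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
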