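# Core study data types and their text-file carriers: the object inventory
# (the N-item universe with presentation positions and attributes), per
# participant x trial recall protocols, and the bundled study dataset.

TRIAL_LABELS <- c("learn1", "learn2", "learn3", "sdfr", "ldfr")

#' Construct and validate an object inventory
#'
#' The inventory is the universe of study objects. Each object carries a
#' unique 1-based presentation position (positions must cover `1..N` with no
#' gaps), a spatial zone, a context-typicality flag (prototypical for the
#' scene vs. novel), and a pointer to a leaf of the concept taxonomy.
#'
#' @param items a data frame with columns `object_id`, `label`, `position`,
#'   `zone`, `is_context_typical`, `taxonomy_leaf`.
#' @param tax optional [taxonomy]; when supplied, every `taxonomy_leaf` must
#'   resolve to one of its leaves.
#' @return The validated data frame with class `object_inventory` and
#'   attribute `n_objects`.
#' @export
object_inventory <- function(items, tax = NULL) {
  req <- c("object_id", "label", "position", "zone", "is_context_typical",
           "taxonomy_leaf")
  missing_cols <- setdiff(req, names(items))
  if (length(missing_cols)) {
    stop("inventory missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  items <- as.data.frame(items, stringsAsFactors = FALSE)[req]
  items$object_id <- as.character(items$object_id)
  items$position <- as.integer(items$position)
  items$is_context_typical <- as.logical(items$is_context_typical)
  n <- nrow(items)
  if (n < 1) stop("inventory is empty")
  dup <- items$object_id[duplicated(items$object_id)]
  if (length(dup)) stop("duplicate object_id: ", paste(unique(dup), collapse = ", "))
  posdup <- items$position[duplicated(items$position)]
  if (length(posdup)) {
    off <- items$object_id[items$position %in% posdup]
    stop("duplicate presentation position(s) ",
         paste(unique(posdup), collapse = ", "), " (objects ",
         paste(off, collapse = ", "), ")")
  }
  if (!setequal(items$position, seq_len(n))) {
    stop("positions must cover 1..", n, " with no gaps; got ",
         paste(sort(items$position), collapse = ","))
  }
  if (!is.null(tax)) {
    leaves <- taxonomy_leaves(tax)
    bad <- items$taxonomy_leaf[!items$taxonomy_leaf %in% leaves]
    if (length(bad)) {
      stop("taxonomy_leaf does not resolve to a leaf of the taxonomy: ",
           paste(unique(bad), collapse = ", "))
    }
  }
  items <- items[order(items$position), , drop = FALSE]
  rownames(items) <- NULL
  structure(items, class = c("object_inventory", "data.frame"), n_objects = n)
}

#' @rdname object_inventory
#' @param x an `object_inventory`.
#' @export
n_objects <- function(x) attr(x, "n_objects")

#' Load an object inventory from JSON or CSV
#'
#' CSV files need the header
#' `object_id,label,position,zone,is_context_typical,taxonomy_leaf`;
#' JSON files hold an array of objects with the same fields.
#'
#' @param path file path (`.json` or `.csv`).
#' @param tax optional [taxonomy] used to validate `taxonomy_leaf` references.
#' @return An [object_inventory].
#' @export
load_inventory <- function(path, tax = NULL) {
  if (!file.exists(path)) stop("inventory file not found: ", path)
  items <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyVector = TRUE)
  } else {
    utils::read.csv(path, stringsAsFactors = FALSE)
  }
  object_inventory(items, tax = tax)
}

#' @rdname load_inventory
#' @param inventory an [object_inventory].
#' @export
write_inventory <- function(inventory, path) {
  stopifnot(inherits(inventory, "object_inventory"))
  utils::write.csv(as.data.frame(inventory), path, row.names = FALSE)
  invisible(path)
}

#' Construct a recall protocol
#'
#' One participant x trial ordered recall sequence. Cleaning removes
#' perseverations (repeats keep their first occurrence) and, in lenient mode,
#' intrusions (recalled ids absent from the inventory); both removals emit a
#' warning with counts. In strict mode an intrusion is an error. `r` is the
#' number of correct unique recalls that remain.
#'
#' @param group group label.
#' @param participant_id participant key.
#' @param trial trial label, one of `learn1, learn2, learn3, sdfr, ldfr`, or
#'   the corresponding number 1..5.
#' @param recalls character vector of object ids in recall order.
#' @param inventory the [object_inventory] recalls refer to.
#' @param mode `"lenient"` (drop intrusions with a warning) or `"strict"`.
#' @return A list of class `recall_protocol` with elements `group`,
#'   `participant_id`, `trial` (integer 1..5), `trial_label`, `recalls`, `r`.
#' @export
recall_protocol <- function(group, participant_id, trial, recalls, inventory,
                            mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(inventory, "object_inventory"))
  trial_num <- .trial_number(trial)
  recalls <- as.character(recalls)
  known <- recalls %in% inventory$object_id
  if (!all(known)) {
    bad <- unique(recalls[!known])
    if (mode == "strict") {
      stop("protocol ", participant_id, "/", TRIAL_LABELS[trial_num],
           " recalls unknown object(s): ", paste(bad, collapse = ", "))
    }
    warning("dropped ", sum(!known), " intrusion(s) from ", participant_id,
            "/", TRIAL_LABELS[trial_num], ": ", paste(bad, collapse = ", "))
    recalls <- recalls[known]
  }
  if (anyDuplicated(recalls)) {
    ndup <- sum(duplicated(recalls))
    warning("dropped ", ndup, " perseveration(s) from ", participant_id, "/",
            TRIAL_LABELS[trial_num], " (first occurrence kept)")
    recalls <- recalls[!duplicated(recalls)]
  }
  structure(
    list(group = as.character(group),
         participant_id = as.character(participant_id),
         trial = trial_num, trial_label = TRIAL_LABELS[trial_num],
         recalls = recalls, r = length(recalls)),
    class = "recall_protocol"
  )
}

.trial_number <- function(trial) {
  if (is.numeric(trial)) {
    t <- as.integer(trial)
    if (is.na(t) || t < 1L || t > 5L) stop("numeric trial must be in 1..5, got ", trial)
    return(t)
  }
  t <- match(as.character(trial), TRIAL_LABELS)
  if (is.na(t)) {
    stop("unknown trial label '", trial, "'; expected one of ",
         paste(TRIAL_LABELS, collapse = ", "))
  }
  t
}

#' Bundle an inventory and a set of protocols into a study dataset
#'
#' @param inventory an [object_inventory].
#' @param protocols list of [recall_protocol] objects referring to it.
#' @return A list of class `study_dataset` with elements `inventory`,
#'   `protocols`, `groups`.
#' @export
study_dataset <- function(inventory, protocols) {
  stopifnot(inherits(inventory, "object_inventory"))
  if (!all(vapply(protocols, inherits, logical(1), "recall_protocol"))) {
    stop("protocols must be a list of recall_protocol objects")
  }
  keys <- vapply(protocols, function(p) paste(p$participant_id, p$trial), "")
  if (anyDuplicated(keys)) {
    stop("duplicate (participant_id, trial) pairs: ",
         paste(unique(keys[duplicated(keys)]), collapse = "; "))
  }
  for (p in protocols) {
    bad <- setdiff(p$recalls, inventory$object_id)
    if (length(bad)) {
      stop("protocol ", p$participant_id, "/", p$trial_label,
           " references objects outside the inventory: ",
           paste(bad, collapse = ", "))
    }
  }
  groups <- sort(unique(vapply(protocols, function(p) p$group, "")))
  structure(list(inventory = inventory, protocols = protocols, groups = groups),
            class = "study_dataset")
}

#' @export
print.study_dataset <- function(x, ...) {
  cat("<study_dataset> ", length(x$protocols), " protocols, ",
      n_objects(x$inventory), " objects, groups: ",
      paste(x$groups, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Load recall protocols from CSV
#'
#' The file needs the header `group,participant_id,trial,recall_rank,object_id`.
#' Within each (participant, trial) block the `recall_rank` must be dense
#' `1..r`; recall order is ascending rank. Cleaning follows
#' [recall_protocol()].
#'
#' @param path CSV file path.
#' @param inventory the [object_inventory] the protocols refer to.
#' @param mode intrusion handling, `"lenient"` or `"strict"`.
#' @return A [study_dataset].
#' @export
load_protocols <- function(path, inventory, mode = c("lenient", "strict")) {
  mode <- match.arg(mode)
  if (!file.exists(path)) stop("protocol file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(object_id = "character",
                                       participant_id = "character"))
  req <- c("group", "participant_id", "trial", "recall_rank", "object_id")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("protocol file missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  key <- paste(df$group, df$participant_id, df$trial, sep = "\r")
  protocols <- lapply(split(df, key), function(block) {
    block <- block[order(block$recall_rank), , drop = FALSE]
    rk <- as.integer(block$recall_rank)
    if (!identical(rk, seq_len(nrow(block)))) {
      stop("non-contiguous recall_rank for participant ",
           block$participant_id[1], ", trial ", block$trial[1],
           ": got ", paste(rk, collapse = ","))
    }
    recall_protocol(block$group[1], block$participant_id[1], block$trial[1],
                    block$object_id, inventory, mode = mode)
  })
  names(protocols) <- NULL
  ord <- order(vapply(protocols, function(p) p$group, ""),
               vapply(protocols, function(p) p$participant_id, ""),
               vapply(protocols, function(p) p$trial, 0L))
  study_dataset(inventory, protocols[ord])
}

#' @rdname load_protocols
#' @param dataset a [study_dataset].
#' @export
write_protocols <- function(dataset, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  rows <- lapply(dataset$protocols, function(p) {
    if (p$r == 0) return(NULL)
    data.frame(group = p$group, participant_id = p$participant_id,
               trial = p$trial_label, recall_rank = seq_len(p$r),
               object_id = p$recalls, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, rows)
  if (is.null(df)) {
    df <- data.frame(group = character(), participant_id = character(),
                     trial = character(), recall_rank = integer(),
                     object_id = character())
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Export a tidy long-format table of clustering records
#'
#' One row per participant x trial x index type, ready for downstream
#' mixed-model tools.
#'
#' @param dataset the [study_dataset] the records were computed from.
#' @param records a data frame of clustering records (see [index_table()]).
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
export_tidy_tables <- function(dataset, records, path) {
  stopifnot(inherits(dataset, "study_dataset"))
  cols <- c("group", "participant_id", "trial", "index_type",
            "lbc_obs", "lbc_exp", "index", "r")
  if (nrow(records) == 0) {
    empty <- stats::setNames(as.data.frame(matrix(nrow = 0, ncol = length(cols))), cols)
    utils::write.csv(empty, path, row.names = FALSE)
    return(invisible(path))
  }
  known <- unique(vapply(dataset$protocols, function(p) p$participant_id, ""))
  unknown <- setdiff(unique(records$participant_id), known)
  if (length(unknown)) {
    stop("records reference participant(s) absent from the dataset: ",
         paste(unknown, collapse = ", "))
  }
  utils::write.csv(records[cols], path, row.names = FALSE)
  invisible(path)
}
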