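#' @title Cell lineage trees and division schedules
#'
#' @description
#' The invariant C. elegans lineage drives cell fate and division timing in
#' the simulator: every cell's fate label and division time are predefined
#' observations, not dynamical variables. A lineage tree is stored as a
#' data frame (one row per cell) with class `lineage_tree` and columns
#' `name`, `parent`, `birth_time`, `division_time`, `fate`. Division is
#' strictly binary: a node has exactly 0 or 2 children, and each child is
#' born at its mother's division time.
#'
#' @name lineage
NULL

FATE_LEVELS <- c("pharynx", "neuron", "hypodermis", "muscle", "gut",
                 "other", "unassigned")

# Founder-cell daughters of the early P lineage (anterior, posterior).
FOUNDER_DAUGHTERS <- list(
  P0  = c("AB", "P1"),
  P1  = c("EMS", "P2"),
  P2  = c("C", "P3"),
  P3  = c("D", "P4"),
  EMS = c("MS", "E")
)

#' Construct and validate a lineage tree
#'
#' @param df data frame with columns `name`, `parent`, `birth_time`,
#'   `division_time`, `fate`. `parent` is `NA` for the root;
#'   `division_time` is `NA` for terminal cells; `fate` must be one of
#'   pharynx, neuron, hypodermis, muscle, gut, other, unassigned
#'   (`NA` is read as "unassigned").
#' @return the validated data frame with class `lineage_tree`.
#' @export
lineage_tree <- function(df) {
  req <- c("name", "parent", "birth_time", "division_time", "fate")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop("lineage table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  df <- as.data.frame(df)[req]
  df$name <- as.character(df$name)
  df$parent <- as.character(df$parent)
  df$parent[!is.na(df$parent) & df$parent == ""] <- NA_character_
  df$birth_time <- as.numeric(df$birth_time)
  df$division_time <- as.numeric(df$division_time)
  df$fate <- as.character(df$fate)
  df$fate[is.na(df$fate) | df$fate == ""] <- "unassigned"
  rownames(df) <- NULL
  class(df) <- c("lineage_tree", "data.frame")
  validate_lineage(df)
  df
}

#' @rdname lineage_tree
#' @param tree a `lineage_tree`.
#' @export
validate_lineage <- function(tree) {
  df <- as.data.frame(tree)
  if (anyDuplicated(df$name)) {
    stop("lineage format error: duplicate cell name(s): ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "),
         call. = FALSE)
  }
  if (any(df$name == "" | is.na(df$name))) {
    stop("lineage format error: empty cell name", call. = FALSE)
  }
  bad_fate <- setdiff(unique(df$fate), FATE_LEVELS)
  if (length(bad_fate)) {
    stop("lineage format error: unknown fate label(s): ",
         paste(bad_fate, collapse = ", "), call. = FALSE)
  }
  roots <- df$name[is.na(df$parent)]
  if (length(roots) != 1L) {
    stop("lineage structure error: expected exactly one root, found ",
         length(roots), call. = FALSE)
  }
  orphan <- setdiff(df$parent[!is.na(df$parent)], df$name)
  if (length(orphan)) {
    stop("lineage structure error: parent(s) not in tree: ",
         paste(unique(orphan), collapse = ", "), call. = FALSE)
  }
  n_children <- table(df$parent[!is.na(df$parent)])
  if (any(n_children != 2L)) {
    bad <- names(n_children)[n_children != 2L]
    stop("lineage structure error: cell(s) with child count != 2: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  # dividing cells are exactly the parents; terminal cells never divide
  parents <- names(n_children)
  has_div <- df$name[!is.na(df$division_time)]
  if (!setequal(parents, has_div)) {
    stop("lineage structure error: division_time must be set exactly for ",
         "cells with children", call. = FALSE)
  }
  idx <- match(df$parent, df$name)
  kids <- !is.na(idx)
  if (any(df$birth_time[kids] != df$division_time[idx[kids]])) {
    stop("lineage structure error: a child's birth_time must equal its ",
         "parent's division_time", call. = FALSE)
  }
  if (any(!is.na(df$division_time) & df$division_time <= df$birth_time)) {
    stop("lineage structure error: division_time must exceed birth_time",
         call. = FALSE)
  }
  if (any(df$birth_time < 0)) {
    stop("lineage structure error: negative birth_time", call. = FALSE)
  }
  invisible(tree)
}

#' Read a lineage table
#'
#' Reads the delimiter-separated lineage format with header
#' `name,parent,birth_time,division_time,fate` (empty fields for the root's
#' parent and for terminal cells' division times) and returns a validated
#' [lineage_tree()]. A data frame may be passed directly.
#'
#' @param x path to a lineage table, or a data frame.
#' @param sep field delimiter.
#' @return a `lineage_tree`.
#' @export
load_lineage <- function(x, sep = ",") {
  if (is.character(x) && length(x) == 1L) {
    x <- utils::read.table(x, header = TRUE, sep = sep,
                           colClasses = "character",
                           na.strings = c("", "NA"),
                           stringsAsFactors = FALSE)
  }
  lineage_tree(x)
}

#' Write a lineage table
#'
#' @param tree a `lineage_tree`.
#' @param path output file path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_lineage_table <- function(tree, path, sep = ",") {
  validate_lineage(tree)
  df <- as.data.frame(tree)
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     na = "", row.names = FALSE)
  invisible(path)
}

#' @export
print.lineage_tree <- function(x, ...) {
  n_leaf <- sum(is.na(x$division_time))
  cat(sprintf("<lineage_tree> %d cells (%d terminal), root %s, t = [%g, %g]\n",
              nrow(x), n_leaf, root_of(x), min(x$birth_time),
              max(c(x$birth_time, x$division_time), na.rm = TRUE)))
  invisible(x)
}

root_of <- function(tree) tree$name[is.na(tree$parent)]

children_of <- function(tree, name) sort(tree$name[!is.na(tree$parent) & tree$parent == name])

#' Name the daughters of a dividing cell
#'
#' Applies Sulston-style anterior/posterior suffixing: the daughter lying in
#' the hemisphere where the division axis points along the
#' anterior-posterior (AP) axis gets suffix `"a"`, the other `"p"`.
#' Founder cells of the early P lineage are special-cased
#' (P0 -> AB,P1; P1 -> EMS,P2; P2 -> C,P3; P3 -> D,P4; EMS -> MS,E).
#'
#' @param mother mother cell name.
#' @param division_axis unit 3-vector along the division axis.
#' @param ap_axis unit 3-vector pointing anterior.
#' @return character 2-vector `(anterior, posterior)`.
#' @export
daughter_names <- function(mother, division_axis, ap_axis = c(1, 0, 0)) {
  if (!is.character(mother) || length(mother) != 1L || !nzchar(mother)) {
    stop("`mother` must be a nonempty cell name", call. = FALSE)
  }
  if (!is.null(FOUNDER_DAUGHTERS[[mother]])) {
    return(FOUNDER_DAUGHTERS[[mother]])
  }
  unit_vector(division_axis)
  unit_vector(ap_axis)
  paste0(mother, c("a", "p"))
}

# Which end of the division axis is anterior: +1 if the daughter displaced
# along +axis lies in the anterior hemisphere (axis . ap >= 0), else -1.
anterior_sign <- function(division_axis, ap_axis) {
  if (sum(unit_vector(division_axis) * unit_vector(ap_axis)) >= 0) 1 else -1
}

#' Cells alive at a time point
#'
#' A cell is alive at time `t` if it has been born (`birth_time <= t`) and
#' has not yet divided (`division_time` absent or `> t`).
#'
#' @param tree a `lineage_tree`.
#' @param t time in minutes.
#' @return character vector of cell names (sorted).
#' @export
cells_alive_at <- function(tree, t) {
  stopifnot_scalar(t, "t")
  root <- root_of(tree)
  if (t < tree$birth_time[tree$name == root]) {
    stop("`t` precedes the root cell's birth", call. = FALSE)
  }
  alive <- tree$birth_time <= t &
    (is.na(tree$division_time) | tree$division_time > t)
  sort(tree$name[alive])
}

#' Division schedule of a lineage
#'
#' @param tree a `lineage_tree`.
#' @return data frame `time`, `dividing_cell`, `daughter_a`, `daughter_p`,
#'   sorted by time then (tie-break) by cell name.
#' @export
division_schedule <- function(tree) {
  div <- tree[!is.na(tree$division_time), , drop = FALSE]
  if (nrow(div) == 0L) {
    return(data.frame(time = numeric(0), dividing_cell = character(0),
                      daughter_a = character(0), daughter_p = character(0),
                      stringsAsFactors = FALSE))
  }
  kids <- t(vapply(div$name, function(nm) children_of(tree, nm), character(2)))
  out <- data.frame(time = div$division_time, dividing_cell = div$name,
                    daughter_a = kids[, 1], daughter_p = kids[, 2],
                    stringsAsFactors = FALSE)
  out <- out[order(out$time, out$dividing_cell), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- Newick export / import -------------------------------------------------

# Node labels optionally carry the fate as "name&fate" (own encoding; Newick
# has no standard per-node annotation that ape preserves).
encode_label <- function(name, fate, include_fates) {
  ifelse(include_fates & fate != "unassigned", paste0(name, "&", fate), name)
}

decode_label <- function(label) {
  parts <- strsplit(label, "&", fixed = TRUE)
  name <- vapply(parts, `[`, "", 1L)
  fate <- vapply(parts, function(p) if (length(p) > 1L) p[2] else "unassigned", "")
  list(name = name, fate = fate)
}

node_lifetime <- function(tree) {
  lt <- tree$division_time - tree$birth_time
  lt[is.na(lt)] <- 0  # terminal cells: convention, lifetime unknown
  lt
}

#' Export a lineage tree to Newick
#'
#' Branch lengths are cell lifetimes in minutes (0 for terminal cells, whose
#' division is unobserved); internal nodes are labelled; the root carries a
#' root edge equal to its own lifetime. Fates other than "unassigned" are
#' appended to labels as `name&fate` so that [import_newick()] recovers them.
#'
#' @param tree a `lineage_tree`.
#' @param path optional output file; if `NULL` the Newick string is returned.
#' @param include_fates append fate labels to node names.
#' @return the Newick string (invisibly if written to `path`).
#' @export
export_newick <- function(tree, path = NULL, include_fates = TRUE) {
  validate_lineage(tree)
  df <- as.data.frame(tree)
  lab <- encode_label(df$name, df$fate, include_fates)
  lt <- node_lifetime(tree)
  if (nrow(df) == 1L) {
    nwk <- sprintf("%s:%s;", lab, format(lt, digits = 15))
  } else {
    phy <- lineage_to_phylo(df, lab, lt)
    nwk <- ape::write.tree(phy)
  }
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}

lineage_to_phylo <- function(df, lab, lt) {
  is_leaf <- is.na(df$division_time)
  tips <- df$name[is_leaf]
  internals <- character(0)
  # preorder over internal nodes so the root gets id n_tip + 1 (ape layout)
  walk <- function(nm) {
    if (is.na(df$division_time[match(nm, df$name)])) return(invisible())
    internals <<- c(internals, nm)
    for (k in children_of(df, nm)) walk(k)
  }
  walk(df$name[is.na(df$parent)])
  id <- c(stats::setNames(seq_along(tips), tips),
          stats::setNames(length(tips) + seq_along(internals), internals))
  kid <- df$name[!is.na(df$parent)]
  edge <- cbind(id[df$parent[!is.na(df$parent)]], id[kid])
  dimnames(edge) <- NULL
  phy <- list(edge = matrix(as.integer(edge), ncol = 2),
              edge.length = lt[match(kid, df$name)],
              Nnode = length(internals),
              tip.label = lab[match(tips, df$name)],
              node.label = lab[match(internals, df$name)],
              root.edge = lt[is.na(df$parent)])
  class(phy) <- "phylo"
  phy
}

#' Import a lineage tree from Newick
#'
#' Inverse of [export_newick()]: rebuilds names, fates, topology, and birth /
#' division times (absolute times need the root's birth time, which Newick
#' does not carry).
#'
#' @param x a Newick string or path to a Newick file.
#' @param root_birth_time birth time of the root cell, minutes.
#' @return a `lineage_tree`.
#' @export
import_newick <- function(x, root_birth_time = 0) {
  if (file.exists(x)) x <- paste(readLines(x), collapse = "")
  x <- trimws(x)
  if (!grepl("(", x, fixed = TRUE)) {
    # single-node tree: "label:length;"
    body <- sub(";$", "", x)
    parts <- strsplit(body, ":", fixed = TRUE)[[1]]
    dl <- decode_label(parts[1])
    return(lineage_tree(data.frame(
      name = dl$name, parent = NA_character_,
      birth_time = root_birth_time, division_time = NA_real_,
      fate = dl$fate, stringsAsFactors = FALSE)))
  }
  phy <- ape::read.tree(text = x)
  n_tip <- length(phy$tip.label)
  labels <- c(phy$tip.label, phy$node.label)
  dl <- decode_label(labels)
  root_id <- n_tip + 1L
  n_all <- n_tip + phy$Nnode
  parent <- rep(NA_integer_, n_all)
  inlen <- rep(NA_real_, n_all)
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  inlen[phy$edge[, 2]] <- phy$edge.length
  inlen[root_id] <- if (is.null(phy$root.edge)) 0 else phy$root.edge
  birth <- rep(NA_real_, n_all)
  division <- rep(NA_real_, n_all)
  # breadth-first down from the root; a node's edge length is its lifetime
  birth[root_id] <- root_birth_time
  queue <- root_id
  while (length(queue)) {
    v <- queue[1]; queue <- queue[-1]
    kids <- phy$edge[phy$edge[, 1] == v, 2]
    if (length(kids)) {
      division[v] <- birth[v] + inlen[v]
      birth[kids] <- division[v]
      queue <- c(queue, kids)
    }
  }
  lineage_tree(data.frame(
    name = dl$name,
    parent = ifelse(is.na(parent), NA_character_, dl$name[parent]),
    birth_time = birth, division_time = division, fate = dl$fate,
    stringsAsFactors = FALSE))
}
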