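#' Label hierarchies for hierarchical multi-label classification
#'
#' A label hierarchy is the partially ordered label set used in protein
#' function annotation: a rooted tree (FunCat-like, every label has a single
#' parent) or a rooted directed acyclic graph (GO-like, labels may have
#' several parents). Labels are opaque strings; parenthood is given
#' explicitly, never parsed from the label text.
#'
#' @param parents named list; one entry per label, each a character vector of
#'   parent labels (length zero for a root).
#' @param kind `"tree"` or `"dag"`. Trees additionally require a single
#'   parent per non-root label.
#' @return An object of class `label_hierarchy` with components `labels`
#'   (in a topological order, parents before children), `parents`,
#'   `children`, `kind`, and `level` (named integer, level by deepest path;
#'   roots are level 1).
#' @examples
#' h <- label_hierarchy(list(`1` = character(), `1.2` = "1", `1.2.3` = "1.2"),
#'                      kind = "tree")
#' ancestors(h, "1.2.3")
#' @seealso [funcat_hierarchy()], [validate_hierarchy()], [ancestors()]
#' @export
label_hierarchy <- function(parents, kind = c("tree", "dag")) {
  kind <- match.arg(kind)
  if (is.null(names(parents)) || anyNA(names(parents)) ||
      any(names(parents) == ""))
    stop("'parents' must be a named list with one entry per label")
  parents <- lapply(parents, as.character)
  h <- structure(list(labels = names(parents), parents = parents,
                      kind = kind), class = "label_hierarchy")
  diag <- validate_hierarchy(h)
  if (!diag$ok)
    stop("invalid hierarchy: ",
         paste(vapply(diag$problems, `[[`, "", "message"), collapse = "; "))
  ord <- topo_order(parents)
  h$labels <- ord
  h$parents <- parents[ord]
  h$children <- children_map(h$parents)
  h$level <- deepest_levels(h$parents, ord)
  h
}

#' @export
print.label_hierarchy <- function(x, ...) {
  cat(sprintf("label_hierarchy (%s): %d labels, %d root(s), max level %d\n",
              x$kind, length(x$labels), sum(lengths(x$parents) == 0L),
              max(x$level)))
  invisible(x)
}

# Kahn topological order over parent -> child edges; assumes acyclic.
topo_order <- function(parents) {
  labs <- names(parents)
  indeg <- lengths(parents)
  ch <- children_map(parents)
  queue <- labs[indeg == 0L]
  out <- character(0)
  while (length(queue)) {
    v <- queue[1L]; queue <- queue[-1L]
    out <- c(out, v)
    for (c in ch[[v]]) {
      indeg[[c]] <- indeg[[c]] - 1L
      if (indeg[[c]] == 0L) queue <- c(queue, c)
    }
  }
  out
}

children_map <- function(parents) {
  ch <- stats::setNames(vector("list", length(parents)), names(parents))
  for (lab in names(parents))
    for (p in parents[[lab]]) ch[[p]] <- c(ch[[p]], lab)
  ch
}

deepest_levels <- function(parents, topo) {
  lev <- stats::setNames(integer(length(topo)), topo)
  for (lab in topo) {
    ps <- parents[[lab]]
    lev[[lab]] <- if (length(ps) == 0L) 1L else 1L + max(lev[ps])
  }
  lev
}

#' Check the structural invariants of a label hierarchy
#'
#' Verifies acyclicity, membership of every referenced parent, existence of
#' at least one root, and (for trees) the single-parent constraint. Returns
#' diagnostics rather than raising conditions, so it can be used on
#' hierarchies assembled from untrusted files.
#'
#' @param h a `label_hierarchy`, or a bare list with `labels`, `parents`,
#'   `kind` fields not yet validated.
#' @return list with `ok` (logical) and `problems`, a list of records each
#'   carrying `type` (`"cycle"`, `"multi_parent"`, `"dangling_parent"`,
#'   `"no_root"`), a witness field, and a human-readable `message`.
#' @export
validate_hierarchy <- function(h) {
  labs <- as.character(h$labels)
  parents <- h$parents
  problems <- list()
  dangling <- setdiff(unique(unlist(parents, use.names = FALSE)), labs)
  if (length(dangling))
    problems <- c(problems, list(list(
      type = "dangling_parent", labels = dangling,
      message = paste0("parent label(s) not declared: ",
                       paste(dangling, collapse = ", ")))))
  if (identical(h$kind, "tree")) {
    multi <- labs[lengths(parents[labs]) > 1L]
    if (length(multi))
      problems <- c(problems, list(list(
        type = "multi_parent", labels = multi,
        message = paste0("tree label(s) with multiple parents: ",
                         paste(multi, collapse = ", ")))))
  }
  if (!any(lengths(parents[labs]) == 0L))
    problems <- c(problems, list(list(
      type = "no_root", labels = character(0),
      message = "no root label (every label has a parent)")))
  if (!length(dangling)) {
    ord <- topo_order(parents)
    if (length(ord) < length(labs)) {
      cyc <- setdiff(labs, ord)
      problems <- c(problems, list(list(
        type = "cycle", labels = cyc,
        message = paste0("cycle through: ", paste(cyc, collapse = ", ")))))
    }
  }
  list(ok = length(problems) == 0L, problems = problems)
}

#' Build a FunCat-style tree hierarchy from dotted codes
#'
#' FunCat identifies functions by dotted numeric codes (`"1.2.3"`); the code
#' text encodes the single path to the root, so the full tree can be
#' reconstructed from any set of codes by adding all prefixes.
#'
#' @param codes character vector of dotted codes.
#' @return a `label_hierarchy` of kind `"tree"` containing `codes` and all
#'   their prefixes.
#' @examples
#' funcat_hierarchy(c("1.2.3", "2.1"))
#' @export
funcat_hierarchy <- function(codes) {
  codes <- unique(as.character(codes))
  all_codes <- unique(unlist(lapply(strsplit(codes, ".", fixed = TRUE),
    function(p) vapply(seq_along(p), function(k)
      paste(p[seq_len(k)], collapse = "."), "")), use.names = FALSE))
  parent_of <- function(code) {
    p <- strsplit(code, ".", fixed = TRUE)[[1L]]
    if (length(p) == 1L) character(0)
    else paste(p[-length(p)], collapse = ".")
  }
  label_hierarchy(stats::setNames(lapply(all_codes, parent_of), all_codes),
                  kind = "tree")
}

check_labels <- function(h, labels) {
  bad <- setdiff(labels, h$labels)
  if (length(bad))
    stop("unknown label(s): ", paste(bad, collapse = ", "))
}

#' Strict ancestors of a label
#'
#' The transitive closure of the parent relation, excluding the label
#' itself; for DAG hierarchies this is the union over all parent paths.
#' The hierarchy constraint requires every ancestor of an assigned label to
#' be assigned as well, so this is the workhorse of label-set closure.
#'
#' @param h a `label_hierarchy`.
#' @param label a single label in `h`.
#' @return character vector of ancestor labels (possibly empty, for roots).
#' @export
ancestors <- function(h, label) {
  stopifnot(length(label) == 1L)
  check_labels(h, label)
  out <- character(0)
  frontier <- h$parents[[label]]
  while (length(frontier)) {
    out <- union(out, frontier)
    frontier <- setdiff(unique(unlist(h$parents[frontier], use.names = FALSE)),
                        out)
  }
  out
}

#' Close a label set under ancestors
#'
#' Returns the smallest superset of `label_set` closed under the hierarchy
#' constraint. Idempotent and monotone in `label_set`.
#'
#' @param h a `label_hierarchy`.
#' @param label_set character vector of labels in `h`.
#' @return character vector; `label_set` plus all ancestors, in hierarchy
#'   (topological) order.
#' @export
close_under_ancestors <- function(h, label_set) {
  label_set <- unique(as.character(label_set))
  check_labels(h, label_set)
  out <- label_set
  frontier <- label_set
  while (length(frontier)) {
    ps <- setdiff(unique(unlist(h$parents[frontier], use.names = FALSE)), out)
    out <- c(out, ps)
    frontier <- ps
  }
  h$labels[h$labels %in% out]
}

#' Level of a label by its deepest path
#'
#' Level is 1 plus the length of the longest directed path from any root to
#' the label; roots are level 1. For DAG hierarchies a label reachable at
#' several depths is assigned the deepest one, the convention used when
#' tabulating GO annotations per level.
#'
#' @param h a `label_hierarchy`.
#' @param label one or more labels in `h`.
#' @return integer vector of levels, named by label.
#' @export
level_by_deepest_path <- function(h, label) {
  check_labels(h, label)
  h$level[label]
}

#' Write / read a hierarchy as child-parent TSV
#'
#' Serialization is a two-column `child<TAB>parent` edge list; roots are
#' written with an empty parent field. A `# kind: tree|dag` comment header
#' records the hierarchy kind.
#'
#' @param h a `label_hierarchy`.
#' @param path file path.
#' @return `write_hierarchy_tsv` returns `path` invisibly;
#'   `read_hierarchy_tsv` returns a `label_hierarchy`.
#' @export
write_hierarchy_tsv <- function(h, path) {
  rows <- unlist(lapply(h$labels, function(lab) {
    ps <- h$parents[[lab]]
    if (length(ps) == 0L) paste(lab, "", sep = "\t")
    else paste(lab, ps, sep = "\t")
  }), use.names = FALSE)
  writeLines(c(paste0("# kind: ", h$kind), rows), path)
  invisible(path)
}

#' @rdname write_hierarchy_tsv
#' @export
read_hierarchy_tsv <- function(path) {
  lines <- readLines(path)
  kind <- "dag"
  km <- grep("^#\\s*kind:", lines, value = TRUE)
  if (length(km)) kind <- trimws(sub("^#\\s*kind:", "", km[1L]))
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  child <- vapply(parts, `[[`, "", 1L)
  parent <- vapply(parts, function(p) if (length(p) > 1L) p[[2L]] else "", "")
  parents <- lapply(split(parent, factor(child, levels = unique(child))),
                    function(p) p[nzchar(p)])
  label_hierarchy(parents, kind = kind)
}
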