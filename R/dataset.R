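#' Hierarchical multi-label datasets
#'
#' An `hmc_dataset` binds instances (ID, numeric feature vector with
#' possible missing values, ancestor-closed label set) to a
#' [label_hierarchy()] and a split tag. Label sets are stored closed under
#' ancestors at all times; constructors close them on entry.
#'
#' @param hierarchy a `label_hierarchy`.
#' @param ids character vector of unique instance identifiers.
#' @param features numeric matrix (instances in rows; `NA` marks a missing
#'   value). Column names are used as feature names when present.
#' @param labels list of character vectors, one label set per instance;
#'   closed under ancestors on construction.
#' @param split one of `"train"`, `"valid"`, `"test"`.
#' @param feature_names optional character vector overriding
#'   `colnames(features)`.
#' @return an object of class `hmc_dataset`.
#' @export
hmc_dataset <- function(hierarchy, ids, features, labels,
                        split = c("train", "valid", "test"),
                        feature_names = NULL) {
  split <- match.arg(split)
  stopifnot(inherits(hierarchy, "label_hierarchy"))
  ids <- as.character(ids)
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  if (anyDuplicated(ids))
    stop("duplicated instance ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (length(ids) != nrow(features) || length(labels) != length(ids))
    stop("ids, features and labels disagree in length")
  if (is.null(feature_names))
    feature_names <- colnames(features)
  if (is.null(feature_names))
    feature_names <- sprintf("f%d", seq_len(ncol(features)))
  colnames(features) <- feature_names
  labels <- lapply(labels, function(s) close_under_ancestors(hierarchy, s))
  structure(list(hierarchy = hierarchy, ids = ids, features = features,
                 labels = labels, split = split,
                 feature_names = feature_names),
            class = "hmc_dataset")
}

#' @export
print.hmc_dataset <- function(x, ...) {
  cat(sprintf(
    "hmc_dataset [%s]: %d instances, %d features, %d labels (%s hierarchy)\n",
    x$split, length(x$ids), ncol(x$features),
    length(x$hierarchy$labels), x$hierarchy$kind))
  invisible(x)
}

## ---------------------------------------------------------------------------
## Clus ARFF dialect

# Path-consistency: a declaration is a tree path list iff, for every element
# with k > 1 components, the (k-1)-component prefix is also declared. DAG
# declarations are child/parent pairs whose first component is the (deeper)
# child, so the prefix test fails for them.
is_tree_path_decl <- function(elems) {
  parts <- strsplit(elems, "/", fixed = TRUE)
  prefixes <- vapply(parts, function(p)
    if (length(p) == 1L) NA_character_
    else paste(p[-length(p)], collapse = "/"), "")
  all(is.na(prefixes) | prefixes %in% elems)
}

parse_hier_decl <- function(decl, hierarchy_format = "auto") {
  elems <- trimws(strsplit(decl, ",", fixed = TRUE)[[1L]])
  elems <- elems[nzchar(elems)]
  if (hierarchy_format == "auto")
    hierarchy_format <- if (is_tree_path_decl(elems)) "tree" else "dag"
  if (hierarchy_format == "tree") {
    parts <- strsplit(elems, "/", fixed = TRUE)
    labs <- vapply(parts, function(p) p[length(p)], "")
    pars <- lapply(parts, function(p)
      if (length(p) == 1L) character(0) else p[length(p) - 1L])
    parents <- stats::setNames(pars, labs)
    label_hierarchy(parents[!duplicated(labs)], kind = "tree")
  } else {
    parents <- list()
    for (e in elems) {
      p <- strsplit(e, "/", fixed = TRUE)[[1L]]
      child <- p[1L]
      if (is.null(parents[[child]])) parents[[child]] <- character(0)
      if (length(p) == 2L) {
        parents[[child]] <- union(parents[[child]], p[2L])
        if (is.null(parents[[p[2L]]])) parents[[p[2L]]] <- character(0)
      } else if (length(p) > 2L) {
        stop("malformed DAG hierarchy element: ", e)
      }
    }
    label_hierarchy(parents, kind = "dag")
  }
}

#' Read a hierarchical multi-label dataset in the Clus ARFF dialect
#'
#' The dialect has numeric feature attributes followed by a single
#' `hierarchical` class attribute declaring the label vocabulary: either
#' root-to-label slash paths (tree hierarchies, e.g. `1,1/1.2,1/1.2/1.2.3`)
#' or `child/parent` edge pairs with roots declared bare (DAG hierarchies).
#' Data rows are comma-separated feature values (`?` for missing) with an
#' `@`-separated label list last (`?` for the empty set). Label sets are
#' closed under ancestors on read.
#'
#' @param path path to the ARFF file.
#' @param split split tag to attach (`"train"`, `"valid"`, `"test"`).
#' @param hierarchy_format `"auto"` (default), `"tree"`, or `"dag"`,
#'   overriding auto-detection of the class-attribute syntax.
#' @return an [hmc_dataset()].
#' @export
read_arff_hmc <- function(path, split = "train", hierarchy_format = "auto") {
  lines <- readLines(path, warn = FALSE)
  n_header <- grep("^\\s*@data\\s*$", lines, ignore.case = TRUE)
  if (length(n_header) != 1L)
    stop("malformed header: expected exactly one @DATA line")
  header <- lines[seq_len(n_header - 1L)]
  attr_lines <- grep("^\\s*@attribute\\b", header, ignore.case = TRUE)
  att <- regmatches(header[attr_lines],
    regexec("^\\s*@attribute\\s+('[^']*'|\\S+)\\s+(.*)$",
            header[attr_lines], ignore.case = TRUE))
  att_names <- gsub("^'|'$", "", vapply(att, `[[`, "", 2L))
  att_types <- trimws(vapply(att, `[[`, "", 3L))
  is_class <- grepl("^hierarchical\\b", att_types, ignore.case = TRUE)
  if (sum(is_class) != 1L)
    stop("malformed header: expected exactly one hierarchical class attribute")
  if (which(is_class) != length(att_types))
    stop("malformed header: the hierarchical class attribute must come last")
  feat_names <- att_names[!is_class]
  bad_type <- !grepl("^(numeric|real|integer)\\b", att_types[!is_class],
                     ignore.case = TRUE)
  if (any(bad_type))
    stop("unsupported feature attribute type at header line ",
         attr_lines[!is_class][bad_type][1L])
  h <- parse_hier_decl(
    sub("^hierarchical\\s+", "", att_types[is_class], ignore.case = TRUE),
    hierarchy_format)

  body_idx <- seq.int(n_header + 1L, length.out = length(lines) - n_header)
  body_idx <- body_idx[nzchar(trimws(lines[body_idx])) &
                         !grepl("^\\s*%", lines[body_idx])]
  n_feat <- length(feat_names)
  ids <- character(0); feats <- list(); labsets <- list()
  for (i in body_idx) {
    fields <- trimws(strsplit(lines[i], ",", fixed = TRUE)[[1L]])
    if (length(fields) != n_feat + 1L)
      stop("row arity mismatch at line ", i, ": expected ", n_feat + 1L,
           " fields, found ", length(fields))
    fv <- fields[seq_len(n_feat)]
    x <- suppressWarnings(as.numeric(fv))
    bad <- is.na(x) & fv != "?"
    if (any(bad))
      stop("unparseable feature value '", fv[bad][1L], "' at line ", i)
    lab_field <- fields[n_feat + 1L]
    labs <- if (lab_field %in% c("?", "")) character(0)
            else trimws(strsplit(lab_field, "@", fixed = TRUE)[[1L]])
    unknown <- setdiff(labs, h$labels)
    if (length(unknown))
      stop("label '", unknown[1L], "' at line ", i,
           " absent from the declared vocabulary")
    feats[[length(feats) + 1L]] <- x
    labsets[[length(labsets) + 1L]] <- labs
  }
  features <- do.call(rbind, feats)
  if (is.null(features)) features <- matrix(numeric(0), 0L, n_feat)
  colnames(features) <- feat_names
  ids <- sprintf("row%05d", seq_len(nrow(features)))
  hmc_dataset(h, ids, features, labsets, split = split)
}

maximal_labels <- function(h, label_set) {
  if (length(label_set) == 0L) return(character(0))
  keep <- vapply(label_set, function(lab)
    !any(h$children[[lab]] %in% label_set), TRUE)
  label_set[keep]
}

#' Write a hierarchical multi-label dataset in the Clus ARFF dialect
#'
#' Label sets are written in reduced form (maximal labels only); closure is
#' restored by [read_arff_hmc()]. Missing feature values are written as `?`,
#' empty label sets as `?`.
#'
#' @param ds an [hmc_dataset()].
#' @param path output file path.
#' @param relation relation name for the `@RELATION` line.
#' @return `path`, invisibly.
#' @export
write_arff_hmc <- function(ds, path, relation = "hmc") {
  h <- ds$hierarchy
  decl <- if (h$kind == "tree") {
    paths <- character(length(h$labels)); names(paths) <- h$labels
    for (lab in h$labels) {  # topo order: parent path known first
      p <- h$parents[[lab]]
      paths[[lab]] <- if (length(p) == 0L) lab
                      else paste0(paths[[p]], "/", lab)
    }
    paste(paths, collapse = ",")
  } else {
    elems <- unlist(lapply(h$labels, function(lab) {
      ps <- h$parents[[lab]]
      if (length(ps) == 0L) lab else paste(lab, ps, sep = "/")
    }), use.names = FALSE)
    paste(elems, collapse = ",")
  }
  fmt_feat <- function(x) ifelse(is.na(x), "?", sprintf("%.10g", x))
  rows <- vapply(seq_along(ds$ids), function(i) {
    labs <- maximal_labels(h, ds$labels[[i]])
    lab_field <- if (length(labs) == 0L) "?" else paste(labs, collapse = "@")
    paste(c(fmt_feat(ds$features[i, ]), lab_field), collapse = ",")
  }, "")
  writeLines(c(paste0("@RELATION ", relation), "",
               sprintf("@ATTRIBUTE %s numeric", ds$feature_names),
               paste0("@ATTRIBUTE class hierarchical ", decl), "",
               "@DATA", rows), path)
  invisible(path)
}

## ---------------------------------------------------------------------------
## Annotation update procedure

#' Specification of an annotation update
#'
#' Carries the ingredients of the dataset-update procedure: the re-queried
#' annotation map, the alternate-ID (secondary label) map merging synonymous
#' labels into their canonical form, and the set of obsolete labels to drop.
#'
#' @param new_annotations named list, instance id -> character vector of
#'   labels (the freshly queried annotations, not necessarily closed).
#' @param alternate_ids named character vector, secondary label -> canonical
#'   label; applied to a fixed point, so chains are allowed but cycles are
#'   rejected.
#' @param obsolete character vector of labels to remove outright.
#' @return an object of class `annotation_update_spec`.
#' @export
annotation_update_spec <- function(new_annotations,
                                   alternate_ids = character(0),
                                   obsolete = character(0)) {
  alternate_ids <- stats::setNames(as.character(alternate_ids),
                                   names(alternate_ids))
  obsolete <- as.character(obsolete)
  for (lab in names(alternate_ids)) canonical_label(lab, alternate_ids)
  clash <- intersect(obsolete, alternate_ids)
  if (length(clash))
    stop("obsolete labels may not be canonical targets: ",
         paste(clash, collapse = ", "))
  structure(list(new_annotations = new_annotations,
                 alternate_ids = alternate_ids, obsolete = obsolete),
            class = "annotation_update_spec")
}

# Follow the alternate-ID map to a fixed point, with a cycle guard.
canonical_label <- function(label, alternate_ids) {
  steps <- 0L
  while (label %in% names(alternate_ids)) {
    label <- alternate_ids[[label]]
    steps <- steps + 1L
    if (steps > length(alternate_ids))
      stop("cycle in alternate-ID map at label ", label)
  }
  label
}

#' Replace a dataset's annotations with a freshly queried set
#'
#' Implements the dataset-update procedure: the 2007-era labels are
#' discarded entirely; each instance receives the newly queried labels,
#' mapped through the alternate-ID table to their canonical form, stripped
#' of obsolete labels, and closed under ancestors in the new hierarchy.
#' Features and split tags are untouched. The dataset's hierarchy becomes
#' the subset of `new_hierarchy` induced by the labels actually used (see
#' [build_hierarchy_subset()]), which is why updated datasets carry
#' different hierarchies.
#'
#' @param ds an [hmc_dataset()].
#' @param spec an [annotation_update_spec()]. Instances missing from
#'   `spec$new_annotations` get an empty label set (reported via `message`).
#' @param new_hierarchy the full updated [label_hierarchy()].
#' @return an updated [hmc_dataset()].
#' @export
update_annotations <- function(ds, spec, new_hierarchy) {
  stopifnot(inherits(spec, "annotation_update_spec"))
  missing_ids <- setdiff(ds$ids, names(spec$new_annotations))
  if (length(missing_ids))
    message(length(missing_ids),
            " instance(s) without new annotations; set to empty: ",
            paste(utils::head(missing_ids, 5L), collapse = ", "),
            if (length(missing_ids) > 5L) ", ..." else "")
  new_sets <- lapply(ds$ids, function(id) {
    labs <- spec$new_annotations[[id]]
    if (is.null(labs)) return(character(0))
    labs <- vapply(labs, canonical_label, "",
                   alternate_ids = spec$alternate_ids, USE.NAMES = FALSE)
    labs <- setdiff(unique(labs), spec$obsolete)
    bad <- setdiff(labs, new_hierarchy$labels)
    if (length(bad))
      stop("instance ", id, ": label(s) absent from the new hierarchy: ",
           paste(bad, collapse = ", "))
    labs
  })
  used <- unique(unlist(new_sets, use.names = FALSE))
  sub_h <- build_hierarchy_subset(new_hierarchy, used)
  hmc_dataset(sub_h, ds$ids, ds$features, new_sets, split = ds$split,
              feature_names = ds$feature_names)
}

#' Hierarchy induced by a set of used labels
#'
#' Restricts a full hierarchy to the ancestor closure of the labels that
#' actually occur in a dataset, with parent links restricted accordingly.
#' Each updated dataset thereby carries its own hierarchy subset.
#'
#' @param full a [label_hierarchy()].
#' @param used_labels labels of `full` retained (their ancestors are
#'   retained implicitly).
#' @return a [label_hierarchy()] of the same kind.
#' @export
build_hierarchy_subset <- function(full, used_labels) {
  keep <- close_under_ancestors(full, used_labels)
  parents <- lapply(full$parents[keep], function(ps) ps[ps %in% keep])
  label_hierarchy(parents, kind = full$kind)
}

## ---------------------------------------------------------------------------
## Dataset statistics

#' Per-level dataset statistics
#'
#' For each hierarchy level (by deepest path): the number of labels at that
#' level, the number of instances with at least one label at that level, and
#' the total number of (instance, label) annotations at that level.
#'
#' @param ds an [hmc_dataset()].
#' @param drop_level1 drop the level-1 row, as done for GO-style hierarchies
#'   whose root terms are present in every instance.
#' @return data.frame with columns `level`, `n_labels`,
#'   `n_annotated_instances`, `n_annotations`.
#' @export
per_level_stats <- function(ds, drop_level1 = FALSE) {
  lev <- ds$hierarchy$level
  levels_all <- seq_len(max(lev))
  lab_lev <- lapply(ds$labels, function(s) lev[s])
  out <- data.frame(
    level = levels_all,
    n_labels = vapply(levels_all, function(L) sum(lev == L), 0L),
    n_annotated_instances = vapply(levels_all, function(L)
      sum(vapply(lab_lev, function(x) any(x == L), TRUE)), 0L),
    n_annotations = vapply(levels_all, function(L)
      sum(vapply(lab_lev, function(x) sum(x == L), 0L)), 0L))
  if (drop_level1) out <- out[out$level != 1L, , drop = FALSE]
  out
}

#' Added and removed annotations per level between two dataset versions
#'
#' Pairs are compared on the intersection of the two label sets, matched by
#' instance id. Added pairs (absent in `old`, present in `new`) are counted
#' at the label's level in the new hierarchy; removed pairs at its level in
#' the old hierarchy.
#'
#' @param old,new two [hmc_dataset()]s over the same instances.
#' @return data.frame with columns `level`, `n_added`, `n_removed`.
#' @export
diff_annotation_stats <- function(old, new) {
  sym <- c(setdiff(old$ids, new$ids), setdiff(new$ids, old$ids))
  if (length(sym))
    stop("instance-id mismatch between versions: ",
         paste(sym, collapse = ", "))
  inter <- intersect(old$hierarchy$labels, new$hierarchy$labels)
  max_lev <- max(old$hierarchy$level, new$hierarchy$level)
  n_added <- n_removed <- integer(max_lev)
  pos_in_new <- match(old$ids, new$ids)
  for (i in seq_along(old$ids)) {
    o <- intersect(old$labels[[i]], inter)
    n <- intersect(new$labels[[pos_in_new[i]]], inter)
    for (lab in setdiff(n, o)) {
      L <- new$hierarchy$level[[lab]]
      n_added[L] <- n_added[L] + 1L
    }
    for (lab in setdiff(o, n)) {
      L <- old$hierarchy$level[[lab]]
      n_removed[L] <- n_removed[L] + 1L
    }
  }
  data.frame(level = seq_len(max_lev), n_added = n_added,
             n_removed = n_removed)
}

#' Report instances sharing identical feature vectors
#'
#' Groups instances by exact feature-vector equality (missing values compare
#' equal to each other) and flags groups whose members carry different label
#' sets — the situation that makes some benchmark feature sets unreliable.
#'
#' @param ds an [hmc_dataset()].
#' @return list with `n_unique` (number of distinct feature vectors),
#'   `n_duplicated` (instances beyond the first of their group; so
#'   `n_unique + n_duplicated` equals the instance count), and
#'   `conflicting_groups`, a list of instance-id vectors for groups whose
#'   members disagree on labels.
#' @export
duplicate_feature_report <- function(ds) {
  keys <- apply(ds$features, 1L, function(x)
    paste(ifelse(is.na(x), "?", sprintf("%.15g", x)), collapse = ","))
  groups <- split(seq_along(ds$ids), keys)
  conflict <- Filter(function(idx) {
    if (length(idx) < 2L) return(FALSE)
    sets <- lapply(ds$labels[idx], sort)
    any(!vapply(sets, identical, TRUE, y = sets[[1L]]))
  }, groups)
  list(n_unique = length(groups),
       n_duplicated = length(ds$ids) - length(groups),
       conflicting_groups = unname(lapply(conflict, function(i) ds$ids[i])))
}

#' Read an annotation map from TSV
#'
#' Two tab-separated columns `instance_id<TAB>label`, one annotation per
#' row; lines starting with `#` are comments. Returns the named list form
#' consumed by [annotation_update_spec()].
#'
#' @param path file path.
#' @return named list, instance id -> character vector of labels.
#' @export
read_annotation_map_tsv <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  id <- vapply(parts, `[[`, "", 1L)
  lab <- vapply(parts, `[[`, "", 2L)
  lapply(split(lab, factor(id, levels = unique(id))), unique)
}
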