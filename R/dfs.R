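# Deep feature synthesis: entity (efeat), relational (rfeat) and direct
# (dfeat) feature primitives, applied recursively toward a target table.
#
# Traversal follows the generation algorithm: mark the current table
# visited; recurse into backward (child) tables then aggregate them with
# rfeat; recurse into unvisited forward (parent) tables then copy them in
# with dfeat; finally apply efeat transforms to the current table. Tables
# and columns are processed in declaration order so output is deterministic.

#' Construct a feature primitive
#'
#' Entity primitives (`efeat`) are per-entry transforms of a single column;
#' relational primitives (`rfeat`) are permutation-invariant aggregations of
#' a child column grouped by the parent key.
#'
#' @param name Short lower-case identifier; upper-cased in feature names.
#' @param kind `"efeat"` or `"rfeat"`.
#' @param fn For `efeat`, `function(x)` returning a vector of `length(x)`;
#'   for `rfeat`, `function(x)` returning a scalar.
#' @param empty_value Value an `rfeat` yields for a parent with no children
#'   (count uses 0; the default is the missing marker `NA`).
#' @return An object of class `feature_primitive`.
#' @export
feature_primitive <- function(name, kind = c("efeat", "rfeat"), fn,
                              empty_value = NA_real_) {
  kind <- match.arg(kind)
  structure(list(name = name, kind = kind, fn = fn, empty_value = empty_value),
            class = "feature_primitive")
}

#' Default primitive vocabulary
#'
#' Aggregations `count`, `sum`, `mean`, `min`, `max`, `std` (sample standard
#' deviation) for relational features and `identity`, `zscore` (population
#' standard deviation) for entity features. `identity` licenses a table's own
#' columns into the feature matrix without renaming; `count` counts child
#' rows and yields a single column per child table.
#'
#' @return List of [feature_primitive()] objects.
#' @export
default_primitives <- function() {
  list(
    feature_primitive("count", "rfeat", function(x) length(x), empty_value = 0),
    feature_primitive("sum", "rfeat", function(x) sum(x)),
    feature_primitive("mean", "rfeat", function(x) mean(x)),
    feature_primitive("min", "rfeat", function(x) min(x)),
    feature_primitive("max", "rfeat", function(x) max(x)),
    feature_primitive("std", "rfeat", function(x) stats::sd(x)),
    feature_primitive("identity", "efeat", function(x) x),
    feature_primitive("zscore", "efeat", function(x) {
      if (length(x) < 2) return(rep(NA_real_, length(x)))
      s <- sqrt(mean((x - mean(x))^2))
      if (!is.finite(s) || s == 0) return(rep(NA_real_, length(x)))
      (x - mean(x)) / s
    })
  )
}

.dfs_log <- function(env, msg) {
  env$log <- c(env$log, msg)
  if (isTRUE(getOption("linacsched.verbose", FALSE))) message("[dfs] ", msg)
}

# Columns of a table usable as feature inputs: numeric, not the key, not a
# foreign key.
.feature_columns <- function(es, table, df) {
  keyish <- es$tables[[table]]$key
  for (r in es$relationships) {
    if (identical(r$child, table)) keyish <- c(keyish, r$child_column)
  }
  cols <- setdiff(names(df), keyish)
  cols[vapply(df[cols], is.numeric, logical(1))]
}

# One-hot encode character/factor columns, map logicals to 0/1. Key and
# foreign-key columns are identifiers and never encoded.
.encode_table <- function(es, table, df) {
  keyish <- es$tables[[table]]$key
  for (r in es$relationships) {
    if (identical(r$child, table)) keyish <- c(keyish, r$child_column)
  }
  out <- df[, intersect(keyish, names(df)), drop = FALSE]
  for (col in setdiff(names(df), keyish)) {
    v <- df[[col]]
    if (is.logical(v)) {
      out[[col]] <- as.numeric(v)
    } else if (is.character(v) || is.factor(v)) {
      for (lev in sort(unique(as.character(v)))) {
        out[[paste0(col, "=", lev)]] <- as.numeric(as.character(v) == lev)
      }
    } else {
      out[[col]] <- v
    }
  }
  out
}

.add_column <- function(env, table, name, values, provenance) {
  if (name %in% names(env$tables[[table]])) return(invisible(FALSE))
  env$tables[[table]][[name]] <- values
  env$provenance[[table]][[name]] <- provenance
  invisible(TRUE)
}

.efeat_onto <- function(env, es, table, prim) {
  df <- env$tables[[table]]
  if (prim$name == "identity") return(invisible(NULL))  # columns already present
  for (col in .feature_columns(es, table, df)) {
    vals <- prim$fn(df[[col]])
    .add_column(env, table, sprintf("%s(%s)", toupper(prim$name), col), vals,
                sprintf("efeat:%s(%s.%s)", prim$name, table, col))
  }
}

.rfeat_onto <- function(env, es, parent, child, prim) {
  rel <- .relationship_between(es, parent, child)
  if (is.null(rel)) {
    stop("no relationship from child '", child, "' to parent '", parent, "'",
         call. = FALSE)
  }
  pdf <- env$tables[[parent]]
  cdf <- env$tables[[child]]
  groups <- split(seq_len(nrow(cdf)),
                  factor(cdf[[rel$child_column]], levels = pdf[[rel$parent_key]]))
  agg_one <- function(values) {
    vapply(groups, function(idx) {
      if (length(idx) == 0) return(as.numeric(prim$empty_value))
      as.numeric(prim$fn(values[idx]))
    }, numeric(1))
  }
  if (prim$name == "count") {
    .add_column(env, parent, sprintf("COUNT(%s)", child),
                agg_one(rep(1, nrow(cdf))),
                sprintf("rfeat:count(%s)", child))
    return(invisible(NULL))
  }
  for (col in .feature_columns(es, child, cdf)) {
    .add_column(env, parent,
                sprintf("%s(%s.%s)", toupper(prim$name), child, col),
                agg_one(cdf[[col]]),
                sprintf("rfeat:%s(%s.%s)", prim$name, child, col))
  }
}

.dfeat_onto <- function(env, es, table, parent) {
  rel <- .relationship_between(es, parent, table)
  if (is.null(rel)) {
    stop("table '", table, "' has no forward relationship to '", parent, "'",
         call. = FALSE)
  }
  cdf <- env$tables[[table]]
  pdf <- env$tables[[parent]]
  idx <- match(cdf[[rel$child_column]], pdf[[rel$parent_key]])
  if (anyNA(idx)) {
    .dfs_log(env, sprintf(
      "dangling foreign key in '%s.%s': %d row(s) have no parent in '%s'",
      table, rel$child_column, sum(is.na(idx)), parent))
  }
  for (col in .feature_columns(es, parent, pdf)) {
    .add_column(env, table, paste0(parent, ".", col), pdf[[col]][idx],
                sprintf("dfeat:%s.%s", parent, col))
  }
}

.make_feature_rec <- function(env, es, table, depth, max_depth, efeats, rfeats) {
  env$visited <- union(env$visited, table)
  for (child in backward_relationships(es, table)) {
    if (!(child %in% env$visited)) {
      if (depth < max_depth) {
        .make_feature_rec(env, es, child, depth + 1, max_depth, efeats, rfeats)
      } else {
        .dfs_log(env, sprintf("max_depth reached: not recursing into '%s'",
                              child))
      }
    }
    for (prim in rfeats) .rfeat_onto(env, es, table, child, prim)
  }
  for (parent in forward_relationships(es, table)) {
    if (parent %in% env$visited) next
    if (depth < max_depth) {
      .make_feature_rec(env, es, parent, depth + 1, max_depth, efeats, rfeats)
    } else {
      env$visited <- union(env$visited, parent)
      .dfs_log(env, sprintf("max_depth reached: not recursing into '%s'",
                            parent))
    }
    .dfeat_onto(env, es, table, parent)
  }
  for (prim in efeats) .efeat_onto(env, es, table, prim)
}

.dfs_env <- function(es) {
  env <- new.env(parent = emptyenv())
  env$tables <- lapply(names(es$tables), function(nm) {
    .encode_table(es, nm, es$tables[[nm]]$df)
  })
  names(env$tables) <- names(es$tables)
  env$provenance <- lapply(es$tables, function(t) list())
  env$visited <- character(0)
  env$log <- character(0)
  env
}

#' Apply a single entity, relational or direct feature primitive
#'
#' Standalone, non-recursive application of the three primitive classes.
#' `apply_efeat()` adds one transformed column per eligible (numeric,
#' non-key) column of `table`; `apply_rfeat()` aggregates child rows grouped
#' by the parent key onto the parent (parents with no children receive the
#' primitive's empty-aggregate value: 0 for `count`, the missing marker
#' otherwise); `apply_dfeat()` copies parent columns onto the child via the
#' foreign-key join, prefixed with the parent table name (dangling keys
#' yield missing markers). Categorical columns are one-hot encoded first.
#'
#' @param es An [entity_set()].
#' @param table,parent,child Table names within `es`.
#' @param primitive A [feature_primitive()] of the matching kind.
#' @return The entity set with the modified table (`apply_efeat()` accepts
#'   and returns a single [entity_table()]).
#' @export
apply_efeat <- function(table, primitive) {
  stopifnot(inherits(table, "entity_table"))
  if (primitive$kind != "efeat") stop("primitive is not an efeat", call. = FALSE)
  es <- entity_set(list(table), list(), table$name)
  env <- .dfs_env(es)
  .efeat_onto(env, es, table$name, primitive)
  entity_table(env$tables[[table$name]], table$name, table$key)
}

#' @rdname apply_efeat
#' @export
apply_rfeat <- function(es, parent, child, primitive) {
  .check_table(es, parent); .check_table(es, child)
  if (primitive$kind != "rfeat") stop("primitive is not an rfeat", call. = FALSE)
  if (!child %in% backward_relationships(es, parent)) {
    stop("no relationship from child '", child, "' to parent '", parent, "'",
         call. = FALSE)
  }
  env <- .dfs_env(es)
  .rfeat_onto(env, es, parent, child, primitive)
  es$tables[[parent]] <- entity_table(env$tables[[parent]], parent,
                                      es$tables[[parent]]$key)
  es
}

#' @rdname apply_efeat
#' @export
apply_dfeat <- function(es, table, parent) {
  .check_table(es, table); .check_table(es, parent)
  if (!parent %in% forward_relationships(es, table)) {
    stop("table '", table, "' has no forward relationship to '", parent, "'",
         call. = FALSE)
  }
  env <- .dfs_env(es)
  .dfeat_onto(env, es, table, parent)
  es$tables[[table]] <- entity_table(env$tables[[table]], table,
                                     es$tables[[table]]$key)
  es
}

#' Generate the feature matrix for an entity set's target table
#'
#' Recursive deep feature synthesis: child tables are synthesized first and
#' aggregated in with the relational primitives, unvisited parent tables are
#' synthesized and copied in with direct features, and entity transforms are
#' applied last to every numeric column then present (so transforms of
#' aggregates, such as a z-scored mean, are generated at depth >= 2). A
#' shared visited set ensures no table is entered twice, and recursion stops
#' at `max_depth` (cycles beyond it are truncated with a log entry, not an
#' error). The target's own encoded columns always appear in the output.
#'
#' @param es An [entity_set()].
#' @param primitives List of [feature_primitive()] objects (mixed kinds);
#'   defaults to [default_primitives()].
#' @param max_depth Maximum recursion depth (>= 1; the target is depth 1).
#' @return Data frame with the target key as first column and one row per
#'   target entry. Attribute `provenance` maps each feature name to its
#'   primitive chain; attribute `log` holds traversal notes.
#' @export
make_features <- function(es, primitives = default_primitives(), max_depth = 2) {
  stopifnot(inherits(es, "entity_set"))
  if (max_depth < 1) stop("max_depth must be >= 1", call. = FALSE)
  efeats <- Filter(function(p) p$kind == "efeat", primitives)
  rfeats <- Filter(function(p) p$kind == "rfeat", primitives)
  env <- .dfs_env(es)
  .make_feature_rec(env, es, es$target, 1L, max_depth, efeats, rfeats)

  tgt <- env$tables[[es$target]]
  key <- es$tables[[es$target]]$key
  feat_cols <- c(key, setdiff(names(tgt), key))
  fk <- character(0)
  for (r in es$relationships) {
    if (identical(r$child, es$target)) fk <- c(fk, r$child_column)
  }
  out <- tgt[, setdiff(feat_cols, fk), drop = FALSE]
  prov <- env$provenance[[es$target]]
  own <- setdiff(names(out), c(key, names(prov)))
  for (col in own) {
    prov[[col]] <- sprintf("efeat:identity(%s.%s)", es$target, col)
  }
  attr(out, "provenance") <- unlist(prov[setdiff(names(out), key)])
  attr(out, "log") <- env$log
  rownames(out) <- NULL
  out
}

#' Numeric design matrix from a feature matrix
#'
#' Drops non-numeric columns (the target key) and imputes missing markers as
#' zero. Missing values arise from degenerate transforms — the z-score of a
#' constant column, the mean over an empty child set, a dangling foreign
#' key — and zero imputation leaves such columns inert in downstream fits.
#'
#' @param fm A feature matrix from [make_features()] (or any data frame).
#' @return Numeric matrix, one row per target entry.
#' @export
feature_design <- function(fm) {
  df <- as.data.frame(fm)
  num <- vapply(df, is.numeric, logical(1))
  x <- as.matrix(df[, num, drop = FALSE])
  x[!is.finite(x)] <- 0
  x
}

#' Write a feature matrix as CSV with a provenance sidecar
#'
#' @param fm A feature matrix from [make_features()].
#' @param path CSV output path; the sidecar is written next to it as
#'   `<path>.provenance.json` (feature name -> primitive chain).
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  utils::write.csv(fm, path, row.names = FALSE)
  prov <- as.list(attr(fm, "provenance"))
  jsonlite::write_json(prov, paste0(path, ".provenance.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
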