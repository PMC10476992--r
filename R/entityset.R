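# Relational entity sets: tables, keys, forward/backward relationships.

#' Construct an entity table
#'
#' @param df Rectangular data frame of entries.
#' @param name Table identifier.
#' @param key Name of the key column; key values must be unique.
#' @return An object of class `entity_table`.
#' @export
entity_table <- function(df, name, key) {
  if (!key %in% names(df)) {
    stop("key column '", key, "' not found in table '", name, "'",
         call. = FALSE)
  }
  if (anyDuplicated(df[[key]]) > 0) {
    stop("key values of table '", name, "' are not unique", call. = FALSE)
  }
  structure(list(name = name, key = key, df = df), class = "entity_table")
}

#' Construct an entity set
#'
#' A named collection of entity tables plus directed relationships, each a
#' many-to-one link from a child table's foreign-key column to a parent
#' table's key, and a designated target table for feature synthesis.
#'
#' @param tables List of [entity_table()] objects.
#' @param relationships List of relationships, each a list with elements
#'   `child`, `child_column`, `parent`, `parent_key`.
#' @param target Name of the target table.
#' @return An object of class `entity_set`.
#' @export
entity_set <- function(tables, relationships = list(), target) {
  names(tables) <- vapply(tables, function(t) t$name, character(1))
  for (r in relationships) {
    for (fld in c("child", "child_column", "parent", "parent_key")) {
      if (is.null(r[[fld]])) {
        stop("relationship missing field '", fld, "'", call. = FALSE)
      }
    }
    if (!r$child %in% names(tables)) {
      stop("relationship child table '", r$child, "' unknown", call. = FALSE)
    }
    if (!r$parent %in% names(tables)) {
      stop("relationship parent table '", r$parent, "' unknown", call. = FALSE)
    }
    if (identical(r$child, r$parent)) {
      stop("self-loop relationship on table '", r$child, "' not allowed",
           call. = FALSE)
    }
    if (!r$child_column %in% names(tables[[r$child]]$df)) {
      stop("child column '", r$child_column, "' not in table '", r$child, "'",
           call. = FALSE)
    }
    if (!identical(r$parent_key, tables[[r$parent]]$key)) {
      stop("parent_key '", r$parent_key, "' is not the key of table '",
           r$parent, "'", call. = FALSE)
    }
  }
  if (!target %in% names(tables)) {
    stop("target table '", target, "' unknown", call. = FALSE)
  }
  structure(list(tables = tables, relationships = relationships,
                 target = target), class = "entity_set")
}

.check_table <- function(es, table) {
  if (!table %in% names(es$tables)) {
    stop("unknown table '", table, "'", call. = FALSE)
  }
}

#' Forward and backward relationships of a table
#'
#' A forward relationship leads from a table to a parent it references
#' (many-to-one: the table holds the foreign key); a backward relationship
#' leads from a table to children referencing it (one-to-many). Tables are
#' returned in relationship declaration order.
#'
#' @param es An [entity_set()].
#' @param table Table name.
#' @return Character vector of table names (possibly empty).
#' @export
forward_relationships <- function(es, table) {
  .check_table(es, table)
  out <- character(0)
  for (r in es$relationships) {
    if (identical(r$child, table)) out <- c(out, r$parent)
  }
  unique(out)
}

#' @rdname forward_relationships
#' @export
backward_relationships <- function(es, table) {
  .check_table(es, table)
  out <- character(0)
  for (r in es$relationships) {
    if (identical(r$parent, table)) out <- c(out, r$child)
  }
  unique(out)
}

.relationship_between <- function(es, parent, child) {
  for (r in es$relationships) {
    if (identical(r$parent, parent) && identical(r$child, child)) return(r)
  }
  NULL
}

#' Load an entity set from a directory of CSV tables and a JSON manifest
#'
#' The manifest (default `entityset.json` inside `dir`) has the form
#' `{"target": ..., "tables": [{"name", "file", "key"}, ...],
#' "relationships": [{"child", "child_column", "parent", "parent_key"}, ...]}`.
#'
#' @param dir Directory containing the CSV files and manifest.
#' @param manifest Path to the manifest JSON.
#' @return An [entity_set()].
#' @export
load_entity_set <- function(dir, manifest = file.path(dir, "entityset.json")) {
  m <- jsonlite::read_json(manifest, simplifyVector = FALSE)
  tables <- lapply(m$tables, function(t) {
    df <- utils::read.csv(file.path(dir, t$file), stringsAsFactors = FALSE)
    entity_table(df, t$name, t$key)
  })
  entity_set(tables, m$relationships, m$target)
}

#' Build the default radiotherapy entity set from a cohort
#'
#' Two tables: `patients` (static positioning and plan features, keyed by
#' patient id) and `fractions` (per-fraction features: first-fraction flag,
#' prescription dose, control points), linked fractions -> patients. The
#' target is `fractions`; true durations are excluded (they are the
#' prediction targets, not features).
#'
#' @param records Cohort data frame (see [generate_cohort()]).
#' @return An [entity_set()] with target `fractions`.
#' @export
cohort_entity_set <- function(records) {
  patients <- records[, c("patient_id", "immobilization_site",
                          "immobilization_method", "six_dimension_table",
                          "vacuum_cushion", "metallic_implant", "igrt",
                          "treatment_site", "irradiation_technology")]
  fractions <- data.frame(
    fraction_id = sprintf("F%05d", seq_len(nrow(records))),
    patient_id = records$patient_id,
    first_fraction = records$first_fraction,
    prescription_dose = records$prescription_dose,
    control_points = records$control_points,
    stringsAsFactors = FALSE
  )
  entity_set(
    tables = list(entity_table(patients, "patients", "patient_id"),
                  entity_table(fractions, "fractions", "fraction_id")),
    relationships = list(list(child = "fractions",
                              child_column = "patient_id",
                              parent = "patients",
                              parent_key = "patient_id")),
    target = "fractions"
  )
}
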