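# Independent oracles and small fixture builders shared across tests.

# ---- toy entity-set builders -------------------------------------------

# Parent/child pair: patients (pk, p1) and fractions (ck, fk -> pk, c1).
toy_parent_child <- function(n_parent = 3, n_child = 5, seed = 1,
                             orphan_parent = FALSE) {
  set.seed(seed)
  parents <- data.frame(pk = paste0("P", seq_len(n_parent)),
                        p1 = round(stats::rnorm(n_parent), 3))
  fk_pool <- parents$pk
  if (orphan_parent && n_parent > 1) fk_pool <- parents$pk[-n_parent]
  children <- data.frame(ck = paste0("C", seq_len(n_child)),
                         fk = sample(fk_pool, n_child, replace = TRUE),
                         c1 = round(stats::rnorm(n_child), 3))
  list(parents = parents, children = children)
}

es_parent_child <- function(tp, target = "children") {
  entity_set(
    tables = list(entity_table(tp$parents, "parents", "pk"),
                  entity_table(tp$children, "children", "ck")),
    relationships = list(list(child = "children", child_column = "fk",
                              parent = "parents", parent_key = "pk")),
    target = target
  )
}

count_mean_identity <- function() {
  prims <- default_primitives()
  prims[vapply(prims, `[[`, character(1), "name") %in%
          c("count", "mean", "identity")]
}

# ---- naive join/group-by oracles ----------------------------------------
# Straight-line re-derivations of the expected feature matrix for fixed
# schema shapes (depth 2, primitives {count, mean, identity}), written with
# plain merge()/tapply() rather than the package's recursion.

oracle_group <- function(values, keys, parent_keys, fn, empty) {
  out <- vapply(parent_keys, function(k) {
    v <- values[keys == k]
    if (length(v) == 0) empty else fn(v)
  }, numeric(1))
  unname(out)
}

# Target = children of a parent/child pair.
oracle_child_target <- function(tp) {
  p <- tp$parents
  p$`COUNT(children)` <- oracle_group(rep(1, nrow(tp$children)),
                                      tp$children$fk, p$pk, length, 0)
  p$`MEAN(children.c1)` <- oracle_group(tp$children$c1, tp$children$fk,
                                        p$pk, mean, NA_real_)
  i <- match(tp$children$fk, p$pk)
  data.frame(ck = tp$children$ck, c1 = tp$children$c1,
             parents.p1 = p$p1[i],
             `parents.COUNT(children)` = p$`COUNT(children)`[i],
             `parents.MEAN(children.c1)` = p$`MEAN(children.c1)`[i],
             check.names = FALSE)
}

# Target = parents of a parent/child pair.
oracle_parent_target <- function(tp) {
  data.frame(pk = tp$parents$pk, p1 = tp$parents$p1,
             `COUNT(children)` = oracle_group(rep(1, nrow(tp$children)),
                                              tp$children$fk, tp$parents$pk,
                                              length, 0),
             `MEAN(children.c1)` = oracle_group(tp$children$c1,
                                                tp$children$fk,
                                                tp$parents$pk, mean,
                                                NA_real_),
             check.names = FALSE)
}

# Three-table chain A <- B <- C with target C (depth 2: no recursion into A,
# so B only contributes A.a1 as a direct feature).
toy_chain <- function(seed = 1) {
  set.seed(seed)
  a <- data.frame(ak = paste0("A", 1:3), a1 = round(stats::rnorm(3), 3))
  b <- data.frame(bk = paste0("B", 1:4),
                  afk = sample(a$ak, 4, replace = TRUE),
                  b1 = round(stats::rnorm(4), 3))
  cc <- data.frame(ck = paste0("C", 1:8),
                   bfk = sample(b$bk, 8, replace = TRUE),
                   c1 = round(stats::rnorm(8), 3))
  list(a = a, b = b, cc = cc)
}

es_chain <- function(tc, target = "fractions") {
  entity_set(
    tables = list(entity_table(tc$a, "patients", "ak"),
                  entity_table(tc$b, "plans", "bk"),
                  entity_table(tc$cc, "fractions", "ck")),
    relationships = list(
      list(child = "plans", child_column = "afk",
           parent = "patients", parent_key = "ak"),
      list(child = "fractions", child_column = "bfk",
           parent = "plans", parent_key = "bk")),
    target = target
  )
}

oracle_chain_target_c <- function(tc) {
  b <- tc$b
  b$`COUNT(fractions)` <- oracle_group(rep(1, nrow(tc$cc)), tc$cc$bfk,
                                       b$bk, length, 0)
  b$`MEAN(fractions.c1)` <- oracle_group(tc$cc$c1, tc$cc$bfk, b$bk,
                                         mean, NA_real_)
  b$`patients.a1` <- tc$a$a1[match(b$afk, tc$a$ak)]
  i <- match(tc$cc$bfk, b$bk)
  data.frame(ck = tc$cc$ck, c1 = tc$cc$c1,
             plans.b1 = b$b1[i],
             `plans.COUNT(fractions)` = b$`COUNT(fractions)`[i],
             `plans.MEAN(fractions.c1)` = b$`MEAN(fractions.c1)`[i],
             `plans.patients.a1` = b$`patients.a1`[i],
             check.names = FALSE)
}

# Compare a feature matrix to an oracle data frame, names included.
expect_fm_equal <- function(fm, oracle) {
  plain <- as.data.frame(fm)
  attr(plain, "provenance") <- NULL
  attr(plain, "log") <- NULL
  rownames(plain) <- rownames(oracle) <- NULL
  testthat::expect_identical(names(plain), names(oracle))
  testthat::expect_equal(plain, oracle)
}

# ---- independent K-fold CV oracle ---------------------------------------
# Explicit fold loop using stats::lm, sharing only the fold labels with the
# implementation under test.

oracle_cv_mae_lm <- function(x, y, folds) {
  k <- max(folds)
  losses <- vapply(seq_len(k), function(i) {
    df <- as.data.frame(x)
    names(df) <- paste0("Z", seq_along(df))
    df$.y <- y
    fit <- stats::lm(.y ~ ., data = df[folds != i, , drop = FALSE])
    pred <- stats::predict(fit, newdata = df[folds == i, , drop = FALSE])
    mean(abs(pred - y[folds == i]))
  }, numeric(1))
  mean(losses)
}

# ---- scheduling fixtures -------------------------------------------------

random_appointments <- function(n, min_s, max_s, seed) {
  set.seed(seed)
  data.frame(patient_id = sprintf("P%03d", seq_len(n)),
             duration_s = sample(seq(min_s, max_s), n, replace = TRUE),
             stringsAsFactors = FALSE)
}

# A degenerate cohort config: every categorical level fixed, no noise.
fixed_cohort_config <- function(n = 25, seed = 3, noise_sd = 0) {
  one_level <- function(levels, pick) {
    stats::setNames(as.numeric(levels == pick), levels)
  }
  dom <- cohort_domains()
  cohort_config(
    n, seed = seed,
    category_probabilities = list(
      treatment_site = one_level(dom$site, "thorax"),
      irradiation_technology = one_level(dom$irradiation_technology, "3D-CRT"),
      six_dimension_table = 1, vacuum_cushion = 0, metallic_implant = 0,
      igrt = 1),
    duration_model = duration_model(noise_sd = noise_sd),
    first_fraction_rate = 0,
    control_point_ranges = list("2D" = c(0L, 50L), "3D-CRT" = c(40L, 40L),
                                "IMRT" = c(80L, 300L), "VMAT" = c(60L, 200L),
                                "SBRT" = c(80L, 360L))
  )
}
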