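#' Diagnostic task specification
#'
#' Three binary tasks are studied: Task 1 separates Parkinson's Disease
#' from healthy controls (PD vs CG), Task 2 all movement disorders from
#' controls (PD+DD vs CG), Task 3 Parkinson's Disease from the diverse
#' movement disorders (PD vs DD). The positive class is the disease group
#' (PD for Tasks 1 and 3, PD+DD for Task 2).
#'
#' @param name `"Task1"`, `"Task2"` or `"Task3"` (also accepts 1, 2, 3).
#' @return Object of class `task_spec` with `name`, `positive`, `negative`.
#' @export
task_spec <- function(name) {
  if (is.numeric(name)) name <- paste0("Task", name)
  name <- match.arg(name, c("Task1", "Task2", "Task3"))
  spec <- switch(name,
    Task1 = list(positive = "PD", negative = "CG"),
    Task2 = list(positive = c("PD", "DD"), negative = "CG"),
    Task3 = list(positive = "PD", negative = "DD")
  )
  structure(c(list(name = name), spec), class = "task_spec")
}

#' Bonferroni-corrected significance threshold
#'
#' With 14 features (QYes + 13 motor features) tested, p-values below
#' `alpha / c` = 0.05/14 ~ 0.0036 are considered significant.
#'
#' @param alpha Family-wise level, default 0.05.
#' @param c Number of tests, default 14.
#' @return The corrected per-test threshold `alpha / c`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, c = 14) {
  if (c < 1) stop("domain error: test count must be >= 1")
  alpha / c
}

#' Significance annotation ladder
#'
#' Boxplot annotation labels after Bonferroni correction with `c` tests:
#' `ns` if p > 0.05/c, `*` if p <= 0.05/c, `**` if p <= 0.01/c, `***` if
#' p <= 0.001/c, `****` if p <= 0.0001/c.
#'
#' @param p P-value(s) in (0, 1].
#' @param c Number of corrected tests, default 14.
#' @return Character vector of labels.
#' @export
significance_annotation <- function(p, c = 14) {
  vapply(p, function(pv) {
    if (is.na(pv)) return(NA_character_)
    if (pv <= 0.0001 / c) "****"
    else if (pv <= 0.001 / c) "***"
    else if (pv <= 0.01 / c) "**"
    else if (pv <= 0.05 / c) "*"
    else "ns"
  }, character(1))
}

#' Spearman correlations of features against task labels and age
#'
#' Rank correlation of every feature against every target column. Binary
#' task membership is encoded 0/1 (positive class 1), so the coefficient is
#' a rank-biserial-equivalent association with the task. Constant features
#' have no defined rank correlation and are reported as `NA` with a
#' warning.
#'
#' @param features Feature table from [extract_features()] (or any data
#'   frame of numeric feature columns).
#' @param targets Data frame of numeric target columns (task labels 0/1,
#'   age, ...), same row order as `features`.
#' @param feature_cols Feature column names; defaults to [feature_names()]
#'   intersected with `features`.
#' @param c Bonferroni test count for the significance flag, default 14.
#' @return Tibble with columns feature, target, rho, p_value, significant,
#'   annotation.
#' @export
spearman_table <- function(features, targets,
                           feature_cols = intersect(feature_names(),
                                                    names(features)),
                           c = 14) {
  thr <- bonferroni_threshold(c = c)
  grid <- expand.grid(feature = feature_cols, target = names(targets),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    x <- features[[grid$feature[i]]]
    y <- targets[[grid$target[i]]]
    keep <- stats::complete.cases(x, y)
    if (length(unique(x[keep])) < 2L || length(unique(y[keep])) < 2L) {
      warning(sprintf("constant input for %s vs %s; correlation undefined",
                      grid$feature[i], grid$target[i]))
      rho <- NA_real_; pv <- NA_real_
    } else {
      ct <- suppressWarnings(
        cor.test(x[keep], y[keep], method = "spearman", exact = FALSE))
      rho <- unname(ct$estimate); pv <- ct$p.value
    }
    tibble::tibble(feature = grid$feature[i], target = grid$target[i],
                   rho = rho, p_value = pv,
                   significant = !is.na(pv) & pv < thr,
                   annotation = significance_annotation(pv, c))
  })
  do.call(rbind, rows)
}

# two-sided Mann-Whitney U with the branch policy used throughout:
# exact enumeration when both groups are <= `exact_max` and tie-free,
# tie- and continuity-corrected normal approximation otherwise (at zero
# z the continuity correction vanishes, so identical groups give p = 1)
mann_whitney_u <- function(x, y, exact_max = 12) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0L || n2 == 0L) stop("validation error: empty group")
  r <- rank(c(x, y))
  u <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(c(x, y)) > 0L
  if (!ties && n1 <= exact_max && n2 <= exact_max) {
    p <- wilcox.test(x, y, exact = TRUE)$p.value
    branch <- "exact"
  } else {
    if (length(unique(c(x, y))) == 1L) {
      p <- 1  # all observations tied: no evidence of separation
    } else {
      p <- suppressWarnings(
        wilcox.test(x, y, exact = FALSE, correct = TRUE)$p.value)
      p <- min(1, p)
    }
    branch <- "approx"
  }
  list(U = u, p_value = p, branch = branch)
}

#' Mann–Whitney U group comparisons for one task
#'
#' Two-sided U test of every feature between the task's positive and
#' negative groups, with Bonferroni-corrected significance flags and
#' annotation labels. Exact enumeration of the U null distribution is used
#' when both groups have at most 12 tie-free observations; otherwise the
#' tie-corrected normal approximation.
#'
#' @param features Feature table including a `group` column.
#' @param task A [task_spec()] (or its name).
#' @param feature_cols Feature columns to test; default [feature_names()].
#' @param c Bonferroni test count, default 14.
#' @return Tibble with columns feature, U, p_value, significant, annotation,
#'   branch.
#' @export
mann_whitney_tests <- function(features, task,
                               feature_cols = intersect(feature_names(),
                                                        names(features)),
                               c = 14) {
  if (!inherits(task, "task_spec")) task <- task_spec(task)
  pos <- features$group %in% task$positive
  neg <- features$group %in% task$negative
  if (sum(pos) == 0L || sum(neg) == 0L) {
    stop(sprintf("validation error: empty group for %s", task$name))
  }
  thr <- bonferroni_threshold(c = c)
  rows <- lapply(feature_cols, function(f) {
    res <- mann_whitney_u(features[[f]][pos], features[[f]][neg])
    tibble::tibble(feature = f, task = task$name, U = res$U,
                   p_value = res$p_value,
                   significant = res$p_value < thr,
                   annotation = significance_annotation(res$p_value, c),
                   branch = res$branch)
  })
  do.call(rbind, rows)
}

#' Binary task labels for a feature table
#'
#' @param features Feature table with a `group` column.
#' @param task A [task_spec()] or name.
#' @return Integer 0/1 vector (NA for rows outside the task's groups).
#' @export
task_labels <- function(features, task) {
  if (!inherits(task, "task_spec")) task <- task_spec(task)
  ifelse(features$group %in% task$positive, 1L,
         ifelse(features$group %in% task$negative, 0L, NA_integer_))
}
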