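# Clinical correlations, group comparisons and multiplicity control.

# Score-type registry: ordinal scores must be analysed with Spearman's rank
# correlation (H&Y stage is the canonical case), continuous ones with
# Pearson's. Users can register additional scores.
.score_registry <- new.env(parent = emptyenv())
assign("types", c(hy_stage = "ordinal", np3_total = "continuous",
                  bis_score = "continuous", barratt = "continuous",
                  conscientiousness = "continuous"),
       envir = .score_registry)

#' Register a clinical score's measurement type
#'
#' The type decides the correlation method under `method = "auto"` and makes
#' Pearson correlation an error for ordinal scores.
#'
#' @param name Score name.
#' @param type `"continuous"` or `"ordinal"`.
#' @return The updated registry, invisibly.
#' @export
register_score <- function(name, type = c("continuous", "ordinal")) {
  type <- match.arg(type)
  types <- get("types", envir = .score_registry)
  types[[name]] <- type
  assign("types", types, envir = .score_registry)
  invisible(types)
}

#' Look up a score's registered type
#'
#' @param name Score name.
#' @return `"continuous"`, `"ordinal"`, or `NA` if unregistered.
#' @export
score_type <- function(name) {
  types <- get("types", envir = .score_registry)
  if (name %in% names(types)) types[[name]] else NA_character_
}

#' Correlate one connection's TPDC values with a clinical score
#'
#' Pearson or Spearman correlation with a two-sided p-value. Under
#' `method = "auto"` the registered score type decides (ordinal scores such
#' as the H&Y stage use Spearman); requesting Pearson for a registered
#' ordinal score is an error.
#'
#' @param values Per-subject TPDC values for one connection.
#' @param scores Per-subject clinical score values (paired with `values`).
#' @param method `"auto"`, `"pearson"` or `"spearman"`.
#' @param score_name Score name (used for the registry lookup and reporting).
#' @param connection Optional `c(source, target)` pair for reporting.
#' @return An object of class `"correlation_result"` with fields `r`, `p`,
#'   `method`, `n`, `score_name`, `connection`, `p_adjusted` (NA until
#'   [bonferroni_adjust()]).
#' @export
correlate <- function(values, scores, method = c("auto", "pearson", "spearman"),
                      score_name = "score", connection = NULL) {
  method <- match.arg(method)
  stopifnot(length(values) == length(scores))
  if (length(values) < 5) stop("need at least 5 paired observations", call. = FALSE)
  if (any(!is.finite(values)) || any(!is.finite(scores)))
    stop("values and scores must be finite", call. = FALSE)
  if (var(values) == 0 || var(scores) == 0)
    stop("zero variance in values or scores", call. = FALSE)
  stype <- score_type(score_name)
  if (method == "auto") {
    method <- if (identical(stype, "ordinal")) "spearman" else "pearson"
  } else if (method == "pearson" && identical(stype, "ordinal")) {
    stop(sprintf("score '%s' is registered as ordinal; use Spearman's rank correlation",
                 score_name), call. = FALSE)
  }
  ct <- suppressWarnings(cor.test(values, scores, method = method,
                                  alternative = "two.sided", exact = FALSE))
  structure(list(connection = connection, score_name = score_name,
                 method = method, r = unname(ct$estimate), p = ct$p.value,
                 n = length(values), p_adjusted = NA_real_),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  conn <- if (is.null(x$connection)) "" else
    sprintf(" [%s -> %s]", x$connection[1], x$connection[2])
  cat(sprintf("<correlation>%s %s vs '%s': r = %.4f, p = %.4g (n = %d)%s\n",
              conn, x$method, x$score_name, x$r, x$p, x$n,
              if (is.na(x$p_adjusted)) "" else
                sprintf(", adjusted p = %.4g", x$p_adjusted)))
  invisible(x)
}

#' Bonferroni correction over an explicit test family
#'
#' Each p-value is multiplied by the family size and capped at 1.
#'
#' @param p Numeric vector of raw p-values, or a list of
#'   `correlation_result`s (whose `p_adjusted` fields are then filled).
#' @return Adjusted p-values (or the updated result list).
#' @export
bonferroni_adjust <- function(p) {
  if (is.list(p) && all(vapply(p, inherits, logical(1), "correlation_result"))) {
    raw <- vapply(p, function(r) r$p, numeric(1))
    adj <- bonferroni_adjust(raw)
    for (i in seq_along(p)) p[[i]]$p_adjusted <- adj[i]
    return(p)
  }
  if (!is.numeric(p) || length(p) == 0)
    stop("p must be a nonempty numeric vector", call. = FALSE)
  if (any(p < 0 | p > 1)) stop("p-values must lie in [0, 1]", call. = FALSE)
  p.adjust(p, method = "bonferroni")
}

#' Compare one connection's TPDC values between two groups
#'
#' Ordinary least-squares regression of the value on a 0/1 group indicator:
#' the slope is the group mean difference, the two-sided t-test p-value
#' equals the classic equal-variance two-sample t-test, and r-squared is the
#' squared point-biserial correlation.
#'
#' @param values_a,values_b Per-subject TPDC values in groups A and B (>= 3
#'   each).
#' @param groups Optional `c(label_a, label_b)`.
#' @param connection Optional `c(source, target)` pair for reporting.
#' @return An object of class `"group_comparison"` with `slope`, `p`,
#'   `r_squared`, `n_a`, `n_b`.
#' @export
compare_groups <- function(values_a, values_b, groups = c("A", "B"),
                           connection = NULL) {
  if (length(values_a) < 3 || length(values_b) < 3)
    stop("each group needs at least 3 subjects", call. = FALSE)
  y <- c(values_a, values_b)
  g <- c(rep(0, length(values_a)), rep(1, length(values_b)))
  if (var(y) == 0) stop("zero pooled variance", call. = FALSE)
  n <- length(y)
  slope <- mean(values_b) - mean(values_a)
  r <- suppressWarnings(stats::cor(y, g))
  r2 <- r^2
  tval <- r * sqrt((n - 2) / (1 - r2))
  p <- 2 * pt(-abs(tval), df = n - 2)
  structure(list(connection = connection, groups = groups, slope = slope,
                 p = p, r_squared = r2,
                 n_a = length(values_a), n_b = length(values_b)),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  conn <- if (is.null(x$connection)) "" else
    sprintf(" [%s -> %s]", x$connection[1], x$connection[2])
  cat(sprintf("<group_comparison>%s %s (n=%d) vs %s (n=%d): slope = %.4f, p = %.4g, r2 = %.3f\n",
              conn, x$groups[1], x$n_a, x$groups[2], x$n_b,
              x$slope, x$p, x$r_squared))
  invisible(x)
}

#' Friedman test of one connection's values across matched groups
#'
#' Non-parametric comparison of k >= 3 groups on n matched subjects (matched
#' by row position): Friedman's chi-square over within-row ranks.
#'
#' @param matched_samples Numeric n x k matrix: rows = matched subjects,
#'   columns = groups.
#' @return List with `statistic`, `p`, `df`, `n`, `k`.
#' @export
friedman_across_groups <- function(matched_samples) {
  m <- as.matrix(matched_samples)
  if (!is.numeric(m)) stop("matched_samples must be numeric", call. = FALSE)
  if (ncol(m) < 3) stop("need at least 3 groups", call. = FALSE)
  if (any(!is.finite(m)))
    stop("groups must have equal n with no missing values", call. = FALSE)
  ft <- friedman.test(m)
  stat <- unname(ft$statistic)
  pval <- ft$p.value
  if (!is.finite(stat)) {
    # fully tied rows (e.g. identical groups): no evidence of any difference
    stat <- 0
    pval <- 1
  }
  list(statistic = stat, p = pval,
       df = unname(ft$parameter), n = nrow(m), k = ncol(m))
}
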