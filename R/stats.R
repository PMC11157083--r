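# Statistical layer: the replicate-averaging hierarchy (technical ->
# biological -> group) plus the standard tests used downstream. The tests
# delegate to base R; the hierarchy is owned here because it is the part
# that is easy to get wrong.

#' Hierarchical replicate averaging
#'
#' Averages measurements technical-first: values are averaged within each
#' (biological replicate, technical replicate), those means are averaged per
#' biological replicate, and the group mean +/- SEM is computed over the
#' biological-replicate means. A biological replicate with many technical
#' values therefore counts exactly once at group level. SEM is `NA`
#' (flagged) for groups with a single biological replicate.
#'
#' @param data Data.frame with columns `value`, `bio` (biological replicate
#'   id), `group`, and optionally `tech` (technical replicate id; if absent
#'   all values of a biological replicate are pooled directly).
#' @return List with `replicate_means` (one row per group x bio) and
#'   `group_stats` (`group`, `mean`, `sem`, `n_bio`).
#' @export
replicate_average <- function(data) {
  data <- as.data.frame(data)
  if (!all(c("value", "bio", "group") %in% names(data)))
    stop("data needs columns value, bio, group")
  if (nrow(data) == 0L) stop("empty group data")
  if (!"tech" %in% names(data)) data$tech <- 1L
  tech_means <- stats::aggregate(value ~ group + bio + tech, data, mean)
  bio_means <- stats::aggregate(value ~ group + bio, tech_means, mean)
  grp <- do.call(rbind, lapply(split(bio_means, bio_means$group), function(g) {
    n <- nrow(g)
    data.frame(group = g$group[1], mean = mean(g$value),
               sem = if (n > 1L) stats::sd(g$value) / sqrt(n) else NA_real_,
               n_bio = n)
  }))
  rownames(grp) <- NULL
  list(replicate_means = bio_means, group_stats = grp)
}

#' Pearson correlation matrix of features
#'
#' @param table Numeric data.frame/matrix, observations in rows, features in
#'   columns (>= 3 observations).
#' @return Symmetric correlation matrix with unit diagonal; zero-variance
#'   features yield `NA` entries with a warning.
#' @export
pearson_matrix <- function(table) {
  m <- as.matrix(table)
  if (nrow(m) < 3L) stop("need at least 3 observations")
  sds <- apply(m, 2L, stats::sd)
  if (any(sds == 0))
    warning("zero-variance feature(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "),
            "; correlations flagged NA")
  suppressWarnings(r <- stats::cor(m, method = "pearson"))
  diag(r) <- ifelse(sds == 0, NA_real_, 1)
  r
}

#' One-way ANOVA with post-hoc Tukey HSD
#'
#' Standard F test across groups followed by Tukey's honestly-significant-
#' difference pairwise comparisons via the studentized range distribution.
#' The conventional decision rule is p < 0.05.
#'
#' @param values Numeric vector.
#' @param groups Factor/character of the same length (>= 2 groups with >= 2
#'   values each).
#' @return List with `F`, `df` (c(between, within)), `p`, and `tukey`
#'   (data.frame: `comparison`, `diff`, `lwr`, `upr`, `p_adj`).
#' @export
one_way_anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (any(table(groups) < 2L)) stop("each group needs at least 2 values")
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  list(F = s[["F value"]][1],
       df = c(between = s[["Df"]][1], within = s[["Df"]][2]),
       p = s[["Pr(>F)"]][1],
       tukey = data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                          lwr = tk[, "lwr"], upr = tk[, "upr"],
                          p_adj = tk[, "p adj"], row.names = NULL))
}

#' Welch's t-test
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom,
#' as used for wild-type vs mutant comparisons.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return List with `t`, `df`, `p`.
#' @export
welch_t <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L) stop("need >= 2 values per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(list(t = 0, df = NA_real_, p = 1))
    stop("degenerate input: both groups constant with different means")
  }
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value)
}
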