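# Community-signal correlation analysis: Pearson correlations between taxon
# abundance and AHL concentration time series, pooled FDR correction,
# positive/negative/neutral classification, complete-linkage clustering, and
# floccular-versus-granular stage comparison.

as_series_matrix <- function(data, row_col, value_col) {
  data <- as_tibble(data)
  assert_columns(data, c(row_col, "timepoint", value_col), "series data")
  wide <- data |>
    tidyr::pivot_wider(id_cols = dplyr::all_of(row_col),
                       names_from = "timepoint",
                       values_from = dplyr::all_of(value_col))
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide[[row_col]]
  if (anyNA(m)) abort("taxa and AHL series must share a complete timepoint axis")
  m
}

#' Pearson correlation matrix between taxa and AHL time series
#'
#' Computes the product-moment correlation between every taxon-abundance row
#' and every AHL-concentration row over the shared timepoints, with
#' two-sided p-values from the t distribution on `n - 2` degrees of freedom.
#' Constant rows (zero variance) give `NA` correlation and are later classed
#' neutral.
#'
#' @param taxa Long tibble with `taxon`, `timepoint`, `abundance`, or a
#'   taxa-by-timepoint matrix.
#' @param ahls Long tibble with `ahl`, `timepoint`, `concentration`, or an
#'   AHL-by-timepoint matrix.
#' @return A list with matrices `r` and `p_raw` (taxa in rows, AHLs in
#'   columns) and `n_timepoints`.
#' @export
pearson_matrix <- function(taxa, ahls) {
  tm <- if (is.matrix(taxa)) taxa else as_series_matrix(taxa, "taxon", "abundance")
  am <- if (is.matrix(ahls)) ahls else as_series_matrix(ahls, "ahl", "concentration")
  if (ncol(tm) != ncol(am)) abort("taxa and AHL series differ in timepoints")
  n <- ncol(tm)
  if (n < 3) abort("need >= 3 shared timepoints for correlation")
  const_t <- apply(tm, 1, sd) == 0
  const_a <- apply(am, 1, sd) == 0
  if (any(const_t) || any(const_a)) {
    inform(sprintf("%d constant taxon row(s) and %d constant AHL row(s): correlation undefined, classed neutral",
                   sum(const_t), sum(const_a)))
  }
  r <- suppressWarnings(cor(t(tm), t(am)))
  r[const_t, ] <- NA_real_
  r[, const_a] <- NA_real_
  tstat <- r * sqrt((n - 2) / pmax(1e-300, 1 - r^2))
  p <- 2 * pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[which(abs(r) >= 1)] <- 0  # perfectly collinear pairs
  list(r = r, p_raw = p, n_timepoints = n)
}

#' Benjamini-Hochberg FDR adjustment over a p-value matrix
#'
#' Applies the step-up false-discovery-rate correction pooled over all
#' taxa-by-AHL tests: sorted ascending,
#' `q_(i) = min_{j >= i} p_(j) * m / j`, capped at 1.
#'
#' @param p_raw Matrix (or vector) of raw p-values in `[0, 1]`; `NA`s pass
#'   through.
#' @return Object of the same shape with q-values.
#' @export
fdr_adjust <- function(p_raw) {
  q <- p.adjust(as.vector(p_raw), method = "BH")
  if (is.matrix(p_raw)) {
    q <- matrix(q, nrow(p_raw), ncol(p_raw), dimnames = dimnames(p_raw))
  }
  q
}

#' Classify taxon-AHL relationships as positive, negative or neutral
#'
#' A pair is *positive* iff `r > r_min` and `q < alpha`, *negative* iff
#' `r < -r_min` and `q < alpha`, and *neutral* otherwise (including
#' undefined correlations). Significance stars follow the usual convention:
#' `*` q < 0.05, `**` q < 0.01, `***` q < 0.001.
#'
#' @param r,q Conformable correlation and q-value matrices.
#' @param alpha Significance level on the q-values (default 0.05).
#' @param r_min Minimum absolute correlation to classify (default 0).
#' @return A list with the `class` character matrix, a `stars` matrix and
#'   `summary`, a tibble of class percentages over all pairs (summing
#'   to 100).
#' @export
classify_relationships <- function(r, q, alpha = 0.05, r_min = 0) {
  stopifnot(all(dim(r) == dim(q)))
  assert_number(alpha, "alpha", lower = 0, upper = 1,
                strict_lower = TRUE, strict_upper = TRUE)
  assert_number(r_min, "r_min", lower = 0, upper = 1, strict_upper = TRUE)
  cls <- matrix("neutral", nrow(r), ncol(r), dimnames = dimnames(r))
  sig <- !is.na(r) & !is.na(q) & q < alpha
  cls[sig & r > r_min] <- "positive"
  cls[sig & r < -r_min] <- "negative"
  stars <- matrix("", nrow(r), ncol(r), dimnames = dimnames(r))
  stars[!is.na(q) & q < 0.05] <- "*"
  stars[!is.na(q) & q < 0.01] <- "**"
  stars[!is.na(q) & q < 0.001] <- "***"
  total <- length(cls)
  summary <- tibble(
    class = c("positive", "negative", "neutral"),
    n = c(sum(cls == "positive"), sum(cls == "negative"),
          sum(cls == "neutral")),
    percent = 100 * c(sum(cls == "positive"), sum(cls == "negative"),
                      sum(cls == "neutral")) / total
  )
  list(class = cls, stars = stars, summary = summary)
}

#' Correlate community member abundances with AHL concentration profiles
#'
#' End-to-end wrapper: Pearson correlation matrix, pooled BH-FDR
#' correction, and positive/negative/neutral classification.
#'
#' @inheritParams pearson_matrix
#' @inheritParams classify_relationships
#' @return A `community_correlation` object: list with `r`, `p_raw`, `q`,
#'   `class`, `stars` matrices, the class `summary` tibble, `alpha`,
#'   `r_min` and `n_timepoints`.
#' @export
correlate_community <- function(taxa, ahls, alpha = 0.05, r_min = 0) {
  pm <- pearson_matrix(taxa, ahls)
  q <- fdr_adjust(pm$p_raw)
  cl <- classify_relationships(pm$r, q, alpha = alpha, r_min = r_min)
  structure(
    list(r = pm$r, p_raw = pm$p_raw, q = q, class = cl$class,
         stars = cl$stars, summary = cl$summary, alpha = alpha,
         r_min = r_min, n_timepoints = pm$n_timepoints),
    class = "community_correlation"
  )
}

#' @export
print.community_correlation <- function(x, ...) {
  cat(sprintf("<community_correlation> %d taxa x %d AHLs over %d timepoints (alpha = %g)\n",
              nrow(x$r), ncol(x$r), x$n_timepoints, x$alpha))
  print(x$summary)
  invisible(x)
}

#' @describeIn correlate_community Long tibble with one row per taxon-AHL
#'   pair (`r`, `p_raw`, `q`, `class`, `stars`).
#' @param x A `community_correlation`.
#' @param ... Unused.
#' @method tidy community_correlation
#' @export
tidy.community_correlation <- function(x, ...) {
  grid <- tidyr::expand_grid(
    taxon = rownames(x$r) %||% as.character(seq_len(nrow(x$r))),
    ahl = colnames(x$r) %||% as.character(seq_len(ncol(x$r)))
  )
  grid |>
    mutate(
      r = as.vector(t(x$r)),
      p_raw = as.vector(t(x$p_raw)),
      q = as.vector(t(x$q)),
      class = as.vector(t(x$class)),
      stars = as.vector(t(x$stars))
    )
}

#' @describeIn correlate_community One-row summary with class percentages.
#' @method glance community_correlation
#' @export
glance.community_correlation <- function(x, ...) {
  s <- setNames(x$summary$percent, x$summary$class)
  tibble(
    n_taxa = nrow(x$r), n_ahls = ncol(x$r), n_timepoints = x$n_timepoints,
    pct_positive = s[["positive"]], pct_negative = s[["negative"]],
    pct_neutral = s[["neutral"]], alpha = x$alpha
  )
}

#' Cluster taxa by their AHL correlation profiles
#'
#' Hierarchical clustering of the taxa rows of the correlation matrix using
#' Euclidean distance and complete linkage, cut into `k` flat clusters.
#' Undefined correlations (constant rows) are imputed as 0 with a message;
#' rows that are entirely undefined can be dropped beforehand.
#'
#' @param x A `community_correlation` object or a taxa-by-AHL correlation
#'   matrix.
#' @param k Number of flat clusters to cut (default 3).
#' @return A list with the `hclust` object (`tree`), the flat `clusters`
#'   (named integer vector) and `leaf_order` (row labels in dendrogram
#'   order).
#' @export
cluster_taxa <- function(x, k = 3) {
  r <- if (inherits(x, "community_correlation")) x$r else as.matrix(x)
  if (nrow(r) < 2) abort("need >= 2 taxa rows to cluster")
  if (anyNA(r)) {
    inform("undefined correlations imputed as 0 for clustering")
    r[is.na(r)] <- 0
  }
  tree <- hclust(dist(r, method = "euclidean"), method = "complete")
  k <- min(k, nrow(r))
  labels <- rownames(r) %||% as.character(seq_len(nrow(r)))
  list(
    tree = tree,
    clusters = setNames(cutree(tree, k = k), labels),
    leaf_order = labels[tree$order]
  )
}

#' Compare the signalling profiles of two community stages
#'
#' Contrasts two stages analysed with identical settings (typically the
#' floccular and the granular sludge): the shift in class percentages and,
#' per AHL, the ratio of stage mean concentrations with a fold-change flag.
#'
#' @param floc,gran `community_correlation` objects for the two stages.
#' @param floc_ahl,gran_ahl Data frames with `ahl` and `mean_conc` (stage
#'   mean concentrations, e.g. pmol/g).
#' @param fold_threshold Flag AHLs whose ratio of stage means is at least
#'   this factor (default 3).
#' @return A list with `class_shift` (per-class percentages and delta) and
#'   `ahl_fold` (per-AHL means, `fold_change` = gran/floc, `flag`). AHLs
#'   absent from one stage get `NA` fold change.
#' @export
compare_stages <- function(floc, gran, floc_ahl, gran_ahl,
                           fold_threshold = 3) {
  stopifnot(inherits(floc, "community_correlation"),
            inherits(gran, "community_correlation"))
  if (floc$alpha != gran$alpha || floc$r_min != gran$r_min) {
    abort("stages must be analysed with identical alpha and r_min settings")
  }
  class_shift <- floc$summary |>
    select("class", floc_percent = "percent") |>
    left_join(gran$summary |> select("class", gran_percent = "percent"),
              by = "class") |>
    mutate(delta = .data$gran_percent - .data$floc_percent)

  floc_ahl <- as_tibble(floc_ahl)
  gran_ahl <- as_tibble(gran_ahl)
  assert_columns(floc_ahl, c("ahl", "mean_conc"), "floc_ahl")
  assert_columns(gran_ahl, c("ahl", "mean_conc"), "gran_ahl")
  ahl_fold <- dplyr::full_join(
    floc_ahl |> rename(floc_mean = "mean_conc"),
    gran_ahl |> rename(gran_mean = "mean_conc"),
    by = "ahl"
  ) |>
    mutate(
      fold_change = .data$gran_mean / .data$floc_mean,
      flag = !is.na(.data$fold_change) & .data$fold_change >= fold_threshold
    )
  if (anyNA(ahl_fold$fold_change)) {
    inform("AHL(s) absent from one stage: fold change undefined")
  }
  list(class_shift = class_shift, ahl_fold = ahl_fold)
}
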