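# Isolate QS/QQ phenotyping: classify each isolate as producer, quencher,
# both or neither from bioassay and residual-AHL tables, and summarise the
# category distribution and quenching spectrum of the panel.

quench_test_ahls <- c("3OC6", "3OC8", "3OC12")

#' Classify isolates as AHL producers and/or quenchers
#'
#' An isolate is called a *producer* iff at least one biosensor was activated
#' AND at least one AHL was confirmed (LC-MS/MS), i.e. `produced_ahls` is
#' non-empty. It is called a *quencher* iff, for at least one of the three
#' test AHLs (short 3OC6-HSL, medium 3OC8-HSL, long 3OC12-HSL, spiked at
#' 5 uM and incubated 2 h), the residual fraction relative to the pH-matched
#' sterile control is at most `quench_threshold`. The two flags combine into
#' the exhaustive categories `both`, `producer`, `quencher`, `neither`.
#'
#' Records whose control culture finished above pH 7.3 are rejected: AHL
#' lactonolysis at alkaline pH would mimic enzymatic quenching.
#'
#' @param data Data frame, one row per isolate, with columns `isolate_id`,
#'   biosensor flags `a136_positive`, `cv026_positive`, `jba357_positive`
#'   (logical), `produced_ahls` (comma-separated acronyms, `""` if none),
#'   residual fractions `residual_3OC6`, `residual_3OC8`, `residual_3OC12`
#'   and matching `control_3OC6`, `control_3OC8`, `control_3OC12`; optional
#'   `control_ph`.
#' @param quench_threshold Maximum residual-to-control ratio still counted
#'   as quenching, in `(0, 1)` (default 0.5, i.e. >= 50% signal reduction).
#' @return The input with added logical `is_producer`, `is_quencher`,
#'   per-AHL `quenched_3OC6/3OC8/3OC12` flags and a `category` factor.
#'   Missing control values exclude that AHL from quench evaluation with a
#'   message.
#' @export
classify_isolate <- function(data, quench_threshold = 0.5) {
  data <- as_tibble(data)
  assert_number(quench_threshold, "quench_threshold", lower = 0, upper = 1,
                strict_lower = TRUE, strict_upper = TRUE)
  biosensors <- c("a136_positive", "cv026_positive", "jba357_positive")
  assert_columns(data, c("isolate_id", biosensors, "produced_ahls",
                         paste0("residual_", quench_test_ahls),
                         paste0("control_", quench_test_ahls)), "data")
  if ("control_ph" %in% names(data) && any(data$control_ph > 7.3, na.rm = TRUE)) {
    abort("control culture(s) ended above pH 7.3; alkaline lactonolysis would confound the quench assay")
  }

  is_producer <- (data$a136_positive | data$cv026_positive |
                    data$jba357_positive) &
    !is.na(data$produced_ahls) & nchar(trimws(data$produced_ahls)) > 0

  quenched <- sapply(quench_test_ahls, function(a) {
    res <- data[[paste0("residual_", a)]]
    ctrl <- data[[paste0("control_", a)]]
    miss <- is.na(ctrl) | is.na(res)
    if (any(miss)) {
      inform(sprintf(
        "%d isolate(s) missing %s-HSL control; AHL excluded from their quench call",
        sum(miss), a))
    }
    out <- res / ctrl <= quench_threshold
    out[miss] <- FALSE
    out
  })
  if (is.null(dim(quenched))) quenched <- matrix(quenched, nrow = nrow(data))
  is_quencher <- rowSums(quenched) > 0

  data |>
    mutate(
      is_producer = is_producer,
      is_quencher = is_quencher,
      quenched_3OC6 = quenched[, 1],
      quenched_3OC8 = quenched[, 2],
      quenched_3OC12 = quenched[, 3],
      category = dplyr::case_when(
        is_producer & is_quencher ~ "both",
        is_producer ~ "producer",
        is_quencher ~ "quencher",
        TRUE ~ "neither"
      )
    )
}

#' Category arithmetic on producer/quencher percentages
#'
#' Given the percentage of isolates with any production activity, any
#' quenching activity, and both, computes the inclusion-exclusion
#' complement: `either = producer_any + quencher_any - both` and
#' `neither = 100 - either`.
#'
#' @param producer_any,quencher_any,both Percentages over the panel.
#' @return A one-row tibble with all five percentages.
#' @examples
#' category_percentages(10, 58.1, 4.8)  # neither = 36.7
#' @export
category_percentages <- function(producer_any, quencher_any, both) {
  either <- producer_any + quencher_any - both
  tibble(
    producer_any = producer_any, quencher_any = quencher_any, both = both,
    either = either, neither = 100 - either
  )
}

#' Summarise the QS/QQ category distribution of a panel
#'
#' @param phenotypes Output of [classify_isolate()].
#' @return A one-row tibble with `n` and the percentages `producer_any`
#'   (producers including dual-activity isolates), `quencher_any`, `both`,
#'   `either` and `neither`, satisfying
#'   `either = producer_any + quencher_any - both = 100 - neither`.
#' @export
summarize_categories <- function(phenotypes) {
  assert_columns(phenotypes, c("is_producer", "is_quencher"), "phenotypes")
  n <- nrow(phenotypes)
  if (n == 0) abort("`phenotypes` must contain >= 1 isolate")
  pct <- function(x) 100 * sum(x) / n
  category_percentages(
    producer_any = pct(phenotypes$is_producer),
    quencher_any = pct(phenotypes$is_quencher),
    both = pct(phenotypes$is_producer & phenotypes$is_quencher)
  ) |>
    mutate(n = n, .before = 1)
}

#' Summarise the quenching spectrum of the quencher subset
#'
#' Among isolates with quenching activity, reports the percentage degrading
#' the long-chain test AHL (3OC12-HSL), the percentage degrading only long
#' chains, and the percentage degrading long chains plus at least one short-
#' or medium-chain AHL (3OC6-HSL or 3OC8-HSL).
#'
#' @param phenotypes Output of [classify_isolate()].
#' @return A one-row tibble with `n_quenchers`, `degrades_long`,
#'   `long_only` and `long_plus_short_or_medium` percentages.
#' @export
quench_spectrum <- function(phenotypes) {
  assert_columns(phenotypes,
                 c("is_quencher", "quenched_3OC6", "quenched_3OC8",
                   "quenched_3OC12"), "phenotypes")
  q <- phenotypes |> filter(.data$is_quencher)
  if (nrow(q) == 0) abort("no quenchers in `phenotypes`")
  sm <- q$quenched_3OC6 | q$quenched_3OC8
  tibble(
    n_quenchers = nrow(q),
    degrades_long = 100 * mean(q$quenched_3OC12),
    long_only = 100 * mean(q$quenched_3OC12 & !sm),
    long_plus_short_or_medium = 100 * mean(q$quenched_3OC12 & sm)
  )
}
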