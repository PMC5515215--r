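# Fast tag-based community profiling: scan each read with the degenerate V6
# primer, take the 33 nt downstream as the taxon tag, filter artefacts, and
# assemble per-sample abundance tables.

#' Find all matches of a degenerate IUPAC primer in a DNA sequence
#'
#' Exact (0-mismatch) matching where each primer position accepts the IUPAC
#' expansion of its code. An `N` in the read is treated as an ambiguous base,
#' not a wildcard: it matches only primer code `N`.
#'
#' @param sequence A single DNA string over `A,C,G,T,N`.
#' @param primer IUPAC primer string, default [v6_primer()].
#' @return Integer vector of 1-based match start positions, ascending;
#'   overlapping matches are all reported. A sequence shorter than the primer
#'   gives `integer(0)`.
#' @examples
#' match_degenerate("AAAACGACAGCCATGCATCACCTGGG")
#' @export
match_degenerate <- function(sequence, primer = v6_primer()) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  if (!is_valid_iupac(primer)) abort("`primer` is not a valid IUPAC string")
  sequence <- toupper(sequence)
  if (!is_valid_dna(sequence, allow_n = TRUE)) {
    abort("`sequence` must be a DNA string over A,C,G,T,N")
  }
  if (nchar(sequence) < nchar(primer)) return(integer(0))
  # Each IUPAC code becomes a character class; primer N additionally accepts
  # a read N. Lookahead makes overlapping matches visible.
  iupac <- iupac_table()
  classes <- vapply(strsplit(primer, "")[[1]], function(ch) {
    opts <- iupac[[ch]]
    if (ch == "N") opts <- c(opts, "N")
    if (length(opts) == 1) opts else paste0("[", paste(opts, collapse = ""), "]")
  }, character(1), USE.NAMES = FALSE)
  pattern <- paste0("(?=", paste(classes, collapse = ""), ")")
  hits <- gregexpr(pattern, sequence, perl = TRUE)[[1]]
  if (hits[1] == -1) integer(0) else as.integer(hits)
}

#' Extract V6 tags from sequencing reads
#'
#' Scans each read with the degenerate primer and records the `tag_length`
#' nucleotides immediately downstream of every match as a tag occurrence,
#' attributed to the read's full sequence (its "read type"). Matches with
#' fewer than `tag_length` nt remaining yield nothing. Scanning is on the
#' given strand; set `scan_revcomp = TRUE` to additionally scan the reverse
#' complement of each read.
#'
#' @param reads Data frame with columns `read_id` and `sequence`.
#' @param primer IUPAC primer string.
#' @param tag_length Tag length in nt (default 33).
#' @param scan_revcomp Also scan reverse complements (default `FALSE`).
#' @return A tibble of aggregated tag support with one row per
#'   (tag, read type): `tag_sequence`, `read_type` (full read sequence) and
#'   `type_count`. Tags containing `N` are dropped.
#' @export
extract_v6_tags <- function(reads, primer = v6_primer(), tag_length = 33,
                            scan_revcomp = FALSE) {
  reads <- as_tibble(reads)
  if (nrow(reads) == 0) abort("`reads` must be non-empty")
  assert_columns(reads, c("read_id", "sequence"), "reads")

  scan_one <- function(seqs) {
    plen <- nchar(primer)
    out <- purrr::map(seqs, function(s) {
      starts <- match_degenerate(s, primer)
      if (length(starts) == 0) return(character(0))
      tag_start <- starts + plen
      ok <- tag_start + tag_length - 1 <= nchar(s)
      if (!any(ok)) return(character(0))
      substring(s, tag_start[ok], tag_start[ok] + tag_length - 1)
    })
    out
  }

  seqs <- toupper(reads$sequence)
  tag_lists <- scan_one(seqs)
  if (scan_revcomp) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(seqs)))
    tag_lists <- purrr::map2(tag_lists, scan_one(rc), c)
  }
  n_per_read <- lengths(tag_lists)
  if (sum(n_per_read) == 0) {
    return(tibble(tag_sequence = character(0), read_type = character(0),
                  type_count = integer(0)))
  }
  occ <- tibble(
    tag_sequence = unlist(tag_lists, use.names = FALSE),
    read_type = rep(seqs, n_per_read)
  )
  occ |>
    filter(!stringr::str_detect(.data$tag_sequence, "N")) |>
    count(.data$tag_sequence, .data$read_type, name = "type_count") |>
    arrange(.data$tag_sequence, .data$read_type)
}

#' Summarise per-tag read support
#'
#' @param raw_tags Output of [extract_v6_tags()].
#' @return A tibble per tag: `tag_sequence`, `total_reads`, `n_read_types`,
#'   `max_type_fraction`.
#' @export
tag_support <- function(raw_tags) {
  assert_columns(raw_tags, c("tag_sequence", "read_type", "type_count"),
                 "raw_tags")
  raw_tags |>
    group_by(.data$tag_sequence) |>
    summarise(
      total_reads = sum(.data$type_count),
      n_read_types = dplyr::n(),
      max_type_fraction = max(.data$type_count) / sum(.data$type_count),
      .groups = "drop"
    )
}

#' Apply the two literal tag filters
#'
#' A tag is kept iff it is observed in at least `min_reads` reads in total
#' AND no single read type (distinct full-read sequence) accounts for
#' `max_type_fraction` or more of the reads covering it. The first rule
#' removes sequencing-error-derived tags; the second removes artefacts where
#' identical duplicated reads were generated from single templates.
#'
#' Note a consequence of applying both rules literally: a tag covered by
#' exactly two reads is always removed (two identical reads are one type at
#' 100%; two distinct reads are each a type at exactly 50%), so the
#' effective minimum viable coverage is three distinct reads.
#'
#' @param raw_tags Output of [extract_v6_tags()].
#' @param min_reads Minimum total covering reads (default 2).
#' @param max_type_fraction Removal threshold on the largest read-type share
#'   (default 0.5); a tag is removed when the share is `>=` this value.
#' @param keep_all Return all tags with a `kept`/`reason` report instead of
#'   only the survivors.
#' @return A tibble as from [tag_support()] restricted to kept tags, or with
#'   `kept` and `reason` columns when `keep_all = TRUE`.
#' @export
filter_tags <- function(raw_tags, min_reads = 2, max_type_fraction = 0.5,
                        keep_all = FALSE) {
  support <- tag_support(raw_tags)
  report <- support |>
    mutate(
      kept = .data$total_reads >= .env$min_reads &
        .data$max_type_fraction < .env$max_type_fraction,
      reason = dplyr::case_when(
        .data$total_reads < .env$min_reads ~
          sprintf("fewer than %d covering reads", min_reads),
        .data$max_type_fraction >= .env$max_type_fraction ~
          sprintf("single read type >= %d%% of coverage",
                  round(100 * .env$max_type_fraction)),
        TRUE ~ NA_character_
      )
    )
  if (keep_all) report else report |> filter(.data$kept) |>
    select(-"kept", -"reason")
}

#' Assemble a per-sample tag abundance table
#'
#' Takes filtered tag support for one or more samples and builds the joint
#' table over the union of tags, with zero counts for tags absent from a
#' sample and per-sample relative abundances.
#'
#' @param per_sample Data frame with columns `sample`, `tag_sequence`,
#'   `total_reads` (e.g. [filter_tags()] output row-bound with a `sample`
#'   column).
#' @return A tibble in long form: `sample`, `tag_sequence`, `count`,
#'   `rel_abundance`. Samples with zero total filtered reads get
#'   `rel_abundance = NA` with a warning.
#' @export
build_tag_table <- function(per_sample) {
  per_sample <- as_tibble(per_sample)
  assert_columns(per_sample, c("sample", "tag_sequence", "total_reads"),
                 "per_sample")
  if (nrow(per_sample) == 0) abort("`per_sample` must contain >= 1 sample")
  full <- tidyr::expand_grid(
    sample = unique(per_sample$sample),
    tag_sequence = sort(unique(per_sample$tag_sequence))
  ) |>
    left_join(
      per_sample |> select("sample", "tag_sequence", count = "total_reads"),
      by = c("sample", "tag_sequence")
    ) |>
    mutate(count = tidyr::replace_na(.data$count, 0L)) |>
    group_by(.data$sample) |>
    mutate(rel_abundance = if (sum(.data$count) > 0) {
      .data$count / sum(.data$count)
    } else NA_real_) |>
    ungroup()
  if (anyNA(full$rel_abundance)) {
    warn("sample(s) with zero filtered reads: relative abundance undefined")
  }
  full
}

#' Restrict a tag table to the top-n most dominant tags
#'
#' Tags are ranked by their mean relative abundance across samples
#' (descending), with ties broken lexicographically by tag sequence; the
#' first `n` are retained. The default `n = 50` mirrors the usual focus on
#' the top 50 most dominant community members.
#'
#' @param tag_table Output of [build_tag_table()].
#' @param n Number of tags to keep (default 50).
#' @return The tag table restricted to the selected tags.
#' @export
top_n_tags <- function(tag_table, n = 50) {
  assert_columns(tag_table, c("sample", "tag_sequence", "rel_abundance"),
                 "tag_table")
  if (n < 1) abort("`n` must be >= 1")
  ranking <- tag_table |>
    group_by(.data$tag_sequence) |>
    summarise(mean_abund = mean(.data$rel_abundance, na.rm = TRUE),
              .groups = "drop") |>
    arrange(desc(.data$mean_abund), .data$tag_sequence)
  if (n > nrow(ranking)) {
    inform(sprintf("requested top %d tags but only %d available; keeping all",
                   n, nrow(ranking)))
    n <- nrow(ranking)
  }
  keep <- ranking$tag_sequence[seq_len(n)]
  tag_table |> filter(.data$tag_sequence %in% keep)
}

#' Profile one or more read sets into a filtered tag table
#'
#' Convenience wrapper chaining [extract_v6_tags()], [filter_tags()],
#' [build_tag_table()] and [top_n_tags()] over named samples.
#'
#' @param read_sets Named list of read tibbles (one per sample).
#' @param primer,tag_length,scan_revcomp Passed to [extract_v6_tags()].
#' @param min_reads,max_type_fraction Passed to [filter_tags()].
#' @param top_n Number of dominant tags to retain; `Inf` keeps all.
#' @return A tag table tibble as from [build_tag_table()].
#' @export
profile_tags <- function(read_sets, primer = v6_primer(), tag_length = 33,
                         scan_revcomp = FALSE, min_reads = 2,
                         max_type_fraction = 0.5, top_n = Inf) {
  stopifnot(is.list(read_sets), length(read_sets) > 0,
            !is.null(names(read_sets)))
  per_sample <- purrr::imap(read_sets, function(reads, nm) {
    extract_v6_tags(reads, primer, tag_length, scan_revcomp) |>
      filter_tags(min_reads, max_type_fraction) |>
      mutate(sample = nm)
  }) |> bind_rows()
  tab <- build_tag_table(per_sample)
  if (is.finite(top_n)) tab <- top_n_tags(tab, top_n)
  tab
}
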